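test_that("per-sample standardization centers and scales each column", {
  mat <- expr_matrix(matrix(c(6, 8, 10), 3, 1,
                            dimnames = list(c("a", "b", "c"), "s1")))
  z <- zscore_per_sample(mat)
  expect_equal(unname(unclass(z)[, 1]), c(-1, 0, 1))
  # mean 0 / sd 1 within 1e-9 on random matrices
  for (seed in 1:5) {
    zz <- unclass(zscore_per_sample(random_log2_matrix(50, 8, seed = seed)))
    expect_lt(max(abs(colMeans(zz))), 1e-9)
    expect_lt(max(abs(apply(zz, 2, sd) - 1)), 1e-9)
  }
})

test_that("a zero-variance sample is an error naming the sample", {
  v <- cbind(s1 = c(6, 8, 10), s2 = c(5, 5, 5))
  rownames(v) <- c("a", "b", "c")
  expect_error(zscore_per_sample(expr_matrix(v)), "s2")
})

test_that("clipping winsorizes to the bound and is a no-op inside it", {
  # one low outlier among ten: raw z of the outlier is -(n-1)/sqrt(n) ~ -2.85,
  # inside [-3, 3], so clipping must change nothing
  v <- matrix(c(0, rep(10, 9)), 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  raw <- zscore_per_sample(expr_matrix(v), clip = FALSE)
  clipped <- zscore_per_sample(expr_matrix(v), clip = TRUE)
  expect_gt(min(raw), -3)
  expect_equal(unclass(clipped)[, 1], unclass(raw)[, 1])
  # one outlier among twenty exceeds the bound and lands exactly at -3
  v2 <- matrix(c(0, rep(10, 19)), 20, 1, dimnames = list(paste0("g", 1:20), "s1"))
  raw2 <- zscore_per_sample(expr_matrix(v2), clip = FALSE)
  clip2 <- zscore_per_sample(expr_matrix(v2), clip = TRUE)
  expect_lt(min(raw2), -3)
  expect_identical(min(unclass(clip2)), -3)
  expect_true(all(unclass(clip2) >= -3 & unclass(clip2) <= 3))
})

test_that("unclipped Z-scores are invariant to per-sample location and scale", {
  mat <- random_log2_matrix(30, 5, seed = 11)
  z0 <- unclass(zscore_per_sample(mat))
  shifted <- unclass(mat)
  shifted[, 2] <- shifted[, 2] + 7.3
  shifted[, 4] <- shifted[, 4] * 2.6
  z1 <- unclass(zscore_per_sample(expr_matrix(shifted)))
  expect_equal(z1, z0, tolerance = 1e-12)
})

test_that("Z-ratio scales gene differences by the across-gene sd of differences", {
  # diffs 0.2, -0.1, 0.5 -> sd 0.3 -> ratios 2/3, -1/3, 5/3
  ds <- matrix(c(0.2, -0.1, 0.5), 3, 1, dimnames = list(c("a", "b", "c"), "d1"))
  ctrl <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  out <- zratio(ds, ctrl)
  expect_equal(out$z_ratio, c(2 / 3, -1 / 3, 5 / 3), tolerance = 1e-12)
  expect_equal(out$overexpressed, c(FALSE, FALSE, FALSE))
  # a gene with equal group means has Z-ratio 0 regardless of the others
  ds2 <- matrix(c(0, 1, -2), 3, 1, dimnames = list(c("a", "b", "c"), "d1"))
  ctrl2 <- matrix(c(0, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  expect_equal(zratio(ds2, ctrl2)$z_ratio[1], 0)
})

test_that("Z-ratio rejects degenerate input", {
  ds <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("d1", "d2")))
  ctrl <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  expect_error(zratio(ds, ctrl), "standard deviation of Z-score differences is zero")
  ctrl_mismatch <- matrix(0, 3, 2, dimnames = list(c("a", "b", "x"), c("c1", "c2")))
  expect_error(zratio(ds, ctrl_mismatch), "identical gene set")
  expect_error(zratio(ds[1, , drop = FALSE], ctrl[1, , drop = FALSE]),
               "at least two genes")
})

test_that("swapping group labels negates every Z-ratio exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    ds <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), paste0("d", 1:4)))
    ctrl <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), paste0("c", 1:4)))
    expect_identical(zratio(ds, ctrl)$z_ratio, -zratio(ctrl, ds)$z_ratio)
  }
})

test_that("vectorized statistics agree with the literal loop oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    v <- matrix(rnorm(20, 8, 1.5), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    z_pkg <- unclass(zscore_per_sample(expr_matrix(v)))
    z_ora <- oracle_zscore(v)
    expect_equal(z_pkg, z_ora, tolerance = 1e-9, ignore_attr = TRUE)
    ds <- z_pkg[, 1:2]; ctrl <- z_pkg[, 3:4]
    expect_equal(zratio(ds, ctrl)$z_ratio, oracle_zratio(ds, ctrl),
                 tolerance = 1e-9)
  }
})

test_that("Z-ratios times the sd of differences recover the differences", {
  set.seed(3)
  ds <- matrix(rnorm(60), 15, 4, dimnames = list(sprintf("g%02d", 1:15), paste0("d", 1:4)))
  ctrl <- matrix(rnorm(60), 15, 4, dimnames = list(sprintf("g%02d", 1:15), paste0("c", 1:4)))
  out <- zratio(ds, ctrl)
  diffs <- rowMeans(ds) - rowMeans(ctrl)
  s <- sd(diffs)
  expect_equal(out$z_ratio * s, unname(diffs), tolerance = 1e-12)
})

test_that("two-tailed p-values follow the standard normal", {
  expect_equal(p_from_z(0), 1)
  expect_equal(p_from_z(1.96), 0.05, tolerance = 0.0005)
  skip_if_not_installed("pracma")
  # independent CDF route: p = erfc(|z| / sqrt(2))
  for (z in c(0.5, 1, 1.96, 2.5, 3)) {
    expect_equal(p_from_z(z), pracma::erfc(z / sqrt(2)), tolerance = 1e-9)
  }
  expect_error(p_from_z(Inf), "finite")
  expect_error(p_from_z(NA_real_), "finite")
})

test_that("the overexpression flag is strict at the cutoff", {
  # engineer diffs whose sd makes one ratio exactly the cutoff
  ds <- matrix(c(1.96, 0, -1.96), 3, 1, dimnames = list(c("a", "b", "c"), "d1"))
  ctrl <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "c1"))
  # sd of diffs = 1.96 -> ratios 1, 0, -1; with cutoff 1 the first gene sits
  # exactly at the threshold and must NOT be flagged ('over', not 'at')
  at_tie <- zratio(ds, ctrl, cutoff = 1)
  expect_equal(at_tie$z_ratio[1], 1, tolerance = 1e-12)
  expect_false(any(at_tie$overexpressed))
  below <- zratio(ds, ctrl, cutoff = 1 - 1e-9)
  expect_equal(below$overexpressed, c(TRUE, FALSE, FALSE))
})
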