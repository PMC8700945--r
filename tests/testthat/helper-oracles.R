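# Literal, loop-based re-implementations of the core statistics, kept
# deliberately independent of the package's vectorized code paths. These
# are the oracles the equivalence tests compare against.

oracle_zscore <- function(mat) {
  z <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    z[, j] <- (x - m) / s
  }
  z
}

oracle_zratio <- function(ds_z, ctrl_z) {
  n_genes <- nrow(ds_z)
  diffs <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    diffs[g] <- sum(ds_z[g, ]) / ncol(ds_z) - sum(ctrl_z[g, ]) / ncol(ctrl_z)
  }
  md <- sum(diffs) / n_genes
  s <- sqrt(sum((diffs - md)^2) / (n_genes - 1))
  diffs / s
}

oracle_m <- function(ds, ctrl) {
  out <- numeric(nrow(ds))
  for (g in seq_len(nrow(ds))) {
    out[g] <- sum(ds[g, ]) / ncol(ds) - sum(ctrl[g, ]) / ncol(ctrl)
  }
  out
}

# 2^m via exp/log, independent of the `^` route used in r_ratio()
oracle_r <- function(m) exp(m * log(2))
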