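test_that("fixture series-matrix files round-trip through the parser", {
  outdir <- withr::local_tempdir()
  paths <- make_fixture_files(outdir)
  parsed <- parse_series_matrix(paths["series_matrix"])
  expect_equal(dim(parsed$matrix), c(6L, 4L))
  expect_equal(nrow(parsed$metadata), 4L)
  expect_setequal(parsed$metadata$group, c("DS", "control"))
  expect_true(all(parsed$metadata$region == "HIP"))
  meta_tsv <- read_sample_metadata(paths["metadata"])
  expect_identical(meta_tsv$sample_id, parsed$metadata$sample_id)
  expect_identical(meta_tsv$group, parsed$metadata$group)
  expect_equal(meta_tsv$age_value, parsed$metadata$age_value)
  expect_identical(meta_tsv$age_unit, parsed$metadata$age_unit)
  expect_identical(meta_tsv$sex, parsed$metadata$sex)
})

test_that("write -> parse round trip preserves values and metadata", {
  mat <- random_log2_matrix(20, 10, seed = 42)
  meta <- data.frame(
    sample_id = colnames(mat),
    group = rep(c("DS", "control"), 5),
    region = rep(c("HIP", "CBC"), each = 5),
    age_value = seq(2, 20, by = 2), age_unit = "Y",
    sex = rep(c("F", "M"), 5), stringsAsFactors = FALSE
  )
  path <- tempfile()
  write_series_matrix(mat, meta, path)
  back <- parse_series_matrix(path)
  expect_identical(colnames(back$matrix), colnames(mat))
  expect_identical(rownames(back$matrix), rownames(mat))
  expect_lt(max(abs(unclass(back$matrix) - unclass(mat))), 1e-5)
  expect_identical(back$metadata$group, meta$group)
  expect_identical(back$metadata$region, meta$region)
  expect_equal(back$metadata$age_value, meta$age_value)
  expect_identical(back$metadata$age_unit, meta$age_unit)
  expect_identical(back$metadata$sex, meta$sex)
})

test_that("parser rejects malformed series-matrix input", {
  # no table markers
  expect_error(parse_series_matrix(write_lines_tmp(c("!Series_title\tfoo"))),
               "markers")
  # markers but zero data rows
  empty <- c("!series_matrix_table_begin",
             paste(c('"ID_REF"', '"sa"'), collapse = "\t"),
             "!series_matrix_table_end")
  expect_error(parse_series_matrix(write_lines_tmp(empty)), "no data rows")
  # non-numeric cell names the probe and sample
  bad_cell <- series_matrix_text('"p1"\t7.1\toops')
  expect_error(parse_series_matrix(write_lines_tmp(bad_cell)),
               "non-numeric.*p1.*sb")
  # duplicate sample id
  dup <- series_matrix_text('"p1"\t7.1\t7.2', samples = c("sa", "sa"))
  expect_error(parse_series_matrix(write_lines_tmp(dup)), "duplicate sample")
})

test_that("writer refuses an empty matrix", {
  m <- expr_matrix(matrix(numeric(), 0, 2,
                          dimnames = list(NULL, c("a", "b"))),
                   probe_ids = character(), sample_ids = c("a", "b"))
  meta <- data.frame(sample_id = c("a", "b"), group = "DS", region = "HIP",
                     age_value = 1, age_unit = "Y", sex = "F")
  expect_error(write_series_matrix(m, meta, tempfile()), "empty")
})

test_that("probe collapse summarizes multi-probe genes and keeps singletons", {
  v <- matrix(c(4, 6, 2, 4, 10, 7,
                4, 6, 2, 4, 10, 7), 6, 2,
              dimnames = list(paste0("p", 1:6), c("sa", "sb")))
  mat <- expr_matrix(v)
  ann <- data.frame(probe_id = paste0("p", 1:6),
                    gene_symbol = c("X", "X", "Y", "Y", "Y", "Z"),
                    stringsAsFactors = FALSE)
  by_mean <- map_probes_to_genes(mat, ann, collapse = "mean")
  expect_equal(unclass(by_mean)["X", "sa"], 5)
  by_median <- map_probes_to_genes(mat, ann, collapse = "median")
  expect_equal(unclass(by_median)["Y", "sa"], 4)
  by_max <- map_probes_to_genes(mat, ann, collapse = "max")
  expect_equal(unclass(by_max)["Y", "sa"], 10)
  # single-probe gene is the identity under every collapse rule
  for (rule in c("mean", "median", "max")) {
    out <- map_probes_to_genes(mat, ann, collapse = rule)
    expect_equal(unclass(out)["Z", ], v["p6", ])
  }
})

test_that("probe collapse drops unmapped probes and validates the annotation", {
  mat <- random_log2_matrix(5, 3)
  ann <- data.frame(probe_id = c("g001", "g002"),
                    gene_symbol = c("A", "B"), stringsAsFactors = FALSE)
  expect_message(out <- map_probes_to_genes(mat, ann), "3 probe")
  expect_equal(nrow(out), 2L)
  expect_error(map_probes_to_genes(mat, ann[0, ]), "empty")
  ambig <- data.frame(probe_id = c("g001", "g001"),
                      gene_symbol = c("A", "B"), stringsAsFactors = FALSE)
  expect_error(map_probes_to_genes(mat, ambig), "more than one gene")
})

test_that("HMGN annotation carries the five family members and matches the bundled fixture", {
  ann <- hmgn_annotation()
  expect_equal(nrow(ann), 5L)
  expect_false(anyDuplicated(ann$entrez_id) > 0)
  expect_equal(ann$entrez_id[ann$gene_symbol == "HMGN1"], 3150L)
  expect_equal(ann$locus[ann$gene_symbol == "HMGN1"], "21q22.2")
  expect_equal(ann$entrez_id[ann$gene_symbol == "HMGN5"], 79366L)
  expect_equal(ann$locus[ann$gene_symbol == "HMGN5"], "Xq21.1")
  bundled <- utils::read.delim(
    system.file("extdata", "hmgn_annotation.tsv", package = "zdosage"),
    stringsAsFactors = FALSE)
  expect_equal(bundled, ann)
})

test_that("metadata samples missing from the matrix raise on join", {
  fix <- two_group_matrix()
  meta <- rbind(fix$metadata,
                data.frame(sample_id = "ghost", group = "DS", region = "HIP",
                           age_value = 20, age_unit = "WG", sex = "F"))
  expect_error(split_by_stratum(fix$matrix, meta, stratum("whole_brain")),
               "absent from expression matrix")
})
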