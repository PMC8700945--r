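# Small in-code fixtures shared across test files.

random_log2_matrix <- function(n_genes, n_samples, seed = 1, mean = 8, sd = 1.5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expr_matrix(m, scale_tag = "log2")
}

# 4 samples (2 DS / 2 control) in one region, DS shifted by `shift` log2
# units on every gene
two_group_matrix <- function(n_genes = 10, shift = 0, region = "HIP", seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n_genes * 4, 8, 1), n_genes, 4)
  base[, 1:2] <- base[, 1:2] + shift
  ids <- paste0("s", 1:4)
  mat <- expr_matrix(base, sprintf("g%02d", seq_len(n_genes)), ids)
  meta <- data.frame(
    sample_id = ids,
    group = c("DS", "DS", "control", "control"),
    region = region,
    age_value = c(20, 18, 21, 19), age_unit = "WG",
    sex = c("F", "M", "F", "M"),
    stringsAsFactors = FALSE
  )
  list(matrix = mat, metadata = meta)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# minimal parseable series-matrix text with given data rows
series_matrix_text <- function(rows, samples = c("sa", "sb")) {
  c(paste(c("!Sample_geo_accession", sprintf('"%s"', samples)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c('"ID_REF"', sprintf('"%s"', samples)), collapse = "\t"),
    rows,
    "!series_matrix_table_end")
}
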