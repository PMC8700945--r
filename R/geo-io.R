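#' Default key patterns for series-matrix sample characteristics
#'
#' GEO sample characteristics lines are free text of the form
#' `"key: value"`; which key encodes the karyotype group, the brain region,
#' the age or the sex varies between series. The parser therefore matches
#' keys with configurable regular expressions. The defaults cover the
#' vocabulary used by brain trisomy-21 series (`disease status`,
#' `karyotype`, `region`, `age`, `Sex`) and classify a sample as `DS`
#' whenever the group value mentions Down Syndrome or trisomy.
#'
#' @return Named list of case-insensitive regular expressions: `group`,
#'   `region`, `age`, `sex` match the characteristic key; `ds_value`
#'   matches group values that denote the trisomic group.
#' @export
default_key_patterns <- function() {
  list(
    group = "karyotype|group|disease|genotype|condition",
    region = "region|brain.?area|tissue",
    age = "^age",
    sex = "^sex$|gender",
    ds_value = "\\bDS\\b|down|trisom"
  )
}

#' Read a GEO-style series-matrix file
#'
#' Parses the tab-separated expression table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers and
#' extracts per-sample metadata from the `!Sample_*` header lines above it.
#'
#' @param path path to a series-matrix text file.
#' @param key_patterns named list of regexes as in [default_key_patterns()].
#' @param scale_tag intensity scale of the stored values (`"log2"` default).
#' @return A list with elements `matrix` (an [expr_matrix()]) and
#'   `metadata` (a data frame with columns `sample_id`, `group`, `region`,
#'   `age_value`, `age_unit`, `sex`; fields the header does not carry are
#'   the explicit `"unknown"` / `NA` sentinels).
#' @seealso [write_series_matrix()] for the inverse operation.
#' @export
parse_series_matrix <- function(path, key_patterns = default_key_patterns(),
                                scale_tag = "log2") {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg) {
    stop("series-matrix table markers not found in ", path, call. = FALSE)
  }
  if (end - beg < 3L) {
    stop("series-matrix table in ", path, " has no data rows", call. = FALSE)
  }
  header <- strip_quotes(strsplit(lines[beg + 1L], "\t", fixed = TRUE)[[1L]])
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in table header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- lines[(beg + 2L):(end - 1L)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  probe_ids <- vapply(rows, function(r) strip_quotes(r[1L]), character(1))
  values <- matrix(NA_real_, length(rows), length(sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != length(sample_ids)) {
      stop(sprintf("row %s has %d values but %d samples", probe_ids[i],
                   length(cells), length(sample_ids)), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(strip_quotes(cells)))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' at probe %s, sample %s",
                   cells[j], probe_ids[i], sample_ids[j]), call. = FALSE)
    }
    values[i, ] <- num
  }
  mat <- expr_matrix(values, probe_ids, sample_ids, scale_tag = scale_tag)
  meta <- parse_sample_header(lines[seq_len(beg - 1L)], sample_ids, key_patterns)
  list(matrix = mat, metadata = meta)
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

parse_sample_header <- function(header_lines, sample_ids, key_patterns) {
  meta <- data.frame(
    sample_id = sample_ids,
    group = "unknown", region = "unknown",
    age_value = NA_real_, age_unit = NA_character_,
    sex = "unknown",
    stringsAsFactors = FALSE
  )
  char_lines <- grep("^!Sample_characteristics", header_lines, value = TRUE)
  for (line in char_lines) {
    cells <- strip_quotes(strsplit(line, "\t", fixed = TRUE)[[1L]])[-1L]
    if (length(cells) != length(sample_ids)) next
    kv <- regmatches(cells, regexec("^\\s*([^:]+):\\s*(.*)$", cells))
    keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else "", character(1))
    vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else "", character(1))
    key <- keys[keys != ""][1L]
    if (is.na(key)) next
    if (grepl(key_patterns$group, key, ignore.case = TRUE)) {
      meta$group <- ifelse(grepl(key_patterns$ds_value, vals, ignore.case = TRUE),
                           "DS", "control")
    } else if (grepl(key_patterns$region, key, ignore.case = TRUE)) {
      up <- toupper(trimws(vals))
      meta$region <- ifelse(up %in% region_codes(), up, "unknown")
    } else if (grepl(key_patterns$age, key, ignore.case = TRUE)) {
      age <- parse_age(vals)
      meta$age_value <- age$value
      meta$age_unit <- age$unit
    } else if (grepl(key_patterns$sex, key, ignore.case = TRUE)) {
      sx <- toupper(substr(trimws(vals), 1L, 1L))
      meta$sex <- ifelse(sx %in% c("F", "M"), sx, "unknown")
    }
  }
  meta
}

# "18 WG", "35 Y", "6 M", "21 PCW" -> value + canonical unit
parse_age <- function(x) {
  m <- regmatches(x, regexec("([0-9]*\\.?[0-9]+)\\s*(PCW|WG|GW|MO|M|YR|Y)",
                             toupper(x)))
  value <- vapply(m, function(g) {
    if (length(g) == 3L) as.numeric(g[2L]) else NA_real_
  }, numeric(1))
  unit <- vapply(m, function(g) {
    if (length(g) < 3L) return(NA_character_)
    switch(g[3L], PCW = , GW = , WG = "WG", MO = , M = "M", YR = , Y = "Y",
           NA_character_)
  }, character(1))
  list(value = value, unit = unit)
}

#' Write a GEO-style series-matrix file
#'
#' Emits the `!Sample_*` metadata header followed by the expression table,
#' in the format [parse_series_matrix()] reads back. Values are written
#' with six decimal places, so a write/parse round trip preserves
#' intensities to better than 1e-5.
#'
#' @param mat an [expr_matrix()].
#' @param metadata sample metadata data frame (columns `sample_id`,
#'   `group`, `region`, `age_value`, `age_unit`, `sex`); must cover exactly
#'   the matrix samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(mat, metadata, path) {
  mat <- as_expr_matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("refusing to write an empty expression matrix", call. = FALSE)
  }
  metadata <- metadata[match(colnames(mat), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id)) {
    stop("metadata must cover every matrix sample", call. = FALSE)
  }
  q <- function(x) paste0('"', x, '"')
  age_txt <- ifelse(is.na(metadata$age_value) | is.na(metadata$age_unit),
                    "unknown",
                    paste(format_num(metadata$age_value), metadata$age_unit))
  header <- c(
    paste(c("!Sample_geo_accession", q(metadata$sample_id)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", q(paste0("group: ", metadata$group))),
          collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", q(paste0("region: ", metadata$region))),
          collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", q(paste0("age: ", age_txt))),
          collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", q(paste0("Sex: ", metadata$sex))),
          collapse = "\t")
  )
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(q(rownames(mat)[i]), sprintf("%.6f", unclass(mat)[i, ])),
          collapse = "\t")
  }, character(1))
  out <- c(header,
           "!series_matrix_table_begin",
           paste(c(q("ID_REF"), q(colnames(mat))), collapse = "\t"),
           body,
           "!series_matrix_table_end")
  writeLines(out, path)
  invisible(path)
}

format_num <- function(x) {
  ifelse(x == round(x), sprintf("%d", as.integer(round(x))), sprintf("%g", x))
}

#' Read / write sample metadata TSV
#'
#' Plain-text companion format to the series matrix: one row per sample
#' with columns `sample_id`, `group`, `region`, `age_value`, `age_unit`,
#' `sex`. Regions must be one of the 11 codes or `"unknown"`; ages must be
#' positive when a unit is given.
#'
#' @param path TSV path.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "region", "age_value", "age_unit", "sex")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) {
    stop("metadata file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_metadata(meta)
  meta[needed]
}

#' @rdname read_sample_metadata
#' @param metadata metadata data frame to write.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad_region <- setdiff(unique(meta$region), c(region_codes(), "unknown"))
  if (length(bad_region)) {
    stop("unknown region code(s): ", paste(bad_region, collapse = ", "),
         " (use one of ", paste(region_codes(), collapse = "/"),
         " or 'unknown')", call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), c("DS", "control", "unknown"))
  if (length(bad_group)) {
    stop("group must be 'DS' or 'control', got: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  has_unit <- !is.na(meta$age_unit)
  if (any(has_unit & (is.na(meta$age_value) | meta$age_value <= 0))) {
    stop("age_value must be > 0 when age_unit is given", call. = FALSE)
  }
  if (any(!meta$age_unit[has_unit] %in% c("WG", "M", "Y"))) {
    stop("age_unit must be one of WG, M, Y", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a probe-to-gene annotation TSV
#'
#' @param path TSV with columns `probe_id`, `gene_symbol` and optionally
#'   `entrez_id`, `locus`.
#' @return Data frame of the annotation.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(ann))) {
    stop("annotation needs columns probe_id and gene_symbol", call. = FALSE)
  }
  ann
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes without a gene mapping are dropped (with a message giving the
#' count); the retained probes must each map to a single gene. Multiple
#' probes for the same gene are summarized per sample by the chosen
#' statistic.
#'
#' @param mat probe-level [expr_matrix()].
#' @param annotation data frame with columns `probe_id`, `gene_symbol`.
#' @param collapse summary over probes of a gene: `"mean"` (default),
#'   `"median"` or `"max"`.
#' @return Gene-level [expr_matrix()] on the same scale.
#' @export
map_probes_to_genes <- function(mat, annotation, collapse = c("mean", "median", "max")) {
  collapse <- match.arg(collapse)
  mat <- as_expr_matrix(mat)
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("empty probe annotation", call. = FALSE)
  }
  ann <- annotation[annotation$probe_id %in% rownames(mat), , drop = FALSE]
  multi <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(multi)) {
    multi_gene <- vapply(multi, function(p) {
      length(unique(ann$gene_symbol[ann$probe_id == p])) > 1L
    }, logical(1))
    if (any(multi_gene)) {
      stop("probe(s) mapping to more than one gene: ",
           paste(multi[multi_gene], collapse = ", "), call. = FALSE)
    }
    ann <- ann[!duplicated(ann$probe_id), , drop = FALSE]
  }
  keep <- rownames(mat) %in% ann$probe_id
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(n_drop, " probe(s) without gene mapping dropped")
  }
  if (!any(keep)) stop("no probe maps to a gene", call. = FALSE)
  v <- unclass(mat)[keep, , drop = FALSE]
  gene <- ann$gene_symbol[match(rownames(v), ann$probe_id)]
  fun <- switch(collapse, mean = mean, median = stats::median, max = max)
  genes <- unique(gene)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (g in genes) {
    rows <- v[gene == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2L, fun)
  }
  expr_matrix(out, scale_tag = expr_scale(mat))
}

#' Annotation of the five human HMGN genes
#'
#' The high-mobility-group nucleosome-binding family: gene symbol, NCBI
#' Entrez identifier and cytogenetic locus. HMGN1 sits on 21q22.2 and is
#' therefore triplicated in trisomy 21; the other four family members lie
#' outside chromosome 21.
#'
#' @return Data frame with columns `gene_symbol`, `entrez_id`, `locus`.
#' @export
hmgn_annotation <- function() {
  data.frame(
    gene_symbol = c("HMGN1", "HMGN2", "HMGN3", "HMGN4", "HMGN5"),
    entrez_id = c(3150L, 3151L, 9324L, 10473L, 79366L),
    locus = c("21q22.2", "1p36.11", "6q14.1", "6p22.2", "Xq21.1"),
    stringsAsFactors = FALSE
  )
}
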