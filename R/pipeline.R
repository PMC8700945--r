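#' Pipeline run configuration
#'
#' Bundles every tunable of an end-to-end run with documented defaults.
#' The `"replication"` profile is the setting used to mirror published
#' Z-ratio tables: Z-scores clipped to [-3, 3] before the Z-ratio, gene
#' universe = all filtered genes.
#'
#' @param profile `"default"` or `"replication"` (alias `"paper"`).
#' @param clip,clip_bound winsorize Z-scores to `[-clip_bound, clip_bound]`
#'   before the Z-ratio (default off; the replication profile turns it on
#'   at 3.0).
#' @param sd_type standard deviation convention everywhere (`"sample"` =
#'   n-1, or `"population"`).
#' @param cutoff Z-ratio overexpression threshold, default 1.96.
#' @param universe `"all_filtered"` (the Z-ratio denominator runs over all
#'   genes surviving the presence filter) or `"listed_genes"` (restrict to
#'   `genes` before the Z-ratio; unstable for short lists).
#' @param genes gene identifiers to report on (and, under
#'   `universe = "listed_genes"`, to compute over); `NULL` = all.
#' @param filter,filter_threshold,filter_min_fraction presence-filter
#'   switch and parameters (signal > threshold in >= min_fraction of
#'   samples, applied to linear intensities).
#' @param dosage_bins dosage bin edges ([default_dosage_bins()]).
#' @param brain_pooling whole-brain column definition: `"all_samples"`
#'   (default; one Z-ratio over every sample) or `"region_mean"` (mean of
#'   the per-region Z-ratios).
#' @param seed integer seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("default", "replication", "paper"),
                       clip = NULL,
                       clip_bound = 3, sd_type = "sample", cutoff = 1.96,
                       universe = c("all_filtered", "listed_genes"),
                       genes = NULL, filter = TRUE, filter_threshold = 100,
                       filter_min_fraction = 0.5,
                       dosage_bins = default_dosage_bins(),
                       brain_pooling = c("all_samples", "region_mean"),
                       seed = 1L) {
  profile <- match.arg(profile)
  if (profile == "paper") profile <- "replication"
  if (is.null(clip)) clip <- (profile == "replication")
  structure(list(
    profile = profile, clip = clip, clip_bound = clip_bound,
    sd_type = sd_type, cutoff = cutoff, universe = match.arg(universe),
    genes = genes, filter = filter, filter_threshold = filter_threshold,
    filter_min_fraction = filter_min_fraction, dosage_bins = dosage_bins,
    brain_pooling = match.arg(brain_pooling), seed = as.integer(seed)
  ), class = "run_config")
}

prepare_gene_matrix <- function(mat, config, annotation = NULL,
                                collapse = "mean") {
  mat <- as_expr_matrix(mat)
  if (isTRUE(config$filter)) {
    lin <- filter_present(to_linear(mat), threshold = config$filter_threshold,
                          min_fraction = config$filter_min_fraction)
    message(attr(lin, "n_filtered"), " probe(s) removed by presence filter")
    if (nrow(lin) == 0L) stop("no probe survives the presence filter", call. = FALSE)
    mat <- to_log2(lin)
  }
  if (!is.null(annotation)) {
    mat <- map_probes_to_genes(mat, annotation, collapse = collapse)
  }
  if (config$universe == "listed_genes") {
    if (is.null(config$genes)) {
      stop("universe = 'listed_genes' needs config$genes", call. = FALSE)
    }
    keep <- intersect(rownames(mat), config$genes)
    if (length(keep) < 2L) {
      stop("fewer than two requested genes survive filtering", call. = FALSE)
    }
    mat <- expr_matrix(unclass(mat)[keep, , drop = FALSE],
                       scale_tag = expr_scale(mat))
  }
  mat
}

report_genes <- function(mat, config) {
  if (is.null(config$genes)) return(rownames(mat))
  found <- intersect(config$genes, rownames(mat))
  if (length(found) == 0L) {
    stop("none of the requested genes survives filtering", call. = FALSE)
  }
  found
}

#' Z-ratio report over a set of strata
#'
#' Runs the full differential-expression pipeline: presence filter
#' (linear scale), optional probe-to-gene collapse, per-sample Z-score
#' standardization (clipped under the replication profile), then one Z-ratio
#' per gene per stratum. Strata in which either karyotype group is empty
#' are skipped with a warning and listed in the result.
#'
#' @param mat probe- or gene-level log2 [expr_matrix()].
#' @param metadata sample metadata covering the matrix samples.
#' @param strata list of [stratum()] objects; default
#'   [default_strata()] of the metadata.
#' @param config a [run_config()].
#' @param annotation optional probe annotation for gene collapse.
#' @return List: `wide` (gene x stratum data frame of Z-ratios), `flags`
#'   (logical gene x stratum matrix of `z_ratio > cutoff`, computed at
#'   full precision), `long` (per gene/stratum records with p-values),
#'   `skipped` (names of skipped strata).
#' @export
zratio_report <- function(mat, metadata, strata = NULL,
                          config = run_config(), annotation = NULL) {
  mat <- prepare_gene_matrix(mat, config, annotation)
  check_samples(mat, metadata)
  metadata <- metadata[metadata$sample_id %in% colnames(mat), , drop = FALSE]
  if (!"age_rank" %in% names(metadata)) {
    metadata <- suppressWarnings(assign_age_rank(metadata))
  }
  if (is.null(strata)) strata <- default_strata(metadata)
  z <- zscore_per_sample(mat, clip = config$clip, clip_bound = config$clip_bound,
                         sd_type = config$sd_type)
  zmat <- expr_matrix(unclass(z), scale_tag = "log2")  # container reuse for subsetting
  long <- list()
  skipped <- character()
  for (strat in strata) {
    parts <- withCallingHandlers(
      split_by_stratum(zmat, metadata, strat),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(parts)) {
      skipped <- c(skipped, strat$name)
      message("stratum '", strat$name, "' skipped (empty group)")
      next
    }
    long[[strat$name]] <- zratio(unclass(parts$ds), unclass(parts$control),
                                 stratum_name = strat$name,
                                 cutoff = config$cutoff,
                                 sd_type = config$sd_type)
  }
  if (length(long) == 0L) stop("no stratum with both groups present", call. = FALSE)
  long <- do.call(rbind, c(long, list(make.row.names = FALSE)))
  genes <- report_genes(mat, config)
  long <- long[long$gene_id %in% genes, , drop = FALSE]
  wide <- long_to_wide(long, genes, value = "z_ratio")
  if (config$brain_pooling == "region_mean" && "Brain" %in% names(wide)) {
    region_cols <- intersect(names(wide), region_codes())
    if (length(region_cols)) {
      wide[["Brain"]] <- rowMeans(as.matrix(wide[region_cols]), na.rm = TRUE)
    }
  }
  flags <- as.matrix(wide[-1]) > config$cutoff
  rownames(flags) <- wide$gene_id
  list(wide = wide, flags = flags, long = long, skipped = skipped)
}

#' Dosage report over a set of strata
#'
#' As [zratio_report()], but computes M, R = 2^M and the dosage category
#' per gene per stratum on the unstandardized log2 intensities.
#'
#' @inheritParams zratio_report
#' @return List: `wide` (gene x stratum data frame of R ratios), `long`
#'   (per gene/stratum M, R, category records), `skipped`.
#' @export
dosage_report <- function(mat, metadata, strata = NULL,
                          config = run_config(), annotation = NULL) {
  mat <- prepare_gene_matrix(mat, config, annotation)
  check_samples(mat, metadata)
  metadata <- metadata[metadata$sample_id %in% colnames(mat), , drop = FALSE]
  if (!"age_rank" %in% names(metadata)) {
    metadata <- suppressWarnings(assign_age_rank(metadata))
  }
  if (is.null(strata)) strata <- default_strata(metadata)
  long <- list()
  skipped <- character()
  for (strat in strata) {
    parts <- withCallingHandlers(
      split_by_stratum(mat, metadata, strat),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(parts)) {
      skipped <- c(skipped, strat$name)
      message("stratum '", strat$name, "' skipped (empty group)")
      next
    }
    long[[strat$name]] <- dosage_table(parts$ds, parts$control,
                                       stratum_name = strat$name,
                                       bins = config$dosage_bins)
  }
  if (length(long) == 0L) stop("no stratum with both groups present", call. = FALSE)
  long <- do.call(rbind, c(long, list(make.row.names = FALSE)))
  genes <- report_genes(mat, config)
  long <- long[long$gene_id %in% genes, , drop = FALSE]
  wide <- long_to_wide(long, genes, value = "r_ratio")
  list(wide = wide, long = long, skipped = skipped)
}

long_to_wide <- function(long, genes, value) {
  strata_names <- unique(long$stratum)
  wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (s in strata_names) {
    sub <- long[long$stratum == s, , drop = FALSE]
    wide[[s]] <- sub[[value]][match(genes, sub$gene_id)]
  }
  wide
}

#' Write a report to TSV files
#'
#' The wide table is written with values rounded to two decimals for
#' display, significant cells marked with a trailing `*`; the long table
#' keeps full precision. Flags are decided on full-precision values
#' before rounding.
#'
#' @param report result of [zratio_report()] or [dosage_report()].
#' @param prefix output path prefix; writes `<prefix>_wide.tsv` and
#'   `<prefix>_long.tsv`.
#' @param cutoff threshold used for the display marks (Z-ratio reports
#'   only; ignored when the report has no `flags`).
#' @return Character vector of the two paths, invisibly.
#' @export
write_report_tsv <- function(report, prefix, cutoff = 1.96) {
  wide <- report$wide
  disp <- wide
  for (col in names(disp)[-1]) {
    val <- wide[[col]]
    mark <- if (!is.null(report$flags)) {
      ifelse(!is.na(val) & val > cutoff, "*", "")
    } else ""
    disp[[col]] <- ifelse(is.na(val), "NA", paste0(sprintf("%.2f", val), mark))
  }
  wide_path <- paste0(prefix, "_wide.tsv")
  long_path <- paste0(prefix, "_long.tsv")
  utils::write.table(disp, wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- report$long
  for (col in names(long)) {
    if (is.numeric(long[[col]])) long[[col]] <- sprintf("%.10g", long[[col]])
  }
  utils::write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(wide = wide_path, long = long_path))
}
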