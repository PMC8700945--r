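#' Presence filter on linear signal intensities
#'
#' Keeps a probe when its signal exceeds `threshold` in at least
#' `min_fraction` of the samples; with the defaults (threshold 100,
#' fraction 0.5) this is the classic "PLIER signal > 100 in at least half
#' the samples" detection filter. The comparison is strict (`> threshold`)
#' and "at least half" is a plain `>=`, so on an even number of samples
#' exactly n/2 qualifying samples is enough. The filter is idempotent.
#'
#' @param mat an [expr_matrix()] on the linear scale (use [to_linear()]
#'   first when holding log2 values).
#' @param threshold signal intensity cut-off, default 100.
#' @param min_fraction minimum fraction of samples above threshold,
#'   default 0.5.
#' @return The filtered [expr_matrix()] (possibly with zero rows), with an
#'   attribute `n_filtered` recording how many probes were removed.
#' @export
filter_present <- function(mat, threshold = 100, min_fraction = 0.5) {
  mat <- as_expr_matrix(mat)
  if (expr_scale(mat) != "linear") {
    stop("filter_present expects linear intensities; call to_linear() first",
         call. = FALSE)
  }
  if (ncol(mat) == 0L) stop("expression matrix has zero samples", call. = FALSE)
  n_above <- rowSums(unclass(mat) > threshold)
  keep <- n_above >= min_fraction * ncol(mat)
  out <- expr_matrix(unclass(mat)[keep, , drop = FALSE], scale_tag = "linear")
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Default age-rank bins
#'
#' The six developmental bins the stratified analysis reports on: one
#' prenatal bin in weeks of gestation, one infancy bin in months, and four
#' bins in years (childhood, adolescence, adulthood, late adulthood). The
#' bins are disjoint by design; ages in the gaps (e.g. 25 Y) stay
#' unassigned.
#'
#' @return Data frame with columns `label`, `low`, `high`, `unit`.
#' @export
default_age_ranks <- function() {
  data.frame(
    label = c("16-22 WG", "0-12 M", "2-10 Y", "12-22 Y", "30-39 Y", "40-42 Y"),
    low = c(16, 0, 2, 12, 30, 40),
    high = c(22, 12, 10, 22, 39, 42),
    unit = c("WG", "M", "Y", "Y", "Y", "Y"),
    stringsAsFactors = FALSE
  )
}

# Postnatal bins are comparable after converting months <-> years (12 M =
# 1 Y); gestational weeks never convert. Returns the bin bounds in years
# for postnatal bins, NA for WG bins.
rank_years <- function(ranks) {
  f <- ifelse(ranks$unit == "M", 1 / 12, ifelse(ranks$unit == "Y", 1, NA))
  cbind(low = ranks$low * f, high = ranks$high * f)
}

validate_age_ranks <- function(ranks) {
  if (any(ranks$low > ranks$high)) {
    stop("age rank with low > high", call. = FALSE)
  }
  if (anyDuplicated(ranks$label)) stop("duplicate age-rank labels", call. = FALSE)
  yr <- rank_years(ranks)
  n <- nrow(ranks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      both_wg <- ranks$unit[i] == "WG" && ranks$unit[j] == "WG"
      both_post <- ranks$unit[i] != "WG" && ranks$unit[j] != "WG"
      if (both_wg) {
        lo <- c(ranks$low[i], ranks$low[j]); hi <- c(ranks$high[i], ranks$high[j])
      } else if (both_post) {
        lo <- yr[c(i, j), "low"]; hi <- yr[c(i, j), "high"]
      } else next
      if (max(lo) <= min(hi)) {
        stop(sprintf("overlapping age ranks: '%s' and '%s'",
                     ranks$label[i], ranks$label[j]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Assign samples to age-rank bins
#'
#' Each sample with an age is matched to the unique bin containing it:
#' gestational ages (WG) only match WG bins; postnatal ages match across
#' the month/year units via 12 M = 1 Y. Samples falling in a gap between
#' bins — or lacking an age — are left unassigned (`NA`), and the number
#' of gap samples is reported via a warning attribute.
#'
#' @param metadata sample metadata data frame (see
#'   [read_sample_metadata()]).
#' @param ranks age-rank definition data frame as in
#'   [default_age_ranks()]; overlapping definitions are a configuration
#'   error.
#' @return `metadata` with an added `age_rank` column (bin label or `NA`);
#'   attribute `n_unassigned` counts aged samples that matched no bin.
#' @export
assign_age_rank <- function(metadata, ranks = default_age_ranks()) {
  validate_age_ranks(ranks)
  yr <- rank_years(ranks)
  one <- function(value, unit) {
    if (is.na(value) || is.na(unit)) return(NA_character_)
    if (unit == "WG") {
      hit <- ranks$unit == "WG" & ranks$low <= value & value <= ranks$high
    } else {
      v_years <- if (unit == "M") value / 12 else value
      hit <- ranks$unit != "WG" & yr[, "low"] <= v_years & v_years <= yr[, "high"]
    }
    if (!any(hit)) NA_character_ else ranks$label[which(hit)[1L]]
  }
  metadata$age_rank <- mapply(one, metadata$age_value, metadata$age_unit,
                              USE.NAMES = FALSE)
  aged <- !is.na(metadata$age_value) & !is.na(metadata$age_unit)
  n_unassigned <- sum(aged & is.na(metadata$age_rank))
  if (n_unassigned > 0L) {
    warning(n_unassigned, " aged sample(s) fall outside every age-rank bin",
            call. = FALSE)
  }
  attr(metadata, "n_unassigned") <- n_unassigned
  metadata
}

#' Define an analysis stratum
#'
#' A stratum is either the whole brain (all samples), a single brain
#' region, or a single age rank; the karyotype comparison (DS vs control)
#' is carried out within each stratum independently.
#'
#' @param kind `"whole_brain"`, `"region"` or `"age_rank"`.
#' @param region region code, required when `kind = "region"`.
#' @param age_rank age-rank label, required when `kind = "age_rank"`.
#' @param name display name; defaults to the region code, rank label, or
#'   `"Brain"`.
#' @return A `stratum` object (named list).
#' @export
stratum <- function(kind = c("whole_brain", "region", "age_rank"),
                    region = NULL, age_rank = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "region") {
    if (is.null(region) || !region %in% region_codes()) {
      stop("region stratum needs one of: ",
           paste(region_codes(), collapse = ", "), call. = FALSE)
    }
    age_rank <- NULL
    if (is.null(name)) name <- region
  } else if (kind == "age_rank") {
    if (is.null(age_rank)) stop("age_rank stratum needs a rank label", call. = FALSE)
    region <- NULL
    if (is.null(name)) name <- age_rank
  } else {
    region <- NULL; age_rank <- NULL
    if (is.null(name)) name <- "Brain"
  }
  structure(list(name = name, kind = kind, region = region, age_rank = age_rank),
            class = "stratum")
}

#' Build the default stratum set for a dataset
#'
#' Whole brain first, then one stratum per region present in the
#' metadata (in canonical region order), then one per age rank present.
#'
#' @param metadata sample metadata; an `age_rank` column is added via
#'   [assign_age_rank()] when absent.
#' @param ranks age-rank definitions.
#' @param include which stratum kinds to include.
#' @return List of [stratum()] objects.
#' @export
default_strata <- function(metadata, ranks = default_age_ranks(),
                           include = c("whole_brain", "region", "age_rank")) {
  if (!"age_rank" %in% names(metadata)) {
    metadata <- suppressWarnings(assign_age_rank(metadata, ranks))
  }
  out <- list()
  if ("whole_brain" %in% include) out <- c(out, list(stratum("whole_brain")))
  if ("region" %in% include) {
    regions <- intersect(region_codes(), unique(metadata$region))
    out <- c(out, lapply(regions, function(r) stratum("region", region = r)))
  }
  if ("age_rank" %in% include) {
    labels <- ranks$label[ranks$label %in% metadata$age_rank]
    out <- c(out, lapply(labels, function(l) stratum("age_rank", age_rank = l)))
  }
  out
}

#' Partition a stratum's samples into DS and control submatrices
#'
#' @param mat an [expr_matrix()] (any scale).
#' @param metadata sample metadata covering the matrix columns; every
#'   metadata sample must be present in the matrix.
#' @param strat a [stratum()].
#' @return `list(ds = , control = )` of column submatrices, or `NULL`
#'   (with a warning) when either group is empty within the stratum — the
#'   caller is expected to skip such strata rather than crash.
#' @export
split_by_stratum <- function(mat, metadata, strat) {
  mat <- as_expr_matrix(mat)
  check_samples(mat, metadata)
  if (strat$kind == "age_rank" && !"age_rank" %in% names(metadata)) {
    metadata <- suppressWarnings(assign_age_rank(metadata))
  }
  in_stratum <- switch(strat$kind,
    whole_brain = rep(TRUE, nrow(metadata)),
    region = metadata$region == strat$region,
    age_rank = !is.na(metadata$age_rank) & metadata$age_rank == strat$age_rank
  )
  ds_ids <- metadata$sample_id[in_stratum & metadata$group == "DS"]
  ctrl_ids <- metadata$sample_id[in_stratum & metadata$group == "control"]
  if (length(ds_ids) == 0L || length(ctrl_ids) == 0L) {
    warning("stratum '", strat$name, "' skipped: empty ",
            if (length(ds_ids) == 0L) "DS" else "control", " group",
            call. = FALSE)
    return(NULL)
  }
  scale <- expr_scale(mat)
  list(
    ds = expr_matrix(unclass(mat)[, ds_ids, drop = FALSE], scale_tag = scale),
    control = expr_matrix(unclass(mat)[, ctrl_ids, drop = FALSE], scale_tag = scale)
  )
}
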