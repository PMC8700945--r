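#' Gene-dosage M value: difference of group means on the log2 scale
#'
#' `M = mean(log2 DS) - mean(log2 control)`, computed on unstandardized
#' log2 intensities (never on Z-scores: only on the log2 scale does
#' `2^M` read as a fold ratio). Inputs may be vectors (one gene) or
#' gene-by-sample matrices, in which case one M per gene is returned.
#'
#' @param ds,ctrl numeric vector or matrix of log2 intensities for the DS
#'   and control groups; both must be nonempty (and share genes when
#'   matrices).
#' @return Numeric vector of M values (named by gene for matrix input).
#' @export
m_value <- function(ds, ctrl) {
  if (length(ds) == 0L || length(ctrl) == 0L) {
    stop("empty group in M-value computation", call. = FALSE)
  }
  if (is.matrix(ds) || is.matrix(ctrl)) {
    ds <- as.matrix(ds); ctrl <- as.matrix(ctrl)
    if (nrow(ds) != nrow(ctrl) || !identical(rownames(ds), rownames(ctrl))) {
      stop("DS and control matrices must share an identical gene set",
           call. = FALSE)
    }
    rowMeans(ds) - rowMeans(ctrl)
  } else {
    mean(ds) - mean(ctrl)
  }
}

#' Dosage ratio R = 2^M
#'
#' Interprets the log2 group difference as a DS/control fold ratio. An
#' M of 0 gives R = 1 (balanced two copies), an M of log2(1.5) = 0.585
#' gives R = 1.5, the 3:2 dose expected of a cleanly triplicated gene.
#'
#' @param m finite numeric vector of M values.
#' @return `2^m`.
#' @export
r_ratio <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("M must be finite numeric", call. = FALSE)
  }
  2^m
}

#' Default dosage classification bins
#'
#' The copy-number style ranges on the R ratio: `[0.80, 1.30]` balanced
#' (two copies), `[1.4, 1.7]` triplicated (three copies), `> 1.8`
#' amplified (more than three copies). The ranges leave gaps —
#' `(1.30, 1.4)` and `(1.7, 1.8]` — and everything below 0.80; those are
#' reported as the explicit categories `gap_low`, `gap_high` and
#' `reduced` rather than snapped to a neighboring call.
#'
#' @return Named list of bin edges:
#'   `balanced = c(0.80, 1.30)`, `triplicated = c(1.4, 1.7)`,
#'   `amplified_above = 1.8`.
#' @export
default_dosage_bins <- function() {
  list(balanced = c(0.80, 1.30), triplicated = c(1.4, 1.7),
       amplified_above = 1.8)
}

#' Ordered dosage categories
#' @return Character vector of the six categories in increasing-dosage order.
#' @export
dosage_categories <- function() {
  c("reduced", "balanced", "gap_low", "triplicated", "gap_high", "amplified")
}

#' Classify an R dosage ratio into a copy-number style category
#'
#' Total on positive R: `reduced` below the balanced range, `balanced`,
#' `gap_low`, `triplicated`, `gap_high`, then `amplified` strictly above
#' the amplification edge. All stated range boundaries are closed;
#' "greater than 1.8" is exclusive at 1.8, so `(1.7, 1.8]` falls in
#' `gap_high`.
#'
#' @param r positive numeric vector of R ratios.
#' @param bins bin edges as from [default_dosage_bins()].
#' @return Ordered factor over [dosage_categories()].
#' @examples
#' classify_dosage(c(1.0, 1.5, 2.0, 0.5, 1.35))
#' @export
classify_dosage <- function(r, bins = default_dosage_bins()) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop("R ratios must be positive and finite", call. = FALSE)
  }
  stopifnot(bins$balanced[2] < bins$triplicated[1],
            bins$triplicated[2] <= bins$amplified_above)
  cat <- character(length(r))
  cat[r < bins$balanced[1]] <- "reduced"
  cat[r >= bins$balanced[1] & r <= bins$balanced[2]] <- "balanced"
  cat[r > bins$balanced[2] & r < bins$triplicated[1]] <- "gap_low"
  cat[r >= bins$triplicated[1] & r <= bins$triplicated[2]] <- "triplicated"
  cat[r > bins$triplicated[2] & r <= bins$amplified_above] <- "gap_high"
  cat[r > bins$amplified_above] <- "amplified"
  factor(cat, levels = dosage_categories(), ordered = TRUE)
}

#' Per-gene dosage table for one stratum
#'
#' Computes M (log2 group-mean difference), R = 2^M and the dosage
#' category for every gene, from unstandardized log2 submatrices.
#'
#' @param ds,ctrl gene-by-sample log2 matrices ([expr_matrix()] or plain)
#'   for the DS and control groups.
#' @param stratum_name label recorded in the output.
#' @param bins dosage bin edges.
#' @return Data frame with columns `gene_id`, `stratum`, `m_value`,
#'   `r_ratio`, `category`.
#' @export
dosage_table <- function(ds, ctrl, stratum_name = "Brain",
                         bins = default_dosage_bins()) {
  ds <- as.matrix(ds); ctrl <- as.matrix(ctrl)
  m <- m_value(ds, ctrl)
  r <- r_ratio(m)
  data.frame(
    gene_id = rownames(ds),
    stratum = stratum_name,
    m_value = unname(m),
    r_ratio = unname(r),
    category = classify_dosage(unname(r), bins = bins),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
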