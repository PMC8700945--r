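#' Per-sample Z-score standardization
#'
#' Standardizes each array (column) across its genes: for gene g in sample
#' s, `z = (x_gs - mean_s) / sd_s`, where the mean and standard deviation
#' run over all genes of that sample. This removes array-level location
#' and scale so that samples are comparable before the Z-ratio is formed.
#' Optionally the standardized values are winsorized (clipped) to
#' `[-clip_bound, +clip_bound]`; the conventional bound of 3.0 corresponds
#' to a two-tailed normal tail probability below 0.003.
#'
#' @param mat an [expr_matrix()] of log2 intensities.
#' @param clip logical; clip standardized values to the bound
#'   (default `FALSE`).
#' @param clip_bound positive clip bound, default 3.0.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A `zscore_matrix`: numeric matrix of standardized values with
#'   the input dimnames and a `clipped` attribute.
#' @export
zscore_per_sample <- function(mat, clip = FALSE, clip_bound = 3,
                              sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mat <- as_expr_matrix(mat)
  v <- unclass(mat)
  attr(v, "scale_tag") <- NULL
  attr(v, "n_filtered") <- NULL
  if (nrow(v) < 2L) stop("need at least two genes per sample", call. = FALSE)
  mu <- colMeans(v)
  cen <- sweep(v, 2L, mu, "-")
  ss <- colSums(cen^2)
  denom <- if (sd_type == "sample") nrow(v) - 1L else nrow(v)
  s <- sqrt(ss / denom)
  if (any(s == 0)) {
    stop("zero within-sample standard deviation in sample(s): ",
         paste(colnames(v)[s == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(cen, 2L, s, "/")
  if (clip) {
    if (!is.numeric(clip_bound) || clip_bound <= 0) {
      stop("clip_bound must be positive", call. = FALSE)
    }
    z <- pmin(pmax(z, -clip_bound), clip_bound)
  }
  structure(z, clipped = isTRUE(clip), class = c("zscore_matrix", "matrix", "array"))
}

#' Z-ratio differential expression between two groups
#'
#' For each gene, the difference of group-mean Z-scores (DS minus control)
#' is divided by the standard deviation of those differences taken across
#' all analyzed genes:
#' `z_ratio_g = (mean_z_ds_g - mean_z_ctrl_g) / sd({diff_1, ..., diff_n})`.
#' The denominator is a property of the analyzed gene set, so the gene
#' universe matters: a larger universe stabilizes it. Genes with a Z-ratio
#' strictly greater than `cutoff` (1.96, the two-tailed 5% normal critical
#' value) are flagged overexpressed; a value exactly at the cutoff is not
#' flagged. Two-tailed normal p-values accompany each ratio, and a
#' Benjamini-Hochberg adjusted column is provided for reference without
#' influencing the flag.
#'
#' @param ds,ctrl `zscore_matrix` (or plain matrix) of the DS and control
#'   samples; rows must be the same gene set in the same order.
#' @param stratum_name label recorded in the output.
#' @param cutoff overexpression threshold on the Z-ratio, default 1.96.
#' @param sd_type standard deviation convention for the denominator,
#'   `"sample"` (n-1, default) or `"population"`.
#' @return Data frame with one row per gene: `gene_id`, `stratum`,
#'   `mean_z_ds`, `mean_z_control`, `z_ratio`, `p_two_tailed`, `p_bh`,
#'   `overexpressed`.
#' @export
zratio <- function(ds, ctrl, stratum_name = "Brain", cutoff = 1.96,
                   sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ds <- as.matrix(ds); ctrl <- as.matrix(ctrl)
  if (nrow(ds) != nrow(ctrl) || !identical(rownames(ds), rownames(ctrl))) {
    stop("DS and control matrices must share an identical gene set",
         call. = FALSE)
  }
  if (nrow(ds) < 2L) {
    stop("Z-ratio needs at least two genes (the denominator is a standard ",
         "deviation across genes)", call. = FALSE)
  }
  mean_ds <- rowMeans(ds)
  mean_ctrl <- rowMeans(ctrl)
  diffs <- mean_ds - mean_ctrl
  n <- length(diffs)
  dev <- diffs - mean(diffs)
  denom_n <- if (sd_type == "sample") n - 1L else n
  s <- sqrt(sum(dev^2) / denom_n)
  if (s == 0) {
    stop("standard deviation of Z-score differences is zero in stratum '",
         stratum_name, "' (all gene differences identical)", call. = FALSE)
  }
  zr <- diffs / s
  p <- p_from_z(zr)
  data.frame(
    gene_id = rownames(ds),
    stratum = stratum_name,
    mean_z_ds = unname(mean_ds),
    mean_z_control = unname(mean_ctrl),
    z_ratio = unname(zr),
    p_two_tailed = unname(p),
    p_bh = unname(stats::p.adjust(p, method = "BH")),
    overexpressed = unname(zr > cutoff),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Two-tailed normal p-value for a Z statistic
#'
#' `p = 2 * (1 - Phi(|z|))` with `Phi` the standard normal CDF.
#'
#' @param z numeric vector of Z statistics; must be finite.
#' @return p-values in `[0, 1]`.
#' @examples
#' p_from_z(1.96)  # ~0.05
#' @export
p_from_z <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("z must be finite numeric", call. = FALSE)
  }
  2 * stats::pnorm(-abs(z))
}
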