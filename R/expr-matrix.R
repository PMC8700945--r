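#' Expression matrix container
#'
#' A thin wrapper around a numeric matrix of expression intensities with
#' probes (or genes) as rows and samples as columns. The only state beyond
#' the matrix itself is a `scale_tag` recording whether values are on the
#' log2 or the linear intensity scale, which downstream operations use to
#' refuse scale-mismatched input (the presence filter wants linear
#' intensities, standardization wants log2).
#'
#' @param values numeric matrix, rows = probes/genes, columns = samples.
#' @param probe_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @param scale_tag `"log2"` or `"linear"`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   dimnames set and a `scale_tag` attribute.
#' @examples
#' m <- expr_matrix(matrix(rnorm(6, 8), 3, 2,
#'                         dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))))
#' expr_scale(m)
#' @export
expr_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values), scale_tag = "log2") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  scale_tag <- match.arg(scale_tag, c("log2", "linear"))
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) {
    stop("length(probe_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe identifiers: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, scale_tag = scale_tag, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x object to coerce / query.
#' @export
as_expr_matrix <- function(x, scale_tag = "log2") {
  if (inherits(x, "expr_matrix")) return(x)
  expr_matrix(as.matrix(x), scale_tag = scale_tag)
}

#' @rdname expr_matrix
#' @export
expr_scale <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) "log2" else tag
}

#' Convert between log2 and linear intensity scales
#'
#' @param x an `expr_matrix`.
#' @return An `expr_matrix` on the requested scale; a no-op when already
#'   there.
#' @export
to_linear <- function(x) {
  x <- as_expr_matrix(x)
  if (expr_scale(x) == "linear") return(x)
  expr_matrix(2^unclass(x), scale_tag = "linear")
}

#' @rdname to_linear
#' @export
to_log2 <- function(x) {
  x <- as_expr_matrix(x)
  if (expr_scale(x) == "log2") return(x)
  v <- unclass(x)
  if (any(v <= 0)) stop("linear intensities must be positive to log2-transform", call. = FALSE)
  expr_matrix(log2(v), scale_tag = "log2")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  v <- unclass(x)
  print(v[seq_len(min(6L, nrow(v))), seq_len(min(6L, ncol(v))), drop = FALSE], ...)
  invisible(x)
}

#' The eleven brain-region codes of the stratified design
#'
#' HIP hippocampus, CBC cerebellar cortex, DFC dorsolateral prefrontal,
#' OFC orbital prefrontal, VFC ventrolateral prefrontal, MFC medial
#' prefrontal, S1C primary somatosensory, IPC inferior parietal, V1C
#' primary visual, STC superior temporal, ITC inferior temporal cortex.
#'
#' @return Character vector of the 11 region codes.
#' @export
region_codes <- function() {
  c("HIP", "CBC", "DFC", "OFC", "VFC", "MFC", "S1C", "IPC", "V1C", "STC", "ITC")
}

# Raise if any metadata sample is missing from the matrix: a silent drop of
# samples on join would bias every group mean downstream.
check_samples <- function(mat, metadata) {
  missing <- setdiff(metadata$sample_id, colnames(mat))
  if (length(missing)) {
    stop("metadata samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
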