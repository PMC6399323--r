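#' GeneNetwork 2Z+8 transform
#'
#' Rescales each transcript to a z-score with mean 8 and SD 2 (sample SD,
#' n - 1 denominator): `2 * (x - mean(x)) / sd(x) + 8`. On this scale a
#' one-unit difference corresponds to a twofold expression difference.
#' Constant transcripts cannot be standardized and are dropped with a
#' warning.
#'
#' @param mat Numeric matrix, transcripts x strains (or a single numeric
#'   vector for one transcript).
#' @return Transformed matrix (possibly with fewer rows) with attribute
#'   `"transform" = "2Z+8"`.
#' @export
transform_2z8 <- function(mat) {
  vec <- is.null(dim(mat))
  if (vec) mat <- matrix(mat, nrow = 1)
  if (ncol(mat) < 2) stop("need >= 2 values per transcript")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant transcript(s) dropped")
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- 2 * (mat - rowMeans(mat)) / sds + 8
  attr(out, "transform") <- "2Z+8"
  if (vec) drop(out) else out
}

#' Filter transcripts by expression level
#'
#' Keeps transcripts whose mean value on the 2Z+8 scale strictly exceeds the
#' threshold (default > 7, i.e. above half a SD below the grand mean).
#'
#' @param mat Transformed expression matrix (transcripts x strains).
#' @param threshold Expression threshold (strict).
#' @return Submatrix of retained transcripts (warned if empty).
#' @export
filter_expressed <- function(mat, threshold = 7) {
  keep <- rowMeans(mat) > threshold
  if (!any(keep)) warning("no transcripts pass the expression filter")
  mat[keep, , drop = FALSE]
}

#' Correlate transcripts against a strain trait
#'
#' Per-transcript correlation (Pearson by default, Spearman optional) between
#' expression and the strain trait over the shared strains, with a two-sided
#' p-value from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#' Results are ranked by `|r|` descending, ties broken by transcript id.
#'
#' @param mat Expression matrix with strain column names.
#' @param trait Named numeric vector of strain trait values.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame: `transcript`, `r`, `p_value`, `n`, `rank`.
#' @export
correlate_trait <- function(mat, trait, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(mat), names(trait))
  if (length(shared) < 3) stop("need >= 3 shared strains")
  y <- trait[shared]
  if (stats::sd(y) == 0) stop("constant trait")
  x <- mat[, shared, drop = FALSE]
  r <- as.numeric(stats::cor(t(x), y, method = method))
  n <- length(shared)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  out <- data.frame(transcript = rownames(mat), r = r, p_value = p, n = n)
  out <- out[order(-abs(out$r), out$transcript), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top trait correlates and their cross-trait intersection
#'
#' For each trait, takes the top `n_top` transcripts by `|r|` among those
#' with `|r| >= r_min` (fewer if not enough pass), and intersects the sets
#' across traits.
#'
#' @param results Named list of correlation results (see
#'   [correlate_trait()]), one per trait.
#' @param n_top Number of top correlates per trait.
#' @param r_min Minimum absolute correlation.
#' @return List: `sets` (named list of transcript id vectors), `intersection`
#'   (ids common to all traits), `counts` (per-trait sizes and intersection
#'   size).
#' @export
top_correlates <- function(results, n_top = 500, r_min = 0.60) {
  sets <- lapply(results, function(res) {
    pass <- res[abs(res$r) >= r_min, ]
    utils::head(pass$transcript, n_top)
  })
  inter <- Reduce(intersect, sets)
  list(sets = sets, intersection = inter,
       counts = c(vapply(sets, length, integer(1)),
                  intersection = length(inter)))
}

#' Relative quantification by the delta-delta-CT method
#'
#' `2^-((ct_target_sample - ct_ref_sample) -
#' (ct_target_calibrator - ct_ref_calibrator))`: fold change of the target
#' gene in the sample relative to the calibrator, normalized to a reference
#' gene.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   Threshold-cycle values (finite). Vectorized.
#' @return Relative quantity (1 = no change).
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  if (!all(is.finite(c(ct_target_sample, ct_ref_sample,
                       ct_target_calibrator, ct_ref_calibrator))))
    stop("all CT values must be finite")
  2^-((ct_target_sample - ct_ref_sample) -
        (ct_target_calibrator - ct_ref_calibrator))
}
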