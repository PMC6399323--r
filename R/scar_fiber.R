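#' Apparent scar wall thickness from a serial-section stack
#'
#' Sections are cut parallel to the epicardial surface; the apparent wall
#' thickness is the distance between the first and last section containing
#' tissue in the section center:
#' `(last_tissue_index - first_tissue_index) * section_thickness`.
#'
#' @param has_tissue Logical vector, one element per section ordered
#'   epicardium to endocardium.
#' @param section_thickness Section thickness in micrometres (default 7).
#' @return Wall thickness in micrometres.
#' @export
wall_thickness <- function(has_tissue, section_thickness = 7) {
  if (section_thickness <= 0) stop("section_thickness must be positive")
  idx <- which(has_tissue)
  if (!length(idx)) stop("no tissue-containing sections")
  if (length(idx) == 1)
    warning("single tissue section; wall thickness is degenerate (0)")
  (max(idx) - min(idx)) * section_thickness
}

#' Select LV midwall sections
#'
#' Returns the indices of sections whose relative depth within the tissue
#' span lies in `[0.40, 0.60]` (inclusive), i.e. the LV midwall used for
#' picrosirius-red collagen analysis.
#'
#' @inheritParams wall_thickness
#' @return Integer section indices.
#' @export
select_midwall <- function(has_tissue) {
  idx <- which(has_tissue)
  if (length(idx) < 5) stop("need >= 5 tissue-containing sections")
  depth <- (idx - min(idx)) / (max(idx) - min(idx))
  idx[depth >= 0.40 & depth <= 0.60]
}

rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

#' Isolate collagen by channel subtraction
#'
#' Both channels are min-max rescaled to `[0, 1]`; the blue-filter
#' brightfield image (collagen dark) is subtracted from the circularly
#' polarized image (collagen bright) and negative values are clamped to zero,
#' leaving a collagen intensity map.
#'
#' @param pair A `scar_image_pair` (or any list with matrices `polarized` and
#'   `brightfield_blue` of identical shape).
#' @return Numeric matrix in `[0, 1]`.
#' @export
subtract_images <- function(pair) {
  p <- pair$polarized; b <- pair$brightfield_blue
  if (!identical(dim(p), dim(b))) stop("image shapes do not match")
  pmax(rescale01(p) - rescale01(b), 0)
}

#' Collagen area fraction
#'
#' Fraction of pixels of the subtracted collagen image above a threshold.
#' By default the threshold is chosen by Otsu's method; for a constant image
#' (where Otsu is undefined) the absolute fallback threshold is used with a
#' warning.
#'
#' @param collagen Numeric matrix (subtracted collagen image, `[0, 1]`).
#' @param threshold_method `"otsu"` or a numeric absolute threshold.
#' @param fallback Absolute threshold used when Otsu is degenerate.
#' @return Fraction in `[0, 1]`.
#' @export
collagen_area_fraction <- function(collagen, threshold_method = "otsu",
                                   fallback = 0.1) {
  if (!length(collagen)) stop("empty image")
  if (is.numeric(threshold_method)) {
    thr <- threshold_method
  } else if (identical(threshold_method, "otsu")) {
    if (diff(range(collagen)) == 0) {
      warning("constant image; falling back to absolute threshold ", fallback)
      thr <- fallback
    } else {
      thr <- EBImage::otsu(collagen, range = range(collagen))
    }
  } else stop("unknown threshold_method")
  mean(collagen > thr)
}

#' Estimate fiber orientations by subwindow structure tensors
#'
#' Tiles the collagen image into non-overlapping square subwindows. Within
#' each subwindow, intensity gradients (central differences) are summed into
#' the 2x2 structure tensor; the fiber orientation is the axial direction of
#' the tensor's minor eigenvector (perpendicular to the dominant gradient),
#' reported in degrees in `[0, 180)` with 0 along the image x-axis
#' (circumferential direction). The subwindow weight is the tensor energy
#' (trace); subwindows with energy below `min_energy` are flagged invalid.
#'
#' @param collagen Numeric matrix.
#' @param subwindow_px Subwindow edge in pixels (>= 8).
#' @param min_energy Minimum gradient energy for a valid subwindow.
#' @param blur_sigma Gaussian regularization SD (pixels) applied before
#'   differentiation; unsmoothed central differences on thin discrete ridges
#'   bias orientations toward the diagonals.
#' @return data.frame of class `"fiber_field"`: `row`, `col` (subwindow
#'   centers in pixels), `theta` (degrees, `[0, 180)`), `weight`, `valid`.
#' @export
estimate_fiber_orientations <- function(collagen, subwindow_px = 16,
                                        min_energy = 0.1, blur_sigma = 1.5) {
  if (subwindow_px < 8) stop("subwindow_px must be >= 8")
  nr <- nrow(collagen); nc <- ncol(collagen)
  if (nr < subwindow_px || nc < subwindow_px)
    stop("image smaller than one subwindow")
  if (blur_sigma > 0 && diff(range(collagen)) > 0)
    collagen <- EBImage::gblur(collagen, sigma = blur_sigma)
  # central-difference gradients; borders zero
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (collagen[, 3:nc] - collagen[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (collagen[3:nr, ] - collagen[1:(nr - 2), ]) / 2
  nwr <- nr %/% subwindow_px; nwc <- nc %/% subwindow_px
  out <- vector("list", nwr * nwc)
  k <- 0L
  for (i in seq_len(nwr)) {
    ri <- ((i - 1) * subwindow_px + 1):(i * subwindow_px)
    for (j in seq_len(nwc)) {
      ci <- ((j - 1) * subwindow_px + 1):(j * subwindow_px)
      a <- gx[ri, ci]; b <- gy[ri, ci]
      jxx <- sum(a * a); jyy <- sum(b * b); jxy <- sum(a * b)
      energy <- jxx + jyy
      # major eigenvector of the tensor = dominant gradient direction;
      # fiber direction is perpendicular to it
      theta <- (0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90) %% 180
      k <- k + 1L
      out[[k]] <- c(mean(ri), mean(ci), theta, energy)
    }
  }
  m <- do.call(rbind, out)
  field <- data.frame(row = m[, 1], col = m[, 2], theta = m[, 3],
                      weight = m[, 4], valid = m[, 4] >= min_energy)
  class(field) <- c("fiber_field", "data.frame")
  field
}

#' Axial circular summary: mean angle and mean vector length
#'
#' Doubles the axial angles to the circular scale, computes the (optionally
#' weighted) mean resultant vector, and reports its length (MVL, 0 = random,
#' 1 = maximally aligned) and half its direction as the mean axial angle
#' `theta_m` in `[0, 180)` degrees.
#'
#' @param theta Axial angles in degrees (or a `fiber_field`, in which case
#'   only valid subwindows are used).
#' @param weights Optional non-negative weights.
#' @param weighted If `theta` is a `fiber_field`, whether to use the gradient
#'   energies as weights.
#' @return List of class `"circular_summary"`: `theta_m` (degrees), `MVL`,
#'   `n`.
#' @export
circular_summary <- function(theta, weights = NULL, weighted = FALSE) {
  if (inherits(theta, "fiber_field")) {
    f <- theta[theta$valid, ]
    if (!nrow(f)) stop("no valid subwindows")
    weights <- if (weighted) f$weight else NULL
    theta <- f$theta
  }
  if (!length(theta)) stop("no valid elements")
  if (is.null(weights)) weights <- rep(1, length(theta))
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  phi <- 2 * theta * pi / 180
  C <- sum(w * cos(phi)); S <- sum(w * sin(phi))
  structure(list(theta_m = (atan2(S, C) * 180 / pi / 2) %% 180,
                 MVL = sqrt(C^2 + S^2), n = length(theta)),
            class = "circular_summary")
}

#' Group collagen alignment significance
#'
#' Tests whether a group of scar samples shares a common fiber orientation.
#' The group mean orientation `theta_m` is the direction of the resultant of
#' the per-sample mean vectors (length `MVL_i`, orientation `theta_i`); each
#' sample contributes `v_i = MVL_i * cos(2*theta_i - 2*theta_m)` and
#' alignment is significant if the `v_i` differ from 0 by a two-sided
#' one-sample t-test.
#'
#' @param samples List of `circular_summary` objects (>= 2), or a data.frame
#'   with columns `MVL` and `theta_m`.
#' @return List of class `"alignment_test"`: `theta_m` (group, degrees), `v`
#'   (per-sample values), `t`, `df`, `p_value` (`NA` with a warning when `v`
#'   has zero variance).
#' @export
alignment_significance <- function(samples) {
  if (is.data.frame(samples)) {
    mvl <- samples$MVL; th <- samples$theta_m
  } else {
    mvl <- vapply(samples, `[[`, numeric(1), "MVL")
    th <- vapply(samples, `[[`, numeric(1), "theta_m")
  }
  n <- length(mvl)
  if (n < 2) stop("need >= 2 samples")
  phi <- 2 * th * pi / 180
  theta_m <- (atan2(sum(mvl * sin(phi)), sum(mvl * cos(phi))) * 180 / pi / 2) %% 180
  v <- mvl * cos(phi - 2 * theta_m * pi / 180)
  if (stats::sd(v) == 0) {
    warning("zero variance in alignment values; p-value undefined")
    return(structure(list(theta_m = theta_m, v = v, t = NA_real_,
                          df = n - 1L, p_value = NA_real_),
                     class = "alignment_test"))
  }
  tt <- stats::t.test(v, mu = 0)
  structure(list(theta_m = theta_m, v = v, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value),
            class = "alignment_test")
}

#' Analyze one scar image pair end to end
#'
#' Convenience wrapper: channel subtraction, collagen area fraction, fiber
#' orientation field, and the axial circular summary.
#'
#' @param pair A `scar_image_pair`.
#' @param subwindow_px,min_energy Passed to [estimate_fiber_orientations()].
#' @param threshold_method Passed to [collagen_area_fraction()].
#' @param weighted Use gradient-energy weights in the circular summary.
#' @return List: `area_fraction`, `field`, `summary` (a `circular_summary`).
#' @export
analyze_scar_pair <- function(pair, subwindow_px = 16, min_energy = 1e-3,
                              threshold_method = "otsu", weighted = TRUE) {
  collagen <- subtract_images(pair)
  af <- collagen_area_fraction(collagen, threshold_method)
  field <- estimate_fiber_orientations(collagen, subwindow_px, min_energy)
  summ <- if (any(field$valid)) circular_summary(field, weighted = weighted) else NULL
  list(area_fraction = af, field = field, summary = summ)
}
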