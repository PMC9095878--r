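# Preprocessing of raw topographs: trace/retrace averaging, plane leveling
# with the membrane mode shifted to 0 nm, slow-axis drift unwarping, and
# pixel-size calibration against an atomic model.

#' Average trace and retrace channels
#'
#' @param trace,retrace [topograph()] objects of identical shape and
#'   pixel size.
#' @return A [topograph()] with channel `"averaged"`.
#' @export
average_trace_retrace <- function(trace, retrace) {
  stopifnot(inherits(trace, "topograph"), inherits(retrace, "topograph"))
  if (!identical(dim(trace$heights), dim(retrace$heights)))
    stop("trace and retrace shapes differ")
  if (any(abs(trace$pixel_size - retrace$pixel_size) > 1e-12))
    stop("trace and retrace pixel sizes differ")
  out <- topograph((trace$heights + retrace$heights) / 2,
                   trace$pixel_size, channel = "averaged",
                   provenance = c(trace$provenance, retrace$provenance))
  append_provenance(out, "trace/retrace averaged")
}

# Mode of a height sample from a fixed-width histogram. Two separated
# near-equal modes (bimodal baseline) trigger a warning; the lower mode
# is chosen.
height_mode <- function(v, bin_width = 0.05) {
  rng <- range(v)
  breaks <- seq(rng[1] - bin_width, rng[2] + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(v, breaks), nbins = length(breaks))
  b <- which.max(cnt)
  far <- which(abs(seq_along(cnt) - b) > 2)
  if (length(far) && max(cnt[far]) >= 0.95 * cnt[b]) {
    warning("ambiguous baseline: two near-equal height modes; using the lower")
    b2 <- far[which.max(cnt[far])]
    b <- min(b, b2)
  }
  ctr <- breaks[b] + bin_width / 2
  # refine: median of the heights in a small window around the modal bin
  win <- v[abs(v - ctr) <= 1.5 * bin_width]
  if (length(win) > 0) stats::median(win) else ctr
}

#' Level a topograph and zero the membrane baseline
#'
#' Removes the best-fit plane and shifts the modal height (the membrane,
#' assumed to occupy the plurality of pixels) to 0 nm. The plane fit is
#' iterated once on membrane-like pixels only, so particles covering up
#' to roughly 40% of the area do not bias the baseline.
#'
#' @param t A [topograph()].
#' @param bin_width Histogram bin width for the membrane mode, nm.
#' @param inlier_band Half-width of the membrane band used for the
#'   refitted plane, nm.
#' @return Leveled [topograph()]; idempotent and invariant to added
#'   planes.
#' @export
level_and_zero <- function(t, bin_width = 0.05, inlier_band = 0.3) {
  stopifnot(inherits(t, "topograph"))
  h <- t$heights
  nr <- nrow(h); nc <- ncol(h)
  rr <- as.vector(row(h)); cc <- as.vector(col(h)); v <- as.vector(h)
  fit <- stats::lm.fit(cbind(1, rr, cc), v)
  res <- fit$residuals
  m0 <- height_mode(res, bin_width)
  keep <- abs(res - m0) <= inlier_band
  if (sum(keep) >= 0.05 * length(v)) {
    fit2 <- stats::lm.fit(cbind(1, rr[keep], cc[keep]), v[keep])
    plane <- fit2$coefficients[1] + fit2$coefficients[2] * rr +
      fit2$coefficients[3] * cc
    res <- v - plane
  }
  res <- res - height_mode(res, bin_width)
  out <- topograph(matrix(res, nr, nc), t$pixel_size, channel = t$channel,
                   provenance = t$provenance)
  append_provenance(out, "leveled; membrane mode at 0 nm")
}

# Moment-based slow-axis drift estimate: for each detected particle the
# crest mask of a circular object stretched by s along y has second
# moments with sqrt(Iyy/Ixx) = s. Mean circularity of the particles is
# maximal when that anisotropy is removed.
estimate_drift_scale <- function(t, min_height = 1) {
  h <- t$heights
  mx <- max(h)
  if (mx < min_height) stop("no particles found for drift estimation")
  mask <- h > pmax(min_height, 0.5 * mx)
  lab <- label_components(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  ratios <- numeric(0)
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < 30) next  # too small to carry shape information
    yr <- ((idx - 1) %% nrow(h) + 1) * t$pixel_size["y"]
    xc <- ((idx - 1) %/% nrow(h) + 1) * t$pixel_size["x"]
    vy <- stats::var(yr); vx <- stats::var(xc)
    if (vx > 0) ratios <- c(ratios, sqrt(vy / vx))
  }
  if (!length(ratios)) stop("no usable particles for drift estimation")
  mean(ratios)
}

#' Unwarp slow-axis drift
#'
#' The drift model is a pure affine stretch of the slow (y) axis. With a
#' known `scale` the image is resampled by the exact inverse (cubic
#' spline per column). With `scale = "auto"` the stretch is estimated by
#' restoring the circularity of detected particles (second-moment
#' anisotropy of their crest masks).
#'
#' @param t A [topograph()].
#' @param scale Known stretch factor, or `"auto"` to estimate it.
#' @return Unwarped [topograph()] with isotropic pixel size; the applied
#'   scale is attached as attribute `"drift_scale"`.
#' @export
unwarp_y <- function(t, scale = "auto") {
  stopifnot(inherits(t, "topograph"))
  if (identical(scale, "auto")) scale <- estimate_drift_scale(t)
  if (!is.finite(scale) || scale < 0.5 || scale > 2)
    stop(sprintf("drift scale %.3f outside [0.5, 2]: drift model invalid",
                 scale))
  h <- t$heights
  nr <- nrow(h)
  n_out <- if (scale > 1) as.integer(floor(nr / scale)) else nr
  r_src <- (seq_len(n_out) - 0.5) * scale + 0.5
  r_src <- r_src[r_src <= nr]
  n_out <- length(r_src)
  out <- matrix(0, n_out, ncol(h))
  for (j in seq_len(ncol(h))) {
    sf <- stats::splinefun(seq_len(nr), h[, j], method = "natural")
    out[, j] <- sf(r_src)
  }
  tt <- topograph(out, t$pixel_size, channel = t$channel,
                  provenance = t$provenance)
  tt <- append_provenance(tt, sprintf("unwarped y by scale %.5f", scale))
  attr(tt, "drift_scale") <- scale
  tt
}

#' Calibrate the pixel size against an atomic model
#'
#' Ring diameters cluster by stoichiometry; the measured mean diameter of
#' the class matching the model stoichiometry fixes the absolute pixel
#' scale.
#'
#' @param diameters_by_n Data frame with columns `n` (stoichiometry) and
#'   `diameter` (measured, nm).
#' @param model_n Stoichiometry of the reference atomic model.
#' @param model_diameter Outer diameter of the reference model, nm (e.g.
#'   from [model_outer_diameter()] of a built ring).
#' @return A `calibration_result`: scale factor, matched stoichiometry,
#'   and the post-fit spread (sd) of the matched class.
#' @export
calibrate_pixel_size <- function(diameters_by_n, model_n, model_diameter) {
  stopifnot(is.data.frame(diameters_by_n),
            all(c("n", "diameter") %in% names(diameters_by_n)))
  sel <- diameters_by_n$n == model_n
  if (!any(sel))
    stop(sprintf("no measured rings with stoichiometry %d", model_n))
  m <- mean(diameters_by_n$diameter[sel])
  sf <- model_diameter / m
  resid <- if (sum(sel) > 1) stats::sd(diameters_by_n$diameter[sel] * sf)
  else 0
  structure(
    list(scale_factor = sf, model_diameter = model_diameter,
         matched_stoichiometry = as.integer(model_n), residual = resid),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration> scale factor %.5f (model %d-mer, D = %.3f nm), residual %.3f nm\n",
    x$scale_factor, x$matched_stoichiometry, x$model_diameter, x$residual))
  invisible(x)
}
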