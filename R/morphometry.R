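# Particle morphometry on leveled topographs: maximum height above the
# membrane, crest diameter ("diameter of maximum height"), lumen depth and
# pre-pore/pore classification, plus the distribution fits, spacing
# conversions, track linking and outcome tallies used downstream.

#' Classify the pore state from the lumen depth
#'
#' An oligomer is in the pore state iff its lumen penetrates the membrane
#' by at least `threshold` nm (inclusive), i.e. `lumen_min <= -threshold`.
#'
#' @param lumen_min Most negative height inside the crest circle, nm
#'   (membrane = 0). Vectorized.
#' @param threshold Penetration threshold, nm (> 0); default 2.
#' @return Character vector, `"pore"` or `"pre_pore"`.
#' @export
classify_pore_state <- function(lumen_min, threshold = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  ifelse(lumen_min <= -threshold, "pore", "pre_pore")
}

# 3x3 box mean with edge replication; light smoothing used only to locate
# maxima and build crest masks, never to report heights.
box_smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    rs <- pmin(pmax(seq_len(nr) + di, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    acc <- acc + m[rs, cs]
  }
  acc / 9
}

# Local maxima (8-neighborhood) of a matrix at or above frac * max;
# returns linear indices.
local_maxima <- function(m, frac = 0.85) {
  best <- matrix(-Inf, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    best <- pmax(best, shift_matrix(m, di, dj))
  }
  which(m >= best & m >= frac * max(m))
}

# Amplitude of a 2D Gaussian bump fitted (nonlinear least squares) to the
# raw 5x5 neighborhood of one crest bump.
gaussian_bump_apex <- function(m, r0, c0) {
  rs <- max(1, r0 - 2):min(nrow(m), r0 + 2)
  cs <- max(1, c0 - 2):min(ncol(m), c0 + 2)
  z <- as.vector(m[rs, cs])
  dy <- rep(rs - r0, times = length(cs))
  dx <- rep(cs - c0, each = length(rs))
  obj <- function(p)
    sum((z - p[1] * exp(-((dx - p[2])^2 + (dy - p[3])^2) / (2 * p[4]^2)))^2)
  op <- try(stats::optim(c(max(m[r0, c0], 0.2), 0, 0, 2), obj,
                         method = "L-BFGS-B",
                         lower = c(0.1, -2, -2, 0.6),
                         upper = c(Inf, 2, 2, 8)),
            silent = TRUE)
  if (inherits(op, "try-error")) return(m[r0, c0])
  op$par[1]
}

# Sub-pixel particle height: per-bump Gaussian amplitude fits at the
# crest local maxima, summarized by the median over bumps. Fitting a
# fixed neighborhood per bump avoids the upward bias a per-pixel maximum
# would inherit from extreme noise values, and the median over bumps
# removes the residual selection bias of picking the single highest one.
peak_height_quadratic <- function(m) {
  sm2 <- box_smooth3(box_smooth3(m))
  idx <- local_maxima(sm2)
  if (!length(idx)) return(max(m))
  nr <- nrow(m)
  vals <- vapply(idx, function(i)
    gaussian_bump_apex(m, (i - 1) %% nr + 1, (i - 1) %/% nr + 1),
    numeric(1))
  stats::median(vals)
}

# Azimuthally averaged radial height profile about a center (px coords).
radial_profile <- function(m, center_px, pixel_size, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- min(pixel_size) / 2
  rr <- (row(m) - center_px[1]) * pixel_size["y"]
  cc <- (col(m) - center_px[2]) * pixel_size["x"]
  r <- sqrt(rr^2 + cc^2)
  bins <- floor(r / bin_width)
  mh <- tapply(as.vector(m), as.vector(bins), mean)
  data.frame(r = (as.numeric(names(mh)) + 0.5) * bin_width,
             h = as.numeric(mh))
}

# Parabolic refinement of a discrete peak (x equally spaced).
refine_peak <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(list(x = x[i], y = y[i]))
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  step <- x[2] - x[1]
  list(x = x[i] + d * step,
       y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d)
}

# Angular-coverage shape rule. The field classifies shapes visually; this
# operationalizes it: rings close the crest circle, slits are closed but
# strongly elongated (or show exactly two angular gaps), everything else
# is an arc.
classify_shape <- function(angles_deg, aspect, gap_min = 30) {
  a <- sort(angles_deg)
  if (length(a) < 3) return("arc")
  d <- c(diff(a), a[1] + 360 - a[length(a)])
  big <- d > gap_min
  coverage <- 360 - sum(d[big])
  n_gaps <- sum(big)
  if (coverage >= 330 && aspect <= 1.25) return("ring")
  if ((n_gaps == 2 && coverage >= 300) || (coverage >= 330 && aspect > 1.25))
    return("slit")
  "arc"
}

#' Measure one particle in a leveled topograph
#'
#' Quantities follow AFM practice for membrane-inserted oligomers:
#' `max_height` is the sub-pixel crest apex height above the membrane
#' baseline (median of per-bump 2D Gaussian amplitude fits, robust to
#' scan noise), `crest_diameter` is twice the
#' peak radius of the azimuthally averaged radial profile for rings
#' (parabolic sub-bin refinement) or the maximal crest-point separation
#' for arcs and slits, `lumen_min` is the most negative height inside the
#' crest circle, and `pore_state` applies the inclusive 2 nm rule.
#'
#' @param t A leveled [topograph()] (membrane at 0 nm).
#' @param roi Pixel bounding box `c(rmin, rmax, cmin, cmax)`.
#' @param pore_threshold Pore-penetration threshold, nm.
#' @param min_height Particles with ROI maximum below this are rejected.
#' @param crest_frac Fraction of the maximum defining crest pixels.
#' @return A `particle_record` (also a one-row data frame via
#'   [as.data.frame()]).
#' @export
measure_particle <- function(t, roi, pore_threshold = 2, min_height = 1,
                             crest_frac = 0.8) {
  stopifnot(inherits(t, "topograph"))
  roi <- as.integer(round(roi))
  h <- t$heights
  roi[1] <- max(roi[1], 1L); roi[3] <- max(roi[3], 1L)
  roi[2] <- min(roi[2], nrow(h)); roi[4] <- min(roi[4], ncol(h))
  sub <- h[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  px <- t$pixel_size
  rec <- list(particle_id = NA_integer_, roi = roi,
              center = c(NA_real_, NA_real_), shape_class = NA_character_,
              max_height = NA_real_, crest_diameter = NA_real_,
              lumen_min = NA_real_, pore_state = NA_character_,
              stoichiometry = NA_integer_, accepted = FALSE)
  class(rec) <- "particle_record"
  if (max(sub) < min_height) return(rec)
  rec$accepted <- TRUE
  rec$max_height <- peak_height_quadratic(sub)
  sm <- box_smooth3(sub)
  mask <- sm >= crest_frac * max(sm)
  idx <- which(mask)
  wr <- sm[idx]
  rpx <- (idx - 1) %% nrow(sub) + 1
  cpx <- (idx - 1) %/% nrow(sub) + 1
  cen <- c(sum(rpx * wr), sum(cpx * wr)) / sum(wr)
  xy <- cbind((cpx - cen[2]) * px["x"], (rpx - cen[1]) * px["y"])
  ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
  aspect <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
  ang <- (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360
  rec$shape_class <- classify_shape(ang, aspect)
  rec$center <- c(x = (roi[3] - 1 + cen[2] - 0.5) * px[["x"]],
                  y = (roi[1] - 1 + cen[1] - 0.5) * px[["y"]])
  if (rec$shape_class == "ring") {
    prof <- radial_profile(sub, cen, px)
    pk <- refine_peak(prof$r, prof$h)
    rec$crest_diameter <- 2 * pk$x
    rr <- sqrt(((row(sub) - cen[1]) * px["y"])^2 +
                 ((col(sub) - cen[2]) * px["x"])^2)
    interior <- rr < 0.75 * pk$x
    rec$lumen_min <- if (any(interior)) min(sub[interior]) else 0
  } else {
    hull <- grDevices::chull(xy)
    hx <- xy[hull, , drop = FALSE]
    dmax <- max(stats::dist(hx))
    rec$crest_diameter <- dmax
    rr <- sqrt(((row(sub) - cen[1]) * px["y"])^2 +
                 ((col(sub) - cen[2]) * px["x"])^2)
    interior <- rr < 0.75 * dmax / 2
    rec$lumen_min <- if (any(interior)) min(sub[interior]) else 0
  }
  rec$pore_state <- classify_pore_state(rec$lumen_min, pore_threshold)
  rec
}

#' @export
print.particle_record <- function(x, ...) {
  if (!x$accepted) {
    cat("<particle_record> rejected (no particle in ROI)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<particle_record> %s: max height %.2f nm, crest diameter %.2f nm, lumen %.2f nm -> %s\n",
    x$shape_class, x$max_height, x$crest_diameter, x$lumen_min,
    x$pore_state))
  invisible(x)
}

#' @export
as.data.frame.particle_record <- function(x, ...) {
  data.frame(particle_id = x$particle_id, shape_class = x$shape_class,
             max_height = x$max_height, crest_diameter = x$crest_diameter,
             lumen_min = x$lumen_min, pore_state = x$pore_state,
             stoichiometry = x$stoichiometry, accepted = x$accepted,
             center_x_nm = unname(x$center[1]),
             center_y_nm = unname(x$center[2]))
}

#' Measure several ROIs and bind the records into a table
#'
#' @param t A leveled [topograph()].
#' @param rois List of ROIs (each `c(rmin, rmax, cmin, cmax)`).
#' @param ... Passed to [measure_particle()].
#' @return Data frame of particle records.
#' @export
measure_all <- function(t, rois, ...) {
  out <- lapply(seq_along(rois), function(i) {
    r <- measure_particle(t, rois[[i]], ...)
    r$particle_id <- i
    as.data.frame(r)
  })
  do.call(rbind, out)
}

#' Pixel bounding box around a point given in nm
#'
#' @param t A [topograph()].
#' @param center_nm `c(x, y)` in nm.
#' @param radius_nm Half-width of the box, nm.
#' @return `c(rmin, rmax, cmin, cmax)` clipped to the image.
#' @export
roi_around <- function(t, center_nm, radius_nm) {
  px <- t$pixel_size
  c0 <- center_nm[1] / px[["x"]] + 0.5
  r0 <- center_nm[2] / px[["y"]] + 0.5
  dr <- radius_nm / px[["y"]]; dc <- radius_nm / px[["x"]]
  c(max(1L, as.integer(floor(r0 - dr))),
    min(nrow(t$heights), as.integer(ceiling(r0 + dr))),
    max(1L, as.integer(floor(c0 - dc))),
    min(ncol(t$heights), as.integer(ceiling(c0 + dc))))
}

#' Extract a height profile along a line
#'
#' Heights are bilinearly interpolated at a spacing of at most half the
#' pixel size, mirroring the height-profile figures drawn along a scan
#' line.
#'
#' @param t A [topograph()].
#' @param from,to Endpoints `c(x, y)` in nm, inside the image.
#' @param spacing Optional sample spacing, nm.
#' @return Data frame with `distance_nm` and `height_nm`.
#' @export
extract_height_profile <- function(t, from, to, spacing = NULL) {
  stopifnot(inherits(t, "topograph"))
  px <- t$pixel_size
  ext <- c(ncol(t$heights) * px[["x"]], nrow(t$heights) * px[["y"]])
  for (p in list(from, to)) {
    if (p[1] < 0.5 * px[["x"]] || p[1] > ext[1] - 0.5 * px[["x"]] ||
        p[2] < 0.5 * px[["y"]] || p[2] > ext[2] - 0.5 * px[["y"]])
      stop("profile endpoint outside the image")
  }
  if (is.null(spacing)) spacing <- min(px) / 2
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, as.integer(ceiling(len / spacing)) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- from[1] + tt * (to[1] - from[1])
  ys <- from[2] + tt * (to[2] - from[2])
  v <- bilinear_sample(t$heights, ys / px[["y"]] + 0.5, xs / px[["x"]] + 0.5)
  data.frame(distance_nm = tt * len, height_nm = v)
}

#' Fit a Gaussian to a sample of measurements
#'
#' Maximum-likelihood fit on the raw values (sample mean and SD) by
#' default; `method = "histogram"` performs the least-squares fit of a
#' Gaussian curve to histogram counts, mirroring the figure workflow of
#' diameter/height distributions.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @param method `"ml"` or `"histogram"`.
#' @return A `gaussian_fit` with `mean`, `sd`, `n`, `fit_rmse`.
#' @export
fit_gaussian <- function(values, method = c("ml", "histogram")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input: sd = 0")
  if (method == "ml") {
    fit <- list(mean = mean(values), sd = stats::sd(values),
                n = length(values), fit_rmse = NA_real_, method = method)
  } else {
    hh <- graphics::hist(values, breaks = "FD", plot = FALSE)
    obj <- function(p) {
      if (p[3] <= 0 || p[2] <= 0) return(1e12)
      sum((hh$counts - p[1] * exp(-(hh$mids - p[2])^2 / (2 * p[3]^2)))^2)
    }
    start <- c(max(hh$counts), mean(values), stats::sd(values))
    op <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    fit <- list(mean = op$par[2], sd = abs(op$par[3]), n = length(values),
                fit_rmse = sqrt(op$value / length(hh$counts)),
                method = method)
  }
  structure(fit, class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean %.3f, sd %.3f (n = %d, %s)\n",
              x$mean, x$sd, x$n, x$method))
  invisible(x)
}

#' Inter-subunit spacing from ring diameter and stoichiometry
#'
#' Three conventions are provided: `"circumferential"` (arc length
#' pi * D / N, the default), `"literal"` (D / N, the wording used when
#' spacings are quoted as diameter divided by subunit number), and
#' `"chord"` (straight-line neighbor distance D * sin(pi / N)).
#'
#' @param crest_diameter Ring diameter, nm.
#' @param n Stoichiometry (>= 3).
#' @param convention Spacing convention.
#' @return Spacing in nm.
#' @export
subunit_spacing <- function(crest_diameter, n,
                            convention = c("circumferential", "literal",
                                           "chord")) {
  convention <- match.arg(convention)
  if (any(n < 3)) stop("n must be >= 3")
  if (any(crest_diameter <= 0)) stop("diameter must be > 0")
  switch(convention,
         circumferential = pi * crest_diameter / n,
         literal = crest_diameter / n,
         chord = crest_diameter * sin(pi / n))
}

#' Link particles across time-lapse frames into tracks
#'
#' Greedy nearest-neighbor linking within `link_radius`. A track is
#' classified `"mobile"` when its maximum displacement from the first
#' position exceeds `mobility_threshold`, or when it appears after the
#' first frame or disappears before the last one (transient particles);
#' otherwise `"immobile"`. A sensible threshold is about one crest
#' diameter over the series.
#'
#' @param frames Time-ordered list; each element a data frame with
#'   columns `x`, `y` (nm), or a list `list(time = , particles = )`.
#' @param link_radius Maximum link distance between consecutive frames,
#'   nm.
#' @param mobility_threshold Displacement threshold, nm.
#' @return List of `track` objects (data frame `positions` + fields).
#' @export
track_particles <- function(frames, link_radius, mobility_threshold = Inf) {
  n_frames <- length(frames)
  get_frame <- function(f, i) {
    if (is.data.frame(f)) list(time = i, particles = f)
    else list(time = f$time %||% i, particles = f$particles)
  }
  tracks <- list()   # each: list(rows = data.frame(frame, time, x, y), open)
  active <- integer(0)
  for (i in seq_len(n_frames)) {
    fr <- get_frame(frames[[i]], i)
    det <- fr$particles
    nd <- if (is.null(det)) 0L else nrow(det)
    assigned_det <- rep(FALSE, nd)
    extended <- rep(FALSE, length(active))
    if (length(active) && nd > 0) {
      heads <- t(vapply(tracks[active], function(tr) {
        unlist(utils::tail(tr$rows[, c("x", "y")], 1))
      }, numeric(2)))
      dmat <- outer(heads[, 1], det$x, "-")^2 + outer(heads[, 2], det$y, "-")^2
      dmat <- sqrt(dmat)
      repeat {
        m <- which.min(dmat)
        if (!length(m) || !is.finite(dmat[m]) || dmat[m] > link_radius) break
        ti <- (m - 1) %% nrow(dmat) + 1
        dj <- (m - 1) %/% nrow(dmat) + 1
        k <- active[ti]
        tracks[[k]]$rows <- rbind(tracks[[k]]$rows,
                                  data.frame(frame = i, time = fr$time,
                                             x = det$x[dj], y = det$y[dj]))
        extended[ti] <- TRUE
        assigned_det[dj] <- TRUE
        dmat[ti, ] <- Inf; dmat[, dj] <- Inf
      }
    }
    active <- active[extended]
    if (nd > 0) for (dj in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <-
        list(rows = data.frame(frame = i, time = fr$time,
                               x = det$x[dj], y = det$y[dj]))
      active <- c(active, length(tracks))
    }
  }
  lapply(seq_along(tracks), function(k) {
    rows <- tracks[[k]]$rows
    disp <- sqrt((rows$x - rows$x[1])^2 + (rows$y - rows$y[1])^2)
    transient <- rows$frame[1] > 1 || rows$frame[nrow(rows)] < n_frames
    structure(
      list(particle_id = k, positions = rows,
           appearance = rows$frame[1], disappearance = rows$frame[nrow(rows)],
           max_displacement = max(disp),
           mobility_class = if (max(disp) > mobility_threshold || transient)
             "mobile" else "immobile"),
      class = "track")
  })
}

#' Tally categorical simulation outcomes
#'
#' @param labels Character/factor vector of outcome labels (e.g.
#'   `"fusion"`, `"nanodisc"`, `"vesicle"`); at least one.
#' @return Data frame with `category`, `count` and `percent`
#'   (100 * count / total, one decimal).
#' @export
tally_outcomes <- function(labels) {
  if (length(labels) < 1) stop("need at least one outcome label")
  labels <- as.character(labels)
  tab <- table(labels)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(labels), 1),
             row.names = NULL)
}
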