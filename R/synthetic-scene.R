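# Synthetic AFM scene generator: membrane-inserted ring/arc/slit oligomers
# rendered as analytic height fields, followed by tip convolution, slow-axis
# drift and scan noise. The generator's defaults reproduce the imaging
# conditions the analysis modules assume (protrusion ~3.4 nm, crest
# diameters ~20-34 nm, pore lumens rendered at -3 nm).

#' Specify one synthetic oligomer particle
#'
#' Protomers are isotropic Gaussian bumps of height `subunit_height` and
#' lateral sigma `subunit_width`, placed on the crest circle of diameter
#' `crest_diameter` at angular steps of `360 / n_subunits` degrees. Arcs
#' are contiguous subunit ranges; slits are two mirrored arcs whose
#' terminal subunits face each other. The lumen renders at `lumen_depth`
#' (<= 0 nm, relative to the membrane); a particle is in the pore state
#' iff its lumen penetrates by at least the 2 nm threshold.
#'
#' @param center Particle center `c(x, y)` in nm (the crest-circle center
#'   for rings and arcs, the two-fold point for slits). May be `NA` for
#'   population templates that are placed into a scene later.
#' @param shape `"ring"`, `"arc"` or `"slit"`.
#' @param n_subunits Stoichiometry N (>= 3): number of subunits of the
#'   full ring the particle is cut from.
#' @param arc_span Number of subunits actually present (arc), or per side
#'   (slit). Defaults to `n_subunits` for rings.
#' @param crest_diameter Diameter of the crest circle in nm.
#' @param subunit_height Protrusion of the subunit bumps above the
#'   membrane, nm.
#' @param subunit_width Gaussian sigma of one protomer bump, nm.
#' @param lumen_depth Height of the lumen floor relative to the membrane
#'   (<= 0 nm); use e.g. -3 for an open pore, 0 for a plugged pre-pore.
#' @param pore_state Optional `"pre_pore"`/`"pore"`; derived from
#'   `lumen_depth` and the 2 nm rule when omitted, validated against it
#'   when given.
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(center = c(NA_real_, NA_real_),
                          shape = c("ring", "arc", "slit"),
                          n_subunits = 30L,
                          arc_span = NULL,
                          crest_diameter = 26.3,
                          subunit_height = 3.4,
                          subunit_width = 1.2,
                          lumen_depth = 0,
                          pore_state = NULL) {
  shape <- match.arg(shape)
  n_subunits <- as.integer(n_subunits)
  if (n_subunits < 3L) stop("n_subunits must be >= 3")
  if (is.null(arc_span)) {
    arc_span <- switch(shape, ring = n_subunits,
                       arc = max(2L, round(n_subunits / 2)),
                       slit = max(2L, round(n_subunits / 4)))
  }
  arc_span <- as.integer(arc_span)
  if (arc_span > n_subunits) stop("arc_span must be <= n_subunits")
  if (shape != "ring" && arc_span >= n_subunits)
    stop("arc_span must be < n_subunits for arcs and slits")
  if (crest_diameter <= 0) stop("crest_diameter must be > 0")
  if (subunit_height <= 0) stop("subunit_height must be > 0")
  if (subunit_width <= 0) stop("subunit_width must be > 0")
  if (is.finite(lumen_depth) && lumen_depth > 0)
    stop("lumen_depth must be <= 0 (relative to the membrane)")
  implied <- if (lumen_depth <= -2) "pore" else "pre_pore"
  if (is.null(pore_state)) {
    pore_state <- implied
  } else {
    pore_state <- match.arg(pore_state, c("pre_pore", "pore"))
    if (pore_state != implied)
      stop(sprintf(
        "pore_state '%s' inconsistent with lumen_depth %.2f nm (2 nm rule)",
        pore_state, lumen_depth))
  }
  structure(
    list(center = as.numeric(center), shape = shape,
         n_subunits = n_subunits, arc_span = arc_span,
         crest_diameter = crest_diameter, subunit_height = subunit_height,
         subunit_width = subunit_width, lumen_depth = lumen_depth,
         pore_state = pore_state),
    class = "particle_spec"
  )
}

#' Specify a synthetic AFM scene
#'
#' @param image_size `c(rows, cols)` in pixels (>= 64 each).
#' @param pixel_size Nominal pixel size, nm/px.
#' @param membrane_level Height of the flat membrane, nm; downstream
#'   leveling restores this to 0.
#' @param particles List of [particle_spec()] objects with finite centers.
#' @param noise_sd Per-pixel Gaussian scan noise, nm.
#' @param line_noise_sd Per-scanline offset noise, nm.
#' @param drift_y_scale Slow-axis (y) affine stretch factor; 1 = no drift.
#' @param tip_radius AFM tip radius for the grayscale-dilation forward
#'   model, nm; 0 disables tip convolution.
#' @param rng_seed Integer master seed; all sub-streams derive from it.
#' @param overlap_tol Allowed overlap (nm) between particle footprints
#'   before rendering is refused.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(96L, 96L), pixel_size = 0.5,
                       membrane_level = 0, particles = list(),
                       noise_sd = 0, line_noise_sd = 0,
                       drift_y_scale = 1, tip_radius = 0,
                       rng_seed = 1L, overlap_tol = 0) {
  image_size <- as.integer(image_size)
  if (length(image_size) == 1) image_size <- rep(image_size, 2L)
  if (any(image_size < 64L)) stop("image_size must be at least 64 x 64")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (noise_sd < 0 || line_noise_sd < 0) stop("noise sd must be >= 0")
  if (drift_y_scale <= 0) stop("drift_y_scale must be > 0")
  if (tip_radius < 0) stop("tip_radius must be >= 0")
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  stopifnot(all(vapply(particles, inherits, logical(1), "particle_spec")))
  structure(
    list(image_size = image_size, pixel_size = pixel_size,
         membrane_level = membrane_level, particles = particles,
         noise_sd = noise_sd, line_noise_sd = line_noise_sd,
         drift_y_scale = drift_y_scale, tip_radius = tip_radius,
         rng_seed = as.integer(rng_seed), overlap_tol = overlap_tol),
    class = "scene_spec"
  )
}

# Crest-bump centers (nm, rows = bumps) and lumen descriptors for one
# particle. Arcs are centered about their bisector; the slit's two-fold
# point sits at the particle center.
particle_geometry <- function(p) {
  r <- p$crest_diameter / 2
  step <- 2 * pi / p$n_subunits
  if (p$shape == "ring") {
    ang <- (seq_len(p$n_subunits) - 1) * step
    bumps <- cbind(p$center[1] + r * cos(ang), p$center[2] + r * sin(ang))
    return(list(bumps = bumps, lumen_centers = rbind(p$center),
                half_span = pi))
  }
  s <- p$arc_span
  ang <- (seq_len(s) - 1 - (s - 1) / 2) * step
  arc1 <- cbind(r * cos(ang), r * sin(ang))
  if (p$shape == "arc") {
    bumps <- sweep(arc1, 2, p$center, "+")
    return(list(bumps = bumps, lumen_centers = rbind(p$center),
                half_span = (s - 1) * step / 2))
  }
  # slit: companion arc is the 180-degree rotation of arc1 about the point
  # P on the bisector, gap/2 beyond the chord midpoint; gap defaults to
  # the intra-ring neighbor spacing so terminal subunits touch.
  gap <- 2 * r * sin(pi / p$n_subunits)
  chord_mid <- c(r * cos((s - 1) * step / 2), 0)
  pp <- chord_mid + c(gap / 2, 0)
  arc2 <- cbind(2 * pp[1] - arc1[, 1], 2 * pp[2] - arc1[, 2])
  shift <- p$center - pp
  bumps <- sweep(rbind(arc1, arc2), 2, shift, "+")
  cen1 <- c(0, 0) + shift
  cen2 <- 2 * pp + shift
  list(bumps = bumps, lumen_centers = rbind(cen1, cen2), half_span = pi)
}

# Smooth radial ramp: 1 inside crest_r - 3 sigma, 0 outside crest_r - sigma.
lumen_ramp <- function(r, crest_r, sigma) {
  inner <- max(crest_r - 3 * sigma, 0)
  outer <- max(crest_r - sigma, inner + 1e-9)
  w <- (outer - r) / (outer - inner)
  w <- pmin(pmax(w, 0), 1)
  0.5 - 0.5 * cos(pi * w)
}

# Evaluate a particle's height field at coordinates (xx, yy) in nm.
# Returns list(pos, neg): protrusion above membrane and lumen depression.
particle_field <- function(p, xx, yy) {
  geom <- particle_geometry(p)
  sig <- p$subunit_width
  d2 <- NULL
  for (k in seq_len(nrow(geom$bumps))) {
    dk <- (xx - geom$bumps[k, 1])^2 + (yy - geom$bumps[k, 2])^2
    d2 <- if (is.null(d2)) dk else pmin(d2, dk)
  }
  pos <- p$subunit_height * exp(-d2 / (2 * sig^2))
  depth <- p$lumen_depth
  if (!is.finite(depth)) depth <- -3  # open-pore sentinel: configured floor
  if (depth == 0) {
    neg <- 0 * pos
  } else {
    crest_r <- p$crest_diameter / 2
    w <- 1
    for (k in seq_len(nrow(geom$lumen_centers))) {
      rr <- sqrt((xx - geom$lumen_centers[k, 1])^2 +
                   (yy - geom$lumen_centers[k, 2])^2)
      w <- w * lumen_ramp(rr, crest_r, sig)
    }
    if (p$shape == "arc") {
      th <- abs(atan2(yy - p$center[2], xx - p$center[1]))
      edge <- sig / crest_r
      aw <- (geom$half_span - th) / edge
      aw <- pmin(pmax(aw, 0), 1)
      w <- w * (0.5 - 0.5 * cos(pi * aw))
    }
    neg <- depth * w
  }
  list(pos = pos, neg = neg)
}

particle_footprint_radius <- function(p) {
  p$crest_diameter / 2 + 3 * p$subunit_width +
    if (p$shape == "slit") p$crest_diameter / 2 else 0
}

#' Render a synthetic scene into a topograph
#'
#' The analytic surface (membrane + particles) is sampled on the scan
#' grid with the slow-axis drift applied exactly (the recorded image is
#' the true surface stretched by `drift_y_scale` along y), then dilated
#' with a spherical tip of `tip_radius`, then corrupted by per-pixel and
#' per-scanline Gaussian noise. Bit-identical for a fixed `rng_seed`.
#'
#' @param spec A [scene_spec()].
#' @return A [topograph()] (channel `"trace"`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  px <- spec$pixel_size
  ext_x <- nc * px
  ext_y <- nr * px / spec$drift_y_scale  # true y extent covered by the scan
  for (p in spec$particles) {
    if (any(!is.finite(p$center)))
      stop("particles in a scene must have finite centers")
    rad <- particle_footprint_radius(p)
    if (p$center[1] - rad < 0 || p$center[1] + rad > ext_x ||
        p$center[2] - rad < 0 || p$center[2] + rad > ext_y)
      stop("particle extends outside the imaged field")
  }
  np <- length(spec$particles)
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      pi_ <- spec$particles[[i]]; pj <- spec$particles[[j]]
      dd <- sqrt(sum((pi_$center - pj$center)^2))
      need <- (pi_$crest_diameter + pj$crest_diameter) / 2 +
        2 * (pi_$subunit_width + pj$subunit_width) - spec$overlap_tol
      if (dd < need)
        stop(sprintf("particles %d and %d overlap beyond tolerance", i, j))
    }
  }
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px / spec$drift_y_scale
  xx <- matrix(rep(xs, each = nr), nr, nc)
  yy <- matrix(ys, nr, nc)
  pos <- matrix(0, nr, nc); neg <- matrix(0, nr, nc)
  for (p in spec$particles) {
    f <- particle_field(p, xx, yy)
    pos <- pmax(pos, f$pos)
    neg <- pmin(neg, f$neg)
  }
  h <- spec$membrane_level + pos + neg
  if (spec$tip_radius > 0) {
    h <- tip_dilate_matrix(h, spec$tip_radius,
                           c(x = px, y = px / spec$drift_y_scale))
  }
  if (spec$noise_sd > 0) {
    h <- h + with_seed(split_seed(spec$rng_seed, 1),
                       matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
  }
  if (spec$line_noise_sd > 0) {
    h <- h + with_seed(split_seed(spec$rng_seed, 2),
                       stats::rnorm(nr, 0, spec$line_noise_sd))
  }
  topograph(h, px, channel = "trace",
            provenance = sprintf(
              "render_scene: %d particle(s), tip %.2g nm, noise %.3g nm, drift %.4g, seed %d",
              np, spec$tip_radius, spec$noise_sd, spec$drift_y_scale,
              spec$rng_seed))
}

# Non-flat grayscale dilation with a spherical tip. The imaged height at
# p is the lowest apex position at which the sphere touches the surface:
# max over offsets o of surface(p + o) - (R - sqrt(R^2 - |o|^2)).
tip_dilate_matrix <- function(h, tip_radius, pixel_size) {
  if (tip_radius == 0) return(h)
  kx <- floor(tip_radius / pixel_size["x"])
  ky <- floor(tip_radius / pixel_size["y"])
  out <- h
  for (di in -ky:ky) for (dj in -kx:kx) {
    if (di == 0 && dj == 0) next
    d2 <- (di * pixel_size["y"])^2 + (dj * pixel_size["x"])^2
    if (d2 > tip_radius^2) next
    drop <- tip_radius - sqrt(tip_radius^2 - d2)
    out <- pmax(out, shift_matrix(h, di, dj) - drop)
  }
  out
}

#' Simulate the finite AFM tip by grayscale dilation
#'
#' Standard AFM forward model: the output is pointwise >= the input and a
#' flat surface is left unchanged.
#'
#' @param surface A [topograph()] or a plain height matrix (nm).
#' @param tip_radius Spherical tip radius, nm (>= 0).
#' @param pixel_size Required when `surface` is a bare matrix.
#' @return Same type as `surface`.
#' @export
render_tip_dilation <- function(surface, tip_radius, pixel_size = NULL) {
  if (tip_radius < 0) stop("tip_radius must be >= 0")
  if (inherits(surface, "topograph")) {
    out <- surface
    out$heights <- tip_dilate_matrix(surface$heights, tip_radius,
                                     surface$pixel_size)
    return(append_provenance(out, sprintf("tip dilation R = %.3g nm",
                                          tip_radius)))
  }
  if (is.null(pixel_size))
    stop("pixel_size is required for a bare matrix input")
  if (length(pixel_size) == 1) pixel_size <- c(x = pixel_size, y = pixel_size)
  tip_dilate_matrix(as.matrix(surface), tip_radius, pixel_size)
}

#' Draw a population of particle specifications
#'
#' Crest diameters, heights, shapes and stoichiometries are drawn from
#' configurable distributions. Defaults follow the measured populations
#' of membrane-inserted gasdermin-A3 oligomers: crest diameters
#' Normal(26.3, 2.2^2) nm, protrusion height 3.4 nm, stoichiometries
#' 18..36 peaked near 30.
#'
#' @param distribution_params Named list overriding any of: `shape_probs`
#'   (named vector over ring/arc/slit), `diameter_mean`, `diameter_sd`,
#'   `height_mean`, `height_sd`, `width`, `stoichiometry` (list with
#'   `values`, `probs`), `arc_span_frac`, `pore_prob`, `pore_floor`.
#' @param n Number of particles (>= 1).
#' @param rng_seed Integer seed; equal seeds give identical populations.
#' @return List of [particle_spec()] with `NA` centers (place them into a
#'   scene with e.g. [single_particle_scene()]).
#' @export
sample_population <- function(distribution_params = list(), n,
                              rng_seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  dp <- list(
    shape_probs = c(ring = 1, arc = 0, slit = 0),
    diameter_mean = 26.3, diameter_sd = 2.2,
    height_mean = 3.4, height_sd = 0,
    width = 1.2,
    stoichiometry = list(values = 18:36,
                         probs = stats::dnorm(18:36, 29.5, 3)),
    arc_span_frac = 0.45,
    pore_prob = 0, pore_floor = -3
  )
  unknown <- setdiff(names(distribution_params), names(dp))
  if (length(unknown))
    stop("unknown distribution parameter(s): ",
         paste(unknown, collapse = ", "))
  dp[names(distribution_params)] <- distribution_params
  if (dp$diameter_sd < 0 || dp$height_sd < 0)
    stop("distribution sd parameters must be >= 0")
  if (length(dp$stoichiometry$values) != length(dp$stoichiometry$probs) ||
      any(dp$stoichiometry$probs < 0) || sum(dp$stoichiometry$probs) <= 0)
    stop("invalid stoichiometry distribution")
  if (dp$pore_prob < 0 || dp$pore_prob > 1) stop("invalid pore_prob")
  with_seed(rng_seed, {
    shapes <- sample(names(dp$shape_probs), n, replace = TRUE,
                     prob = dp$shape_probs)
    nn <- sample(dp$stoichiometry$values, n, replace = TRUE,
                 prob = dp$stoichiometry$probs)
    dd <- stats::rnorm(n, dp$diameter_mean, dp$diameter_sd)
    hh <- stats::rnorm(n, dp$height_mean, dp$height_sd)
    pore <- stats::runif(n) < dp$pore_prob
    lapply(seq_len(n), function(i) {
      span <- switch(shapes[i],
                     ring = nn[i],
                     arc = max(2L, as.integer(round(dp$arc_span_frac * nn[i]))),
                     slit = max(2L, as.integer(round(dp$arc_span_frac * nn[i] / 2))))
      particle_spec(
        center = c(NA_real_, NA_real_), shape = shapes[i],
        n_subunits = nn[i], arc_span = span,
        crest_diameter = max(dd[i], 6 * dp$width),
        subunit_height = max(hh[i], 0.5),
        subunit_width = dp$width,
        lumen_depth = if (pore[i]) dp$pore_floor else 0
      )
    })
  })
}

#' Build a scene holding a single centered particle
#'
#' Convenience wrapper used throughout the measurement round-trip tests:
#' the particle is placed at the center of a field just large enough for
#' its footprint plus `margin`.
#'
#' @param p A [particle_spec()].
#' @param pixel_size nm/px.
#' @param margin Clearance around the particle footprint, nm.
#' @inheritParams scene_spec
#' @return A [scene_spec()].
#' @export
single_particle_scene <- function(p, pixel_size = 0.5, margin = 8,
                                  noise_sd = 0, line_noise_sd = 0,
                                  drift_y_scale = 1, tip_radius = 0,
                                  rng_seed = 1L) {
  rad <- particle_footprint_radius(p)
  side_nm <- 2 * (rad + margin)
  npx <- max(64L, as.integer(ceiling(side_nm / pixel_size)))
  ext <- npx * pixel_size
  p$center <- c(ext / 2, ext / 2 / drift_y_scale)
  scene_spec(image_size = c(npx, npx), pixel_size = pixel_size,
             membrane_level = 0, particles = list(p),
             noise_sd = noise_sd, line_noise_sd = line_noise_sd,
             drift_y_scale = drift_y_scale, tip_radius = tip_radius,
             rng_seed = rng_seed)
}

#' Write the ground-truth particle table of a scene as CSV
#'
#' @param spec A [scene_spec()].
#' @param path Output CSV path.
#' @export
write_particle_table <- function(spec, path) {
  ps <- spec$particles
  df <- data.frame(
    particle_id = seq_along(ps),
    shape = vapply(ps, `[[`, character(1), "shape"),
    N = vapply(ps, `[[`, integer(1), "n_subunits"),
    crest_diameter_nm = vapply(ps, `[[`, numeric(1), "crest_diameter"),
    height_nm = vapply(ps, `[[`, numeric(1), "subunit_height"),
    lumen_depth_nm = vapply(ps, `[[`, numeric(1), "lumen_depth"),
    pore_state = vapply(ps, `[[`, character(1), "pore_state"),
    center_x_nm = vapply(ps, function(p) p$center[1], numeric(1)),
    center_y_nm = vapply(ps, function(p) p$center[2], numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
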