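# Shared fixtures and independent brute-force oracles. Oracles are
# written as plain loops, independent of the implementation paths they
# check.

full_roi <- function(t) c(1L, nrow(t$heights), 1L, ncol(t$heights))

# Render a single centered particle, level, and measure it.
measure_single <- function(p, noise_sd = 0, tip_radius = 0, rng_seed = 1,
                           pixel_size = 0.5, drift_y_scale = 1, ...) {
  sc <- single_particle_scene(p, pixel_size = pixel_size,
                              noise_sd = noise_sd, tip_radius = tip_radius,
                              drift_y_scale = drift_y_scale,
                              rng_seed = rng_seed)
  t <- suppressWarnings(level_and_zero(render_scene(sc)))
  measure_particle(t, full_roi(t), ...)
}

# Brute-force tip-sample contact oracle: for every pixel, lower a sphere
# of radius R until it touches the surface; the image is the apex height.
oracle_tip_dilation <- function(h, tip_radius, px) {
  nr <- nrow(h); nc <- ncol(h)
  k <- ceiling(tip_radius / px)
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- h[i, j]
    for (di in -k:k) for (dj in -k:k) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      d2 <- (di * px)^2 + (dj * px)^2
      if (d2 > tip_radius^2) next
      cand <- h[ii, jj] - (tip_radius - sqrt(tip_radius^2 - d2))
      if (cand > best) best <- cand
    }
    out[i, j] <- best
  }
  out
}

# Brute-force DFT-sum oracle for the angular power spectrum of signal s.
oracle_dft_power <- function(s, k_max = floor(length(s) / 2)) {
  s <- s - mean(s)
  n <- length(s)
  vapply(seq_len(k_max), function(k) {
    re <- sum(s * cos(2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(s * sin(2 * pi * k * (seq_len(n) - 1) / n))
    (re^2 + im^2) / n^2
  }, numeric(1))
}

# Exhaustive coarse-grid alignment oracle (plain loops, no refinement).
oracle_align <- function(img, ref, angles, max_shift) {
  best <- list(corr = -2, rotation = NA, shift = c(NA, NA))
  for (a in angles) {
    rimg <- poremorph:::rotate_image(img, a, fill = NA_real_)
    for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
      sh <- poremorph:::shift_matrix(rimg, dr, dc, fill = NA_real_)
      keep <- !is.na(sh)
      if (sum(keep) < 10) next
      v <- suppressWarnings(stats::cor(sh[keep], ref[keep]))
      if (!is.na(v) && v > best$corr)
        best <- list(corr = v, rotation = a, shift = c(dr, dc))
    }
  }
  best
}

# All-pairs geometric hydrogen-bond oracle on small atom tables.
oracle_hb <- function(a, b, r_max = 0.35, angle_max = 30) {
  cnt <- 0L
  count_dir <- function(don_df, acc_df) {
    n <- 0L
    for (i in seq_len(nrow(don_df))) {
      if (don_df$element[i] != "N") next
      hs <- which(don_df$element == "H" & don_df$resid == don_df$resid[i])
      hpos <- list()
      for (hh in hs) {
        d <- sqrt(sum((c(don_df$x[hh], don_df$y[hh], don_df$z[hh]) -
                         c(don_df$x[i], don_df$y[i], don_df$z[i]))^2))
        if (d <= 0.125) hpos[[length(hpos) + 1]] <-
            c(don_df$x[hh], don_df$y[hh], don_df$z[hh])
      }
      if (!length(hpos)) next
      for (j in seq_len(nrow(acc_df))) {
        if (acc_df$element[j] != "O") next
        dvec <- c(acc_df$x[j], acc_df$y[j], acc_df$z[j]) -
          c(don_df$x[i], don_df$y[i], don_df$z[i])
        dd <- sqrt(sum(dvec^2))
        if (dd > r_max || dd < 1e-6) next
        ok <- FALSE
        for (hp in hpos) {
          hv <- hp - c(don_df$x[i], don_df$y[i], don_df$z[i])
          ang <- acos(max(-1, min(1, sum(hv * dvec) /
                                    (sqrt(sum(hv^2)) * sqrt(sum(dvec^2)))))) * 180 / pi
          if (ang <= angle_max) ok <- TRUE
        }
        if (ok) n <- n + 1L
      }
    }
    n
  }
  cnt + count_dir(a, b) + count_dir(b, a)
}

# Minimal atom-table constructor for structure-metric fixtures.
atoms_df <- function(elety, resid, resname, element, xyz) {
  data.frame(elety = elety, resid = resid, resname = resname,
             element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

# Random rigid transform of an atom table (for invariance tests).
random_rigid <- function(df, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  R <- poremorph:::rot_axis(ax, stats::runif(1, 0, 360))
  sh <- stats::rnorm(3, 0, 3)
  list(df = poremorph:::transform_atoms(df, R, sh), rotation = R, shift = sh)
}
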