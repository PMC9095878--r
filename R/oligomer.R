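# Geometric construction of ring, arc, slit and linear oligomer
# coordinate models from a monomer: a ring places N copies at angular
# steps of 360/N degrees on a radius R about the membrane normal, arcs
# are contiguous cuts from rings, slits are two arcs facing each other at
# their terminals, and linear oligomers are evenly spaced translated
# copies (the infinite-curvature limit of a ring).

transform_atoms <- function(df, rot = diag(3), shift = c(0, 0, 0)) {
  m <- coords_matrix(df) %*% t(rot)
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}

#' Oligomer coordinate model
#'
#' @param subunits List of atom data frames (one per subunit, columns as
#'   in [make_monomer_fixture()]).
#' @param shape `"ring"`, `"arc"`, `"slit"` or `"linear"`.
#' @param radius Crest-circle radius R (nm) for rings/arcs, else `NA`.
#' @param rotation_step Angular step between subunits, degrees.
#' @param spacing Neighbor spacing (nm) for linear oligomers.
#' @param monomer Optional monomer fixture the model was built from
#'   (carries the domain map and interface markers).
#' @return An object of class `oligomer_model`; the ring axis is z (the
#'   membrane normal).
#' @export
oligomer_model <- function(subunits, shape, radius = NA_real_,
                           rotation_step = NA_real_, spacing = NA_real_,
                           monomer = NULL) {
  shape <- match.arg(shape, c("ring", "arc", "slit", "linear"))
  if (length(subunits) < 2) stop("an oligomer needs at least 2 subunits")
  structure(
    list(subunits = subunits, shape = shape, n = length(subunits),
         radius = radius, rotation_step = rotation_step, spacing = spacing,
         monomer = monomer),
    class = "oligomer_model")
}

#' @export
print.oligomer_model <- function(x, ...) {
  cat(sprintf("<oligomer_model> %s, N = %d subunits", x$shape, x$n))
  if (is.finite(x$radius)) cat(sprintf(", R = %.3f nm", x$radius))
  if (is.finite(x$rotation_step))
    cat(sprintf(", step = %.4g deg", x$rotation_step))
  if (is.finite(x$spacing)) cat(sprintf(", spacing = %.3f nm", x$spacing))
  cat(sprintf(" (%d atoms/subunit)\n", nrow(x$subunits[[1]])))
  invisible(x)
}

#' Flatten a model into one atom table
#'
#' @param model An [oligomer_model()].
#' @return Data frame of all atoms with a `subunit` index column.
#' @export
model_atoms <- function(model) {
  do.call(rbind, lapply(seq_along(model$subunits), function(k) {
    df <- model$subunits[[k]]
    df$subunit <- k
    df
  }))
}

subunit_centroid <- function(df) colMeans(coords_matrix(df))

#' Outer diameter of a coordinate model
#'
#' Twice the largest radial (xy) atom distance from the ring axis; used
#' as the atomic-model reference for pixel-size calibration.
#'
#' @param model An [oligomer_model()].
#' @return Diameter in nm.
#' @export
model_outer_diameter <- function(model) {
  a <- model_atoms(model)
  2 * max(sqrt(a$x^2 + a$y^2))
}

#' Build a ring-shaped oligomer
#'
#' Places the monomer at radius R on the +x axis and rotates it N times
#' by 360/N degrees about z, giving exact N-fold symmetry.
#'
#' @param monomer A `monomer_fixture` (hairpin axis along z, +x radial
#'   outward).
#' @param n Stoichiometry (>= 3).
#' @param radius Ring radius R, nm; a warning is issued when R is
#'   smaller than the monomer's radial extent (subunits clash).
#' @return An [oligomer_model()] of shape `"ring"`.
#' @export
build_ring <- function(monomer, n, radius) {
  n <- as.integer(n)
  if (n < 3) stop("ring stoichiometry must be >= 3")
  if (radius <= 0) stop("radius must be > 0")
  ext <- max(monomer$x) - min(monomer$x)
  if (radius < ext)
    warning(sprintf(
      "radius %.2f nm smaller than monomer radial extent %.2f nm: subunits clash",
      radius, ext))
  step <- 360 / n
  template <- monomer
  template$x <- template$x + radius
  subunits <- lapply(seq_len(n) - 1L, function(k)
    transform_atoms(template, rot_z(k * step)))
  oligomer_model(subunits, "ring", radius = radius, rotation_step = step,
                 monomer = monomer)
}

# Surrogate inter-subunit pair energy: soft-core repulsion (quadratic
# inside core_radius, over all atom pairs) plus a Gaussian contact
# attraction between the designated interface atoms of adjacent
# subunits. Not a force field: just the clash/contact trade-off needed
# to select a ring radius.
surrogate_pair_energy <- function(a, b, iface,
                                  core_radius = 0.25, repulsion_k = 200,
                                  contact_weight = 30, contact_sigma = 0.6) {
  pa <- coords_matrix(a); pb <- coords_matrix(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  rep_e <- repulsion_k * sum(pmax(core_radius - d, 0)^2)
  att_e <- 0
  if (!is.null(iface) && length(iface$plus) && length(iface$minus)) {
    dpm <- d[iface$plus, iface$minus, drop = FALSE]
    att_e <- -contact_weight * sum(exp(-dpm^2 / (2 * contact_sigma^2)))
  }
  c(repulsion = rep_e, attraction = att_e)
}

model_adjacency <- function(model) {
  n <- model$n
  pairs <- cbind(seq_len(n - 1), 2:n)
  if (model$shape == "ring") pairs <- rbind(pairs, c(n, 1))
  pairs
}

#' Surrogate assembly energy of an oligomer model
#'
#' Sum of nearest-neighbor pair energies (cyclic for rings, chain
#' otherwise): soft-core repulsion over all inter-subunit atom pairs plus
#' a Gaussian contact attraction between designated interface atoms.
#' Stands in for a force-field in-vacuo energy only as far as radius
#' selection needs a clash/contact trade-off.
#'
#' @param model An [oligomer_model()] built from a monomer that carries
#'   interface markers.
#' @param ... Passed to the pair term (`core_radius`, `repulsion_k`,
#'   `contact_weight`, `contact_sigma`).
#' @return A `surrogate_energy`: `total`, per-pair terms, parameters.
#' @export
surrogate_ring_energy <- function(model, ...) {
  iface <- if (!is.null(model$monomer)) attr(model$monomer, "interface")
  pairs <- model_adjacency(model)
  sym <- model$shape %in% c("ring", "arc")  # congruent neighbor pairs
  if (sym) {
    e1 <- surrogate_pair_energy(model$subunits[[1]], model$subunits[[2]],
                                iface, ...)
    per <- matrix(rep(e1, nrow(pairs)), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, names(e1)))
  } else {
    per <- t(apply(pairs, 1, function(pr)
      surrogate_pair_energy(model$subunits[[pr[1]]],
                            model$subunits[[pr[2]]], iface, ...)))
  }
  structure(
    list(total = sum(per), pairs = pairs, per_pair = per,
         parameters = list(...)),
    class = "surrogate_energy")
}

#' Optimal ring radius from an energy scan
#'
#' Builds rings over a radius grid, evaluates the (surrogate) assembly
#' energy, and returns the grid argmin refined by a parabolic fit. The
#' grid must bracket an interior minimum; a monotone energy curve is an
#' error.
#'
#' @param monomer A `monomer_fixture`.
#' @param n Stoichiometry.
#' @param r_grid Radii to scan, nm (increasing).
#' @param energy_fn Energy function `f(monomer, n, radius) -> numeric`;
#'   defaults to the total [surrogate_ring_energy()] of the built ring.
#' @param ... Passed to the default energy function.
#' @return A `ring_radius_scan`: `r_opt`, `energies` (data frame) and
#'   `n`.
#' @export
optimal_ring_radius <- function(monomer, n, r_grid, energy_fn = NULL, ...) {
  r_grid <- sort(r_grid)
  if (length(r_grid) < 3) stop("r_grid needs at least 3 radii")
  if (is.null(energy_fn)) {
    energy_fn <- function(monomer, n, radius) {
      model <- suppressWarnings(build_ring(monomer, n, radius))
      surrogate_ring_energy(model, ...)$total
    }
  }
  e <- vapply(r_grid, function(r) energy_fn(monomer, n, r), numeric(1))
  i <- which.min(e)
  if (i == 1 || i == length(r_grid))
    stop("no interior energy minimum on the radius grid")
  pk <- refine_peak(r_grid[(i - 1):(i + 1)], -e[(i - 1):(i + 1)])
  structure(
    list(r_opt = pk$x, n = as.integer(n),
         energies = data.frame(radius = r_grid, energy = e)),
    class = "ring_radius_scan")
}

#' @export
print.ring_radius_scan <- function(x, ...) {
  cat(sprintf("<ring_radius_scan> N = %d: R_opt = %.4f nm (grid %g..%g nm)\n",
              x$n, x$r_opt, min(x$energies$radius), max(x$energies$radius)))
  invisible(x)
}

#' Cut an arc from a ring
#'
#' Retains the first `m` contiguous subunits with unchanged geometry.
#'
#' @param ring A ring [oligomer_model()].
#' @param m Subunits to keep (`2 <= m < N`).
#' @return An [oligomer_model()] of shape `"arc"`.
#' @export
build_arc <- function(ring, m) {
  stopifnot(inherits(ring, "oligomer_model"))
  if (ring$shape != "ring") stop("build_arc expects a ring model")
  m <- as.integer(m)
  if (m < 2 || m >= ring$n) stop("m must satisfy 2 <= m < N")
  oligomer_model(ring$subunits[seq_len(m)], "arc", radius = ring$radius,
                 rotation_step = ring$rotation_step, monomer = ring$monomer)
}

#' Join two arcs into a slit
#'
#' The second arc is rotated by 180 degrees about the membrane normal
#' and translated so its terminal subunits face the first arc's
#' terminals at the requested gap; for two congruent arcs the result has
#' an exact two-fold symmetry axis. The construction is purely rigid:
#' arcs longer than half their ring mesh with ring-like clearance, while
#' shallow arcs enclose a narrow slot in which subunit clouds may
#' approach closely (relax `clash_radius` to accept such geometries, as
#' a downstream energy minimization would).
#'
#' @param arc1,arc2 Arc [oligomer_model()]s as produced by [build_arc()]
#'   (ring center at the origin).
#' @param gap Terminal-terminal (subunit centroid) distance, nm;
#'   defaults to the intra-ring neighbor spacing of `arc1`.
#' @param clash_radius Inter-arc atom pairs closer than this raise a
#'   steric-overlap error, nm.
#' @return An [oligomer_model()] of shape `"slit"`.
#' @export
build_slit <- function(arc1, arc2, gap = NULL, clash_radius = 0.1) {
  stopifnot(inherits(arc1, "oligomer_model"), inherits(arc2, "oligomer_model"))
  if (arc1$shape != "arc" || arc2$shape != "arc")
    stop("build_slit expects two arc models")
  if (is.null(gap))
    gap <- 2 * arc1$radius * sin(pi * arc1$rotation_step / 360)
  chord_frame <- function(arc) {
    t1 <- subunit_centroid(arc$subunits[[1]])[1:2]
    t2 <- subunit_centroid(arc$subunits[[arc$n]])[1:2]
    mid <- (t1 + t2) / 2
    out <- if (sqrt(sum(mid^2)) > 1e-6) unit_vec(mid)
    else {  # half-ring arc: chord through the center; use the bulge side
      cen <- rowMeans(vapply(arc$subunits, subunit_centroid, numeric(3)))[1:2]
      unit_vec(cen)
    }
    list(mid = mid, out = out)  # ring center at origin
  }
  f1 <- chord_frame(arc1); f2 <- chord_frame(arc2)
  th <- (atan2(f1$out[2], f1$out[1]) + pi) - atan2(f2$out[2], f2$out[1])
  rot <- rot_z(rad2deg(th))
  m2r <- (rot %*% c(f2$mid, 0))[1:2]
  shift <- c(f1$mid + gap * f1$out - m2r, 0)
  sub2 <- lapply(arc2$subunits, transform_atoms, rot = rot, shift = shift)
  a1 <- coords_matrix(do.call(rbind, arc1$subunits))
  a2 <- coords_matrix(do.call(rbind, sub2))
  d2 <- outer(rowSums(a1^2), rowSums(a2^2), "+") - 2 * a1 %*% t(a2)
  if (min(d2) < clash_radius^2)
    stop(sprintf("steric overlap: inter-arc atoms closer than %.2f nm",
                 clash_radius))
  oligomer_model(c(arc1$subunits, sub2), "slit", radius = arc1$radius,
                 rotation_step = arc1$rotation_step, monomer = arc1$monomer)
}

#' Build a linear oligomer
#'
#' `m` translated copies along the tangential (y) direction with spacing
#' `s`: the infinite-curvature limit of a ring at fixed neighbor
#' spacing.
#'
#' @param monomer A `monomer_fixture`.
#' @param m Number of subunits (>= 2).
#' @param s Neighbor spacing, nm (> 0).
#' @return An [oligomer_model()] of shape `"linear"`.
#' @export
build_linear <- function(monomer, m, s) {
  m <- as.integer(m)
  if (m < 2) stop("m must be >= 2")
  if (s <= 0) stop("spacing must be > 0")
  subunits <- lapply(seq_len(m) - 1L, function(k)
    transform_atoms(monomer, shift = c(0, k * s, 0)))
  oligomer_model(subunits, "linear", spacing = s, monomer = monomer)
}

pdb_chain_ids <- c(LETTERS, letters, as.character(0:9))

#' Write / read oligomer models as PDB
#'
#' One chain per subunit, coordinates in Angstrom at the file boundary
#' (nm internally), occupancy 1.00 and B-factor 0.00. Models with more
#' than 62 subunits are segmented into numbered files with a warning.
#'
#' @param model An [oligomer_model()].
#' @param file Output path.
#' @return `write_pdb()` returns the written path(s) invisibly;
#'   `read_pdb()` returns an [oligomer_model()] with one subunit per
#'   chain (the shape class is not encoded in PDB, so the generic
#'   `"linear"` tag is used for the container).
#' @export
write_pdb <- function(model, file) {
  stopifnot(inherits(model, "oligomer_model"))
  n_chain <- length(pdb_chain_ids)
  groups <- split(seq_len(model$n), ceiling(seq_len(model$n) / n_chain))
  paths <- character(0)
  if (length(groups) > 1)
    warning(sprintf(
      "model has %d subunits (> %d chains): writing %d segmented files",
      model$n, n_chain, length(groups)))
  for (gi in seq_along(groups)) {
    path <- if (length(groups) == 1) file
    else sub("(\\.pdb)?$", sprintf("_part%d.pdb", gi), file)[1]
    dfs <- lapply(seq_along(groups[[gi]]), function(j) {
      k <- groups[[gi]][j]
      df <- model$subunits[[k]]
      df$chain <- pdb_chain_ids[j]
      df
    })
    all <- do.call(rbind, dfs)
    xyz <- as.vector(t(coords_matrix(all))) * 10  # nm -> Angstrom
    bio3d::write.pdb(file = path, xyz = xyz, resno = all$resid,
                     resid = all$resname, elety = all$elety,
                     chain = all$chain, o = rep(1, nrow(all)),
                     b = rep(0, nrow(all)))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_pdb
#' @param path PDB file to read.
#' @export
read_pdb <- function(path) {
  p <- bio3d::read.pdb(path)
  at <- p$atom
  df <- data.frame(
    elety = at$elety, resid = at$resno, resname = at$resid,
    element = ifelse(!is.na(at$elesy) & nzchar(at$elesy), at$elesy,
                     substr(at$elety, 1, 1)),
    x = at$x / 10, y = at$y / 10, z = at$z / 10)
  chains <- unique(at$chain)
  subunits <- lapply(chains, function(ch) df[at$chain == ch, , drop = FALSE])
  if (length(subunits) == 1)
    return(structure(list(subunits = subunits, shape = "linear",
                          n = 1L, radius = NA_real_,
                          rotation_step = NA_real_, spacing = NA_real_,
                          monomer = NULL), class = "oligomer_model"))
  oligomer_model(subunits, "linear")
}
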