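# Synthetic pseudo-monomer: a planar two-strand "hairpin" block spanning
# the membrane plus an ellipsoidal "head" block above it, with labeled
# domains, hydrogen-bond donors/acceptors and charged groups on the
# tangential faces, and interface markers for the surrogate ring-assembly
# potential. Geometry is chosen so the head's principal axes coincide
# with the hairpin's reference frame when tilt and roll are zero.

default_monomer_geometry <- function() {
  list(
    hairpin_length = 3.0,    # nm, transmembrane span (z in [-3, -0.2])
    strand_sep = 0.7,        # nm, separation of the two strands along x
    face_offset = 0.45,      # nm, tangential (y) offset of face sites
    n_face_sites = 4L,       # H-bond donor/acceptor sites per face
    head_semiaxes = c(1.4, 0.9, 0.6),  # nm, a > b > c
    head_center_z = 1.6,     # nm, head centroid above the membrane
    head_tilt_deg = 0,       # tilt of the head long axis, about y
    head_roll_deg = 0,       # roll of the head about the hairpin axis (z)
    jitter_sd = 0.01         # nm, positional jitter
  )
}

#' Build a synthetic pseudo-monomer fixture
#'
#' The monomer follows the membrane convention used by the oligomer
#' builder: the hairpin long axis is parallel to the membrane normal
#' (z), the head domain sits above z = 0, and +x is the radial-outward
#' direction. With zero tilt and roll the head principal axes coincide
#' with the hairpin reference axes, so the downstream orientation angles
#' are tau = 0, chi = 90 and alpha = 0 by construction; `head_tilt_deg`
#' rotates the head about y (changing tau) and `head_roll_deg` about the
#' hairpin axis z (changing alpha).
#'
#' @param n_head_atoms,n_hairpin_atoms Approximate atom counts per
#'   domain (>= 3 each; the head grid rounds to multiples of 8).
#' @param geometry_params Named list overriding any default geometry
#'   value (see source of `default_monomer_geometry`).
#' @param rng_seed Seed for the positional jitter.
#' @return A `monomer_fixture`: atom table (`elety`, `resid`, `resname`,
#'   `element`, `x`, `y`, `z` in nm) with attributes `domain_map`
#'   (residue ids for head / hairpin / connector) and `interface`
#'   (tangential face atom indices for the surrogate potential).
#' @export
make_monomer_fixture <- function(n_head_atoms = 64L, n_hairpin_atoms = 40L,
                                 geometry_params = list(),
                                 rng_seed = 1L) {
  if (n_head_atoms < 3 || n_hairpin_atoms < 3)
    stop("need at least 3 atoms per domain")
  g <- default_monomer_geometry()
  unknown <- setdiff(names(geometry_params), names(g))
  if (length(unknown))
    stop("unknown geometry parameter(s): ", paste(unknown, collapse = ", "))
  g[names(geometry_params)] <- geometry_params

  atoms <- list()
  rid <- 0L
  add <- function(elety, resname, element, xyz, new_res = TRUE) {
    if (new_res) rid <<- rid + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = rid, resname = resname, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3])
    rid
  }

  # hairpin: two CA strands along z
  n_s <- max(2L, as.integer(ceiling(n_hairpin_atoms / 2)))
  zs <- seq(-g$hairpin_length, -0.2, length.out = n_s)
  hairpin_res <- integer(0)
  for (z in zs) hairpin_res <- c(hairpin_res,
                                 add("CA", "GLY", "C", c(-g$strand_sep / 2, 0, z)))
  for (z in zs) hairpin_res <- c(hairpin_res,
                                 add("CA", "GLY", "C", c(+g$strand_sep / 2, 0, z)))
  # tangential face sites: donors (N-H) on +y, acceptors (O) on -y
  zf <- seq(-g$hairpin_length + 0.4, -0.6, length.out = g$n_face_sites)
  for (z in zf) {
    r <- add("N", "GLY", "N", c(0, +g$face_offset, z))
    add("H", "GLY", "H", c(0, +g$face_offset + 0.101, z), new_res = FALSE)
    hairpin_res <- c(hairpin_res, r)
  }
  for (z in zf) hairpin_res <- c(hairpin_res,
                                 add("O", "GLY", "O", c(0, -g$face_offset, z)))
  # interface markers for the surrogate contact attraction
  if_plus <- add("IFP", "IFX", "C", c(0, +g$face_offset, -1.4))
  if_minus <- add("IFN", "IFX", "C", c(0, -g$face_offset, -1.4))
  hairpin_res <- c(hairpin_res, if_plus, if_minus)

  # connector: short strand bridging membrane surface and head
  connector_res <- integer(0)
  for (z in seq(0, 0.6, length.out = 4)) {
    connector_res <- c(connector_res, add("CA", "GLY", "C", c(0, 0.05, z)))
  }

  # head: symmetric ellipsoid surface grid, long axis along z, second
  # axis along y (so PH2 matches the hairpin's PB3 at zero roll)
  n_rows <- max(3L, as.integer(round(n_head_atoms / 8)))
  th <- (seq_len(n_rows) - 0.5) * pi / n_rows
  ph <- (seq_len(8L) - 0.5) * 2 * pi / 8
  a <- g$head_semiaxes[1]; b <- g$head_semiaxes[2]; cc <- g$head_semiaxes[3]
  shell <- do.call(rbind, lapply(th, function(t0)
    cbind(cc * sin(t0) * cos(ph), b * sin(t0) * sin(ph), a * cos(t0))))
  # solid cloud (outer + inner shell): interpenetrating heads then always
  # raise the soft-core repulsion, keeping the assembly-energy landscape
  # single-welled
  head_pts <- rbind(shell, 0.55 * shell)
  # face decorations: donor/acceptor plus one charged pair, and one
  # unpaired CB marking the "+tangential" face (the resulting third
  # moment makes the sign of the head's second principal axis
  # well-defined and equivariant, so the roll angle alpha is signed)
  deco <- rbind(
    c(0, +b * 0.9, 0.30), c(0, +b * 0.9 + 0.101, 0.30),  # N, its H
    c(0, -b * 0.9, 0.30),                                # O
    c(0, +b * 0.9, -0.30),                               # ARG NH1
    c(0, -b * 0.9, -0.30),                               # GLU OE1
    c(0, +b * 0.95, 0))                                  # CB (face marker)
  orient <- rot_z(g$head_roll_deg) %*% rot_y(g$head_tilt_deg)
  head_all <- rbind(head_pts, deco) %*% t(orient)
  head_all[, 3] <- head_all[, 3] + g$head_center_z
  head_res <- integer(0)
  for (i in seq_len(nrow(head_pts))) {
    head_res <- c(head_res, add("CA", "GLY", "C", head_all[i, ]))
  }
  i0 <- nrow(head_pts)
  r <- add("N", "GLY", "N", head_all[i0 + 1, ])
  add("H", "GLY", "H", head_all[i0 + 2, ], new_res = FALSE)
  head_res <- c(head_res, r)
  head_res <- c(head_res, add("O", "GLY", "O", head_all[i0 + 3, ]))
  head_res <- c(head_res, add("NH1", "ARG", "N", head_all[i0 + 4, ]))
  head_res <- c(head_res, add("OE1", "GLU", "O", head_all[i0 + 5, ]))
  head_res <- c(head_res, add("CB", "GLY", "C", head_all[i0 + 6, ]))

  df <- do.call(rbind, atoms)
  jit <- with_seed(rng_seed,
                   matrix(stats::rnorm(3 * nrow(df), 0, g$jitter_sd),
                          ncol = 3))
  df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] + jit

  check_domain <- function(resids, label) {
    m <- coords_matrix(df[df$resid %in% resids & df$element != "H", ])
    ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    if ((ev[1] - ev[2]) / max(ev[1], 1e-12) < 1e-9 ||
        (ev[2] - ev[3]) / max(ev[1], 1e-12) < 1e-9)
      stop(sprintf("degenerate %s domain: principal axes undefined", label))
  }
  check_domain(head_res, "head")
  check_domain(hairpin_res, "hairpin")

  structure(
    df,
    domain_map = list(head = unique(head_res),
                      hairpin = unique(hairpin_res),
                      connector = unique(connector_res)),
    interface = list(plus = which(df$elety == "IFP"),
                     minus = which(df$elety == "IFN")),
    geometry = g,
    class = c("monomer_fixture", "data.frame"))
}

#' @export
print.monomer_fixture <- function(x, ...) {
  dm <- attr(x, "domain_map")
  cat(sprintf(
    "<monomer_fixture> %d atoms; head %d res, hairpin %d res, connector %d res\n",
    nrow(x), length(dm$head), length(dm$hairpin), length(dm$connector)))
  invisible(x)
}

#' Domain partition of a fixture or model
#'
#' @param x A `monomer_fixture` (or model built from one).
#' @return List with `head`, `hairpin`, `connector` residue-id vectors.
#' @export
domain_partition <- function(x) {
  dm <- attr(x, "domain_map")
  if (is.null(dm)) stop("object carries no domain map")
  dm
}
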