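# Per-subunit structural observables on coordinate models: head-domain
# orientation angles (tau, chi, alpha) from domain principal axes,
# geometric hydrogen-bond and salt-bridge counts between neighboring
# subunits, and C-alpha RMSD.

#' Principal axes of a domain point cloud
#'
#' Eigenvectors of the positional covariance about the centroid, ordered
#' by descending eigenvalue. Sign convention: P1 is oriented toward
#' `up`, P2 toward `radial`, and P3 = P1 x P2 (right-handed).
#'
#' @param coords n x 3 matrix or data frame with `x`, `y`, `z` (>= 3
#'   non-collinear points).
#' @param up,radial Reference directions fixing the axis signs (membrane
#'   normal and radial-outward by default). When the cloud is skewed
#'   along P2, the sign of P2 follows the positive third moment instead
#'   of `radial`; this makes the frame equivariant under rigid rotation
#'   of the cloud (needed for well-defined signed rotation angles).
#' @return 3 x 3 matrix with columns `P1`, `P2`, `P3` and attribute
#'   `eigenvalues`. If only the second and third eigenvalues are
#'   degenerate (e.g. collinear points), `P1` is returned with `P2`,
#'   `P3` set to `NA` and a warning.
#' @export
principal_axes <- function(coords, up = c(0, 0, 1), radial = c(1, 0, 0)) {
  m <- coords_matrix(coords)
  if (nrow(m) < 3) stop("need at least 3 points")
  e <- eigen(stats::cov(m), symmetric = TRUE)
  ev <- e$values
  scale <- max(ev[1], 1e-12)
  if ((ev[1] - ev[2]) / scale < 1e-9)
    stop("degenerate principal axes: two leading eigenvalues coincide")
  p1 <- e$vectors[, 1]
  if (sum(p1 * up) < 0) p1 <- -p1
  out <- matrix(NA_real_, 3, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  out[, 1] <- p1
  if ((ev[2] - ev[3]) / scale < 1e-9) {
    warning("second and third principal axes degenerate; only P1 defined")
  } else {
    p2 <- e$vectors[, 2]
    ctr <- sweep(m, 2, colMeans(m))
    proj <- as.vector(ctr %*% p2)
    skew <- mean(proj^3)
    if (abs(skew) > 1e-3 * mean(proj^2)^1.5) {
      if (skew < 0) p2 <- -p2
    } else if (sum(p2 * radial) < 0) {
      p2 <- -p2
    }
    out[, 2] <- p2
    out[, 3] <- cross3(p1, p2)
  }
  attr(out, "eigenvalues") <- ev
  out
}

#' Head-domain orientation angles of one subunit
#'
#' With head principal axes PH1/PH2 and hairpin principal axes PB1/PB3:
#' tau = angle(PH1, PB1) describes the vertical movement of the head
#' along the membrane normal; chi = angle(PH1, PB3) its horizontal
#' movement in the membrane plane; alpha is the signed rotation of PH2
#' about PB1, measured from PB3 projected into the plane perpendicular
#' to PB1 (the zero reference).
#'
#' @param subunit Atom data frame of one subunit (as in models built
#'   from [make_monomer_fixture()]).
#' @param partition Domain partition (list with `head` and `hairpin`
#'   residue ids), e.g. [domain_partition()].
#' @param up,radial Sign references passed to [principal_axes()]; rotate
#'   them together with the model under rigid motion.
#' @return An `angle_triple`: `tau`, `chi` in `[0, 180]`, `alpha` in
#'   `(-180, 180]` (degrees) plus the axes `PH1`, `PH2`, `PB1`, `PB3`.
#' @export
head_angles <- function(subunit, partition, up = c(0, 0, 1),
                        radial = c(1, 0, 0)) {
  heavy <- subunit$element != "H"
  head <- subunit[heavy & subunit$resid %in% partition$head, ]
  hairpin <- subunit[heavy & subunit$resid %in% partition$hairpin, ]
  if (!nrow(head) || !nrow(hairpin))
    stop("partition does not match the subunit's residues")
  ph <- principal_axes(head, up = up, radial = radial)
  pb <- principal_axes(hairpin, up = up, radial = radial)
  if (any(is.na(ph)) || any(is.na(pb)))
    stop("degenerate domain axes: angles undefined")
  tau <- vec_angle(ph[, 1], pb[, 1])
  chi <- vec_angle(ph[, 1], pb[, 3])
  alpha <- signed_angle_about(pb[, 1], pb[, 3], ph[, 2])
  structure(
    list(tau = tau, chi = chi, alpha = alpha,
         PH1 = ph[, 1], PH2 = ph[, 2], PB1 = pb[, 1], PB3 = pb[, 3]),
    class = "angle_triple")
}

#' @export
print.angle_triple <- function(x, ...) {
  cat(sprintf("<angle_triple> tau %.2f, chi %.2f, alpha %.2f deg\n",
              x$tau, x$chi, x$alpha))
  invisible(x)
}

# Donor (N with attached or idealized H) and acceptor (O) inventories of
# an atom table. Hydrogens attach to a donor within the same residue at
# covalent range; when a structure carries no hydrogens at all, each
# donor gets one idealized hydrogen pointing away from its bonded heavy
# neighbors, and the result is flagged with a warning.
hb_sites <- function(df) {
  m <- coords_matrix(df)
  is_h <- df$element == "H"
  is_n <- df$element == "N"
  is_o <- df$element == "O"
  donors <- list()
  if (any(is_n)) {
    hs <- which(is_h)
    for (i in which(is_n)) {
      hpos <- NULL
      if (length(hs)) {
        same <- hs[df$resid[hs] == df$resid[i]]
        if (length(same)) {
          d <- sqrt(colSums((t(m[same, , drop = FALSE]) - m[i, ])^2))
          hit <- same[d <= 0.125]
          if (length(hit)) hpos <- m[hit, , drop = FALSE]
        }
      }
      if (is.null(hpos) && !any(is_h)) {
        heavy <- which(!is_h)
        d <- sqrt(colSums((t(m[heavy, , drop = FALSE]) - m[i, ])^2))
        bonded <- heavy[d > 1e-9 & d <= 0.17]
        dir <- if (length(bonded))
          m[i, ] - colMeans(m[bonded, , drop = FALSE])
        else c(0, 0, 1)
        if (sqrt(sum(dir^2)) < 1e-9) dir <- c(0, 0, 1)
        hpos <- matrix(m[i, ] + 0.101 * unit_vec(dir), 1)
        attr(donors, "idealized") <- TRUE
      }
      if (!is.null(hpos))
        donors[[length(donors) + 1L]] <- list(pos = m[i, ], h = hpos)
    }
  }
  list(donors = donors, acceptors = m[is_o, , drop = FALSE],
       idealized = isTRUE(attr(donors, "idealized")))
}

count_hb_directed <- function(sa, sb, r_max, angle_max) {
  if (!length(sa$donors) || !nrow(sb$acceptors)) return(0L)
  n <- 0L
  for (dn in sa$donors) {
    dv <- sweep(sb$acceptors, 2, dn$pos)
    dist <- sqrt(rowSums(dv^2))
    cand <- which(dist <= r_max & dist > 1e-6)
    for (j in cand) {
      # best hydrogen: smallest H-donor-acceptor angle
      angs <- apply(dn$h, 1, function(h)
        vec_angle(h - dn$pos, sb$acceptors[j, ] - dn$pos))
      if (min(angs) <= angle_max) n <- n + 1L
    }
  }
  n
}

#' Count geometric hydrogen bonds between two atom regions
#'
#' A bond is a donor/acceptor pair with donor-acceptor distance at most
#' `r_max` and hydrogen-donor-acceptor angle at most `angle_max` (the
#' convention of the trajectory-analysis ecosystem); each donor-acceptor
#' pair counts once. Both directions (donors of A to acceptors of B and
#' vice versa) are included.
#'
#' @param a,b Atom data frames (columns as in
#'   [make_monomer_fixture()]).
#' @param r_max Donor-acceptor distance cutoff, nm.
#' @param angle_max H-donor-acceptor angle cutoff, degrees.
#' @return Integer bond count (0 with a warning when a region has no
#'   donors or acceptors at all).
#' @export
count_hydrogen_bonds <- function(a, b, r_max = 0.35, angle_max = 30) {
  sa <- hb_sites(a); sb <- hb_sites(b)
  if ((!length(sa$donors) && !nrow(sa$acceptors)) ||
      (!length(sb$donors) && !nrow(sb$acceptors))) {
    warning("a region has no hydrogen-bond donors or acceptors")
    return(0L)
  }
  if (sa$idealized || sb$idealized)
    warning("no hydrogens present: idealized donor hydrogens were placed")
  count_hb_directed(sa, sb, r_max, angle_max) +
    count_hb_directed(sb, sa, r_max, angle_max)
}

# Charged-group inventory: basic side-chain nitrogens and acidic
# carboxylate oxygens, grouped per residue; termini (first-residue N,
# OXT) included.
charged_groups <- function(df, include_termini = TRUE) {
  basic_sel <- (df$resname == "ARG" & df$elety %in% c("NH1", "NH2", "NE")) |
    (df$resname == "LYS" & df$elety == "NZ")
  acidic_sel <- (df$resname == "ASP" & df$elety %in% c("OD1", "OD2")) |
    (df$resname == "GLU" & df$elety %in% c("OE1", "OE2"))
  if (include_termini) {
    basic_sel <- basic_sel | (df$resid == min(df$resid) & df$elety == "N")
    acidic_sel <- acidic_sel | df$elety == "OXT"
  }
  split_groups <- function(sel) {
    if (!any(sel)) return(list())
    sub <- df[sel, , drop = FALSE]
    lapply(split(seq_len(nrow(sub)), sub$resid),
           function(i) coords_matrix(sub[i, , drop = FALSE]))
  }
  list(basic = split_groups(basic_sel), acidic = split_groups(acidic_sel))
}

min_group_dist <- function(ga, gb) {
  d2 <- outer(rowSums(ga^2), rowSums(gb^2), "+") - 2 * ga %*% t(gb)
  sqrt(max(min(d2), 0))
}

#' Count salt bridges between two atom regions
#'
#' A salt bridge is an oppositely charged residue pair (Arg/Lys
#' side-chain nitrogens or the N-terminus vs Asp/Glu carboxylate oxygens
#' or the C-terminus) whose minimum heavy-atom distance is at most
#' `r_max`; each residue pair counts once.
#'
#' @inheritParams count_hydrogen_bonds
#' @param r_max Minimum heavy-atom distance cutoff, nm.
#' @param include_termini Count the charged termini as groups.
#' @return Integer count.
#' @export
count_salt_bridges <- function(a, b, r_max = 0.40, include_termini = TRUE) {
  ga <- charged_groups(a, include_termini)
  gb <- charged_groups(b, include_termini)
  n <- 0L
  for (x in ga$basic) for (y in gb$acidic)
    if (min_group_dist(x, y) <= r_max) n <- n + 1L
  for (x in ga$acidic) for (y in gb$basic)
    if (min_group_dist(x, y) <= r_max) n <- n + 1L
  n
}

#' Per-subunit neighbor interaction report
#'
#' For every adjacent subunit pair (cyclic for rings, chain otherwise)
#' counts hydrogen bonds between the hairpin domains (`HB_beta`),
#' hydrogen bonds between the head domains (`HB_head`) and salt bridges
#' between the head domains (`SB_head`); per-subunit totals sum over
#' both neighbors. For a list of coordinate frames a per-frame series
#' plus quartile summaries (boxplot convention: Q1, median, Q3) are
#' returned.
#'
#' @param model An [oligomer_model()] or list of models (frames).
#' @param partition Domain partition (see [domain_partition()]); taken
#'   from the model's monomer when omitted.
#' @param hb_r_max,hb_angle_max,sb_r_max Geometric cutoffs.
#' @return An `interaction_report` with `per_subunit` (data frame:
#'   frame, subunit, HB_beta, HB_head, SB_head) and `summary`.
#' @export
neighbor_interaction_report <- function(model, partition = NULL,
                                        hb_r_max = 0.35, hb_angle_max = 30,
                                        sb_r_max = 0.40) {
  frames <- if (inherits(model, "oligomer_model")) list(model) else model
  out <- list()
  for (fi in seq_along(frames)) {
    fm <- frames[[fi]]
    part <- partition %||%
      (if (!is.null(fm$monomer)) domain_partition(fm$monomer))
    if (is.null(part)) stop("a domain partition is required")
    pairs <- model_adjacency(fm)
    nsub <- fm$n
    counts <- matrix(0L, nsub, 3,
                     dimnames = list(NULL, c("HB_beta", "HB_head", "SB_head")))
    region <- function(k, dom) {
      df <- fm$subunits[[k]]
      df[df$resid %in% part[[dom]], , drop = FALSE]
    }
    for (pi in seq_len(nrow(pairs))) {
      i <- pairs[pi, 1]; j <- pairs[pi, 2]
      hb_b <- suppressWarnings(
        count_hydrogen_bonds(region(i, "hairpin"), region(j, "hairpin"),
                             hb_r_max, hb_angle_max))
      hb_h <- suppressWarnings(
        count_hydrogen_bonds(region(i, "head"), region(j, "head"),
                             hb_r_max, hb_angle_max))
      sb_h <- count_salt_bridges(region(i, "head"), region(j, "head"),
                                 sb_r_max)
      counts[i, ] <- counts[i, ] + c(hb_b, hb_h, sb_h)
      counts[j, ] <- counts[j, ] + c(hb_b, hb_h, sb_h)
    }
    out[[fi]] <- data.frame(frame = fi, subunit = seq_len(nsub), counts)
  }
  per <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(c("HB_beta", "HB_head", "SB_head"),
                                function(mcol) {
    v <- per[[mcol]]
    data.frame(metric = mcol, mean = mean(v),
               q1 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q3 = unname(stats::quantile(v, 0.75)))
  }))
  structure(list(per_subunit = per, summary = summ),
            class = "interaction_report")
}

#' @export
print.interaction_report <- function(x, ...) {
  cat("<interaction_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' C-alpha RMSD between a frame and a reference
#'
#' With `fit = TRUE` the frame is first superposed onto the reference by
#' the optimal least-squares rigid transform (Kabsch); with `fit =
#' FALSE` the direct RMSD is computed. Always `rmsd(fit) <= rmsd(raw)`.
#'
#' @param frame,reference Atom data frames (CA atoms are selected and
#'   must match in order and count) or plain n x 3 coordinate matrices.
#' @param fit Superpose before computing the deviation.
#' @return RMSD in nm.
#' @export
rmsd_ca <- function(frame, reference, fit = TRUE) {
  get_ca <- function(x) {
    if (is.matrix(x)) return(x)
    if (!is.null(x$elety) && any(x$elety == "CA"))
      return(coords_matrix(x[x$elety == "CA", , drop = FALSE]))
    coords_matrix(x)
  }
  p <- get_ca(frame); q <- get_ca(reference)
  if (nrow(p) != nrow(q)) stop("C-alpha atom counts differ")
  if (fit) {
    k <- kabsch(p, q)
    p <- sweep(sweep(p, 2, k$center_p) %*% k$rotation, 2, k$center_q, "+")
  }
  sqrt(mean(rowSums((p - q)^2)))
}
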