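# Structural metrics: principal axes, head angles, hydrogen bonds, salt
# bridges, interaction reports, RMSD.

test_that("principal axes order, orient, and detect degeneracy", {
  # line along z: P1 = z, transverse axes undefined
  line <- cbind(rep(0, 20), rep(0, 20), seq(0, 5, length.out = 20))
  expect_warning(ax <- principal_axes(line), "degenerate")
  expect_gt(abs(sum(ax[, 1] * c(0, 0, 1))), 1 - 1e-4)
  # axis-aligned ellipsoid cloud -> coordinate axes in order
  set.seed(7)
  ell <- cbind(rnorm(400, 0, 0.4), rnorm(400, 0, 1.0), rnorm(400, 0, 2.5))
  ax2 <- principal_axes(ell)
  expect_gt(abs(sum(ax2[, 1] * c(0, 0, 1))), 0.999)
  expect_gt(abs(sum(ax2[, 2] * c(0, 1, 0))), 0.999)
  expect_gt(abs(sum(ax2[, 3] * c(1, 0, 0))), 0.999)
  # rotated cloud: axes are the applied rotation of the unrotated axes
  R <- poremorph:::rot_axis(c(1, 1, 2), 35)
  ax3 <- principal_axes(ell %*% t(R), up = R %*% c(0, 0, 1),
                        radial = R %*% c(1, 0, 0))
  for (j in 1:3)
    expect_lt(min(sum((ax3[, j] - R %*% ax2[, j])^2),
                  sum((ax3[, j] + R %*% ax2[, j])^2)), 1e-4)
  # spherical cloud: leading axes degenerate -> error
  sph <- matrix(rnorm(3000), ncol = 3)
  ed <- eigen(cov(sph))
  sph_deg <- sph %*% ed$vectors %*% diag(1 / sqrt(ed$values))  # whitened
  expect_error(principal_axes(sph_deg), "degenerate")
  expect_error(principal_axes(cbind(1:2, 1:2, 1:2)), "at least 3")
})

test_that("head angles recover constructed tilts and rolls", {
  part <- domain_partition(make_monomer_fixture())
  m0 <- make_monomer_fixture(geometry_params = list(jitter_sd = 0))
  a0 <- head_angles(m0, part)
  expect_equal(a0$tau, 0, tolerance = 1e-6)
  expect_equal(a0$chi, 90, tolerance = 1e-6)
  expect_equal(a0$alpha, 0, tolerance = 1e-6)
  # tilt toward the membrane plane shows up in tau only
  m15 <- make_monomer_fixture(geometry_params = list(jitter_sd = 0,
                                                     head_tilt_deg = 15))
  a15 <- head_angles(m15, part)
  expect_equal(a15$tau, 15, tolerance = 0.5)
  # roll about the hairpin axis shows up in alpha, tau unchanged
  m25 <- make_monomer_fixture(geometry_params = list(jitter_sd = 0,
                                                     head_roll_deg = 25))
  a25 <- head_angles(m25, part)
  expect_equal(a25$alpha, 25, tolerance = 0.5)
  expect_equal(a25$tau, a0$tau, tolerance = 0.5)
})

test_that("alpha is additive under composed rolls (mod 360)", {
  part <- domain_partition(make_monomer_fixture())
  rolls <- c(20, 55, 140, -70)
  for (i in seq_along(rolls)) for (j in seq_along(rolls)) {
    mij <- make_monomer_fixture(
      geometry_params = list(jitter_sd = 0,
                             head_roll_deg = rolls[i] + rolls[j]))
    a <- head_angles(mij, part)
    want <- ((rolls[i] + rolls[j] + 180) %% 360) - 180
    expect_equal(((a$alpha - want + 180) %% 360) - 180, 0,
                 tolerance = 1e-6)
  }
})

test_that("angles and counts are invariant to global rigid motion", {
  mono <- make_monomer_fixture(geometry_params = list(head_roll_deg = 30,
                                                      head_tilt_deg = 10))
  part <- domain_partition(mono)
  ring <- build_ring(mono, 12, 4.2)
  rep0 <- neighbor_interaction_report(ring, part)
  a0 <- head_angles(ring$subunits[[1]], part)
  for (seed in 1:3) {
    tr <- random_rigid(model_atoms(ring), seed)
    moved <- ring
    moved$subunits <- lapply(ring$subunits, function(s)
      poremorph:::transform_atoms(s, tr$rotation, tr$shift))
    rep1 <- neighbor_interaction_report(moved, part)
    expect_identical(rep1$per_subunit, rep0$per_subunit)
    a1 <- head_angles(moved$subunits[[1]], part,
                      up = as.vector(tr$rotation %*% c(0, 0, 1)),
                      radial = as.vector(tr$rotation %*% c(1, 0, 0)))
    expect_equal(a1$tau, a0$tau, tolerance = 1e-6)
    expect_equal(a1$chi, a0$chi, tolerance = 1e-6)
    expect_equal(a1$alpha, a0$alpha, tolerance = 1e-6)
  }
})

test_that("hydrogen-bond counting follows the geometric criterion", {
  # two ideal strand fragments: four N-H...O bonds at 0.29 nm, collinear
  z <- seq(0, 2.1, by = 0.7)
  don <- atoms_df(rep(c("N", "H"), 4), rep(1:4, each = 2), "GLY",
                  rep(c("N", "H"), 4),
                  cbind(0, rep(c(0, 0.101), 4), rep(z, each = 2)))
  acc <- atoms_df(rep("O", 4), 5:8, "GLY", rep("O", 4),
                  cbind(0, 0.29, z))
  expect_equal(count_hydrogen_bonds(don, acc), 4L)
  # pulled apart to 0.50 nm: none
  acc_far <- acc; acc_far$y <- 0.50
  expect_equal(count_hydrogen_bonds(don, acc_far), 0L)
  # bent geometry beyond 30 degrees does not count
  acc_bent <- acc; acc_bent$y <- 0.29 * cos(pi / 4)
  acc_bent$x <- 0.29 * sin(pi / 4)
  expect_equal(count_hydrogen_bonds(don, acc_bent), 0L)
  # random fixtures match the all-pairs oracle
  set.seed(9)
  for (rep in 1:3) {
    n <- 14
    a <- atoms_df(rep(c("N", "H", "O"), n), rep(seq_len(n), each = 3),
                  "GLY", rep(c("N", "H", "O"), n),
                  matrix(runif(9 * n, 0, 1.6), ncol = 3))
    # attach H 0.101 nm from its N
    for (i in seq_len(n)) {
      k <- (i - 1) * 3 + 1
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      a[k + 1, c("x", "y", "z")] <- a[k, c("x", "y", "z")] + 0.101 * dirv
    }
    b <- a
    b$x <- b$x + runif(1, 0, 0.4)
    expect_equal(count_hydrogen_bonds(a, b), oracle_hb(a, b))
  }
  # region without donors or acceptors warns and returns 0
  carb <- atoms_df("CA", 1, "GLY", "C", cbind(0, 0, 0))
  expect_warning(n0 <- count_hydrogen_bonds(carb, acc), "donors")
  expect_equal(n0, 0L)
})

test_that("salt bridges pair opposite charges within the cutoff", {
  arg <- atoms_df("NH1", 1, "ARG", "N", cbind(0, 0, 0))
  glu <- atoms_df("OE1", 2, "GLU", "O", cbind(0.35, 0, 0))
  expect_equal(count_salt_bridges(arg, glu), 1L)
  glu_far <- glu; glu_far$x <- 0.45
  expect_equal(count_salt_bridges(arg, glu_far), 0L)
  # one count per residue pair even with several close atoms
  arg2 <- atoms_df(c("NH1", "NH2"), c(1, 1), "ARG", c("N", "N"),
                   rbind(c(0, 0, 0), c(0.05, 0, 0)))
  glu2 <- atoms_df(c("OE1", "OE2"), c(2, 2), "GLU", c("O", "O"),
                   rbind(c(0.3, 0, 0), c(0.33, 0, 0)))
  expect_equal(count_salt_bridges(arg2, glu2), 1L)
  # multi-pair fixture vs direct residue-pair enumeration
  set.seed(13)
  mk <- function(base_res, resname, elety) {
    atoms_df(rep(elety, 6), base_res + rep(1:6, each = 1), resname,
             substr(elety, 1, 1), matrix(runif(18, 0, 1.2), ncol = 3))
  }
  A <- mk(0, "ARG", "NH1")
  B <- mk(10, "GLU", "OE1")
  want <- 0L
  for (i in 1:6) for (j in 1:6) {
    d <- sqrt(sum((as.numeric(A[i, c("x", "y", "z")]) -
                     as.numeric(B[j, c("x", "y", "z")]))^2))
    if (d <= 0.40) want <- want + 1L
  }
  expect_equal(count_salt_bridges(A, B), want)
})

test_that("interaction reports respect topology and constructed counts", {
  mono <- make_monomer_fixture()
  part <- domain_partition(mono)
  # choose the ring radius so the four hairpin face sites sit exactly
  # 0.29 nm from the neighbor's acceptors -> 4 bonds per neighbor pair
  pair_no_dist <- function(R, n = 12) {
    ring <- suppressWarnings(build_ring(mono, n, R))
    s1 <- ring$subunits[[1]]; s2 <- ring$subunits[[2]]
    d1 <- s1[s1$elety == "N" & s1$resname == "GLY" &
               s1$resid %in% part$hairpin, ][1, ]
    zs <- abs(s2$z - d1$z)
    o2 <- s2[s2$elety == "O" & s2$resid %in% part$hairpin, ]
    min(sqrt((o2$x - d1$x)^2 + (o2$y - d1$y)^2 + (o2$z - d1$z)^2))
  }
  R <- uniroot(function(r) pair_no_dist(r) - 0.29, c(1.5, 6))$root
  ring <- suppressWarnings(build_ring(mono, 12, R))
  rep_ring <- neighbor_interaction_report(ring, part)
  hb_beta <- rep_ring$per_subunit$HB_beta
  expect_true(all(hb_beta == 8))  # 4 bonds to each of 2 neighbors
  # arc terminals have one neighbor -> half the interior count
  arc <- build_arc(ring, 6)
  rep_arc <- neighbor_interaction_report(arc, part)
  hb_arc <- rep_arc$per_subunit$HB_beta
  expect_equal(hb_arc[1], hb_arc[3] / 2)
  expect_equal(hb_arc[6], hb_arc[3] / 2)
  # far-apart subunits -> all zeros
  lin <- build_linear(mono, 3, 10)
  rep_lin <- neighbor_interaction_report(lin, part)
  expect_true(all(rep_lin$per_subunit[, c("HB_beta", "HB_head",
                                          "SB_head")] == 0))
  # multi-frame input yields per-frame series and quartile summaries
  rep_fr <- neighbor_interaction_report(list(ring, ring), part)
  expect_equal(sort(unique(rep_fr$per_subunit$frame)), 1:2)
  expect_true(all(c("q1", "median", "q3") %in% names(rep_fr$summary)))
})

test_that("C-alpha RMSD obeys its closed forms", {
  mono <- make_monomer_fixture()
  ca <- poremorph:::coords_matrix(mono[mono$elety == "CA", ])
  expect_equal(rmsd_ca(ca, ca), 0)
  shifted <- sweep(ca, 2, c(1, 0, 0), "+")
  expect_equal(rmsd_ca(shifted, ca, fit = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd_ca(shifted, ca, fit = FALSE), 1.0, tolerance = 1e-12)
  # random rotation + iid noise: fitted RMSD ~ sqrt(3) * sd
  set.seed(21)
  big <- matrix(rnorm(300 * 3, 0, 1.5), ncol = 3)
  R <- poremorph:::rot_axis(c(0.3, -1, 2), 77)
  noisy <- big %*% t(R) + matrix(rnorm(900, 0, 0.05), ncol = 3)
  got <- rmsd_ca(noisy, big, fit = TRUE)
  expect_equal(got, sqrt(3) * 0.05, tolerance = 0.05 * sqrt(3) * 0.05)
  expect_lte(rmsd_ca(noisy, big, fit = TRUE),
             rmsd_ca(noisy, big, fit = FALSE))
  expect_error(rmsd_ca(big[1:10, ], big), "counts differ")
})
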