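# Particle morphometry: heights, diameters, pore calls, fits, spacing,
# tracking, tallies.

test_that("pore-state classification applies the inclusive 2 nm rule", {
  expect_identical(classify_pore_state(-2.5), "pore")
  expect_identical(classify_pore_state(0.0), "pre_pore")
  expect_identical(classify_pore_state(-2.0), "pore")   # inclusive
  expect_identical(classify_pore_state(-1.9), "pre_pore")
  expect_error(classify_pore_state(-1, threshold = 0), "threshold")
  # monotone: deepening the lumen never flips pore -> pre_pore
  lum <- seq(0, -4, by = -0.05)
  states <- classify_pore_state(lum)
  expect_true(all(diff(states == "pore") >= 0))
})

test_that("a noiseless ring measures at its configured truth", {
  p <- particle_spec(shape = "ring", n_subunits = 30,
                     crest_diameter = 26.3, subunit_height = 3.4)
  rec <- measure_single(p)
  expect_identical(rec$shape_class, "ring")
  expect_equal(rec$max_height, 3.4, tolerance = 0.05)
  expect_equal(rec$crest_diameter, 26.3, tolerance = 0.5)
  expect_identical(rec$pore_state, "pre_pore")
  expect_true(rec$accepted)
})

test_that("pore calls at the threshold boundary are exact", {
  at <- particle_spec(shape = "ring", lumen_depth = -2.0)
  expect_identical(measure_single(at)$pore_state, "pore")
  below <- particle_spec(shape = "ring", lumen_depth = -1.9)
  rec <- measure_single(below)
  expect_identical(rec$pore_state, "pre_pore")
  expect_equal(rec$lumen_min, -1.9, tolerance = 0.05)
  open <- particle_spec(shape = "ring", lumen_depth = -3)
  expect_identical(measure_single(open)$pore_state, "pore")
})

test_that("an empty ROI is rejected", {
  t <- topograph(matrix(rnorm(64 * 64, 0, 0.1), 64, 64), 0.5)
  rec <- measure_particle(t, c(1, 64, 1, 64))
  expect_false(rec$accepted)
})

test_that("height measurement is invariant to translation and rotation", {
  p <- particle_spec(center = c(20, 20), shape = "arc", n_subunits = 27,
                     arc_span = 12)
  sc <- scene_spec(image_size = c(128, 128), pixel_size = 0.5,
                   particles = list(p))
  t1 <- render_scene(sc)
  r1 <- measure_particle(level_and_zero(t1), c(1, 80, 1, 80))
  # translate the particle within the scene
  p2 <- p; p2$center <- c(40, 38)
  t2 <- render_scene(scene_spec(image_size = c(128, 128), pixel_size = 0.5,
                                particles = list(p2)))
  r2 <- measure_particle(level_and_zero(t2), c(36, 116, 40, 120))
  # sub-pixel sampling shifts move the fitted apex by < 0.01 nm
  expect_equal(r1$max_height, r2$max_height, tolerance = 0.01)
  expect_equal(r1$crest_diameter, r2$crest_diameter, tolerance = 0.1)
  # 90-degree rotation of the scene = transposed/flipped heights
  t3 <- t1
  t3$heights <- t(t1$heights)[ncol(t1$heights):1, ]
  r3 <- measure_particle(level_and_zero(t3),
                         c(129 - 80, 128, 1, 80))
  expect_equal(r1$max_height, r3$max_height, tolerance = 1e-3)
})

test_that("shape classes separate rings, arcs and slits", {
  ring <- measure_single(particle_spec(shape = "ring", n_subunits = 30))
  arc <- measure_single(particle_spec(shape = "arc", n_subunits = 27,
                                      arc_span = 10))
  slit <- measure_single(particle_spec(shape = "slit", n_subunits = 28,
                                       arc_span = 7))
  expect_identical(ring$shape_class, "ring")
  expect_identical(arc$shape_class, "arc")
  expect_identical(slit$shape_class, "slit")
})

test_that("height profiles cross ring crests and pore lumens", {
  t0 <- suppressWarnings(level_and_zero(render_scene(
    scene_spec(image_size = c(64, 64), pixel_size = 0.5))))
  prof <- extract_height_profile(t0, c(4, 16), c(28, 16))
  expect_lt(max(abs(prof$height_nm)), 1e-6)
  expect_error(extract_height_profile(t0, c(-4, 16), c(28, 16)),
               "outside")
  p <- particle_spec(shape = "ring", n_subunits = 30,
                     crest_diameter = 26.3, subunit_height = 3.4,
                     lumen_depth = -3)
  sc <- single_particle_scene(p)
  t <- level_and_zero(render_scene(sc))
  cen <- sc$particles[[1]]$center
  prof <- extract_height_profile(t, cen - c(16, 0), cen + c(16, 0))
  mid <- abs(prof$distance_nm - 16) < 6
  expect_lte(min(prof$height_nm[mid]), -2.0)  # pore penetrates >= 2 nm
  crest_l <- prof$height_nm[prof$distance_nm < 10]
  crest_r <- prof$height_nm[prof$distance_nm > 22]
  expect_equal(max(crest_l), 3.4, tolerance = 0.2)
  d <- prof$distance_nm[prof$distance_nm > 22][which.max(crest_r)] -
    prof$distance_nm[which.max(crest_l)]
  expect_equal(d, 26.3, tolerance = 1)
})

test_that("gaussian fits recover closed forms and configured truths", {
  f <- fit_gaussian(c(1, 2, 3))
  expect_equal(f$mean, 2)
  expect_equal(f$sd, 1)
  set.seed(42)
  v <- rnorm(149, 26.3, 2.2)
  fml <- fit_gaussian(v)
  expect_lt(abs(fml$mean - 26.3), 3 * 2.2 / sqrt(149))
  v <- rnorm(3000, 26.3, 2.2)  # cross-method check on a dense sample
  fml <- fit_gaussian(v)
  fh <- fit_gaussian(v, method = "histogram")
  expect_equal(fh$mean, fml$mean, tolerance = 0.05 * fml$mean)
  expect_equal(fh$sd, fml$sd, tolerance = 0.05 * max(fml$sd, 1))
  expect_error(fit_gaussian(c(1, 2)), "at least 3")
  expect_error(fit_gaussian(rep(2, 10)), "constant")
})

test_that("subunit spacing conventions follow their formulas", {
  expect_equal(subunit_spacing(26.3, 28, "circumferential"),
               pi * 26.3 / 28, tolerance = 1e-12)
  expect_equal(subunit_spacing(26.3, 28, "circumferential"), 2.951,
               tolerance = 1e-3)
  expect_equal(subunit_spacing(26.3, 28, "literal"), 0.939,
               tolerance = 1e-3)
  # chord / circumferential -> 1 as N grows
  ratio <- function(n) subunit_spacing(10, n, "chord") /
    subunit_spacing(10, n, "circumferential")
  expect_true(all(diff(vapply(c(5, 10, 50, 200), ratio, numeric(1))) > 0))
  expect_equal(ratio(1000), 1, tolerance = 1e-5)
})

test_that("track linking classifies static, transient and crossing particles", {
  static <- lapply(1:5, function(i) data.frame(x = 10, y = 10))
  tr <- track_particles(static, link_radius = 5, mobility_threshold = 3)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$max_displacement, 0)
  expect_identical(tr[[1]]$mobility_class, "immobile")
  # transient particle present only in frames 3-4
  frames <- lapply(1:5, function(i) {
    if (i %in% 3:4) data.frame(x = c(10, 30), y = c(10, 30))
    else data.frame(x = 10, y = 10)
  })
  tr2 <- track_particles(frames, link_radius = 5, mobility_threshold = 3)
  cls <- vapply(tr2, `[[`, character(1), "mobility_class")
  app <- vapply(tr2, `[[`, numeric(1), "appearance")
  expect_identical(cls[app == 3], "mobile")
  expect_identical(cls[app == 1], "immobile")
  # two crossing particles: greedy links match the global-assignment
  # optimum computed by explicit enumeration
  fa <- list(data.frame(x = c(0, 10), y = c(0, 0)),
             data.frame(x = c(4, 6), y = c(0, 0)))
  tr3 <- track_particles(fa, link_radius = 6, mobility_threshold = 100)
  ends <- sort(vapply(tr3, function(t) utils::tail(t$positions$x, 1),
                      numeric(1)))
  # enumeration: assignments (0->4,10->6) cost 4+4=8 vs (0->6,10->4) 6+6=12
  expect_equal(ends, c(4, 6))
  expect_length(tr3, 2)
})

test_that("outcome tallies reproduce printed percentages", {
  tab <- tally_outcomes(rep(c("fusion", "nanodisc", "vesicle"), c(5, 7, 2)))
  expect_equal(tab$percent[tab$category == "fusion"], 35.7)
  expect_equal(tab$percent[tab$category == "nanodisc"], 50.0)
  expect_equal(tab$percent[tab$category == "vesicle"], 14.3)
  expect_lt(abs(sum(tab$percent) - 100), 0.1)
  expect_equal(tally_outcomes(rep("vesicle", 13))$percent, 100)
  expect_equal(tally_outcomes("fusion")$percent, 100)
  expect_error(tally_outcomes(character(0)), "at least one")
})
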