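# physical -> lattice mapping, presets and sweeps

test_that("physical parameters map to the published lattice sizes", {
  # 1.3 mm of DNA at b = 50 nm is 26000 bonds; a 2.0 um cell is H = 40
  phys <- physical_parameters(contour_length_um = 1300, kuhn_nm = 50,
                              cell_length_um = 2.0, cell_width_um = 0.5)
  sc <- to_lattice(phys, model = "bare", topology = "closed")
  expect_equal(sc$walk_length, 26000L)
  expect_equal(unname(unclass(sc$box)), c(11L, 11L, 41L))
  expect_equal(unname(sc$box[3]) - 1L, 40L)  # H = 40, the Fig-3 reference
  expect_false(sc$self_avoiding)

  # genome in bp: 4.02 Mbp * 0.34 nm/bp ~ 1.37 mm (the rounded 1.3 mm is
  # accepted in presets rather than recomputed)
  phys2 <- physical_parameters(genome_bp = 4.02e6)
  expect_equal(phys2$contour_length_um, 4.02e6 * 0.34 / 1000)

  expect_error(to_lattice(physical_parameters(contour_length_um = 1300,
                                              cell_width_um = 0.02),
                          model = "bare"), "extent")
})

test_that("scale consistency: doubling lengths and the bond leaves the spec", {
  p1 <- physical_parameters(contour_length_um = 100, kuhn_nm = 50,
                            cell_length_um = 1, cell_width_um = 0.5)
  p2 <- physical_parameters(contour_length_um = 200, kuhn_nm = 100,
                            cell_length_um = 2, cell_width_um = 1)
  s1 <- to_lattice(p1, "bare"); s2 <- to_lattice(p2, "bare")
  expect_equal(s1$walk_length, s2$walk_length)
  expect_equal(unclass(s1$box), unclass(s2$box))
})

test_that("ensemble sweeps preserve their defining invariants", {
  phys <- physical_parameters(contour_length_um = 1300, blob_d_nm = 50,
                              n_blobs = 2000, cell_length_um = 2,
                              cell_width_um = 0.5)
  # ensemble (i): N d^3 constant => N / (box length)^3 constant
  sw1 <- ensemble_sweep(phys, "constant_density", c(30, 40, 50, 60, 75))
  ratios <- vapply(sw1, function(s) s$walk_length / (s$box[3] - 1)^3, 1)
  expect_lt(max(ratios) / min(ratios), 1.1)  # within rounding
  # endpoint cross-check: (154 / 27)^3 ~ 24578 / 128 (within rounding of the
  # published integer endpoints)
  expect_equal((154 / 27)^3, 24578 / 128, tolerance = 0.05)

  # ensemble (ii): N constant at 2000
  sw2 <- ensemble_sweep(phys, "constant_blob_number", c(13, 20, 32))
  expect_true(all(vapply(sw2, `[[`, 1L, "walk_length") == 2000L))

  # cell-length sweep at fixed cross-section: H = 33..165
  sw3 <- ensemble_sweep(phys, "cell_length", c(33, 66, 165))
  expect_equal(vapply(sw3, function(s) s$box[3] - 1L, 1L),
               c(`33` = 33L, `66` = 66L, `165` = 165L))
  w <- vapply(sw3, function(s) s$box[1], 1L)
  expect_equal(unname(unique(w)), w[[1]])

  # blob-number sweep spans the linear range
  sw4 <- ensemble_sweep(phys, "blob_number", c(200, 2000))
  expect_equal(unname(vapply(sw4, `[[`, 1L, "walk_length")), c(200L, 2000L))

  # infeasible points are dropped with a warning, the sweep continues
  expect_warning(sw5 <- ensemble_sweep(phys, "constant_blob_number",
                                       c(2000, 20)), "infeasible")
  expect_equal(length(sw5), 1L)
})

test_that("presets encode the simulated experiments", {
  m <- preset("caulo_mutant_ter3")
  expect_equal(m$pin_beads, c(1L, 1501L))
  expect_equal(m$segment_targets, c(1500L, 500L))
  expect_equal(m$walk_length, 2000L)
  expect_true(m$self_avoiding)

  b <- preset("caulo_bare_bridge_4b")
  expect_equal(b$walk_length, 13000L)
  expect_equal(b$pin_sites[, 3], c(4L, 36L))
  expect_false(b$self_avoiding)
  expect_equal(preset("caulo_bare_bridge_wall")$pin_sites[, 3], c(0L, 40L))

  wt <- preset("caulo_blob_wt")
  expect_equal(wt$segment_targets, c(1000L, 1000L))
  free <- preset("caulo_blob_free_ter")
  expect_equal(free$pin_beads, 1L)

  two <- preset("ecoli_two_chromosomes")
  expect_equal(two$topology, "open")
  expect_equal(sum(two$segment_targets), 4001L)  # twice as long (+ ter bond)

  d <- preset("ecoli_daughter_strand")
  expect_length(d$extra_chains, 1L)
  expect_equal(d$extra_chains[[1]]$walk_length, 1000L)
  expect_equal(d$extra_chains[[1]]$pin_sites[, 3], c(33L, 33L))  # midplane

  perp <- preset("ecoli_midcell_perpendicular")
  expect_equal(perp$pin_sites[1, 3], perp$pin_sites[2, 3])  # same height
  expect_false(perp$pin_sites[1, 1] == perp$pin_sites[2, 1])

  expect_error(preset("caulo_blob_imaginary"), "unknown preset")
  for (nm in preset_names()) expect_s3_class(preset(nm), "scenario_spec")
})

test_that("every preset builds, samples briefly and keeps its pins", {
  set.seed(47)
  for (nm in preset_names()) {
    spec <- preset(nm)
    # scale chromosome-length presets down for the smoke run
    if (!is.null(spec$segment_targets)) {
      spec$segment_targets <- pmax(spec$segment_targets %/% 10L, 1L)
      spec$walk_length <- sum(spec$segment_targets)
    } else spec$walk_length <- spec$walk_length %/% 10L
    if (!is.null(spec$extra_chains))
      spec$extra_chains[[1]]$walk_length <-
        spec$extra_chains[[1]]$walk_length %/% 10L
    x <- build_scenario(spec)
    e <- mos_sample(x, n_samples = 5, burn_in = 500, thinning = 100)
    last <- e$samples[[5]]
    chains <- if (inherits(x, "multi_chain")) x$chains else list(x)
    for (k in seq_along(chains)) {
      w2 <- lattice_walk(last[[k]], chains[[k]]$topology,
                         chains[[k]]$self_avoiding, chains[[k]]$pins,
                         chains[[k]]$box)
      expect_identical(unname(pin_sites(w2)), unname(pin_sites(chains[[k]])))
    }
  }
})

test_that("scenario specs round-trip through the run manifest", {
  spec <- preset("caulo_blob_wt")
  cfg <- nucleoidwalk:::resolve_config(sampler_config(10), spec$walk_length)
  man <- run_manifest(spec, cfg, list(), seed = 5)
  expect_equal(man$scenario$segment_targets, c(1000L, 1000L))
  expect_equal(man$sampler$thinning, 2000)
  expect_equal(man$sampler$burn_in, 2e5)
})

test_that("run_scenario produces a coherent report end to end", {
  spec <- preset("caulo_mutant_ter3")
  spec$segment_targets <- c(150L, 50L)
  spec$walk_length <- 200L
  r <- run_scenario(spec, n_samples = 50, burn_in = 1e5, thinning = 500,
                    seed = 77)
  expect_s3_class(r$profile, "axial_profile")
  expect_s3_class(r$report, "linearity_report")
  expect_equal(r$report$positive_fraction, 0.75)
  expect_equal(r$report$negative_fraction, 0.25)
  expect_gt(r$counters$acceptance_rate, 0)
})

test_that("midcell ter pinning demixes the two chromosome halves", {
  # scaled pre-division geometry: one open chain of twice the chromosome
  # length, ori ends at opposite poles; pinning the ter midpoint at
  # midcell lowers the axial overlap of the two halves vs end pins only
  box <- lattice_box(7, 7, 17)
  staircase_sites <- nucleoidwalk:::staircase_sites
  score <- function(mid_pinned, seed) {
    set.seed(seed)
    sites <- staircase_sites(c(3, 3, 1), c(3, 3, 15))
    pins <- if (mid_pinned) c(1L, 8L, 15L) else c(1L, 15L)
    w <- lattice_walk(sites, "open", TRUE, pins = pins, box = box)
    w <- grow_walk(w, segment_targets = if (mid_pinned) c(101, 101) else 202)
    e <- mos_sample(w, n_samples = 150, burn_in = 4e5, thinning = 2000)
    demixing_score(e, split = 102L)
  }
  s_pinned <- mean(vapply(1:3, function(k) score(TRUE, 800 + k), 1))
  s_free <- mean(vapply(1:3, function(k) score(FALSE, 900 + k), 1))
  expect_lt(s_pinned, s_free)
  expect_gte(s_pinned, 0); expect_lte(s_free, 1)
})
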