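# profiles, linear reference, RMS, plateau onset, correlation fractions,
# densities, demixing

make_profile <- function(mean_z, topology = "open", pins = NULL, nz = 41,
                         std_z = rep(1, length(mean_z))) {
  s <- seq_along(mean_z) - 1
  p <- nucleoidwalk:::new_axial_profile(s, mean_z, std_z, 1000L)
  attr(p, "topology") <- topology
  if (!is.null(pins)) attr(p, "pin_s") <- pins
  attr(p, "box") <- lattice_box(11, 11, nz)
  p
}

test_that("axial profiles average ensembles with exact pins", {
  w <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)))
  p1 <- axial_profile(w)
  expect_equal(p1$mean_z, c(0, 1, 1))
  expect_equal(p1$std_z, c(0, 0, 0))

  box <- lattice_box(4, 4, 8)
  set.seed(19)
  w0 <- grow_to_length(rbind(c(1, 1, 1), c(1, 1, 5)), box, 26, "closed")
  e <- mos_sample(w0, n_samples = 400, burn_in = 1e5, thinning = 60, seed = 2)
  p <- axial_profile(e)
  expect_equal(nrow(p), 26)
  expect_equal(p$std_z[1], 0)         # ori pinned
  expect_equal(p$mean_z[1], 1)
  expect_true(all(p$std_z[-c(1, w0$pins[2])] > 0))
  # the z-record variant gives the same moments
  ez <- mos_sample(w0, n_samples = 400, burn_in = 1e5, thinning = 60,
                   seed = 2, record = "z")
  pz <- axial_profile(ez)
  expect_equal(pz$mean_z, p$mean_z)
  expect_equal(pz$std_z, p$std_z)

  bad <- list(lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1))),
              lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))))
  expect_error(axial_profile(bad), "differ in length")
})

test_that("the linear reference interpolates and tents", {
  expect_equal(linear_reference(0, 4, 36, 100), 4)
  expect_equal(linear_reference(50, 4, 36, 100), 20)
  expect_equal(linear_reference(c(0, 100), 4, 36, 100), c(4, 36))
  # closed chromosome: tent over the two arms, midheight on the return arm
  expect_equal(linear_reference(150, 0, 40, 200, s_ter = 100), 20)
  expect_equal(linear_reference(100, 0, 40, 200, s_ter = 100), 40)
  expect_error(linear_reference(-1, 0, 1, 10), "range")
})

test_that("rms_from_linear has its closed forms and reflection symmetry", {
  L <- 400
  lin <- make_profile(seq(0, 40, length.out = L + 1), pins = c(0L, L))
  expect_equal(rms_from_linear(lin, 0, 40), 0)

  # constant mid-profile vs 0 -> 40 ramp: discrete closed form
  # mean over s of (20 - 40 s/L)^2 = 1600 * (1 + 2/L) / 12
  const <- make_profile(rep(20, L + 1), pins = c(0L, L))
  expect_equal(rms_from_linear(const, 0, 40),
               40 * sqrt((1 + 2 / L) / 12), tolerance = 1e-12)
  # converges to H / sqrt(12) = 11.547 for long chains
  expect_equal(rms_from_linear(const, 0, 40), 40 / sqrt(12), tolerance = 3e-3)

  # reflection z -> (nz-1) - z with reflected anchors leaves the RMS alone
  set.seed(23)
  prof <- make_profile(runif(101, 0, 40), pins = c(0L, 100L))
  refl <- make_profile(40 - prof$mean_z, pins = c(0L, 100L))
  expect_equal(rms_from_linear(prof, 4, 36), rms_from_linear(refl, 36, 4))
})

test_that("plateau onset finds the first midplane contact", {
  expect_equal(plateau_onset(make_profile(rep(20, 11)), 0.5), 0)
  # exactly linear 0 -> 40: first grid point with |z - 20| <= 0.5
  L <- 400
  lin <- make_profile(seq(0, 40, length.out = L + 1))
  expect_equal(plateau_onset(lin, 0.5) / L, 0.4875)
  expect_true(is.na(plateau_onset(make_profile(rep(1, 11)), 0.5)))
  expect_error(plateau_onset(make_profile(rep(1, 11)), -1), "tol")
})

test_that("correlation-sign fractions track the arm split", {
  expect_equal(
    correlation_sign_fractions(make_profile(0:40), segment_breaks = 0),
    c(positive_fraction = 1, negative_fraction = 0))
  # symmetric closed tent: 0.5 / 0.5
  tent <- make_profile(c(seq(0, 40, by = 0.5), seq(39.5, 0.5, by = -0.5)),
                       topology = "closed", pins = c(0L, 80L))
  expect_equal(unname(correlation_sign_fractions(tent)), c(0.5, 0.5))
  # 75/25 arm split
  tent2 <- make_profile(c(seq(0, 37.5, length.out = 151),
                          seq(38, 0.25, length.out = 49)),
                        topology = "closed", pins = c(0L, 150L))
  expect_equal(unname(correlation_sign_fractions(tent2)), c(0.75, 0.25))
  expect_error(
    correlation_sign_fractions(make_profile(0:40),
                               segment_breaks = c(0, 40)),
    NA)
  expect_error(
    correlation_sign_fractions(make_profile(0:40), segment_breaks = 40),
    "length < 2")
})

test_that("occupation density sums to the bead count with unit pins", {
  box <- lattice_box(3, 3, 3)
  w <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), box = box)
  d <- radial_density(w)
  expect_equal(sum(d), 3)
  expect_equal(d[1, 1, ], c(1, 1, 1))

  set.seed(29)
  w0 <- grow_to_length(rbind(c(1, 1, 0), c(1, 1, 2)), box, 8, "closed")
  e <- mos_sample(w0, n_samples = 300, burn_in = 5000, thinning = 20, seed = 4)
  de <- radial_density(e)
  expect_equal(sum(de), 8, tolerance = 1e-12)
  expect_equal(de[2, 2, 1], 1)  # pinned ori site always occupied
  # matches the streaming density from mos_profile
  p <- mos_profile(w0, n_samples = 300, burn_in = 5000, thinning = 20,
                   seed = 4, density = TRUE)
  expect_equal(attr(p, "density"), de, tolerance = 1e-12)
})

test_that("density from sampling matches the enumeration oracle", {
  box <- lattice_box(3, 3, 3)
  pins <- list(`1` = c(1, 1, 0), `3` = c(1, 1, 2))
  en <- enumerate_walks(6, box = box, pins = pins, topology = "closed",
                        self_avoiding = FALSE, density = TRUE)
  ex <- exact_statistics(en)
  w0 <- lattice_walk(en$walks[[1]], "closed", FALSE, pins = c(1L, 3L),
                     box = box)
  n <- 20000
  e <- mos_sample(w0, n_samples = n, burn_in = 5000, thinning = 25, seed = 8)
  de <- radial_density(e)
  # sites can be multiply occupied (non-SAW), so bound the absolute error
  # at a generous multiple of the 1/sqrt(n) sampling scale
  expect_lt(max(abs(de - ex$density)), 6 / sqrt(n))
  expect_equal(sum(de), sum(ex$density), tolerance = 1e-12)
})

test_that("demixing scores are 0 for disjoint and 1 for identical", {
  box <- lattice_box(3, 3, 6)
  a <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1)), box = box)
  b <- lattice_walk(rbind(c(0, 0, 4), c(0, 0, 5)), box = box)
  mc <- multi_chain(list(a, b), mutual_exclusion = FALSE)
  ens <- structure(list(template = mc,
                        samples = list(list(a$sites, b$sites))),
                   class = "walk_ensemble")
  expect_equal(demixing_score(ens), 0)
  mc2 <- multi_chain(list(a, a), mutual_exclusion = FALSE)
  ens2 <- structure(list(template = mc2,
                         samples = list(list(a$sites, a$sites))),
                    class = "walk_ensemble")
  expect_equal(demixing_score(ens2), 1)
  # single double-length walk split into halves
  w <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3)),
                    box = box)
  ens3 <- structure(list(template = w, samples = list(list(w$sites))),
                    class = "walk_ensemble")
  expect_equal(demixing_score(ens3, split = 2), 0)
})
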