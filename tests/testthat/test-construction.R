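# minimal loops, staircase bridges and hook growth

test_that("minimal loops through two pins are minimal closed SAWs", {
  box <- lattice_box(3, 3, 3)
  w <- minimal_loop(rbind(c(0, 0, 0), c(0, 0, 2)), box)
  expect_equal(walk_length(w), 6L)
  expect_valid_walk(w)
  expect_true(is_self_avoiding(w))
  expect_equal(unname(pin_sites(w)), rbind(c(0L, 0L, 0L), c(0L, 0L, 2L)))
  # minimality: no closed SAW of 4 bonds passes through both pins
  en4 <- enumerate_walks(4, box = box,
                         pins = list(`1` = c(0, 0, 0), `3` = c(0, 0, 2)),
                         topology = "closed")
  expect_equal(en4$count, 0)
  en6 <- enumerate_walks(6, box = box,
                         pins = list(`1` = c(0, 0, 0), `3` = c(0, 0, 2)),
                         topology = "closed")
  expect_gt(en6$count, 0)

  # long collinear pins: 2 * 32 + 2 bonds
  big <- lattice_box(11, 11, 41)
  w2 <- minimal_loop(rbind(c(5, 5, 4), c(5, 5, 36)), big)
  expect_equal(walk_length(w2), 66L)
  expect_valid_walk(w2)

  # adjacent pins: the unit square
  w3 <- minimal_loop(rbind(c(0, 0, 0), c(0, 0, 1)), box)
  expect_equal(walk_length(w3), 4L)

  # non-collinear pins: 2 * manhattan
  w4 <- minimal_loop(rbind(c(0, 0, 0), c(1, 1, 2)), lattice_box(4, 4, 4))
  expect_equal(walk_length(w4), 8L)
  expect_valid_walk(w4)

  expect_error(minimal_loop(rbind(c(0, 0, 0), c(0, 0, 5)), box), "outside")
  expect_error(minimal_loop(rbind(c(0, 0, 0), c(0, 0, 1)),
                            lattice_box(1, 1, 3)), "thin")
})

test_that("single-pin loop (free ter) is a unit square through the pin", {
  w <- minimal_loop(c(2, 2, 2), lattice_box(5, 5, 5))
  expect_equal(walk_length(w), 4L)
  expect_equal(w$pins, 1L)
  expect_equal(w$sites[1, ], c(2L, 2L, 2L))
})

test_that("hook insertion adds exactly two bonds and honours exclusion", {
  # unit square in a 2x2x1 slab: every one of the 16 bond/direction
  # proposals is blocked (in-plane sites occupied or outside; no z room)
  slab <- lattice_box(2, 2, 1)
  sq <- lattice_walk(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     "closed", self_avoiding = TRUE, box = slab)
  for (bond in 1:4) for (dir in 1:4) {
    r <- hook_step(sq, bond, dir)
    expect_false(r$accepted)
    expect_identical(r$walk$sites, sq$sites)
  }
  # the same square in 2x2x2: hooks into the free z=1 plane are accepted
  box2 <- lattice_box(2, 2, 2)
  sq2 <- lattice_walk(sq$sites, "closed", self_avoiding = TRUE, box = box2)
  acc <- 0
  for (bond in 1:4) for (dir in 1:4) {
    r <- hook_step(sq2, bond, dir)
    if (r$accepted) {
      acc <- acc + 1
      expect_equal(walk_length(r$walk), 6L)
      expect_valid_walk(r$walk)
    }
  }
  expect_equal(acc, 4)  # one free perpendicular direction (+z) per bond
  # non-self-avoiding walks may hook into occupied sites
  sq3 <- lattice_walk(sq$sites, "closed", self_avoiding = FALSE, box = slab)
  r3 <- hook_step(sq3, 1, 1)
  expect_true(r3$accepted)
  expect_equal(walk_length(r3$walk), 6L)
})

test_that("growth reaches the target, keeps pins, and respects parity", {
  box <- lattice_box(5, 5, 5)
  set.seed(11)
  w <- grow_to_length(rbind(c(0, 0, 0), c(0, 0, 2)), box, 10, "closed")
  expect_equal(walk_length(w), 10L)
  expect_valid_walk(w)
  expect_true(is_self_avoiding(w))
  expect_equal(unname(pin_sites(w)), rbind(c(0L, 0L, 0L), c(0L, 0L, 2L)))

  seed_loop <- minimal_loop(rbind(c(0, 0, 0), c(0, 0, 2)), box)
  expect_warning(g <- grow_walk(minimal_loop(c(1, 1, 1), box),
                                target_length = 7), "parity")
  expect_equal(walk_length(g), 8L)

  # every intermediate state of growth is a valid SAW
  w2 <- minimal_loop(c(2, 2, 2), box)
  repeat {
    r <- hook_step(w2)
    if (r$accepted) {
      expect_valid_walk(r$walk)
      expect_equal(walk_length(r$walk), walk_length(w2) + 2L)
      w2 <- r$walk
    }
    if (walk_length(w2) >= 20) break
  }

  # jammed growth errors out with diagnostics
  slab <- lattice_box(2, 2, 1)
  sq <- lattice_walk(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     "closed", self_avoiding = TRUE, box = slab, pins = 1L)
  expect_error(grow_walk(sq, target_length = 8, max_attempts = 500),
               "jammed")
})

test_that("segment growth controls the chromosome arm lengths", {
  box <- lattice_box(9, 9, 21)
  set.seed(13)
  seed_loop <- minimal_loop(rbind(c(4, 4, 2), c(4, 4, 18)), box)
  w <- grow_walk(seed_loop, segment_targets = c(150, 50))
  expect_equal(walk_length(w), 200L)
  expect_equal(w$pins, c(1L, 151L))
  expect_equal(unname(pin_sites(w)), rbind(c(4L, 4L, 2L), c(4L, 4L, 18L)))
  expect_valid_walk(w)
})

test_that("open bridges achieve exactly the lengths allowed by parity", {
  box <- lattice_box(4, 4, 4)
  from <- c(0, 0, 0); to <- c(0, 0, 2)
  set.seed(17)
  for (target in c(2, 4, 6, 8)) {
    w <- grow_to_length(rbind(from, to), box, target, "open",
                        self_avoiding = FALSE)
    expect_equal(walk_length(w), target)
    expect_equal(w$sites[1, ], as.integer(from))
    expect_equal(w$sites[n_beads(w), ], as.integer(to))
    expect_valid_walk(w)
  }
  # achievable lengths are |delta| + 2k: enumeration finds no odd-length one
  expect_equal(enumerate_walks(3, box = box,
                               pins = list(`1` = from, `4` = to),
                               topology = "open",
                               self_avoiding = FALSE)$count, 0)
  expect_gt(enumerate_walks(4, box = box,
                            pins = list(`1` = from, `5` = to),
                            topology = "open",
                            self_avoiding = FALSE)$count, 0)
})
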