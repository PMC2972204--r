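# the MOS move set: bead flips, crankshafts, 3-D crankshaft rebridging

test_that("bead flips move corner beads across their unit square", {
  # straight bead: inapplicable
  straight <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
  r <- apply_move(straight, 2, "bead_flip")
  expect_false(r$outcome$accepted)
  expect_equal(r$outcome$reason, "inapplicable")

  # corner bead of an L-walk flips to the opposite corner
  L <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)))
  r <- apply_move(L, 2, "bead_flip")
  expect_true(r$outcome$accepted)
  expect_equal(r$walk$sites[2, ], c(1L, 0L, 0L))

  # symbol effect: the two adjacent step symbols swap, 2122 -> 2212
  w <- decode_walk(c(0, 0, 0), symbols_from_digits("2122"))
  r <- apply_move(w, 3, "bead_flip")
  expect_true(r$outcome$accepted)
  expect_equal(digits_from_symbols(encode_walk(r$walk)), "2212")

  # pinned corners may not flip; occupied targets reject
  Lp <- lattice_walk(L$sites, pins = 2L)
  expect_equal(apply_move(Lp, 2, "bead_flip")$outcome$reason, "pin")
  hook <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 0),
                             c(2, 0, 0)), self_avoiding = TRUE,
                       box = lattice_box(5, 5, 5))
  r <- apply_move(hook, 2, "bead_flip")  # target (1,0,0) occupied by bead 4
  expect_equal(r$outcome$reason, "occupancy")
  tight <- lattice_walk(L$sites, box = lattice_box(2, 1, 2))
  r <- apply_move(tight, 2, "bead_flip")
  expect_true(r$outcome$accepted)  # (1,0,0) inside 2x1x2
})

test_that("crankshafts rotate U-segments onto the brute-force rotation set", {
  # U-segment +z,+x,-z about the x chord: targets are -z, +y, -y placements
  u <- lattice_walk(rbind(c(1, 1, 1), c(1, 1, 2), c(2, 1, 2), c(2, 1, 1)),
                    box = lattice_box(5, 5, 5))
  got <- list()
  for (b in 1:3) {
    r <- apply_move(u, 1, "crankshaft", branch = b)
    expect_true(r$outcome$accepted)
    got[[b]] <- r$walk$sites[2:3, ]
  }
  # brute force: all rigid placements of the two interior beads at unit
  # distance perpendicular to the chord, excluding the current one
  expected <- list()
  for (v in list(c(0, 0, -1), c(0, 1, 0), c(0, -1, 0))) {
    expected[[length(expected) + 1]] <-
      rbind(c(1, 1, 1) + v, c(2, 1, 1) + v)
  }
  key <- function(m) paste(m, collapse = ",")
  expect_setequal(vapply(got, key, ""), vapply(expected, key, ""))

  # a U hugging the wall with every rotation target outside is rejected
  wall <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 0)),
                       box = lattice_box(2, 1, 2))
  for (b in 1:3) {
    r <- apply_move(wall, 1, "crankshaft", branch = b)
    expect_false(r$outcome$accepted)
    expect_equal(r$outcome$reason, "volume")
  }

  # non-U windows are inapplicable
  s <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3)))
  expect_equal(apply_move(s, 1, "crankshaft")$outcome$reason, "inapplicable")
})

test_that("crankshaft moves succeed where bead flips are blocked", {
  # middle bead of a U cannot flip (both steps along the same axes pattern
  # blocks the flip target), but the crankshaft rotates the whole arc
  u <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 0),
                          c(2, 0, 0), c(2, 0, 1)),
                    self_avoiding = TRUE, box = lattice_box(5, 5, 5))
  flip <- apply_move(u, 2, "bead_flip")
  expect_equal(flip$outcome$reason, "occupancy")
  crank <- apply_move(u, 1, "crankshaft", branch = 2)
  expect_true(crank$outcome$accepted)
})

test_that("3-D crankshaft introduces new step symbols atomically", {
  # a walk confined to the xz-plane acquires a +-y step in one rebridge
  planar <- decode_walk(c(2, 2, 2), c("+z", "+x", "-z"),
                        box = lattice_box(6, 6, 6))
  expect_false(any(grepl("y", encode_walk(planar))))
  found_y <- FALSE
  for (b in 1:20) {
    r <- apply_move(planar, 1, "crankshaft3d", branch = b)
    if (r$outcome$accepted && any(grepl("y", encode_walk(r$walk))))
      found_y <- TRUE
  }
  expect_true(found_y)

  # atomicity: a rejected rebridge leaves the walk byte-identical
  cramped <- lattice_walk(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1),
                                c(0, 1, 0)),
                          "closed", self_avoiding = TRUE,
                          box = lattice_box(1, 2, 2))
  for (i in 1:4) for (b in 1:20) {
    r <- apply_move(cramped, i, "crankshaft3d", branch = b)
    if (!r$outcome$accepted) expect_identical(r$walk$sites, cramped$sites)
    else expect_valid_walk(r$walk)
  }
})

test_that("the full move set reaches states bead flips alone cannot", {
  # the unit square pinned at one bead: flips alone never leave its plane,
  # the crankshaft moves rotate it through all three plane orientations
  box <- lattice_box(3, 3, 3)
  sq <- lattice_walk(rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1), c(1, 2, 1)),
                     "closed", self_avoiding = TRUE, pins = 1L, box = box)
  flips_only <- new.env(parent = emptyenv())
  frontier <- list(sq$sites)
  assign(walk_key(sq$sites), TRUE, envir = flips_only)
  while (length(frontier) > 0) {
    nxt <- list()
    for (m in frontier) {
      w <- lattice_walk(m, "closed", TRUE, pins = 1L, box = box)
      for (i in seq_len(n_beads(w))) {
        r <- apply_move(w, i, "bead_flip")
        if (r$outcome$accepted) {
          k <- walk_key(r$walk$sites)
          if (!exists(k, envir = flips_only)) {
            assign(k, TRUE, envir = flips_only)
            nxt[[length(nxt) + 1]] <- r$walk$sites
          }
        }
      }
    }
    frontier <- nxt
  }
  all_moves <- bfs_reachable(sq$sites, "closed", 1L, box, TRUE)
  expect_gt(length(all_moves), length(ls(flips_only)))
  # and the full set reaches every enumerated state of this instance
  en <- enumerate_walks(4, box = box, pins = list(`1` = c(1, 1, 1)),
                        topology = "closed")
  expect_setequal(all_moves, vapply(en$walks, walk_key, ""))
})

test_that("moves conserve length, topology, pins and containment", {
  set.seed(31)
  box <- lattice_box(4, 4, 6)
  w <- grow_to_length(rbind(c(1, 1, 0), c(1, 1, 4)), box, 20, "closed")
  for (rep in 1:400) {
    i <- sample(n_beads(w), 1)
    kind <- sample(MOVE_KINDS, 1)
    r <- apply_move(w, i, kind)
    if (r$outcome$accepted) {
      w <- r$walk
      expect_valid_walk(w)
      expect_equal(walk_length(w), 20L)
      expect_equal(unname(pin_sites(w)),
                   rbind(c(1L, 1L, 0L), c(1L, 1L, 4L)))
    } else {
      expect_identical(r$walk$sites, w$sites)
    }
  }
})
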