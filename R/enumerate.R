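# Exhaustive ground truth on tiny instances: enumerate every walk satisfying
# the constraints and compute exact statistics, the oracle against which the
# MOS sampler is validated.

#' Enumerate all walks satisfying the constraints
#'
#' Depth-first enumeration (deterministic lexicographic step order
#' +x,-x,+y,-y,+z,-z) of every lattice walk of the given length through the
#' pinned sites, inside the box, optionally self-avoiding. Branches are
#' pruned by the Manhattan-distance and parity bounds to the next pinned
#' bead (closed walks treat the closure as a pin at the start site).
#' Feasible only for short chains -- exact enumeration of self-avoiding
#' walks stops being practical around 20-30 bonds -- which is exactly what
#' makes it the ground truth for sampler validation.
#'
#' @param n_bonds walk length in bonds.
#' @param box a [lattice_box()] or `NULL` for the unbounded lattice
#'   (requires a start).
#' @param pins named list mapping 1-based bead indices to sites, e.g.
#'   `list("1" = c(0,0,0), "3" = c(0,0,2))`; bead 1 must be pinned unless
#'   `start` is given (or, bounded and unpinned, all start sites are
#'   aggregated).
#' @param topology `"open"` or `"closed"`.
#' @param self_avoiding logical.
#' @param start shorthand for pinning bead 1.
#' @param cap feasibility guard: error out if more than this many walks are
#'   found.
#' @param return_walks keep the walks themselves (list of site matrices);
#'   turn off to stream only the statistics through memory.
#' @param density accumulate the exact per-site visit counts (bounded boxes
#'   only).
#' @return a `walk_enumeration`: list with `count`, `walks`, `sum_z`,
#'   `sumsq_z`, `density`, plus the instance description.
#' @export
enumerate_walks <- function(n_bonds, box = NULL, pins = NULL,
                            topology = c("open", "closed"),
                            self_avoiding = TRUE, start = NULL,
                            cap = 1e7, return_walks = TRUE, density = FALSE) {
  topology <- match.arg(topology)
  closed <- topology == "closed"
  pin_idx <- integer(0); pin_sites <- matrix(integer(0), 0, 3)
  if (!is.null(pins)) {
    pin_idx <- as.integer(names(pins))
    ord <- order(pin_idx)
    pin_idx <- pin_idx[ord]
    pin_sites <- as_site_matrix(do.call(rbind, pins[ord]))
  }
  if (!is.null(start)) {
    if (length(pin_idx) == 0 || pin_idx[1] != 1L) {
      pin_idx <- c(1L, pin_idx)
      pin_sites <- rbind(as.integer(start), pin_sites)
    }
  }
  run_one <- function(idx, sites) {
    enumerate_cpp(box_dim_for(box), sites, idx - 1L, n_bonds, closed,
                  self_avoiding, cap, return_walks, density)
  }
  if (length(pin_idx) == 0 || pin_idx[1] != 1L) {
    if (is.null(box))
      stop("unbounded enumeration requires a pinned first bead or a start")
    # aggregate over all start sites of the box
    grid <- as.matrix(expand.grid(x = 0:(box[1] - 1), y = 0:(box[2] - 1),
                                  z = 0:(box[3] - 1)))
    agg <- NULL
    for (k in seq_len(nrow(grid))) {
      r <- run_one(c(1L, pin_idx), rbind(grid[k, ], pin_sites))
      if (is.null(agg)) agg <- r
      else {
        agg$count <- agg$count + r$count
        agg$sum_z <- agg$sum_z + r$sum_z
        agg$sumsq_z <- agg$sumsq_z + r$sumsq_z
        if (!is.null(agg$density)) agg$density <- agg$density + r$density
        agg$walks <- c(agg$walks, r$walks)
      }
      if (agg$count > cap) stop("enumeration exceeds cap")
    }
    res <- agg
  } else {
    res <- run_one(pin_idx, pin_sites)
  }
  structure(list(count = res$count, walks = res$walks,
                 sum_z = res$sum_z, sumsq_z = res$sumsq_z,
                 density = if (!is.null(res$density))
                   array(res$density, dim = unname(unclass(box))) else NULL,
                 n_bonds = n_bonds, topology = topology,
                 self_avoiding = self_avoiding, box = box,
                 pins = stats::setNames(lapply(seq_len(nrow(pin_sites)),
                                               function(i) pin_sites[i, ]),
                                        pin_idx)),
            class = "walk_enumeration")
}

#' @export
print.walk_enumeration <- function(x, ...) {
  cat(sprintf("<walk_enumeration: %s %s%s, %d bonds, %.0f walks>\n",
              x$topology, if (x$self_avoiding) "SAW" else "walk",
              if (is.null(x$box)) " (unbounded)" else "",
              x$n_bonds, x$count))
  invisible(x)
}

#' Exact statistics of an enumerated ensemble
#'
#' Unweighted averages over the complete walk set: the exact mean/sd axial
#' profile and (when accumulated) the exact per-site occupation
#' probability. The density sums over sites to the number of beads per
#' walk.
#'
#' @param enumeration a `walk_enumeration` from [enumerate_walks()].
#' @return list with `profile` (an [axial_profile]) and `density` (3-D
#'   array or `NULL`).
#' @export
exact_statistics <- function(enumeration) {
  if (enumeration$count == 0) stop("empty enumeration: no walk satisfies the constraints")
  n <- enumeration$count
  m <- enumeration$sum_z / n
  v <- pmax(enumeration$sumsq_z / n - m^2, 0)
  prof <- new_axial_profile(seq_along(m) - 1L, m, sqrt(v), n)
  attr(prof, "topology") <- enumeration$topology
  attr(prof, "pin_s") <- as.integer(names(enumeration$pins)) - 1L
  attr(prof, "box") <- enumeration$box
  list(profile = prof,
       density = if (!is.null(enumeration$density))
         enumeration$density / n else NULL)
}

#' Canonical state key of a walk
#'
#' A compact string identifying a configuration (start site plus symbol
#' string); used to match sampled states against an enumerated state list.
#' @param sites site matrix or [lattice_walk()].
#' @export
walk_key <- function(sites) {
  if (inherits(sites, "lattice_walk")) sites <- sites$sites
  paste(sites, collapse = ",")
}
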