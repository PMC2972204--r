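# Initial-configuration construction: minimal rectangular loops through the
# pinned loci, canonical staircase bridges, and stochastic hook-insertion
# growth to target length.

# canonical monotone staircase between two sites, axes in x, y, z order
staircase_sites <- function(from, to) {
  from <- as.integer(from); to <- as.integer(to)
  path <- list(from)
  cur <- from
  for (ax in 1:3) {
    step <- sign(to[ax] - cur[ax])
    while (cur[ax] != to[ax]) {
      cur[ax] <- cur[ax] + step
      path[[length(path) + 1]] <- cur
    }
  }
  do.call(rbind, path)
}

# first axis (x < y < z order) with room for a unit lateral detour at `site`,
# excluding axes in `excl`; returns a signed unit 3-vector
lateral_dir <- function(site, box, excl = integer(0)) {
  for (ax in setdiff(1:3, excl)) {
    if (is.null(box) || site[ax] + 1 < box[ax]) {
      d <- c(0L, 0L, 0L); d[ax] <- 1L; return(d)
    }
    if (site[ax] - 1 >= 0) {
      d <- c(0L, 0L, 0L); d[ax] <- -1L; return(d)
    }
  }
  stop("box too thin to host the loop (no lateral direction with room)")
}

#' Minimal rectangular loop through the pinned sites
#'
#' Constructs the shortest closed self-avoiding walk through one or two
#' pinned sites, the deterministic seed configuration for hook growth. With
#' two pins the loop consists of two monotone staircases (axes taken in
#' x, y, z order on both legs); if the pins are collinear the return leg
#' detours one lattice unit in the first lateral direction with room. The
#' loop length is `2 * manhattan + 2` for collinear pins and `2 * manhattan`
#' otherwise. With a single pin (a chromosome anchored only at *ori*) the
#' loop is a unit square through that site.
#'
#' @param pins one site (3-vector) or two sites (2 x 3 matrix / list of two
#'   3-vectors).
#' @param box a [lattice_box()] or `NULL`.
#' @param self_avoiding flag stored on the returned walk (the loop itself is
#'   always self-avoiding).
#' @return a closed [lattice_walk()] whose first bead is the first pin; with
#'   two pins the second pin's bead index is `manhattan + 1`.
#' @export
minimal_loop <- function(pins, box = NULL, self_avoiding = TRUE) {
  if (is.list(pins)) pins <- do.call(rbind, pins)
  pins <- as_site_matrix(pins)
  if (!is.null(box) && !all(box_contains(box, pins)))
    stop("pins outside box")
  if (nrow(pins) == 1) {
    p <- pins[1, ]
    d1 <- lateral_dir(p, box)
    d2 <- lateral_dir(p, box, excl = which(d1 != 0))
    sites <- rbind(p, p + d1, p + d1 + d2, p + d2)
    return(lattice_walk(sites, "closed", self_avoiding, pins = 1L, box = box))
  }
  if (nrow(pins) != 2) stop("minimal_loop takes one or two pins")
  p <- pins[1, ]; q <- pins[2, ]
  dd <- q - p
  if (all(dd == 0)) stop("the two pins coincide")
  if (sum(dd != 0) == 1) {
    u <- lateral_dir(p, box, excl = which(dd != 0))
    fwd <- staircase_sites(p, q)
    back <- staircase_sites(q + u, p + u)
    sites <- rbind(fwd, back)
  } else {
    fwd <- staircase_sites(p, q)
    back <- staircase_sites(q, p)
    sites <- rbind(fwd, back[-c(1, nrow(back)), , drop = FALSE])
  }
  # drop the duplicated closure bead when present
  if (all(sites[nrow(sites), ] == sites[1, ]))
    sites <- sites[-nrow(sites), , drop = FALSE]
  w <- lattice_walk(sites, "closed", self_avoiding,
                    pins = c(1L, nrow(fwd)), box = box)
  w
}

#' Canonical open bridge between two endpoints
#'
#' The monotone staircase (axes in x, y, z order) between the endpoints,
#' pinned at both ends: the seed configuration for growing open bridges.
#'
#' @param from,to endpoint sites.
#' @inheritParams minimal_loop
#' @export
bridge_init <- function(from, to, box = NULL, self_avoiding = FALSE) {
  sites <- staircase_sites(from, to)
  if (!is.null(box) && !all(box_contains(box, sites)))
    stop("staircase between the pins leaves the box")
  lattice_walk(sites, "open", self_avoiding,
               pins = c(1L, nrow(sites)), box = box)
}

#' One hook-insertion growth attempt
#'
#' Deletes a bond and replaces it by a three-bond detour displaced one unit
#' perpendicular to the bond, adding two beads. The attempt is rejected if a
#' detour site lies outside the box or (self-avoiding walks) is already
#' occupied; rejection leaves the walk unchanged.
#'
#' @param walk a [lattice_walk()].
#' @param bond 1-based bond index, or `NULL` to pick uniformly at random.
#' @param dir perpendicular direction id 1..4 (the two non-bond axes in
#'   x < y < z order, each `+` then `-`), or `NULL` for uniform random.
#' @return list with `accepted`, `reason` (`NA`, `"volume"` or
#'   `"occupancy"`) and the (possibly grown) `walk`.
#' @export
hook_step <- function(walk, bond = NULL, dir = NULL) {
  pinned <- seq_len(n_beads(walk)) %in% walk$pins
  res <- hook_step_cpp(walk$sites, walk$topology == "closed", pinned,
                       box_dim_for(walk$box), walk$self_avoiding,
                       if (is.null(bond)) -1L else as.integer(bond) - 1L,
                       if (is.null(dir)) -1L else as.integer(dir) - 1L)
  new_walk <- walk
  if (res$code == 0) {
    new_walk$sites <- res$sites
    new_walk$pins <- which(res$pinned)
  }
  list(accepted = res$code == 0,
       reason = c(NA, NA, NA, "volume", "occupancy")[res$code + 1],
       walk = new_walk)
}

box_dim_for <- function(box) {
  if (is.null(box)) c(-1L, -1L, -1L) else as.integer(unclass(box))
}

#' Grow a walk to target length by hook insertion
#'
#' Repeats random hook insertions (see [hook_step()]) until every contour
#' segment delimited by pinned beads has reached its target bond count.
#' Growth adds exactly two bonds per accepted hook, so each segment target
#' must exceed the current segment length by an even number; pinned beads
#' never move, and the chromosomal-arm lengths (e.g. the *ori*--*ter* and
#' *ter*--*ori* segments) are controlled individually through
#' `segment_targets`.
#'
#' @param walk a [lattice_walk()] (typically from [minimal_loop()] or
#'   [bridge_init()]).
#' @param target_length total target bond count; used when the walk has a
#'   single growth segment. For multi-segment walks give `segment_targets`.
#' @param segment_targets integer vector of per-segment bond targets, in
#'   contour order (closed walks: segments between consecutive pins starting
#'   at the first pin; open walks: endpoints count as boundaries).
#' @param max_attempts give up (with an error) after this many attempted
#'   hooks.
#' @param blocked optional n x 3 matrix of lattice sites treated as occupied
#'   (other chains in a shared volume).
#' @return the grown [lattice_walk()]; attempt counts in attribute
#'   `"growth"`.
#' @export
grow_walk <- function(walk, target_length = NULL, segment_targets = NULL,
                      max_attempts = 1e7, blocked = NULL) {
  if (is.null(segment_targets)) {
    if (is.null(target_length)) stop("give target_length or segment_targets")
    segment_targets <- default_segment_targets(walk, target_length)
  }
  pinned <- seq_len(n_beads(walk)) %in% walk$pins
  res <- grow_segments_cpp(walk$sites, walk$topology == "closed", pinned,
                           box_dim_for(walk$box), walk$self_avoiding,
                           as.integer(segment_targets), max_attempts,
                           if (is.null(blocked)) matrix(integer(0), 0, 3)
                           else as_site_matrix(blocked))
  out <- walk
  out$sites <- res$sites
  out$pins <- which(res$pinned)
  attr(out, "growth") <- list(attempts = res$attempts, rejected = res$rejected)
  out
}

# Distribute a total bond target over the walk's growth segments: a single
# segment takes it all (parity-adjusted +1 with a warning); two segments
# (a two-pin closed chromosome) default to equal arms, shifted by one bond
# if an arm's parity demands it.
default_segment_targets <- function(walk, target_length) {
  nseg <- n_growth_segments(walk)
  arms <- current_segment_lengths(walk)
  if (target_length < sum(arms)) stop("target shorter than current walk")
  if (nseg == 1) {
    if ((target_length - arms) %% 2 != 0) {
      warning(sprintf(
        "target %d has wrong parity (growth adds 2 bonds); using %d",
        target_length, target_length + 1))
      target_length <- target_length + 1
    }
    return(target_length)
  }
  if (nseg == 2) {
    if (target_length %% 2 != 0)
      stop("two-segment walks need an even total length")
    t1 <- target_length %/% 2
    if ((t1 - arms[1]) %% 2 != 0) t1 <- t1 - 1L
    tg <- c(t1, target_length - t1)
    if (any(tg < arms))
      stop("target_length too short for the seed configuration")
    return(tg)
  }
  stop("walk has ", nseg, " growth segments; give segment_targets")
}

n_growth_segments <- function(walk) {
  k <- length(walk$pins)
  if (walk$topology == "closed") max(k, 1L) else {
    interior <- setdiff(walk$pins, c(1L, n_beads(walk)))
    length(interior) + 1L
  }
}

#' Build and grow a constrained walk in one call
#'
#' Convenience wrapper: seed a minimal loop (closed topology) or canonical
#' staircase bridge (open topology) through the pins, then hook-grow to the
#' target length.
#'
#' @param pins one or two sites (closed) / exactly two endpoint sites (open).
#' @param box a [lattice_box()].
#' @param target_length target bond count.
#' @param topology `"closed"` or `"open"`.
#' @param self_avoiding logical.
#' @param segment_targets optional per-arm bond counts (see [grow_walk()]).
#' @param max_attempts growth attempt budget.
#' @export
grow_to_length <- function(pins, box, target_length,
                           topology = c("closed", "open"),
                           self_avoiding = TRUE, segment_targets = NULL,
                           max_attempts = 1e7) {
  topology <- match.arg(topology)
  if (is.list(pins)) pins <- do.call(rbind, pins)
  pins <- as_site_matrix(pins)
  seed_walk <- if (topology == "closed") {
    minimal_loop(pins, box, self_avoiding)
  } else {
    if (nrow(pins) != 2) stop("open bridges need exactly two endpoint pins")
    bridge_init(pins[1, ], pins[2, ], box, self_avoiding)
  }
  grow_walk(seed_walk, target_length = target_length,
            segment_targets = segment_targets, max_attempts = max_attempts)
}

current_segment_lengths <- function(walk) {
  n <- n_beads(walk)
  if (walk$topology == "closed") {
    if (length(walk$pins) <= 1) return(walk_length(walk))
    b <- sort(walk$pins)
    diff(c(b, b[1] + n))
  } else {
    b <- sort(union(walk$pins, c(1L, n)))
    diff(b)
  }
}
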