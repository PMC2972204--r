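# Single-move interface to the MOS move set. The sampler applies the same
# compiled kernels in bulk; these wrappers expose one proposal at a time for
# inspection and testing.

MOVE_KINDS <- c("bead_flip", "crankshaft", "crankshaft3d")
REJECT_REASONS <- c("inapplicable", "pin", "volume", "occupancy")

#' Apply one Monte-Carlo move proposal to a walk
#'
#' The three move kinds of the Madras-Orlitsky-Shepp set:
#'
#' * `bead_flip`: a 90-degree corner bead jumps to the diagonally opposite
#'   corner of its unit square; the two adjacent step symbols swap.
#' * `crankshaft`: the two interior beads of a 3-bond U-shaped segment
#'   (steps a, b, -a with a perpendicular to b) rotate about the segment's
#'   chord into one of the 3 alternative perpendicular orientations.
#' * `crankshaft3d`: an atomic rebridging of a 3-bond window (beads
#'   i..i+3): the interior is replaced by one of the alternative 3-step
#'   lattice paths between the window's fixed endpoints, chosen uniformly.
#'   This composite step can introduce step symbols absent from the current
#'   walk (e.g. give a planar walk a +y bond), which the two elementary
#'   moves alone cannot always do; all constraint checks apply to the final
#'   state, all-or-nothing.
#'
#' Every kernel is symmetric (the number of alternatives depends only on
#' quantities the move conserves), so acceptance-by-constraint yields the
#' uniform distribution over admissible configurations.
#'
#' @param walk a [lattice_walk()].
#' @param i 1-based bead index (for `bead_flip`) or window start (for the
#'   crankshafts: beads `i..i+3`, wrapping on closed walks).
#' @param kind one of `"bead_flip"`, `"crankshaft"`, `"crankshaft3d"`.
#' @param branch deterministic alternative id (1-based) instead of a random
#'   choice; `NULL` picks uniformly.
#' @return list with `walk` (updated on acceptance) and `outcome`: a list
#'   `accepted`, `move_kind`, `site_index`, `reason` (`NA` when accepted,
#'   otherwise `"inapplicable"`, `"pin"`, `"volume"` or `"occupancy"`).
#' @export
apply_move <- function(walk, i, kind = MOVE_KINDS, branch = NULL) {
  kind <- match.arg(kind)
  pinned <- seq_len(n_beads(walk)) %in% walk$pins
  res <- apply_move_cpp(walk$sites, walk$topology == "closed", pinned,
                        box_dim_for(walk$box), walk$self_avoiding,
                        as.integer(i) - 1L, match(kind, MOVE_KINDS) - 1L,
                        if (is.null(branch)) -1L else as.integer(branch) - 1L)
  out <- walk
  out$sites <- res$sites
  list(walk = out,
       outcome = list(accepted = res$code == 0, move_kind = kind,
                      site_index = as.integer(i),
                      reason = if (res$code == 0) NA_character_
                               else REJECT_REASONS[res$code]))
}

#' All states reachable from a walk in one accepted move
#'
#' Enumerates every accepted outcome of every move kind at every index
#' (deduplicated). Used to explore the move graph on small instances, e.g.
#' to check by breadth-first search that the move set connects the whole
#' constraint-satisfying state space.
#'
#' @param walk a [lattice_walk()].
#' @return list of site matrices.
#' @export
move_neighbors <- function(walk) {
  pinned <- seq_len(n_beads(walk)) %in% walk$pins
  nb <- move_neighbors_cpp(walk$sites, walk$topology == "closed", pinned,
                           box_dim_for(walk$box), walk$self_avoiding)
  keys <- vapply(nb, function(m) paste(m, collapse = ","), "")
  nb[!duplicated(keys)]
}
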