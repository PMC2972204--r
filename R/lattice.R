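# Core geometric types: confining box, lattice walks, symbol encoding.

STEP_SYMBOLS <- c("+x", "-x", "+y", "-y", "+z", "-z")
STEP_VECTORS <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
                       ncol = 3, byrow = TRUE,
                       dimnames = list(STEP_SYMBOLS, c("x", "y", "z")))

#' Confining lattice box
#'
#' The cellular volume, discretised as the set of integer sites
#' \code{{0..nx-1} x {0..ny-1} x {0..nz-1}}. The z axis is the cell axis
#' (pole to pole), so a cell of length `H` bond units has `nz = H + 1` site
#' rows, with the wall-adjacent rows at `z = 0` and `z = nz - 1`.
#'
#' @param nx,ny,nz positive integer extents (number of sites per axis).
#' @return an object of class `lattice_box`.
#' @examples
#' b <- lattice_box(3, 3, 3)
#' box_contains(b, c(0, 0, 0))
#' box_contains(b, c(3, 0, 0))
#' @export
lattice_box <- function(nx, ny, nz) {
  dims <- c(nx = nx, ny = ny, nz = nz)
  if (any(dims != round(dims)) || any(dims < 1))
    stop("box extents must be positive integers")
  structure(as.integer(dims), names = names(dims), class = "lattice_box")
}

#' @export
print.lattice_box <- function(x, ...) {
  cat(sprintf("<lattice_box %d x %d x %d (%d sites)>\n",
              x[1], x[2], x[3], prod(x)))
  invisible(x)
}

#' Test whether sites lie inside a box
#'
#' @param box a [lattice_box()].
#' @param sites an integer 3-vector or an n x 3 matrix of sites.
#' @return a logical vector, one entry per site.
#' @export
box_contains <- function(box, sites) {
  stopifnot(inherits(box, "lattice_box"))
  sites <- as_site_matrix(sites)
  sites[, 1] >= 0 & sites[, 1] < box[1] &
    sites[, 2] >= 0 & sites[, 2] < box[2] &
    sites[, 3] >= 0 & sites[, 3] < box[3]
}

as_site_matrix <- function(sites) {
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 3, byrow = TRUE)
  if (ncol(sites) != 3) stop("sites must have 3 columns (x, y, z)")
  storage.mode(sites) <- "integer"
  dimnames(sites) <- NULL
  sites
}

#' Lattice walk configuration
#'
#' An ordered sequence of lattice sites representing the chromosome. Open
#' walks store `n_bonds + 1` beads; closed walks store one bead per bond, the
#' closure bond (last bead back to the first) being implicit. Bead `i`
#' corresponds to contour coordinate `s = i - 1` (bonds from the first bead),
#' so for a chromosome the first bead is *ori* and `s` runs along the
#' chromosomal map. Pinned beads (e.g. *ori*, *ter*) are given as bead
#' indices; their sites are fixed under all sampling moves.
#'
#' @param sites n x 3 integer matrix of bead positions (0-based coordinates).
#' @param topology `"open"` or `"closed"`.
#' @param self_avoiding logical; if `TRUE` all beads must occupy distinct
#'   sites and sampling enforces excluded volume.
#' @param pins integer vector of pinned bead indices (1-based).
#' @param box a [lattice_box()] or `NULL` for an unbounded lattice.
#' @param validate check all invariants (bond validity, containment, pins,
#'   self-avoidance) on construction.
#' @return an object of class `lattice_walk`.
#' @export
lattice_walk <- function(sites, topology = c("open", "closed"),
                         self_avoiding = FALSE, pins = integer(0),
                         box = NULL, validate = TRUE) {
  topology <- match.arg(topology)
  sites <- as_site_matrix(sites)
  pins <- sort(unique(as.integer(pins)))
  w <- structure(list(sites = sites, topology = topology,
                      self_avoiding = isTRUE(self_avoiding),
                      pins = pins, box = box),
                 class = "lattice_walk")
  if (validate) validate_walk(w)
  w
}

#' Number of beads of a walk
#' @param walk a [lattice_walk()].
#' @export
n_beads <- function(walk) nrow(walk$sites)

#' Walk length in bonds
#'
#' Open walks have one bond fewer than beads; closed walks have one bond per
#' bead (the closure bond is implicit).
#' @param walk a [lattice_walk()].
#' @export
walk_length <- function(walk) {
  if (walk$topology == "closed") nrow(walk$sites) else nrow(walk$sites) - 1L
}

#' Sites of the pinned beads
#' @param walk a [lattice_walk()].
#' @return a matrix with one row per pin, rownames = bead index.
#' @export
pin_sites <- function(walk) {
  m <- walk$sites[walk$pins, , drop = FALSE]
  rownames(m) <- walk$pins
  m
}

walk_steps <- function(walk) {
  s <- walk$sites
  d <- diff(s)
  if (walk$topology == "closed") d <- rbind(d, s[1, ] - s[nrow(s), ])
  d
}

#' Validate all invariants of a walk
#'
#' Checks bond validity (consecutive beads differ by one unit step, including
#' the closure bond of closed walks), box containment, pin-index range and,
#' when the walk is flagged self-avoiding, distinctness of all sites.
#'
#' @param walk a [lattice_walk()].
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_walk <- function(walk) {
  n <- n_beads(walk)
  if (n < 1) stop("walk must have at least one bead")
  if (walk$topology == "closed" && n < 4)
    stop("closed walks need at least 4 beads")
  if (n > 1) {
    d <- walk_steps(walk)
    if (any(rowSums(abs(d)) != 1))
      stop("invalid walk: consecutive sites must differ by one unit step")
  }
  if (length(walk$pins) > 0 &&
      (min(walk$pins) < 1 || max(walk$pins) > n))
    stop("pin index out of range")
  if (!is.null(walk$box) && !all(box_contains(walk$box, walk$sites)))
    stop("walk leaves the confining box")
  if (walk$self_avoiding && !is_self_avoiding(walk))
    stop("walk flagged self-avoiding but visits a site twice")
  invisible(TRUE)
}

#' Is a walk self-avoiding?
#'
#' `TRUE` iff no lattice site is visited twice. The implicit closure of a
#' closed walk is exempt (the first bead is stored once).
#' @param walk a [lattice_walk()].
#' @export
is_self_avoiding <- function(walk) {
  anyDuplicated(walk$sites) == 0
}

#' @export
print.lattice_walk <- function(x, ...) {
  cat(sprintf("<lattice_walk %s%s: %d beads, %d bonds, %d pin(s)%s>\n",
              x$topology, if (x$self_avoiding) " SAW" else "",
              n_beads(x), walk_length(x), length(x$pins),
              if (is.null(x$box)) ", unbounded"
              else sprintf(", box %dx%dx%d", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

# --- symbol-string encoding -------------------------------------------------

#' Encode a walk as a string of step symbols
#'
#' Each bond becomes one token from `+x,-x,+y,-y,+z,-z`. Decoding from the
#' start site reproduces the walk exactly ([decode_walk()]).
#'
#' @param walk a [lattice_walk()] with at least one bond.
#' @return character vector of length `walk_length(walk)`.
#' @export
encode_walk <- function(walk) {
  if (walk_length(walk) < 1) stop("cannot encode a walk with no bonds")
  validate_walk(walk)
  d <- walk_steps(walk)
  idx <- apply(d, 1, function(v) which(colSums(t(STEP_VECTORS) == v) == 3))
  STEP_SYMBOLS[idx]
}

#' Decode a symbol string into a walk
#'
#' @param start integer 3-vector, site of the first bead.
#' @param symbols character vector of step tokens (see [encode_walk()]).
#' @param topology,self_avoiding,pins,box passed to [lattice_walk()]. A
#'   closed decoding requires the symbols to return to `start`; the closure
#'   bead is dropped.
#' @export
decode_walk <- function(start, symbols, topology = c("open", "closed"),
                        self_avoiding = FALSE, pins = integer(0), box = NULL) {
  topology <- match.arg(topology)
  bad <- setdiff(symbols, STEP_SYMBOLS)
  if (length(bad) > 0) stop("unknown step symbols: ", paste(bad, collapse = ", "))
  steps <- STEP_VECTORS[symbols, , drop = FALSE]
  cum <- apply(steps, 2, cumsum)
  if (length(symbols) == 1) cum <- matrix(cum, nrow = 1)
  sites <- matrix(as.integer(start), nrow = length(symbols) + 1, ncol = 3,
                  byrow = TRUE) + rbind(0, cum)
  if (topology == "closed") {
    if (!all(sites[nrow(sites), ] == sites[1, ]))
      stop("closed decoding must return to the start site")
    sites <- sites[-nrow(sites), , drop = FALSE]
  }
  lattice_walk(sites, topology, self_avoiding, pins, box)
}

#' Convert between digit and axis step notation
#'
#' A compact digit notation for step strings: `1` is up (+z), `2` right
#' (+x), `3` is +y, and a leading minus flips the direction (so `"2122"`
#' reads +x, +z, +x, +x). Useful for terse test fixtures and logs.
#'
#' @param digits a single string such as `"2122"` or `"2,1,-2"` (commas
#'   optional when all tokens are single digits).
#' @return character vector of axis tokens.
#' @export
symbols_from_digits <- function(digits) {
  toks <- if (grepl(",", digits)) strsplit(digits, ",")[[1]]
          else regmatches(digits, gregexpr("-?[123]", digits))[[1]]
  if (paste(toks, collapse = "") != gsub(",", "", digits))
    stop("invalid digit token in ", digits)
  map <- c(`1` = "+z", `-1` = "-z", `2` = "+x", `-2` = "-x",
           `3` = "+y", `-3` = "-y")
  out <- map[toks]
  if (anyNA(out)) stop("invalid digit token in ", digits)
  unname(out)
}

#' @rdname symbols_from_digits
#' @param symbols character vector of axis tokens.
#' @export
digits_from_symbols <- function(symbols) {
  map <- c(`+z` = "1", `-z` = "-1", `+x` = "2", `-x` = "-2",
           `+y` = "3", `-y` = "-3")
  paste(map[symbols], collapse = "")
}

# --- multi-chain configurations --------------------------------------------

#' Several chains sharing one box
#'
#' Used for pre-division and replicating-cell scenarios where the cell holds
#' more than one DNA strand. With `mutual_exclusion` the chains may not share
#' lattice sites (the occupancy grid is common during sampling).
#'
#' @param chains list of [lattice_walk()] objects with identical boxes.
#' @param mutual_exclusion logical.
#' @return an object of class `multi_chain`.
#' @export
multi_chain <- function(chains, mutual_exclusion = TRUE) {
  if (length(chains) < 1 || !all(vapply(chains, inherits, TRUE, "lattice_walk")))
    stop("chains must be a non-empty list of lattice_walk objects")
  box <- chains[[1]]$box
  for (ch in chains)
    if (!identical(unclass(ch$box), unclass(box)))
      stop("all chains must share one box")
  if (mutual_exclusion) {
    all_sites <- do.call(rbind, lapply(chains, `[[`, "sites"))
    if (anyDuplicated(all_sites) != 0)
      stop("mutual exclusion violated: chains share a lattice site")
  }
  structure(list(chains = chains, mutual_exclusion = isTRUE(mutual_exclusion),
                 box = box),
            class = "multi_chain")
}

#' @export
print.multi_chain <- function(x, ...) {
  cat(sprintf("<multi_chain: %d chains, %s beads, mutual exclusion %s>\n",
              length(x$chains),
              paste(vapply(x$chains, n_beads, 1L), collapse = "+"),
              if (x$mutual_exclusion) "on" else "off"))
  invisible(x)
}
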