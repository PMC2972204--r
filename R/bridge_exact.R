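# Exact axial statistics of confined non-self-avoiding bridges by transfer
# (dynamic-programming) propagation over the box graph. Complements the
# depth-first enumeration: walks without excluded volume can be counted by
# matrix powers of the box adjacency, which scales to full chromosome
# lengths and provides an exact reference profile for the sampler.

box_adjacency <- function(box) {
  box <- unname(unclass(box))
  nx <- box[1]; ny <- box[2]; nz <- box[3]
  idx <- function(x, y, z) 1 + x + nx * (y + ny * z)
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1), z = 0:(nz - 1))
  from <- to <- integer(0)
  for (ax in c("x", "y", "z")) {
    lim <- c(x = nx, y = ny, z = nz)[ax]
    ok <- g[[ax]] + 1 < lim
    g2 <- g[ok, ]
    g2[[ax]] <- g2[[ax]] + 1
    from <- c(from, idx(g$x[ok], g$y[ok], g$z[ok]))
    to <- c(to, idx(g2$x, g2$y, g2$z))
  }
  n <- nx * ny * nz
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(n, n))
}

# Backward count vectors g_t = A^t e_to (renormalised each step), stored as
# checkpoints every `block` steps; `rebuild` regenerates the vectors of one
# block on demand.
backward_checkpoints <- function(A, start_vec, n_bonds, block) {
  ck <- vector("list", n_bonds %/% block + 1L)
  g <- start_vec
  ck[[1]] <- g
  if (n_bonds > 0) for (t in 1:n_bonds) {
    g <- as.numeric(A %*% g)
    g <- g / sum(g)
    if (t %% block == 0) ck[[t %/% block + 1L]] <- g
  }
  ck
}

rebuild_block <- function(ck, A, lo, block, n_bonds) {
  cache <- vector("list", block)
  gg <- ck[[lo %/% block + 1L]]
  cache[[1]] <- gg
  top <- min(block - 1L, n_bonds - lo)
  if (top >= 1) for (k in 1:top) {
    gg <- as.numeric(A %*% gg)
    gg <- gg / sum(gg)
    cache[[k + 1L]] <- gg
  }
  cache
}

#' Exact axial profile of a confined non-self-avoiding bridge
#'
#' Computes the exact per-contour-index mean and standard deviation of the
#' axial position over the uniform ensemble of all `n_bonds`-step lattice
#' walks from `from` to `to` confined to `box`, by forward/backward
#' propagation of site-count vectors through the box adjacency (checkpointed
#' so memory stays modest even for chromosome-scale lengths). This is the
#' exact counterpart of sampling the non-compacted chromosome: the number
#' of walks through site w at step s factorises into the `s`-step count
#' from *ori* and the `(N-s)`-step count to *ter*.
#'
#' @param box a [lattice_box()].
#' @param from,to endpoint sites (e.g. the *ori* and *ter* anchors).
#' @param n_bonds bridge length in bonds; its parity must match the
#'   Manhattan distance between the endpoints.
#' @param block checkpoint spacing for the backward vectors.
#' @return an [axial_profile] with `n_samples = Inf` (exact).
#' @export
exact_bridge_profile <- function(box, from, to, n_bonds, block = 200L) {
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(inherits(box, "lattice_box"))
  if (!all(box_contains(box, rbind(from, to)))) stop("endpoints outside box")
  man <- sum(abs(to - from))
  if (man > n_bonds || (n_bonds - man) %% 2 != 0)
    stop("no bridge of that length exists (Manhattan/parity constraint)")
  A <- box_adjacency(box)
  n <- nrow(A)
  site_z <- rep(0:(box[3] - 1), each = box[1] * box[2])
  sidx <- function(p) 1 + p[1] + box[1] * (p[2] + box[2] * p[3])

  e_to <- numeric(n); e_to[sidx(to)] <- 1
  ck <- backward_checkpoints(A, e_to, n_bonds, block)

  mean_z <- sd_z <- numeric(n_bonds + 1)
  f <- numeric(n); f[sidx(from)] <- 1
  cache_lo <- -1L; cache <- NULL
  for (s in 0:n_bonds) {
    t <- n_bonds - s
    lo <- (t %/% block) * block
    if (lo != cache_lo) {
      cache <- rebuild_block(ck, A, lo, block, n_bonds)
      cache_lo <- lo
    }
    g_t <- cache[[t - lo + 1L]]
    w <- f * g_t
    tot <- sum(w)
    if (tot <= 0) stop("no walks satisfy the constraints (empty bridge)")
    m1 <- sum(w * site_z) / tot
    m2 <- sum(w * site_z^2) / tot
    mean_z[s + 1] <- m1
    sd_z[s + 1] <- sqrt(max(m2 - m1^2, 0))
    if (s < n_bonds) {
      f <- as.numeric(A %*% f)
      f <- f / sum(f)
    }
  }
  prof <- new_axial_profile(0:n_bonds, mean_z, sd_z, Inf)
  attr(prof, "topology") <- "open"
  attr(prof, "pin_s") <- c(0L, n_bonds)
  attr(prof, "box") <- box
  prof
}

#' Exact sampling of confined non-self-avoiding bridges
#'
#' Draws independent configurations uniformly from the set of all
#' `n_bonds`-step lattice walks between the endpoints inside the box, by
#' sequential sampling from the exact transfer-matrix conditionals: the
#' walker at site u after s steps moves to neighbour v with probability
#' proportional to the number of `(n_bonds - s - 1)`-step walks from v to
#' the terminal pin. Unlike Markov-chain sampling, every configuration is
#' an exact independent draw, so chromosome-scale non-compacted ensembles
#' need no equilibration at all.
#'
#' @inheritParams exact_bridge_profile
#' @param n_samples number of independent bridges.
#' @param return `"profile"` (streaming mean/sd of z per contour index; the
#'   default, memory-light) or `"walks"` (list of site matrices; intended
#'   for small instances).
#' @return an [axial_profile] (with `n_samples` drawn samples), or a list
#'   of site matrices.
#' @export
sample_bridges <- function(box, from, to, n_bonds, n_samples,
                           return = c("profile", "walks"), block = 200L) {
  return <- match.arg(return)
  from <- as.integer(from); to <- as.integer(to)
  stopifnot(inherits(box, "lattice_box"))
  if (!all(box_contains(box, rbind(from, to)))) stop("endpoints outside box")
  man <- sum(abs(to - from))
  if (man > n_bonds || (n_bonds - man) %% 2 != 0)
    stop("no bridge of that length exists (Manhattan/parity constraint)")
  bx <- unname(unclass(box))
  A <- box_adjacency(box)
  n <- nrow(A)
  sidx <- function(p) 1 + p[1] + bx[1] * (p[2] + bx[2] * p[3])
  site_z <- rep(0:(bx[3] - 1), each = bx[1] * bx[2])

  # neighbour index table (0 = outside the box)
  xs <- rep_len(0:(bx[1] - 1), n)
  ys <- rep(rep(0:(bx[2] - 1), each = bx[1]), times = bx[3])
  zs <- site_z
  nbr <- matrix(0L, n, 6)
  off <- c(1L, -1L, bx[1], -bx[1], bx[1] * bx[2], -bx[1] * bx[2])
  ok <- list(xs + 1 < bx[1], xs - 1 >= 0, ys + 1 < bx[2], ys - 1 >= 0,
             zs + 1 < bx[3], zs - 1 >= 0)
  for (k in 1:6) nbr[ok[[k]], k] <- seq_len(n)[ok[[k]]] + off[k]

  e_to <- numeric(n); e_to[sidx(to)] <- 1
  ck <- backward_checkpoints(A, e_to, n_bonds, block)

  m <- n_samples
  cur <- rep(sidx(from), m)
  sum_z <- sumsq_z <- numeric(n_bonds + 1)
  sum_z[1] <- m * from[3]; sumsq_z[1] <- m * from[3]^2
  walks <- if (return == "walks")
    lapply(seq_len(m), function(i) matrix(0L, n_bonds + 1, 3)) else NULL
  if (return == "walks")
    for (i in seq_len(m)) walks[[i]][1, ] <- from

  cache_lo <- -1L; cache <- NULL
  gpad <- numeric(n + 1)  # index 1 = "outside", weight 0
  for (s in 0:(n_bonds - 1)) {
    t <- n_bonds - s - 1L
    lo <- (t %/% block) * block
    if (lo != cache_lo) {
      cache <- rebuild_block(ck, A, lo, block, n_bonds)
      cache_lo <- lo
    }
    gpad[-1] <- cache[[t - lo + 1L]]
    nb <- nbr[cur, , drop = FALSE]          # m x 6 neighbour site ids
    w <- matrix(gpad[nb + 1L], m, 6)        # weights, 0 outside
    cs <- w
    for (k in 2:6) cs[, k] <- cs[, k] + cs[, k - 1]
    u <- stats::runif(m) * cs[, 6]
    pick <- 7L - (u < cs[, 1]) - (u < cs[, 2]) - (u < cs[, 3]) -
      (u < cs[, 4]) - (u < cs[, 5]) - (u < cs[, 6])
    cur <- nb[cbind(seq_len(m), pick)]
    z <- site_z[cur]
    sum_z[s + 2] <- sum(z); sumsq_z[s + 2] <- sum(z^2)
    if (return == "walks")
      for (i in seq_len(m))
        walks[[i]][s + 2, ] <- c(xs[cur[i]], ys[cur[i]], zs[cur[i]])
  }
  if (return == "walks") return(walks)
  tmpl <- lattice_walk(rbind(from, to), "open", FALSE,
                       pins = c(1L, 2L), box = box, validate = FALSE)
  prof <- profile_from_moments(sum_z, sumsq_z, m, NULL)
  attr(prof, "topology") <- "open"
  attr(prof, "pin_s") <- c(0L, n_bonds)
  attr(prof, "box") <- box
  prof
}
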