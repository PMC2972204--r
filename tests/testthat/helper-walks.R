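# shared fixtures and small oracles, all built in code

# random valid non-self-avoiding open walk of n bonds from a start site
random_walk_sites <- function(n_bonds, start = c(0L, 0L, 0L)) {
  steps <- STEP_VECTORS[sample(STEP_SYMBOLS, n_bonds, replace = TRUE), ,
                        drop = FALSE]
  cum <- apply(steps, 2, cumsum)
  if (n_bonds == 1) cum <- matrix(cum, nrow = 1)
  matrix(as.integer(start), n_bonds + 1, 3, byrow = TRUE) + rbind(0L, cum)
}

# brute-force enumeration of all n-step walks from `start` (6^n sequences),
# independent of the package's DFS enumerator
brute_force_walks <- function(n_bonds, start = c(0L, 0L, 0L), box = NULL,
                              closed = FALSE, saw = FALSE, end = NULL) {
  out <- list()
  rec <- function(sites) {
    t <- nrow(sites) - 1
    if (t == n_bonds) {
      if (closed && !all(sites[nrow(sites), ] == sites[1, ])) return()
      if (!is.null(end) && !all(sites[nrow(sites), ] == end)) return()
      keep <- if (closed) sites[-nrow(sites), , drop = FALSE] else sites
      if (saw && anyDuplicated(keep) != 0) return()
      out[[length(out) + 1]] <<- keep
      return()
    }
    for (k in 1:6) {
      nxt <- sites[nrow(sites), ] + STEP_VECTORS[k, ]
      if (!is.null(box) && !all(box_contains(box, nxt))) next
      rec(rbind(sites, nxt))
    }
  }
  rec(matrix(as.integer(start), 1, 3))
  out
}

# breadth-first search over the move graph; returns the reachable state keys
bfs_reachable <- function(start_sites, topology, pins, box, saw = TRUE) {
  seen <- new.env(parent = emptyenv())
  frontier <- list(start_sites)
  assign(walk_key(start_sites), TRUE, envir = seen)
  while (length(frontier) > 0) {
    nxt <- list()
    for (m in frontier) {
      w <- lattice_walk(m, topology, saw, pins = pins, box = box)
      for (nb in move_neighbors(w)) {
        k <- walk_key(nb)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1]] <- nb
        }
      }
    }
    frontier <- nxt
  }
  ls(seen)
}

expect_valid_walk <- function(w) expect_true(validate_walk(w))
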