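# Ensemble sampling with the MOS move set: equilibrate and sample walks of
# fixed length, fixed pins, confined to the box, with self-avoidance
# optionally enforced.

#' Sampler configuration
#'
#' Defaults follow the package conventions: `burn_in = 100 * L` attempted
#' moves and `thinning = max(L, 1000)` attempted moves between retained
#' samples, where `L` is the total bond count. "Moves" always counts
#' attempted (not accepted) proposals. The proposal kernel picks a contour
#' index uniformly and a move kind by `move_weights`; inapplicable proposals
#' count as rejected.
#'
#' @param n_samples number of retained configurations.
#' @param burn_in attempted moves discarded before the first sample.
#' @param thinning attempted moves between retained samples (>= 1).
#' @param move_weights probabilities over bead_flip, crankshaft,
#'   crankshaft3d; must sum to 1.
#' @param seed optional integer; if given, `set.seed(seed)` is called before
#'   sampling.
#' @export
sampler_config <- function(n_samples, burn_in = NULL, thinning = NULL,
                           move_weights = c(bead_flip = 0.6, crankshaft = 0.3,
                                            crankshaft3d = 0.1),
                           seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(move_weights) != 3 || any(move_weights < 0) ||
      abs(sum(move_weights) - 1) > 1e-8)
    stop("move_weights must be 3 nonnegative probabilities summing to 1")
  if (!is.null(thinning) && thinning < 1) stop("thinning must be >= 1")
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 thinning = thinning, move_weights = unname(move_weights),
                 seed = seed),
            class = "sampler_config")
}

resolve_config <- function(cfg, L) {
  if (is.null(cfg$burn_in)) cfg$burn_in <- 100 * L
  if (is.null(cfg$thinning)) cfg$thinning <- max(L, 1000)
  cfg
}

chains_of <- function(x) {
  if (inherits(x, "multi_chain")) x$chains
  else if (inherits(x, "lattice_walk")) list(x)
  else stop("expected a lattice_walk or multi_chain")
}

mos_run <- function(x, cfg, record_walks = FALSE, record_z = FALSE,
                    profile = FALSE, density = FALSE, validate_every = 0L) {
  chains <- chains_of(x)
  saw <- any(vapply(chains, `[[`, TRUE, "self_avoiding")) ||
    (inherits(x, "multi_chain") && x$mutual_exclusion)
  L <- sum(vapply(chains, walk_length, 1L))
  cfg <- resolve_config(cfg, L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (ch in chains) validate_walk(ch)
  res <- mos_run_cpp(lapply(chains, `[[`, "sites"),
                     vapply(chains, function(ch) ch$topology == "closed", TRUE),
                     lapply(chains, function(ch) seq_len(n_beads(ch)) %in% ch$pins),
                     box_dim_for(chains[[1]]$box), saw,
                     cfg$n_samples, cfg$burn_in, cfg$thinning,
                     cfg$move_weights,
                     record_walks, record_z, profile, density,
                     as.integer(validate_every))
  res$counters <- list(
    attempts = stats::setNames(res$attempts, MOVE_KINDS),
    accepts = stats::setNames(res$accepts, MOVE_KINDS),
    rejects = stats::setNames(res$rejects, REJECT_REASONS),
    acceptance_rate = sum(res$accepts) / max(1, sum(res$attempts)))
  res$config <- cfg
  res
}

#' Sample an ensemble of walks with the MOS algorithm
#'
#' Runs the Markov chain from `x` and retains `n_samples` configurations,
#' each separated by `thinning` attempted moves after `burn_in`. Every
#' retained walk satisfies the length, pin, volume and (if set)
#' self-avoidance constraints; because all proposal kernels are symmetric,
#' the stationary distribution is uniform over the reachable
#' constraint-satisfying configurations.
#'
#' @param x a [lattice_walk()] or [multi_chain()] satisfying all its
#'   constraints.
#' @param n_samples,burn_in,thinning,move_weights,seed see
#'   [sampler_config()].
#' @param config a [sampler_config()]; overrides the individual arguments.
#' @param record `"walks"` to store full site matrices, `"z"` to store only
#'   the axial coordinate per bead (much lighter for long chains).
#' @return a `walk_ensemble`: list with `template` (the input), `samples`
#'   (when recording walks; per sample a list of per-chain site matrices),
#'   `z` (when recording z: per chain an `n_samples x n_beads` matrix),
#'   `counters` (attempt/acceptance statistics) and `final` (the last
#'   state's site matrices).
#' @export
mos_sample <- function(x, n_samples = 100, burn_in = NULL, thinning = NULL,
                       move_weights = c(0.6, 0.3, 0.1), seed = NULL,
                       config = NULL, record = c("walks", "z")) {
  record <- match.arg(record)
  cfg <- if (is.null(config))
    sampler_config(n_samples, burn_in, thinning, move_weights, seed)
  else config
  res <- mos_run(x, cfg, record_walks = record == "walks",
                 record_z = record == "z")
  structure(list(template = x, samples = res$samples, z = res$z,
                 final = res$final, counters = res$counters,
                 config = res$config),
            class = "walk_ensemble")
}

#' @export
print.walk_ensemble <- function(x, ...) {
  n <- if (length(x$samples) > 0) length(x$samples) else
    if (length(x$z) > 0) nrow(x$z[[1]]) else 0
  cat(sprintf("<walk_ensemble: %d samples, acceptance %.3f>\n",
              n, x$counters$acceptance_rate))
  invisible(x)
}

#' Streaming axial statistics from the MOS sampler
#'
#' Like [mos_sample()] but accumulates the per-contour-index mean and
#' standard deviation of the axial position (and optionally the per-site
#' occupation density) on the fly, so arbitrarily many samples can be drawn
#' without storing configurations. This is the workhorse for
#' chromosome-scale runs.
#'
#' @inheritParams mos_sample
#' @param density also accumulate the mean per-site occupation (3-D array).
#' @param validate_every audit all invariants every this many attempted
#'   moves (0 = never); any violation is an error. Used by stress tests.
#' @return for a single chain, an [axial_profile] (with `counters`,
#'   `config`, and optionally `density` attached as attributes); for a
#'   multi-chain configuration, a list of profiles with those attributes.
#' @export
mos_profile <- function(x, n_samples = 100, burn_in = NULL, thinning = NULL,
                        move_weights = c(0.6, 0.3, 0.1), seed = NULL,
                        config = NULL, density = FALSE, validate_every = 0L) {
  cfg <- if (is.null(config))
    sampler_config(n_samples, burn_in, thinning, move_weights, seed)
  else config
  res <- mos_run(x, cfg, profile = TRUE, density = density,
                 validate_every = validate_every)
  chains <- chains_of(x)
  profs <- vector("list", length(chains))
  for (c in seq_along(chains)) {
    p <- res$profile[[c]]
    profs[[c]] <- profile_from_moments(p$sum_z, p$sumsq_z, cfg$n_samples,
                                       chains[[c]])
    if (density) {
      box <- chains[[c]]$box
      attr(profs[[c]], "density") <-
        array(res$density[[c]] / cfg$n_samples, dim = unname(unclass(box)))
    }
    attr(profs[[c]], "counters") <- res$counters
    attr(profs[[c]], "config") <- res$config
  }
  if (inherits(x, "lattice_walk")) profs[[1]] else profs
}
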