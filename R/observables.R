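# Summary statistics of walk ensembles: axial mean-position profiles, RMS
# deviation from the linear arrangement, plateau onset, correlation-sign
# fractions, occupation densities and chromosome demixing.

new_axial_profile <- function(s, mean_z, std_z, n_samples, walk = NULL) {
  L <- length(s) - 1L
  df <- data.frame(s = s, s_over_L = if (L > 0) s / max(s) else 0,
                   mean_z = mean_z, std_z = std_z)
  structure(df, class = c("axial_profile", "data.frame"),
            n_samples = n_samples,
            topology = if (!is.null(walk)) walk$topology else NA_character_,
            pin_s = if (!is.null(walk)) walk$pins - 1L else integer(0),
            box = if (!is.null(walk)) walk$box else NULL)
}

profile_from_moments <- function(sum_z, sumsq_z, n, walk) {
  m <- sum_z / n
  v <- pmax(sumsq_z / n - m^2, 0)
  new_axial_profile(seq_along(sum_z) - 1L, m, sqrt(v), n, walk)
}

#' Axial mean-position profile of an ensemble
#'
#' The average z-position (the pole-to-pole cell axis) as a function of the
#' contour coordinate `s`, together with the standard deviation between the
#' individual configurations: the population-level statistic that the
#' experiments on gene positioning measure. Pinned contour indices have
#' standard deviation exactly 0.
#'
#' @param x a `walk_ensemble` from [mos_sample()], a single
#'   [lattice_walk()], or a plain list of walks of equal length.
#' @param chain for multi-chain ensembles, which chain to profile.
#' @param ... unused.
#' @return an `axial_profile`: data frame with columns `s` (contour
#'   coordinate in bonds, starting at 0), `s_over_L`, `mean_z`, `std_z`,
#'   plus attributes `n_samples`, `topology`, `pin_s`, `box`.
#' @export
axial_profile <- function(x, ...) UseMethod("axial_profile")

#' @rdname axial_profile
#' @export
axial_profile.walk_ensemble <- function(x, chain = 1L, ...) {
  template <- chains_of(x$template)[[chain]]
  if (length(x$z) > 0) {
    zm <- x$z[[chain]]
    return(profile_from_moments(colSums(zm), colSums(zm^2), nrow(zm), template))
  }
  if (length(x$samples) == 0) stop("ensemble records no samples")
  zs <- vapply(x$samples, function(snap) snap[[chain]][, 3],
               numeric(n_beads(template)))
  if (is.null(dim(zs))) zs <- matrix(zs, nrow = 1)
  profile_from_moments(rowSums(zs), rowSums(zs^2), ncol(zs), template)
}

#' @rdname axial_profile
#' @export
axial_profile.lattice_walk <- function(x, ...) {
  new_axial_profile(seq_len(n_beads(x)) - 1L, x$sites[, 3],
                    rep(0, n_beads(x)), 1L, x)
}

#' @rdname axial_profile
#' @export
axial_profile.list <- function(x, ...) {
  if (length(x) == 0) stop("empty ensemble")
  n <- vapply(x, n_beads, 1L)
  if (length(unique(n)) != 1) stop("walks in the ensemble differ in length")
  zs <- vapply(x, function(w) as.numeric(w$sites[, 3]), numeric(n[1]))
  if (is.null(dim(zs))) zs <- matrix(zs, nrow = 1)
  profile_from_moments(rowSums(zs), rowSums(zs^2), length(x), x[[1]])
}

#' Idealised linear reference configuration
#'
#' The straight-line arrangement interpolating from `z_ori` at `s = 0` to
#' `z_ter` at `s = s_ter` -- and, for a circular chromosome, back to `z_ori`
#' at `s = L` (a piecewise-linear tent over the two arms).
#'
#' @param s contour coordinate(s), in bonds.
#' @param z_ori,z_ter anchor heights (lattice units).
#' @param L total contour length in bonds.
#' @param s_ter contour position of *ter*; `NULL` (default) means an open
#'   segment ending at *ter* (`s_ter = L`).
#' @return reference height(s), same length as `s`.
#' @export
linear_reference <- function(s, z_ori, z_ter, L, s_ter = NULL) {
  if (is.null(s_ter)) s_ter <- L
  if (any(s < 0 | s > L)) stop("s out of range [0, L]")
  up <- s <= s_ter
  out <- numeric(length(s))
  out[up] <- z_ori + (z_ter - z_ori) * s[up] / s_ter
  if (any(!up))
    out[!up] <- z_ter + (z_ori - z_ter) * (s[!up] - s_ter) / (L - s_ter)
  out
}

profile_anchor_defaults <- function(profile, z_ori, z_ter, s_ter) {
  pin_s <- attr(profile, "pin_s")
  closed <- identical(attr(profile, "topology"), "closed")
  L <- if (closed) nrow(profile) else nrow(profile) - 1L
  if (is.null(s_ter)) {
    s_ter <- if (!closed) L
             else if (length(pin_s) >= 2) pin_s[2]
             else L %/% 2  # free ter: reference tent peaks mid-contour
  }
  if (is.null(z_ori)) z_ori <- profile$mean_z[1]
  if (is.null(z_ter)) z_ter <- profile$mean_z[profile$s == s_ter]
  list(z_ori = z_ori, z_ter = z_ter, L = L, s_ter = s_ter, closed = closed)
}

#' RMS deviation of the mean configuration from the linear arrangement
#'
#' The root-mean-square difference, averaged over the contour grid, between
#' the ensemble-mean axial profile and the idealised linear reference
#' connecting the anchors ([linear_reference()]). Zero iff the mean
#' configuration is exactly linear; large values signal the midcell plateau
#' of long non-compacted chains.
#'
#' @param profile an [axial_profile].
#' @param z_ori,z_ter anchor heights; default: the profile's own values at
#'   the anchors.
#' @param s_ter *ter* contour position for circular chromosomes; defaults
#'   to the second pinned index (closed profiles) or `L` (open).
#' @return nonnegative scalar, lattice units.
#' @export
rms_from_linear <- function(profile, z_ori = NULL, z_ter = NULL, s_ter = NULL) {
  a <- profile_anchor_defaults(profile, z_ori, z_ter, s_ter)
  ref <- linear_reference(profile$s, a$z_ori, a$z_ter,
                          L = if (a$closed) nrow(profile) else a$L,
                          s_ter = a$s_ter)
  sqrt(mean((profile$mean_z - ref)^2))
}

#' Contour step at which the mean profile reaches the midplane
#'
#' The smallest contour coordinate whose ensemble-mean axial position lies
#' within `tol` of the cell midplane: the onset of the midcell plateau that
#' characterises long non-compacted chains.
#'
#' @param profile an [axial_profile].
#' @param tol tolerance in lattice units (default 0.5).
#' @param midplane midplane height; defaults to `(nz - 1) / 2` from the
#'   profile's box.
#' @return contour coordinate (bonds), or `NA` if the profile never comes
#'   within `tol`.
#' @export
plateau_onset <- function(profile, tol = 0.5, midplane = NULL) {
  if (tol <= 0) stop("tol must be positive")
  if (is.null(midplane)) {
    box <- attr(profile, "box")
    if (is.null(box)) stop("profile has no box; give midplane explicitly")
    midplane <- (box[3] - 1) / 2
  }
  hit <- which(abs(profile$mean_z - midplane) <= tol)
  if (length(hit) == 0) return(NA_real_)
  profile$s[hit[1]]
}

#' Correlation-sign fractions over contour segments
#'
#' For each contour segment (e.g. the *ori*-to-*ter* and *ter*-to-*ori*
#' chromosome arms) the sign of the Pearson correlation between the
#' ensemble-mean axial position and the contour coordinate is computed, and
#' the fractions of the contour lying on positively and negatively
#' correlated segments are returned. In the wild-type symmetric arrangement
#' the fractions are 0.5/0.5; relocating *ter* on the chromosomal map
#' shifts them to the arm-length split.
#'
#' @param profile an [axial_profile].
#' @param segment_breaks contour coordinates of the segment boundaries in
#'   increasing order (e.g. `c(0, 1500)` for a closed 2000-bond chain with
#'   arms 1500 and 500). Closed profiles wrap the final segment back to the
#'   first break; open profiles must be covered by
#'   `c(breaks, L)`.
#' @return named numeric vector `positive_fraction`, `negative_fraction`
#'   (contour shares; segments with exactly zero correlation count in
#'   neither).
#' @export
correlation_sign_fractions <- function(profile, segment_breaks = NULL) {
  closed <- identical(attr(profile, "topology"), "closed")
  L <- if (closed) nrow(profile) else nrow(profile) - 1L
  if (is.null(segment_breaks)) {
    pin_s <- attr(profile, "pin_s")
    if (length(pin_s) < 2) stop("give segment_breaks (profile has < 2 pins)")
    segment_breaks <- pin_s
  }
  segment_breaks <- sort(unique(as.integer(segment_breaks)))
  ends <- if (closed) c(segment_breaks[-1], segment_breaks[1] + L)
          else unique(c(segment_breaks[-1], L))
  starts <- segment_breaks[seq_along(ends)]
  pos <- neg <- 0
  for (k in seq_along(starts)) {
    ss <- starts[k]:ends[k]
    if (length(ss) < 2) stop("segment of length < 2")
    z <- profile$mean_z[(ss %% L) + 1]
    if (!closed) z <- profile$mean_z[ss + 1]
    r <- suppressWarnings(stats::cor(ss, z))
    share <- (ends[k] - starts[k]) / L
    if (is.na(r) || r == 0) next
    if (r > 0) pos <- pos + share else neg <- neg + share
  }
  c(positive_fraction = pos, negative_fraction = neg)
}

#' Mean per-site occupation density of an ensemble
#'
#' The probability that each lattice site is occupied by a bead, averaged
#' over the ensemble (the lattice analogue of the radial DNA density). Sums
#' over all sites to the number of beads per configuration; pinned sites
#' have density exactly 1.
#'
#' @param x a `walk_ensemble` (with recorded walks) or a list of walks.
#' @param box the confining [lattice_box()]; defaults to the walks' box.
#' @param chain chain index for multi-chain ensembles.
#' @return a 3-D array `nx x ny x nz`.
#' @export
radial_density <- function(x, box = NULL, chain = 1L) {
  walks <- if (inherits(x, "walk_ensemble")) {
    if (length(x$samples) == 0) stop("ensemble records no walks")
    lapply(x$samples, function(snap) snap[[chain]])
  } else if (inherits(x, "lattice_walk")) list(x$sites)
  else lapply(x, function(w) if (inherits(w, "lattice_walk")) w$sites else w)
  if (is.null(box)) {
    box <- if (inherits(x, "walk_ensemble")) chains_of(x$template)[[chain]]$box
           else if (inherits(x, "lattice_walk")) x$box
           else x[[1]]$box
  }
  if (is.null(box)) stop("no box available for the density grid")
  bx <- unname(unclass(box))
  dens <- numeric(prod(bx))
  for (m in walks) {
    # linear indices; tabulate() counts revisited sites with multiplicity
    lin <- 1L + m[, 1] + bx[1] * (m[, 2] + bx[2] * m[, 3])
    dens <- dens + tabulate(lin, nbins = prod(bx))
  }
  array(dens / length(walks), dim = bx)
}

#' Axial demixing score of two chromosome halves
#'
#' Overlap coefficient of the axial occupation distributions of two chain
#' halves (or two chains): the z-histograms of the beads in each half,
#' normalised, and summed as `sum(min(p, q))`. 0 means fully demixed
#' (disjoint axial territories), 1 identical distributions. Used to
#' quantify the pre-division segregation of the two chromosome copies.
#'
#' @param x a `walk_ensemble`; either a single chain with `split` giving the
#'   last bead of the first half, or a two-chain ensemble.
#' @param split 1-based bead index ending the first half (single-chain
#'   case). Defaults to half the chain.
#' @return overlap coefficient in `[0, 1]`.
#' @export
demixing_score <- function(x, split = NULL) {
  if (!inherits(x, "walk_ensemble")) stop("expected a walk_ensemble")
  chains <- chains_of(x$template)
  nz <- chains[[1]]$box[3]
  if (is.null(nz)) stop("demixing needs a bounded box")
  zhist <- function(z) tabulate(z + 1L, nbins = nz)
  h1 <- h2 <- numeric(nz)
  get_z <- function(snap, chain) snap[[chain]][, 3]
  if (length(x$samples) == 0) stop("ensemble records no walks")
  if (length(chains) >= 2) {
    for (snap in x$samples) {
      h1 <- h1 + zhist(get_z(snap, 1L))
      h2 <- h2 + zhist(get_z(snap, 2L))
    }
  } else {
    n <- n_beads(chains[[1]])
    if (is.null(split)) split <- n %/% 2
    for (snap in x$samples) {
      z <- get_z(snap, 1L)
      h1 <- h1 + zhist(z[seq_len(split)])
      h2 <- h2 + zhist(z[(split + 1):n])
    }
  }
  sum(pmin(h1 / sum(h1), h2 / sum(h2)))
}

#' Linearity report for a profile
#'
#' Bundles the scalar diagnostics of spatial ordering: RMS deviation from
#' the linear arrangement, anchor heights, plateau onset and
#' correlation-sign fractions.
#'
#' @param profile an [axial_profile].
#' @param tol plateau tolerance (lattice units).
#' @param segment_breaks see [correlation_sign_fractions()]; `NULL` uses
#'   the profile's pins when there are two, else skips the fractions.
#' @return a list of class `linearity_report`.
#' @export
linearity_report <- function(profile, tol = 0.5, segment_breaks = NULL) {
  a <- profile_anchor_defaults(profile, NULL, NULL, NULL)
  fr <- c(positive_fraction = NA_real_, negative_fraction = NA_real_)
  if (!is.null(segment_breaks) || length(attr(profile, "pin_s")) >= 2)
    fr <- correlation_sign_fractions(profile, segment_breaks)
  onset <- tryCatch(plateau_onset(profile, tol), error = function(e) NA_real_)
  structure(list(rms = rms_from_linear(profile),
                 z_ori = a$z_ori, z_ter = a$z_ter,
                 plateau_onset = onset,
                 positive_fraction = unname(fr[1]),
                 negative_fraction = unname(fr[2]),
                 n_samples = attr(profile, "n_samples")),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat(sprintf(paste0("<linearity_report: rms %.3f, anchors %.1f/%.1f, ",
                     "plateau onset %s, fractions %.2f/%.2f>\n"),
              x$rms, x$z_ori, x$z_ter,
              if (is.na(x$plateau_onset)) "none" else format(x$plateau_onset),
              x$positive_fraction, x$negative_fraction))
  invisible(x)
}
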