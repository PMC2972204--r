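# Physical parameterisation and named scenario presets: map genome size,
# Kuhn length / blob diameter and cell dimensions to lattice parameters, and
# encode the simulated experiments for C. crescentus and E. coli.

BP_NM <- 0.34  # contour length per base pair

#' Physical parameters of a simulated cell and chromosome
#'
#' Collects the physical quantities from which a lattice scenario is
#' derived. Lengths use nm for the bond-scale quantities (Kuhn length `b`,
#' blob diameter `d`) and um for cell dimensions; the chromosome contour
#' length defaults to `genome_bp * 0.34 nm`. In the compacted (blob) model
#' exactly two of `{blob_d_nm, n_blobs, dna_per_blob_kb}` determine the
#' third through the contour length; `n_blobs` is taken as primary when
#' given.
#'
#' @param genome_bp genome size in base pairs.
#' @param contour_length_um chromosome contour length (um); default derived
#'   from `genome_bp`.
#' @param kuhn_nm Kuhn length b (nm), twice the persistence length; the
#'   lattice constant of the non-compacted model.
#' @param blob_d_nm blob diameter d (nm); the lattice constant of the
#'   compacted model.
#' @param n_blobs number of blobs representing the chromosome.
#' @param cell_length_um,cell_width_um cell dimensions (um); the cell axis
#'   is z.
#' @param anchor_fractions heights of *ori* and *ter* as fractions of the
#'   cell length.
#' @export
physical_parameters <- function(genome_bp = NULL, contour_length_um = NULL,
                                kuhn_nm = 50, blob_d_nm = NULL,
                                n_blobs = NULL,
                                cell_length_um = 2.0, cell_width_um = 0.5,
                                anchor_fractions = c(0.05, 0.95)) {
  if (is.null(contour_length_um)) {
    if (is.null(genome_bp)) stop("give genome_bp or contour_length_um")
    contour_length_um <- genome_bp * BP_NM / 1000
  }
  p <- list(genome_bp = genome_bp, contour_length_um = contour_length_um,
            kuhn_nm = kuhn_nm, blob_d_nm = blob_d_nm, n_blobs = n_blobs,
            cell_length_um = cell_length_um, cell_width_um = cell_width_um,
            anchor_fractions = anchor_fractions)
  stopifnot(contour_length_um > 0, kuhn_nm > 0,
            cell_length_um > 0, cell_width_um > 0)
  structure(p, class = "physical_parameters")
}

#' @export
print.physical_parameters <- function(x, ...) {
  cat(sprintf("<physical_parameters: contour %.3g um, b %.3g nm, cell %.2g x %.2g um>\n",
              x$contour_length_um, x$kuhn_nm, x$cell_length_um, x$cell_width_um))
  invisible(x)
}

new_scenario <- function(label, box, walk_length, topology, self_avoiding,
                         pin_beads, pin_sites, segment_targets = NULL,
                         extra_chains = NULL, model = "blob", bond_nm = NA) {
  structure(list(label = label, box = box,
                 walk_length = as.integer(walk_length), topology = topology,
                 self_avoiding = self_avoiding,
                 pin_beads = as.integer(pin_beads), pin_sites = pin_sites,
                 segment_targets = if (is.null(segment_targets)) NULL
                                   else as.integer(segment_targets),
                 extra_chains = extra_chains,
                 model = model, bond_nm = bond_nm),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario '%s': %s %s, %d bonds, box %dx%dx%d, %d pin(s)%s>\n",
              x$label, x$topology,
              if (x$self_avoiding) "SAW (blob chain)" else "walk",
              x$walk_length, x$box[1], x$box[2], x$box[3],
              length(x$pin_beads),
              if (length(x$extra_chains)) sprintf(", +%d extra chain(s)",
                                                  length(x$extra_chains)) else ""))
  invisible(x)
}

# A cell of length H bond units has nz = H + 1 site rows; cross-section
# extents likewise round(width / bond) + 1.
extent_from <- function(len_nm, bond_nm) as.integer(round(len_nm / bond_nm)) + 1L

# If the arm parities are incompatible with the anchors' Manhattan
# separation, nudge the ter height one lattice unit (preferring away from
# ori); the discretisation error is <= 1 lattice unit.
fix_anchor_parity <- function(z_ori, z_ter, arm_bonds, nz) {
  if ((abs(z_ter - z_ori) - arm_bonds[1]) %% 2 == 0) return(z_ter)
  for (cand in c(z_ter + sign(z_ter - z_ori), z_ter - sign(z_ter - z_ori))) {
    if (cand >= 0 && cand < nz && cand != z_ori) return(cand)
  }
  stop("cannot reconcile anchor parity with the arm lengths")
}

#' Map physical parameters to a lattice scenario
#'
#' Non-compacted (`"bare"`) model: one lattice bond is one Kuhn length b,
#' the walk length is `round(contour / b)` and the box extents follow from
#' the cell dimensions in units of b. Compacted (`"blob"`) model: one bond
#' is one blob diameter d and the walk length is the blob count. The cell
#' axis extent is `H + 1` sites for a cell of `H` bond units; anchors map
#' to the nearest lattice row on the cell axis, adjusted by at most one
#' unit if the walk parity requires it.
#'
#' @param phys a [physical_parameters()].
#' @param model `"bare"` or `"blob"`.
#' @param topology `"closed"` (whole circular chromosome) or `"open"`.
#' @param arm_fraction chromosomal-map position of *ter* as a fraction of
#'   the contour (0.5 = the wild-type 12 o'clock position).
#' @param label scenario label.
#' @return a `scenario_spec`.
#' @export
to_lattice <- function(phys, model = c("blob", "bare"),
                       topology = c("closed", "open"),
                       arm_fraction = 0.5, label = "custom") {
  model <- match.arg(model)
  topology <- match.arg(topology)
  contour_nm <- phys$contour_length_um * 1000
  if (model == "bare") {
    bond <- phys$kuhn_nm
    L <- as.integer(round(contour_nm / bond))
  } else {
    if (is.null(phys$n_blobs) && is.null(phys$blob_d_nm))
      stop("blob model needs n_blobs or blob_d_nm")
    bond <- if (!is.null(phys$blob_d_nm)) phys$blob_d_nm
            else phys$cell_length_um * 1000 / 40  # default: cell ~40 blobs long
    L <- if (!is.null(phys$n_blobs)) as.integer(phys$n_blobs)
         else as.integer(round(contour_nm / bond))
  }
  nz <- extent_from(phys$cell_length_um * 1000, bond)
  nxy <- extent_from(phys$cell_width_um * 1000, bond)
  if (min(nxy, nz) < 2) stop("infeasible geometry: box extent < 2 sites")
  box <- lattice_box(nxy, nxy, nz)
  H <- nz - 1L
  cx <- as.integer((nxy - 1) %/% 2)
  if (L %% 2 != 0 && topology == "closed") {
    message("adjusting walk length ", L, " -> ", L + 1, " (closed-walk parity)")
    L <- L + 1L
  }
  z_ori <- as.integer(round(phys$anchor_fractions[1] * H))
  z_ter <- as.integer(round(phys$anchor_fractions[2] * H))
  if (topology == "closed") {
    arm1 <- as.integer(round(arm_fraction * L))
    arms <- c(arm1, L - arm1)
    z_ter <- fix_anchor_parity(z_ori, z_ter, arms, nz)
    new_scenario(label, box, L, "closed", model == "blob",
                 pin_beads = c(1L, arm1 + 1L),
                 pin_sites = rbind(c(cx, cx, z_ori), c(cx, cx, z_ter)),
                 segment_targets = arms, model = model, bond_nm = bond)
  } else {
    if ((abs(z_ter - z_ori) - L) %% 2 != 0) z_ter <- fix_anchor_parity(z_ori, z_ter, L, nz)
    new_scenario(label, box, L, "open", model == "blob",
                 pin_beads = c(1L, L + 1L),
                 pin_sites = rbind(c(cx, cx, z_ori), c(cx, cx, z_ter)),
                 model = model, bond_nm = bond)
  }
}

# --- presets ---------------------------------------------------------------

# Shared geometry conventions (documented assumptions; the published cell
# cross-sections are not recoverable as printed numbers):
#  C. crescentus: cell 2.0 x 0.5 um, b = d = 50 nm -> box 11 x 11 x 41
#  (H = 40 bond units), blob chain N = 2000.
#  E. coli newborn: cell 1.65 x 0.85 um, d = 50 nm -> box 18 x 18 x 34
#  (H = 33 blobs), N = 2000; pre-division cell doubled to H = 66.
caulo_box <- function() lattice_box(11, 11, 41)
ecoli_box <- function(H = 33) lattice_box(18, 18, H + 1)

#' Named scenario presets
#'
#' Fully specified lattice scenarios for each simulated experiment:
#'
#' * `caulo_bare_bridge_wall`, `caulo_bare_bridge_4b`: non-compacted
#'   *C. crescentus* half-chromosome, a 13000-bond non-self-avoiding open
#'   bridge (one Kuhn segment per bond) with *ori*/*ter* on the cell axis
#'   at the walls (`z = 0, 40`) or 4 bond units off (`z = 4, 36`).
#' * `caulo_blob_wt`: compacted wild type -- closed 2000-blob self-avoiding
#'   chain, *ori* and *ter* pinned near opposite poles (anchor fractions
#'   0.05/0.95), arms 1000/1000.
#' * `caulo_blob_free_ter`: as wild type but only *ori* pinned (the walk
#'   starts and ends at *ori*; *ter* free).
#' * `caulo_mutant_ter3`: *ter* relocated to 3 o'clock on the chromosomal
#'   map -- arms of 1500 and 500 blobs between the polar anchors.
#' * `ecoli_newborn`: closed 2000-blob chain in a newborn cell (H = 33
#'   blobs), anchors at opposite poles.
#' * `ecoli_two_chromosomes`: pre-division cell, the two chromosomes as one
#'   open chain (twice as long) with the two *ori* ends at opposite poles
#'   and the two *ter* (adjacent beads at the chain midpoint) at midcell.
#' * `ecoli_daughter_strand`: mother chain plus a half-length daughter
#'   strand whose ends are anchored in the midplane (replication half
#'   done), mutual exclusion on.
#' * `ecoli_midcell_both`: *ori* and *ter* around midcell (fractions
#'   0.4/0.6) as upon initiation of replication.
#' * `ecoli_ori_pole_ter_mid`: *ori* back at the pole, *ter* held at
#'   midcell (post-replication).
#' * `ecoli_midcell_perpendicular`: *ori* and *ter* at midcell at the same
#'   height but different x, the connecting line perpendicular to the cell
#'   axis.
#' * `ecoli_mutant_ter3`: the *ter*-at-3-o'clock mutant in the newborn
#'   *E. coli* geometry.
#'
#' @param name preset name; see [preset_names()].
#' @return a `scenario_spec`.
#' @export
preset <- function(name) {
  cx <- 5L  # caulo box centre
  ex <- 8L  # e.coli box centre
  switch(name,
    caulo_bare_bridge_wall = new_scenario(
      name, caulo_box(), 13000L, "open", FALSE,
      pin_beads = c(1L, 13001L),
      pin_sites = rbind(c(cx, cx, 0L), c(cx, cx, 40L)), model = "bare",
      bond_nm = 50),
    caulo_bare_bridge_4b = new_scenario(
      name, caulo_box(), 13000L, "open", FALSE,
      pin_beads = c(1L, 13001L),
      pin_sites = rbind(c(cx, cx, 4L), c(cx, cx, 36L)), model = "bare",
      bond_nm = 50),
    caulo_blob_wt = new_scenario(
      name, caulo_box(), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1001L),
      pin_sites = rbind(c(cx, cx, 2L), c(cx, cx, 38L)),
      segment_targets = c(1000L, 1000L), bond_nm = 50),
    caulo_blob_free_ter = new_scenario(
      name, caulo_box(), 2000L, "closed", TRUE,
      pin_beads = 1L, pin_sites = rbind(c(cx, cx, 2L)),
      segment_targets = 2000L, bond_nm = 50),
    caulo_mutant_ter3 = new_scenario(
      name, caulo_box(), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1501L),
      pin_sites = rbind(c(cx, cx, 2L), c(cx, cx, 38L)),
      segment_targets = c(1500L, 500L), bond_nm = 50),
    ecoli_newborn = new_scenario(
      name, ecoli_box(33), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1001L),
      pin_sites = rbind(c(ex, ex, 2L), c(ex, ex, 30L)),
      segment_targets = c(1000L, 1000L), bond_nm = 50),
    ecoli_two_chromosomes = new_scenario(
      name, ecoli_box(66), 4001L, "open", TRUE,
      pin_beads = c(1L, 2001L, 2002L, 4002L),
      pin_sites = rbind(c(ex, ex, 3L), c(ex, ex, 33L),
                        c(ex, ex + 1L, 33L), c(ex, ex + 1L, 63L)),
      segment_targets = c(2000L, 1L, 2000L), bond_nm = 50),
    ecoli_daughter_strand = {
      sc <- new_scenario(
        name, ecoli_box(66), 2000L, "closed", TRUE,
        pin_beads = c(1L, 1001L),
        pin_sites = rbind(c(ex, ex, 3L), c(ex, ex, 63L)),
        segment_targets = c(1000L, 1000L), bond_nm = 50)
      sc$extra_chains <- list(list(
        walk_length = 1000L, topology = "open",
        pin_beads = c(1L, 1001L),
        pin_sites = rbind(c(ex + 2L, ex, 33L), c(ex + 2L, ex + 2L, 33L))))
      sc
    },
    ecoli_midcell_both = new_scenario(
      name, ecoli_box(33), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1001L),
      pin_sites = rbind(c(ex, ex, 13L), c(ex, ex, 21L)),
      segment_targets = c(1000L, 1000L), bond_nm = 50),
    ecoli_ori_pole_ter_mid = new_scenario(
      name, ecoli_box(33), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1001L),
      pin_sites = rbind(c(ex, ex, 2L), c(ex, ex, 16L)),
      segment_targets = c(1000L, 1000L), bond_nm = 50),
    ecoli_midcell_perpendicular = new_scenario(
      name, ecoli_box(33), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1001L),
      pin_sites = rbind(c(ex - 2L, ex, 16L), c(ex + 2L, ex, 16L)),
      segment_targets = c(1000L, 1000L), bond_nm = 50),
    ecoli_mutant_ter3 = new_scenario(
      name, ecoli_box(33), 2000L, "closed", TRUE,
      pin_beads = c(1L, 1501L),
      pin_sites = rbind(c(ex, ex, 2L), c(ex, ex, 30L)),
      segment_targets = c(1500L, 500L), bond_nm = 50),
    stop("unknown preset: ", name)
  )
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("caulo_bare_bridge_wall", "caulo_bare_bridge_4b", "caulo_blob_wt",
    "caulo_blob_free_ter", "caulo_mutant_ter3", "ecoli_newborn",
    "ecoli_two_chromosomes", "ecoli_daughter_strand", "ecoli_midcell_both",
    "ecoli_ori_pole_ter_mid", "ecoli_midcell_perpendicular",
    "ecoli_mutant_ter3")
}

#' Parameter sweeps over blob ensembles and cell geometry
#'
#' Generates a family of scenarios under one of the sweep rules:
#'
#' * `"constant_density"` (ensemble i): the DNA content per blob scales as
#'   d^3, so the blob count N scales as d^-3 and the box extents as d^-1.
#'   `values` are blob diameters (nm).
#' * `"constant_blob_number"` (ensemble ii): N is fixed (default 2000) and
#'   the blob diameter varies; `values` are blob diameters (nm).
#' * `"cell_length"`: cross-section fixed, axial extent varied; `values`
#'   are H in bond units (e.g. 33..165 for E. coli).
#' * `"blob_number"`: blob count varied at fixed blob diameter; `values`
#'   are N.
#'
#' Points whose geometry is infeasible are dropped with a warning.
#'
#' @param phys a [physical_parameters()] (reference point: its `blob_d_nm`
#'   and derived N anchor the `constant_density` rule).
#' @param rule sweep rule, see above.
#' @param values sweep values, see above.
#' @param ... passed to [to_lattice()].
#' @return list of `scenario_spec`s (named by value).
#' @export
ensemble_sweep <- function(phys, rule = c("constant_density",
                                          "constant_blob_number",
                                          "cell_length", "blob_number"),
                           values, ...) {
  rule <- match.arg(rule)
  ref_d <- if (!is.null(phys$blob_d_nm)) phys$blob_d_nm else 50
  ref_N <- if (!is.null(phys$n_blobs)) phys$n_blobs else 2000
  out <- list()
  for (v in values) {
    p <- phys
    sc <- tryCatch({
      if (rule == "constant_density") {
        # DNA per blob ~ d^3 (constant density) => N ~ d^-3
        p$blob_d_nm <- v
        p$n_blobs <- as.integer(round(ref_N * (ref_d / v)^3))
        to_lattice(p, model = "blob", label = sprintf("d=%gnm", v), ...)
      } else if (rule == "constant_blob_number") {
        p$blob_d_nm <- v
        p$n_blobs <- ref_N
        to_lattice(p, model = "blob", label = sprintf("d=%gnm", v), ...)
      } else if (rule == "cell_length") {
        p$blob_d_nm <- ref_d
        p$n_blobs <- ref_N
        p$cell_length_um <- v * ref_d / 1000
        to_lattice(p, model = "blob", label = sprintf("H=%g", v), ...)
      } else {
        p$blob_d_nm <- ref_d
        p$n_blobs <- as.integer(v)
        to_lattice(p, model = "blob", label = sprintf("N=%g", v), ...)
      }
    }, error = function(e) {
      warning("sweep point ", v, " infeasible: ", conditionMessage(e))
      NULL
    })
    if (!is.null(sc)) out[[as.character(v)]] <- sc
  }
  out
}

# --- scenario execution ----------------------------------------------------

#' Build the initial configuration of a scenario
#'
#' Seeds the minimal loop / staircase bridge through the scenario's pins
#' and hook-grows each contour segment to its target, honouring mutual
#' exclusion for scenarios with extra chains.
#'
#' @param spec a `scenario_spec` from [preset()] or [to_lattice()].
#' @param max_attempts growth budget per chain.
#' @return a [lattice_walk()], or a [multi_chain()] if the scenario has
#'   extra chains.
#' @export
build_scenario <- function(spec, max_attempts = 1e7) {
  main_seed <- if (spec$topology == "closed") {
    minimal_loop(spec$pin_sites, spec$box, spec$self_avoiding)
  } else {
    seed_open_multipin(spec)
  }
  extras <- lapply(spec$extra_chains %||% list(), function(ec)
    bridge_init(ec$pin_sites[1, ], ec$pin_sites[2, ], spec$box,
                self_avoiding = spec$self_avoiding))
  blocked <- if (length(extras))
    do.call(rbind, lapply(extras, `[[`, "sites")) else NULL
  main <- grow_walk(main_seed,
                    target_length = if (is.null(spec$segment_targets))
                      spec$walk_length else NULL,
                    segment_targets = spec$segment_targets,
                    max_attempts = max_attempts, blocked = blocked)
  # The seed loop is not arm-exchange symmetric (the return staircase
  # carries the lateral detour). For equal-arm chromosomes, randomise the
  # traversal orientation so the built ensemble is exactly symmetric and
  # slow-mode memory of the seed cannot bias one arm.
  if (main$topology == "closed" && length(spec$segment_targets) == 2 &&
      spec$segment_targets[1] == spec$segment_targets[2] &&
      stats::runif(1) < 0.5) {
    n <- n_beads(main)
    main$sites <- main$sites[c(1L, n:2L), , drop = FALSE]
  }
  if (length(extras) == 0) return(main)
  grown_extras <- list()
  occupied <- main$sites
  for (k in seq_along(extras)) {
    ec <- spec$extra_chains[[k]]
    g <- grow_walk(extras[[k]], target_length = ec$walk_length,
                   max_attempts = max_attempts,
                   blocked = rbind(occupied,
                                   if (length(grown_extras))
                                     do.call(rbind, lapply(grown_extras, `[[`, "sites"))))
    grown_extras[[k]] <- g
  }
  multi_chain(c(list(main), grown_extras), mutual_exclusion = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seed_open_multipin <- function(spec) {
  # staircase through all pinned beads in order; pins at their given indices
  ps <- spec$pin_sites
  pieces <- list()
  for (k in seq_len(nrow(ps) - 1)) {
    st <- staircase_sites(ps[k, ], ps[k + 1, ])
    pieces[[k]] <- if (k == 1) st else st[-1, , drop = FALSE]
  }
  sites <- do.call(rbind, pieces)
  idx <- integer(nrow(ps)); pos <- 1L
  for (k in seq_len(nrow(ps))) {
    idx[k] <- pos
    if (k < nrow(ps)) pos <- pos + sum(abs(ps[k + 1, ] - ps[k, ]))
  }
  lattice_walk(sites, "open", spec$self_avoiding, pins = idx, box = spec$box)
}

#' Run a scenario end to end
#'
#' [build_scenario()], equilibrate and sample with [mos_profile()], and
#' summarise with [linearity_report()].
#'
#' @param spec a `scenario_spec` (or preset name).
#' @param n_samples,burn_in,thinning,seed sampler settings (see
#'   [sampler_config()]).
#' @param density accumulate the occupation density as well.
#' @return list with `spec`, `profile` (or list of per-chain profiles),
#'   `report`, `counters`.
#' @export
run_scenario <- function(spec, n_samples = 500, burn_in = NULL,
                         thinning = NULL, seed = NULL, density = FALSE) {
  if (is.character(spec)) spec <- preset(spec)
  if (!is.null(seed)) set.seed(seed)
  x <- build_scenario(spec)
  prof <- mos_profile(x, n_samples = n_samples, burn_in = burn_in,
                      thinning = thinning, density = density)
  main_prof <- if (inherits(prof, "axial_profile")) prof else prof[[1]]
  rep <- linearity_report(main_prof)
  list(spec = spec, profile = prof, report = rep,
       counters = attr(main_prof, "counters"))
}
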