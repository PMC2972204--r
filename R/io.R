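# Readers and writers: walks (JSON and plain text), axial profiles (CSV),
# linearity reports and run manifests (JSON).

#' Write / read a walk as JSON
#'
#' Lossless round-trip of a [lattice_walk()] (box, topology, self-avoidance
#' flag, pins and sites).
#' @param walk a [lattice_walk()].
#' @param path file path.
#' @export
write_walk_json <- function(walk, path) {
  obj <- list(format = "nucleoidwalk/walk", version = 1L,
              box = if (is.null(walk$box)) NULL else as.integer(walk$box),
              topology = walk$topology,
              self_avoiding = walk$self_avoiding,
              pins = walk$pins,
              sites = walk$sites)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_walk_json
#' @export
read_walk_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nucleoidwalk/walk"))
    stop("not a walk file: ", path)
  box <- if (is.null(obj$box) || length(obj$box) == 0) NULL
         else lattice_box(obj$box[1], obj$box[2], obj$box[3])
  lattice_walk(matrix(as.integer(obj$sites), ncol = 3),
               obj$topology, obj$self_avoiding,
               as.integer(obj$pins), box)
}

#' Write / read a walk as plain text
#'
#' An XYZ-like text format: `#`-prefixed header lines (box, topology,
#' self-avoidance, pins) followed by one integer triple per bead.
#' @inheritParams write_walk_json
#' @export
write_walk_text <- function(walk, path) {
  hdr <- c(sprintf("# nucleoidwalk walk v1"),
           sprintf("# box %s", if (is.null(walk$box)) "none"
                   else paste(as.integer(walk$box), collapse = " ")),
           sprintf("# topology %s", walk$topology),
           sprintf("# self_avoiding %s", walk$self_avoiding),
           sprintf("# pins %s", paste(walk$pins, collapse = " ")))
  body <- apply(walk$sites, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_walk_text
#' @export
read_walk_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# nucleoidwalk walk", lines[1]))
    stop("not a walk text file: ", path)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key) sub(paste0("^# ", key, " ?"), "", hdr[grepl(paste0("^# ", key, " "), hdr)][1])
  boxs <- get("box")
  box <- if (identical(boxs, "none")) NULL else {
    v <- as.integer(strsplit(boxs, " ")[[1]])
    lattice_box(v[1], v[2], v[3])
  }
  pins_s <- sub("^# pins ?", "", hdr[grepl("^# pins", hdr)][1])
  pins <- if (nchar(pins_s) == 0) integer(0)
          else as.integer(strsplit(trimws(pins_s), " ")[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  sites <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
  lattice_walk(sites, get("topology"), as.logical(get("self_avoiding")),
               pins, box)
}

#' Write / read an axial profile as CSV
#'
#' Columns `s, s_over_L, mean_z, std_z`. `NaN`/`NA` standard deviations
#' (single-sample profiles) are serialised as empty fields and read back as
#' `NA`. Malformed files raise a parse error naming the offending line.
#'
#' @param profile an [axial_profile].
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)[, c("s", "s_over_L", "mean_z", "std_z")]
  df$std_z[!is.finite(df$std_z)] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error: empty profile file ", path)
  df <- tryCatch(
    utils::read.csv(path, na.strings = ""),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  need <- c("s", "s_over_L", "mean_z", "std_z")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, " (line 1): expected columns ",
         paste(need, collapse = ", "))
  bad <- which(!is.finite(df$s) | !is.finite(df$mean_z))
  if (length(bad) > 0)
    stop("parse error in ", path, " (line ", bad[1] + 1, "): non-numeric value")
  new_axial_profile(df$s, df$mean_z, df$std_z, NA_integer_)
}

#' Reproducibility manifest of a pipeline run
#'
#' All resolved parameters, seeds, move counters and versions needed to
#' reproduce a run bit-identically with the same build.
#' @param scenario a `scenario_spec`.
#' @param config resolved sampler configuration.
#' @param counters sampler counters.
#' @param seed master seed.
#' @export
run_manifest <- function(scenario, config, counters, seed) {
  list(package = "nucleoidwalk",
       version = as.character(utils::packageVersion("nucleoidwalk")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = seed,
       scenario = list(label = scenario$label,
                       box = as.integer(scenario$box),
                       walk_length = scenario$walk_length,
                       topology = scenario$topology,
                       self_avoiding = scenario$self_avoiding,
                       pin_beads = scenario$pin_beads,
                       pin_sites = scenario$pin_sites,
                       segment_targets = scenario$segment_targets,
                       model = scenario$model, bond_nm = scenario$bond_nm,
                       n_extra_chains = length(scenario$extra_chains)),
       sampler = list(n_samples = config$n_samples, burn_in = config$burn_in,
                      thinning = config$thinning,
                      move_weights = config$move_weights),
       counters = counters)
}
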