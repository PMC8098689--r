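# Configuration files, trial outputs, and deterministic test fixtures.
#
# A trial is fully determined by one YAML file with maps `condition`,
# `arena`, `physics`, `agent`, `limits`, `run` plus a top-level `seed` and
# `capacity`; every output directory embeds the echoed config, its hash and
# the seed, so a result directory is sufficient to re-run the trial
# bit-identically.

CONFIG_SECTIONS <- c("seed", "capacity", "condition", "arena", "physics",
                     "agent", "limits", "run")

#' Load a trial configuration file
#'
#' Reads a YAML trial description, validates it against the schema (unknown
#' keys rejected, ranges enforced), fills documented defaults and returns
#' the resulting [trialConfig()].
#'
#' @param path Path to a YAML config file.
#' @return A `trial_config` with every default applied.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  checkKeys(raw, CONFIG_SECTIONS, "config")
  cond_raw <- raw$condition
  if (is.null(cond_raw)) cond_raw <- list(kind = "still_wet")
  checkKeys(cond_raw, c("kind", "fan_side"), "condition")
  cond <- condition(cond_raw$kind, fan_side = cond_raw$fan_side)
  phys_raw <- if (is.null(raw$physics)) list() else raw$physics
  checkKeys(phys_raw, c("D", "ambient_rh", "evap_rate", "k_evap",
                        "lambda_open", "lambda_fan", "gamma"), "physics")
  phys <- do.call(physicsParams, phys_raw)
  agent_raw <- if (is.null(raw$agent)) list() else raw$agent
  checkKeys(agent_raw, c("rh_threshold", "step_length", "drip_per_step",
                         "sense_offset", "heading_noise_sd", "max_forward_y",
                         "reach_radius"), "agent")
  agent <- do.call(agentParams, agent_raw)
  trialConfig(seed = if (is.null(raw$seed)) 1L else raw$seed,
              condition = cond,
              arena = if (is.null(raw$arena)) list() else raw$arena,
              physics = phys, agent = agent,
              capacity = if (is.null(raw$capacity)) 2 else raw$capacity,
              limits = if (is.null(raw$limits)) list() else raw$limits,
              run = if (is.null(raw$run)) list() else raw$run)
}

#' Write a trial configuration file
#'
#' Dumps the fully-expanded configuration (all defaults echoed) so that
#' loading the written file reproduces the config exactly.
#'
#' @param config A `trial_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  cond <- list(kind = config$condition$kind)
  if (config$condition$kind == "fan") cond$fan_side <- config$condition$fan_side
  doc <- list(seed = config$seed,
              capacity = config$capacity,
              condition = cond,
              arena = config$arena,
              physics = unclass(config$physics),
              agent = unclass(config$agent),
              limits = config$limits,
              run = config$run)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  dumpConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

writeGridCsv <- function(mat, path) {
  # rows = y index (tunnel axis), columns = x index
  utils::write.table(t(mat), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

writeGridPng <- function(mat, path, lo = 0, hi = 100) {
  # 8-bit grayscale; image rows run from the arena front (top) to the rear
  g <- (t(mat)[rev(seq_len(ncol(mat))), , drop = FALSE] - lo) / (hi - lo)
  png::writePNG(pmin(pmax(g, 0), 1), path)
  invisible(path)
}

#' Write all outputs of a trial to a directory
#'
#' Writes `events.csv` (the deposition log), `summary.json`,
#' `occupancy.csv`/`occupancy.png`, `field.csv`/`field.png`, `config.yaml`
#' and `provenance.json` (config hash, seed, package version).
#'
#' @param result A `trial_result`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeTrialOutputs <- function(result, dir) {
  stopifnot(inherits(result, "trial_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  dists <- suppressWarnings(triggerDistances(result))
  summary <- list(condition = result$config$condition$kind,
                  fan_side = result$config$condition$fan_side,
                  seed = result$config$seed,
                  termination = result$termination,
                  abort_reason = result$abort_reason,
                  n_events = nrow(result$events),
                  n_forced = sum(result$events$forced),
                  final_gap_cm = maxGapWidth(result$geometry),
                  lid_extent_y = result$geometry$lid_extent_y,
                  mean_distance_cm = if (nrow(dists)) mean(dists$distance)
                                     else NA,
                  water = result$ledger)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeGridCsv(result$geometry$occupancy, file.path(dir, "occupancy.csv"))
  writeGridPng(result$geometry$occupancy, file.path(dir, "occupancy.png"),
               lo = 0, hi = 2)
  writeGridCsv(result$field$values, file.path(dir, "field.csv"))
  writeGridPng(result$field$values, file.path(dir, "field.png"))
  dumpConfig(result$config, file.path(dir, "config.yaml"))
  prov <- list(config_hash = configHash(result$config),
               seed = result$config$seed,
               package = "humitect",
               version = as.character(utils::packageVersion("humitect")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Deterministic fixtures for tests and examples
#'
#' Small constructed instances: `"toy_arena"` (a 10 x 15 arena with short
#' walls), `"prebuilt_closure"` (a default arena with a hand-placed bar
#' leaving an opening exactly at the 5 cm closure threshold), and
#' `"threshold_trace"` (a humidity sample sequence crossing 75% RH at a
#' known index).
#'
#' @param kind One of `"toy_arena"`, `"prebuilt_closure"`,
#'   `"threshold_trace"`.
#' @return The fixture object.
#' @export
makeFixture <- function(kind = c("toy_arena", "prebuilt_closure",
                                 "threshold_trace")) {
  kind <- match.arg(kind)
  switch(kind,
    toy_arena = defaultArena(nx = 10, ny = 15, wall_length = 5,
                             wall_gap = 4, block_size = 2),
    prebuilt_closure = {
      geo <- defaultArena()
      # horizontal bar across the left of the mouth, attached to the left
      # wall tip, leaving a 5-cm-wide passage on the right
      j <- as.integer(geo$initial_wall_front_y / geo$cell_size) + 1L
      iL <- geo$lid_x_range[1]
      bar <- cbind(iL:(geo$lid_x_range[2] - 6L), j)
      placeBlock(geo, bar, cycle = 1L)
    },
    threshold_trace = list(samples = c(85, 80, 76, 74), threshold = 75,
                           first_below = 4L))
}
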