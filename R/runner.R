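# Experiment runner: single trials and condition batches.

CONDITION_KINDS <- c("still_wet", "fan", "dry")

#' Experimental condition
#'
#' The three treatments: still air with a full water reservoir
#' (`"still_wet"`), a fan blowing across the arena (`"fan"`, with the fan
#' side alternated between trials of a batch), and still air with an empty
#' reservoir (`"dry"`, no water dripped).
#'
#' @param kind One of `"still_wet"`, `"fan"`, `"dry"`.
#' @param fan_side `"left"` or `"right"`; only meaningful for `"fan"`.
#' @return An object of class `condition`.
#' @export
condition <- function(kind = c("still_wet", "fan", "dry"), fan_side = NULL) {
  kind <- match.arg(kind)
  if (kind == "fan") {
    if (is.null(fan_side)) fan_side <- "left"
    if (!fan_side %in% c("left", "right")) stop("fan_side must be left or right")
  } else {
    fan_side <- NA_character_
  }
  structure(list(kind = kind, fan_side = fan_side), class = "condition")
}

# default still-air condition (avoids self-referential argument defaults)
defaultCondition <- function() condition("still_wet")

#' Trial configuration
#'
#' Bundles everything that determines a trial: the seed, the condition, the
#' arena geometry parameters, physics and agent parameters, the termination
#' limits (5 cm gap, 14 blocks), and run quantization (field substeps per
#' agent action, burn-in).
#'
#' @param seed Integer seed; with the config it fully determines the trial.
#' @param condition A [condition()].
#' @param arena List of overrides for [defaultArena()] arguments.
#' @param physics A [physicsParams()].
#' @param agent An [agentParams()].
#' @param capacity Substrate saturation capacity, g per cell.
#' @param limits List with `gap_threshold` (cm, default 5) and `max_blocks`
#'   (default 14).
#' @param run List with `dt` (s; default a quarter of the stability bound),
#'   `steps_per_action` (field substeps per agent action, default 40, i.e.
#'   10 s of field time per action), `burn_in_steps` (field steps before the
#'   first action, default 16000, about 67 simulated minutes, enough to reach
#'   the quasi-steady humidity bubble), `max_actions` (safety cap, 4000).
#' @return An object of class `trial_config`.
#' @export
trialConfig <- function(seed, condition = defaultCondition(),
                        arena = list(), physics = physicsParams(),
                        agent = agentParams(), capacity = 2,
                        limits = list(), run = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  arena_def <- list(nx = 35, ny = 55, cell_size = 1, wall_length = 20,
                    wall_gap = 18, block_size = 3)
  checkKeys(arena, names(arena_def), "arena")
  arena <- utils::modifyList(arena_def, arena)
  limits_def <- list(gap_threshold = 5, max_blocks = 14)
  checkKeys(limits, names(limits_def), "limits")
  limits <- utils::modifyList(limits_def, limits)
  run_def <- list(dt = NULL, steps_per_action = 40, burn_in_steps = 16000,
                  max_actions = 4000)
  checkKeys(run, names(run_def), "run")
  run <- utils::modifyList(run_def, run, keep.null = TRUE)
  if (is.null(run$dt)) {
    run$dt <- 0.25 * stabilityDt(physics$D, arena$cell_size)
  }
  if (run$dt > stabilityDt(physics$D, arena$cell_size) + 1e-12) {
    stop("run$dt violates the diffusion stability bound")
  }
  if (physics$lambda_fan * run$dt > 1) {
    stop("lambda_fan * dt must not exceed 1 (relaxation overshoot)")
  }
  stopifnot(limits$gap_threshold > 0, limits$max_blocks >= 0, capacity > 0,
            run$steps_per_action >= 1, run$burn_in_steps >= 0,
            run$max_actions >= 1)
  structure(list(seed = as.integer(seed), condition = condition,
                 arena = arena, physics = physics, agent = agent,
                 capacity = capacity, limits = limits, run = run),
            class = "trial_config")
}

checkKeys <- function(given, allowed, where) {
  extra <- setdiff(names(given), allowed)
  if (length(extra)) {
    stop(sprintf("unknown %s key(s): %s", where, paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

# interior (between-wall) mask of the initial tunnel
tunnelInteriorMask <- function(geometry) {
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  h <- geometry$cell_size
  iL <- geometry$lid_x_range[1]; iR <- geometry$lid_x_range[2]
  wall_j <- as.integer(round(geometry$initial_wall_front_y / h))
  m <- matrix(FALSE, nx, ny)
  if (iR - iL >= 2 && wall_j >= 1) {
    m[(iL + 1):(iR - 1), seq_len(wall_j)] <- TRUE
  }
  m
}

#' Run a single trial
#'
#' Builds the arena, saturates the tiles between the walls (dry beyond the
#' tunnel's end), sets the humidity field to saturation over the wet
#' interior and ambient elsewhere, runs a burn-in so the humidity bubble
#' forms at the wet/dry boundary, then interleaves field substeps with agent
#' actions, extending the lid after each deposition cycle, until the closure
#' or block-limit rule fires.
#'
#' @param config A [trialConfig()].
#' @return An object of class `trial_result`: `events` (one row per
#'   deposition: cycle, trigger position, humidity at trigger, forced flag,
#'   block id, simulated time), `termination` (`"CLOSURE"`,
#'   `"BLOCK_LIMIT"` or `"ABORT"`), the final `geometry`, `field`,
#'   `moisture`, a water `ledger`, and the echoed `config`.
#' @export
runTrial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  geometry <- do.call(defaultArena, config$arena)
  params <- config$agent
  if (config$condition$kind == "dry") params$drip_per_step <- 0

  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  wet <- tunnelInteriorMask(geometry)
  rh0 <- matrix(config$physics$ambient_rh, nx, ny)
  rh0[wet] <- 100
  field <- humidityField(rh0, geometry$cell_size, config$run$dt,
                         D = config$physics$D)
  mass0 <- matrix(0, nx, ny)
  mass0[wet] <- config$capacity
  moisture <- substrateMoisture(mass0, config$capacity)

  ledger <- list(initial_mass = sum(mass0), dripped = 0, runoff = 0,
                 ambient_loss = 0)

  for (s in seq_len(config$run$burn_in_steps)) {
    st <- stepField(field, moisture, geometry, config$physics,
                    config$condition)
    field <- st$field; moisture <- st$moisture
    ledger$ambient_loss <- ledger$ambient_loss + st$ambient_loss
  }

  agent <- newAgent(geometry)
  events <- list()
  blocks_placed <- 0L
  termination <- NA_character_
  abort_reason <- NA_character_
  actions <- 0L
  sim_time <- config$run$burn_in_steps * config$run$dt

  repeat {
    term <- checkTermination(geometry, blocks_placed, config$limits)
    if (term != "NONE") { termination <- term; break }
    if (actions >= config$run$max_actions) {
      termination <- "ABORT"; abort_reason <- "action budget exhausted"; break
    }
    for (s in seq_len(config$run$steps_per_action)) {
      st <- stepField(field, moisture, geometry, config$physics,
                      config$condition)
      field <- st$field; moisture <- st$moisture
      ledger$ambient_loss <- ledger$ambient_loss + st$ambient_loss
    }
    sim_time <- sim_time + config$run$steps_per_action * config$run$dt
    res <- stepStateMachine(agent, geometry, field, moisture, params)
    agent <- res$agent; geometry <- res$geometry; moisture <- res$moisture
    ledger$dripped <- ledger$dripped + res$dripped
    ledger$runoff <- ledger$runoff + res$runoff
    actions <- actions + 1L
    if (res$status == "aborted") {
      termination <- "ABORT"; abort_reason <- res$reason; break
    }
    if (!is.null(res$event)) {
      ev <- res$event
      ev$sim_time <- sim_time
      events[[length(events) + 1L]] <- ev
      blocks_placed <- blocks_placed + 1L
      geometry <- extendLid(geometry)
    }
  }

  events_df <- if (length(events)) {
    do.call(rbind, lapply(events, function(e) {
      data.frame(cycle = e$cycle, trigger_x = e$trigger_x,
                 trigger_y = e$trigger_y, rh_at_trigger = e$rh_at_trigger,
                 forced = e$forced, block_id = e$block_id,
                 sim_time = e$sim_time)
    }))
  } else {
    data.frame(cycle = integer(0), trigger_x = numeric(0),
               trigger_y = numeric(0), rh_at_trigger = numeric(0),
               forced = logical(0), block_id = integer(0),
               sim_time = numeric(0))
  }

  structure(list(events = events_df, termination = termination,
                 abort_reason = abort_reason, geometry = geometry,
                 field = field, moisture = moisture, ledger = ledger,
                 config = config),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s / seed %d: %d depositions, termination %s\n",
              x$config$condition$kind, x$config$seed, nrow(x$events),
              x$termination))
  invisible(x)
}

#' Run a batch of independent trials
#'
#' Runs `n` seeded replicates of a base configuration. Fan batches alternate
#' the fan side between trials, starting from the base condition's side.
#'
#' @param base A [trialConfig()].
#' @param n Number of trials (>= 1).
#' @param seeds Integer vector of `n` distinct seeds; defaults to
#'   `base$seed + 0:(n-1)`.
#' @return A list of `trial_result` objects.
#' @export
runBatch <- function(base, n, seeds = NULL) {
  stopifnot(inherits(base, "trial_config"), n >= 1)
  if (is.null(seeds)) seeds <- base$seed + seq_len(n) - 1L
  if (length(seeds) != n) stop("need exactly n seeds")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  sides <- c("left", "right")
  first <- if (base$condition$kind == "fan" &&
               !is.na(base$condition$fan_side)) base$condition$fan_side
           else "left"
  offset <- match(first, sides) - 1L
  lapply(seq_len(n), function(k) {
    cfg <- base
    cfg$seed <- as.integer(seeds[k])
    if (cfg$condition$kind == "fan") {
      cfg$condition$fan_side <- sides[((k - 1L + offset) %% 2L) + 1L]
    }
    runTrial(cfg)
  })
}
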