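# Agent: the builder's behavioural state machine.
#
# One loop (cycle): collect a block at the rear supply, turn to face the
# tunnel mouth, advance in small steps dripping water and sampling humidity
# ahead of itself, deposit the block against existing structure where the
# sampled humidity first falls below threshold, then return to the rear.

AGENT_STATES <- c("COLLECT_BLOCK", "ORIENT_FORWARD", "ADVANCE_SAMPLE",
                  "DEPOSIT", "RETURN_REAR")

#' Agent parameters
#'
#' @param rh_threshold Deposition trigger threshold, % RH; the agent deposits
#'   where the sampled humidity falls strictly below it. Default 75.
#' @param step_length Forward step, cm. Default 2.
#' @param drip_per_step Water passively dripped onto the substrate per
#'   outbound step, g. Default 0.2; the dry treatment sets it to 0.
#' @param sense_offset Distance ahead of the agent at which humidity is
#'   sampled, cm. Default 2.
#' @param heading_noise_sd Gaussian heading noise applied when the agent
#'   turns to face the mouth, degrees. Default 3; set 0 for exact tests.
#' @param max_forward_y Travel cap along the tunnel axis, cm; reaching it
#'   forces a deposition (flagged, and excluded from statistics). Default 48.
#' @param reach_radius Radius around the agent within which it can attach a
#'   block, cm. Default 5.
#' @return An object of class `agent_params`.
#' @export
agentParams <- function(rh_threshold = 75, step_length = 2,
                        drip_per_step = 0.2, sense_offset = 2,
                        heading_noise_sd = 3, max_forward_y = 48,
                        reach_radius = 5) {
  stopifnot(rh_threshold > 0, rh_threshold < 100, step_length > 0,
            drip_per_step >= 0, sense_offset >= 0, heading_noise_sd >= 0,
            max_forward_y > 0, reach_radius > 0)
  structure(list(rh_threshold = rh_threshold, step_length = step_length,
                 drip_per_step = drip_per_step, sense_offset = sense_offset,
                 heading_noise_sd = heading_noise_sd,
                 max_forward_y = max_forward_y, reach_radius = reach_radius),
            class = "agent_params")
}

#' Create an agent at the supply position
#'
#' @param geometry An `arena_geometry`; the agent starts at the centre of the
#'   supply cell, facing the mouth.
#' @return An object of class `builder_agent`.
#' @export
newAgent <- function(geometry) {
  h <- geometry$cell_size
  pos <- (geometry$supply_cell - 0.5) * h
  structure(list(position = pos, heading = c(0, 1), state = "COLLECT_BLOCK",
                 carrying = FALSE, cycle = 0L, pending = NULL,
                 blocked = 0L, path = NULL),
            class = "builder_agent")
}

#' @export
print.builder_agent <- function(x, ...) {
  cat(sprintf("<builder_agent> cycle %d, state %s, at (%.1f, %.1f) cm%s\n",
              x$cycle, x$state, x$position[1], x$position[2],
              if (x$carrying) ", carrying" else ""))
  invisible(x)
}

cellOf <- function(position, geometry) {
  h <- geometry$cell_size
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  c(min(max(floor(position[1] / h) + 1L, 1L), nx),
    min(max(floor(position[2] / h) + 1L, 1L), ny))
}

clampPosition <- function(position, geometry) {
  h <- geometry$cell_size
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  c(min(max(position[1], h / 2), nx * h - h / 2),
    min(max(position[2], h / 2), ny * h - h / 2))
}

# breadth-first shortest path over empty cells, 4-adjacency;
# returns an n x 2 matrix of cells (excluding `from`) or NULL
bfsPath <- function(geometry, from, to) {
  occ <- geometry$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  idx <- function(c2) (c2[2] - 1L) * nx + c2[1]
  from_i <- idx(from); to_i <- idx(to)
  if (occ[from_i] != OCC_EMPTY || occ[to_i] != OCC_EMPTY) return(NULL)
  prev <- integer(nx * ny)
  seen <- logical(nx * ny)
  seen[from_i] <- TRUE
  queue <- from_i
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to_i) break
    i <- ((cur - 1L) %% nx) + 1L
    j <- ((cur - 1L) %/% nx) + 1L
    nb <- neighbours4(i, j, nx, ny)
    nb_idx <- (nb[, 2] - 1L) * nx + nb[, 1]
    fresh <- nb_idx[occ[nb_idx] == OCC_EMPTY & !seen[nb_idx]]
    seen[fresh] <- TRUE
    prev[fresh] <- cur
    queue <- c(queue, fresh)
  }
  if (!seen[to_i]) return(NULL)
  path <- integer(0)
  cur <- to_i
  while (cur != from_i) {
    path <- c(cur, path)
    cur <- prev[cur]
  }
  if (!length(path)) return(matrix(integer(0), 0, 2))
  cbind(((path - 1L) %% nx) + 1L, ((path - 1L) %/% nx) + 1L)
}

# all valid square footprints: empty, attached to structure, not under the
# agent; returns anchors (n x 2) and centroids in cm
validFootprints <- function(geometry, agent_cell = NULL) {
  occ <- geometry$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  b <- geometry$block_size
  h <- geometry$cell_size
  empty <- occ == OCC_EMPTY
  solid <- !empty
  # squares of empty cells via summed-area table
  sat <- t(apply(apply(empty, 2, cumsum), 1, cumsum))
  # structure within one cell of the square (4-adjacency on the perimeter):
  # test by dilating the solid mask one step in each axis direction
  dil <- solid
  dil[-1, ] <- dil[-1, ] | solid[-nx, ]
  dil[-nx, ] <- dil[-nx, ] | solid[-1, ]
  dil[, -1] <- dil[, -1] | solid[, -ny]
  dil[, -ny] <- dil[, -ny] | solid[, -1]
  satd <- t(apply(apply(dil, 2, cumsum), 1, cumsum))
  boxSum <- function(s, i1, j1, i2, j2) {
    v <- s[i2, j2]
    if (i1 > 1) v <- v - s[i1 - 1L, j2]
    if (j1 > 1) v <- v - s[i2, j1 - 1L]
    if (i1 > 1 && j1 > 1) v <- v + s[i1 - 1L, j1 - 1L]
    v
  }
  anchors <- NULL
  for (i in seq_len(nx - b + 1L)) {
    for (j in seq_len(ny - b + 1L)) {
      if (boxSum(sat, i, j, i + b - 1L, j + b - 1L) != b * b) next
      # attached iff some footprint cell has a solid 4-neighbour, i.e. the
      # dilated-solid mask overlaps the footprint
      if (boxSum(satd, i, j, i + b - 1L, j + b - 1L) == 0) next
      if (!is.null(agent_cell) &&
          agent_cell[1] >= i && agent_cell[1] <= i + b - 1L &&
          agent_cell[2] >= j && agent_cell[2] <= j + b - 1L) next
      anchors <- rbind(anchors, c(i, j))
    }
  }
  if (is.null(anchors)) {
    return(list(anchors = matrix(integer(0), 0, 2),
                centroids = matrix(numeric(0), 0, 2)))
  }
  centroids <- cbind((anchors[, 1] + (b - 2) / 2) * h,
                     (anchors[, 2] + (b - 2) / 2) * h)
  list(anchors = anchors, centroids = centroids)
}

#' Choose where to attach the carried block
#'
#' Among all valid square footprints (empty, 4-adjacent to a wall or block,
#' not under the agent) within the agent's reach, returns the one whose
#' centroid is nearest the trigger position; ties break toward smaller x,
#' then smaller y. If none is in reach the agent sidesteps toward the
#' nearest structure cell and retries.
#'
#' @param agent A `builder_agent` in state `DEPOSIT` (its `pending` trigger
#'   is used as the target).
#' @param geometry An `arena_geometry`.
#' @param params An `agent_params` (reach radius).
#' @return List with `footprint` (cells matrix), `anchor`, and the possibly
#'   sidestepped `agent`.
#' @export
selectDepositionSite <- function(agent, geometry, params) {
  trigger <- agent$pending$position
  b <- geometry$block_size
  h <- geometry$cell_size
  for (attempt in seq_len(60L)) {
    vf <- validFootprints(geometry, agent_cell = cellOf(agent$position, geometry))
    if (nrow(vf$anchors) == 0) stop("no attachment point")
    d_agent <- sqrt((vf$centroids[, 1] - agent$position[1])^2 +
                    (vf$centroids[, 2] - agent$position[2])^2)
    in_reach <- d_agent <= params$reach_radius + 1e-9
    if (any(in_reach)) {
      anchors <- vf$anchors[in_reach, , drop = FALSE]
      cents <- vf$centroids[in_reach, , drop = FALSE]
      d_trig <- sqrt((cents[, 1] - trigger[1])^2 + (cents[, 2] - trigger[2])^2)
      ord <- order(round(d_trig, 9), anchors[, 1], anchors[, 2])
      pick <- ord[1]
      return(list(footprint = footprintSquare(anchors[pick, ], b),
                  anchor = anchors[pick, ], agent = agent))
    }
    # sidestep one cell toward the nearest structure cell and retry
    occ <- geometry$occupancy
    solid_idx <- which(occ != OCC_EMPTY)
    if (!length(solid_idx)) stop("no attachment point")
    nx <- nrow(occ)
    si <- ((solid_idx - 1L) %% nx) + 1L
    sj <- ((solid_idx - 1L) %/% nx) + 1L
    sx <- (si - 0.5) * h; sy <- (sj - 0.5) * h
    k <- which.min((sx - agent$position[1])^2 + (sy - agent$position[2])^2)
    dir <- c(sx[k], sy[k]) - agent$position
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) stop("no attachment point")
    cand <- clampPosition(agent$position + dir / nrm * h, geometry)
    if (all(occ[t(cellOf(cand, geometry))] == OCC_EMPTY)) {
      agent$position <- cand
    } else {
      stop("no attachment point")
    }
  }
  stop("no attachment point")
}

#' Advance the behavioural state machine by one action
#'
#' Executes one action of the agent's current state and performs the
#' corresponding transition: collect a block at the supply, turn toward the
#' mouth with seeded heading noise, advance one step while dripping water
#' and sampling humidity ahead (a sample strictly below the threshold, or
#' reaching the travel cap, triggers deposition), deposit the block against
#' existing structure, or walk the return path to the supply.
#'
#' Uses R's global random-number stream (seed it via the trial runner).
#'
#' @param agent A `builder_agent`.
#' @param geometry An `arena_geometry`.
#' @param field A `humidity_field`.
#' @param moisture A `substrate_moisture`.
#' @param params An `agent_params`.
#' @return List with updated `agent`, `geometry`, `moisture`, `dripped` and
#'   `runoff` (g this action), `event` (a deposition record or `NULL`), and
#'   `status` (`"ok"` or `"aborted"` with a `reason`).
#' @export
stepStateMachine <- function(agent, geometry, field, moisture, params) {
  out <- list(agent = agent, geometry = geometry, moisture = moisture,
              dripped = 0, runoff = 0, event = NULL, status = "ok",
              reason = NA_character_)
  h <- geometry$cell_size
  a <- agent

  if (a$state == "COLLECT_BLOCK") {
    a$position <- (geometry$supply_cell - 0.5) * h
    a$carrying <- TRUE
    a$cycle <- a$cycle + 1L
    a$state <- "ORIENT_FORWARD"
    a$blocked <- 0L

  } else if (a$state == "ORIENT_FORWARD") {
    theta <- stats::rnorm(1, 0, params$heading_noise_sd) * pi / 180
    a$heading <- c(sin(theta), cos(theta))
    a$state <- "ADVANCE_SAMPLE"

  } else if (a$state == "ADVANCE_SAMPLE") {
    target <- clampPosition(a$position + params$step_length * a$heading,
                            geometry)
    tcell <- cellOf(target, geometry)
    if (geometry$occupancy[tcell[1], tcell[2]] == OCC_EMPTY) {
      a$position <- target
      a$blocked <- 0L
    } else {
      # structure ahead: straighten up and count the stall
      a$heading <- c(0, 1)
      a$blocked <- a$blocked + 1L
    }
    if (params$drip_per_step > 0) {
      dw <- depositWater(moisture, cellOf(a$position, geometry),
                         params$drip_per_step)
      moisture <- dw$moisture
      out$dripped <- params$drip_per_step
      out$runoff <- dw$runoff
    }
    sense <- clampPosition(a$position + params$sense_offset * a$heading,
                           geometry)
    rh <- sampleHumidity(field, sense)
    if (rh < params$rh_threshold) {
      a$pending <- list(position = sense, rh = rh, forced = FALSE)
      a$state <- "DEPOSIT"
    } else if (a$position[2] >= params$max_forward_y || a$blocked >= 3L) {
      a$pending <- list(position = sense, rh = rh, forced = TRUE)
      a$state <- "DEPOSIT"
    }

  } else if (a$state == "DEPOSIT") {
    site <- tryCatch(selectDepositionSite(a, geometry, params),
                     error = function(e) e)
    if (inherits(site, "error")) {
      out$status <- "aborted"
      out$reason <- conditionMessage(site)
      out$agent <- a
      out$moisture <- moisture
      return(out)
    }
    a <- site$agent
    geometry <- placeBlock(geometry, site$footprint, cycle = a$cycle)
    id <- length(geometry$blocks)
    out$event <- list(cycle = a$cycle,
                      trigger_x = a$pending$position[1],
                      trigger_y = a$pending$position[2],
                      rh_at_trigger = a$pending$rh,
                      forced = a$pending$forced,
                      block_id = id)
    a$pending <- NULL
    a$carrying <- FALSE
    a$state <- "RETURN_REAR"
    a$path <- NULL

  } else if (a$state == "RETURN_REAR") {
    cur <- cellOf(a$position, geometry)
    if (is.null(a$path) || !nrow(a$path)) {
      a$path <- bfsPath(geometry, cur, geometry$supply_cell)
      if (is.null(a$path)) {
        out$status <- "aborted"
        out$reason <- "trapped agent"
        out$agent <- a
        out$moisture <- moisture
        return(out)
      }
    }
    k <- min(max(1L, as.integer(round(params$step_length / h))), nrow(a$path))
    if (k >= 1 && nrow(a$path)) {
      dest <- a$path[k, ]
      a$path <- a$path[-seq_len(k), , drop = FALSE]
      a$position <- (dest - 0.5) * h
    }
    if (all(cellOf(a$position, geometry) == geometry$supply_cell)) {
      a$state <- "COLLECT_BLOCK"
      a$path <- NULL
    }
  } else {
    stop("unknown agent state: ", a$state)
  }

  out$agent <- a
  out$geometry <- geometry
  out$moisture <- moisture
  out
}
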