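# Field physics: 2D relative-humidity lattice coupled to substrate moisture.
#
# Units used throughout: lengths in cm, time in s, water mass in g, humidity
# in % RH. The field evolves by explicit finite-difference diffusion with
# no-flux boundaries at walls, blocks and the arena edge; uncovered cells
# relax toward ambient humidity; wet substrate evaporates into the local air
# with a linear saturation-deficit law.

RH_SAT <- 100

#' Stability bound for the explicit diffusion scheme
#'
#' Largest time step for which the forward-time centred-space update of the
#' diffusion equation is stable on a square lattice: `dt <= h^2 / (4 D)`.
#'
#' @param D Diffusion coefficient, cm^2/s.
#' @param cell_size Lattice spacing, cm.
#' @return Maximum stable time step, s.
#' @export
stabilityDt <- function(D, cell_size) {
  stopifnot(D > 0, cell_size > 0)
  cell_size^2 / (4 * D)
}

#' Calibrate the evaporation coefficient to a measured hourly loss
#'
#' Under the evaporation law
#' `mass_loss_per_step = k_evap * max(0, 100 - RH_local) * dt`,
#' returns the coefficient `k_evap` for which a fully saturated cell held at
#' a fixed local humidity equal to `ambient_rh` loses exactly `target_rate`
#' grams over one simulated hour. The tile substrate loses 0.75 g/h at 40%
#' ambient humidity; the reference clay-heavy soil loses 0.6 g/h.
#'
#' @param target_rate Measured loss, g/h (>= 0).
#' @param ambient_rh Ambient relative humidity during the measurement, % RH,
#'   in `[0, 100)`.
#' @return Evaporation coefficient, g per s per % RH of saturation deficit.
#' @examples
#' calibrateEvaporation(0.75, 40)  # tile preset
#' calibrateEvaporation(0.6, 40)   # soil preset
#' @export
calibrateEvaporation <- function(target_rate, ambient_rh) {
  stopifnot(is.numeric(target_rate), length(target_rate) == 1L,
            is.numeric(ambient_rh), length(ambient_rh) == 1L)
  if (target_rate < 0) stop("target_rate must be >= 0")
  if (ambient_rh < 0 || ambient_rh >= RH_SAT) {
    stop("uncalibratable: ambient humidity leaves no saturation deficit")
  }
  target_rate / 3600 / (RH_SAT - ambient_rh)
}

#' Integrate one hour of single-cell evaporation
#'
#' Explicit time integration of the evaporation law for one saturated cell
#' whose local humidity is clamped to `ambient_rh` (a well-ventilated cell):
#' the round-trip check on [calibrateEvaporation()].
#'
#' @param target_rate Calibration target, g/h.
#' @param ambient_rh Clamped local humidity, % RH.
#' @param dt Time step, s; must divide one hour evenly.
#' @param initial_mass Starting water mass of the cell, g.
#' @return Total mass lost over one simulated hour, g.
#' @export
evaporationHourLoss <- function(target_rate, ambient_rh, dt = 0.25,
                                initial_mass = 2) {
  k <- calibrateEvaporation(target_rate, ambient_rh)
  n <- 3600 / dt
  if (abs(n - round(n)) > 1e-9) stop("dt must divide 3600 s evenly")
  n <- as.integer(round(n))
  per_step <- k * (RH_SAT - ambient_rh) * dt
  mass <- initial_mass
  lost <- 0
  for (i in seq_len(n)) {
    d <- min(mass, per_step)
    mass <- mass - d
    lost <- lost + d
  }
  lost
}

#' Physics parameter set
#'
#' Bundles the constants of the humidity-moisture model. `k_evap` defaults to
#' the tile calibration (`evap_rate` g/h at `ambient_rh`).
#'
#' @param D Vapour diffusion coefficient, cm^2/s. Default 0.25, the
#'   diffusivity of water vapour in room-temperature air.
#' @param ambient_rh Ambient (far-field) relative humidity, % RH. Default 40.
#' @param evap_rate Calibration target for the substrate, g/h. Default 0.75
#'   (saturated unglazed tile); 0.6 is the soil preset.
#' @param k_evap Evaporation coefficient; computed from `evap_rate` unless
#'   given directly.
#' @param lambda_open Ambient-exchange rate for uncovered cells in still air,
#'   1/s. Default 5e-4 (slow mixing of still indoor air).
#' @param lambda_fan Exchange rate for fan-swept cells, 1/s. Default 1 (about
#'   one air change per second in the fan stream);
#'   must be >= `lambda_open`.
#' @param gamma Coupling constant: % RH rise of one cell's air column per
#'   gram evaporated into it. Default 3e4, so saturating a cell's air from
#'   40 to 100% RH consumes 0.002 g (well under 1% of cell capacity) and a
#'   saturated cell holds its own air near saturation against still-air
#'   exchange (`k_evap * gamma >> lambda_open`).
#' @return An object of class `physics_params`.
#' @export
physicsParams <- function(D = 0.25, ambient_rh = 40, evap_rate = 0.75,
                          k_evap = calibrateEvaporation(evap_rate, ambient_rh),
                          lambda_open = 5e-4, lambda_fan = 1,
                          gamma = 3e4) {
  stopifnot(D > 0, ambient_rh >= 0, ambient_rh < RH_SAT,
            k_evap >= 0, lambda_open >= 0, lambda_fan >= 0, gamma > 0)
  if (lambda_fan < lambda_open) stop("lambda_fan must be >= lambda_open")
  structure(list(D = D, ambient_rh = ambient_rh, evap_rate = evap_rate,
                 k_evap = k_evap, lambda_open = lambda_open,
                 lambda_fan = lambda_fan, gamma = gamma),
            class = "physics_params")
}

#' Relative-humidity lattice
#'
#' @param values nx x ny matrix of relative humidity, % RH, each in
#'   `[0, 100]`. Row index i runs along x (across the tunnel), column index
#'   j along y (the tunnel axis, pointing out of the mouth).
#' @param cell_size Lattice spacing, cm.
#' @param dt Time step, s.
#' @param D Optional diffusion coefficient; when given, `dt` is checked
#'   against the explicit-scheme stability bound at construction.
#' @return An object of class `humidity_field`.
#' @export
humidityField <- function(values, cell_size = 1, dt = 0.25, D = NULL) {
  stopifnot(is.matrix(values), nrow(values) >= 1, ncol(values) >= 1,
            cell_size > 0, dt > 0)
  if (any(!is.finite(values)) || any(values < 0) || any(values > RH_SAT)) {
    stop("humidity values must be finite and in [0, 100]")
  }
  if (!is.null(D) && dt > stabilityDt(D, cell_size) + 1e-12) {
    stop("dt violates the explicit-scheme stability bound h^2/(4D)")
  }
  structure(list(values = values, cell_size = cell_size, dt = dt),
            class = "humidity_field")
}

#' Substrate moisture lattice
#'
#' Per-cell water mass of the absorbent floor, bounded by a common
#' saturation capacity.
#'
#' @param mass nx x ny matrix of water mass, g.
#' @param capacity Saturation capacity of one cell, g. Default 2.
#' @return An object of class `substrate_moisture`.
#' @export
substrateMoisture <- function(mass, capacity = 2) {
  stopifnot(is.matrix(mass), capacity > 0)
  if (any(!is.finite(mass)) || any(mass < -1e-12) ||
      any(mass > capacity + 1e-12)) {
    stop("moisture mass must be finite and within [0, capacity]")
  }
  structure(list(mass = pmin(pmax(mass, 0), capacity), capacity = capacity),
            class = "substrate_moisture")
}

#' @export
print.humidity_field <- function(x, ...) {
  cat(sprintf("<humidity_field> %d x %d cells, %.3g cm, dt = %.3g s, RH %.1f-%.1f%%\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$dt,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.substrate_moisture <- function(x, ...) {
  cat(sprintf("<substrate_moisture> %d x %d cells, %.3g g stored (capacity %.3g g/cell)\n",
              nrow(x$mass), ncol(x$mass), sum(x$mass), x$capacity))
  invisible(x)
}

#' Advance field and moisture by one explicit time step
#'
#' Applies, in order: (1) diffusion of humidity with no-flux conditions at
#' walls, blocks and the arena boundary; (2) relaxation toward ambient
#' humidity at rate `lambda_open` for open uncovered cells, `lambda_fan` for
#' fan-swept cells under the fan condition, and zero under the lid;
#' (3) evaporation from wet substrate into the local air, capped by the
#' available water and by the saturation deficit.
#'
#' @param field A [humidityField()].
#' @param moisture A [substrateMoisture()] on the same lattice.
#' @param geometry An [arenaGeometry()] on the same lattice.
#' @param params A [physicsParams()].
#' @param condition A [condition()]; fan-swept exchange applies only when its
#'   kind is `"fan"`.
#' @return A list with elements `field`, `moisture`, and `ambient_loss` — the
#'   net water-equivalent mass (g) lost to the ambient air this step
#'   (humidity removed by relaxation divided by `gamma`).
#' @export
stepField <- function(field, moisture, geometry, params,
                      condition = defaultCondition()) {
  v <- field$values
  nx <- nrow(v); ny <- ncol(v)
  if (!all(dim(moisture$mass) == c(nx, ny)) ||
      !all(dim(geometry$occupancy) == c(nx, ny))) {
    stop("field, moisture and geometry lattices must have identical dimensions")
  }
  h <- field$cell_size; dt <- field$dt
  alpha <- params$D * dt / h^2
  if (alpha > 0.25 + 1e-12) {
    stop("dt violates the explicit-scheme stability bound h^2/(4D)")
  }
  open <- geometry$occupancy == OCC_EMPTY

  # (1) diffusion: pairwise fluxes between open 4-neighbours only (no-flux
  # elsewhere), which conserves the open-cell humidity sum exactly
  lap <- matrix(0, nx, ny)
  if (nx > 1) {
    d <- (v[-nx, , drop = FALSE] - v[-1, , drop = FALSE]) *
      (open[-nx, , drop = FALSE] & open[-1, , drop = FALSE])
    lap[-1, ] <- lap[-1, , drop = FALSE] + d
    lap[-nx, ] <- lap[-nx, , drop = FALSE] - d
  }
  if (ny > 1) {
    d <- (v[, -ny, drop = FALSE] - v[, -1, drop = FALSE]) *
      (open[, -ny, drop = FALSE] & open[, -1, drop = FALSE])
    lap[, -1] <- lap[, -1, drop = FALSE] + d
    lap[, -ny] <- lap[, -ny, drop = FALSE] - d
  }
  v1 <- v + alpha * lap

  # (2) ambient exchange for open cells not under the lid
  lam <- matrix(0, nx, ny)
  exch <- open & !coveredMask(geometry)
  lam[exch] <- params$lambda_open
  if (identical(condition$kind, "fan")) {
    lam[exch & fanMask(geometry, condition$fan_side)] <- params$lambda_fan
  }
  v2 <- v1 + lam * dt * (params$ambient_rh - v1)
  ambient_loss <- sum(v1 - v2) / params$gamma

  # (3) evaporation: transfer limited by stored water and by the deficit so
  # humidity never overshoots saturation (keeps the mass ledger exact)
  deficit <- pmax(0, RH_SAT - v2)
  transfer <- pmin(moisture$mass, params$k_evap * deficit * dt,
                   deficit / params$gamma)
  transfer[!open] <- 0
  mass <- moisture$mass - transfer
  v3 <- v2 + params$gamma * transfer

  if (any(!is.finite(v3)) || any(v3 < -1e-9) || any(v3 > RH_SAT + 1e-9)) {
    stop("internal-consistency error: humidity left [0, 100] after step")
  }
  v3 <- pmin(pmax(v3, 0), RH_SAT)

  list(field = humidityField(v3, h, dt),
       moisture = substrateMoisture(mass, moisture$capacity),
       ambient_loss = ambient_loss)
}

#' Add water to a substrate cell
#'
#' Water dripped by the agent soaks into the cell up to its saturation
#' capacity; the excess runs off and is reported.
#'
#' @param moisture A [substrateMoisture()].
#' @param cell Integer cell index `c(i, j)`.
#' @param amount Water added, g (>= 0).
#' @return A list with the updated `moisture` and the `runoff` in g.
#' @export
depositWater <- function(moisture, cell, amount) {
  stopifnot(length(cell) == 2, amount >= 0)
  nx <- nrow(moisture$mass); ny <- ncol(moisture$mass)
  i <- as.integer(cell[1]); j <- as.integer(cell[2])
  if (i < 1 || i > nx || j < 1 || j > ny) stop("cell outside the lattice")
  new_mass <- min(moisture$mass[i, j] + amount, moisture$capacity)
  runoff <- moisture$mass[i, j] + amount - new_mass
  moisture$mass[i, j] <- new_mass
  list(moisture = moisture, runoff = runoff)
}

#' Sample humidity at a continuous position
#'
#' Bilinear interpolation of the four cell-centre values surrounding a
#' continuous position (cm from the rear-left origin). Positions within half
#' a cell of the arena edge use the edge cell's value in that direction.
#'
#' @param field A [humidityField()].
#' @param position Numeric `c(x, y)` in cm.
#' @return Interpolated relative humidity, % RH.
#' @export
sampleHumidity <- function(field, position) {
  stopifnot(length(position) == 2)
  v <- field$values; h <- field$cell_size
  nx <- nrow(v); ny <- ncol(v)
  x <- position[1]; y <- position[2]
  if (!is.finite(x) || !is.finite(y) ||
      x < 0 || x > nx * h || y < 0 || y > ny * h) {
    stop("position outside the arena")
  }
  # cell centres sit at index - 0.5 (in cell units)
  gx <- min(max(x / h + 0.5, 1), nx)
  gy <- min(max(y / h + 0.5, 1), ny)
  i0 <- min(max(floor(gx), 1), max(nx - 1, 1))
  j0 <- min(max(floor(gy), 1), max(ny - 1, 1))
  fx <- gx - i0; fy <- gy - j0
  i1 <- min(i0 + 1, nx); j1 <- min(j0 + 1, ny)
  (1 - fx) * (1 - fy) * v[i0, j0] + fx * (1 - fy) * v[i1, j0] +
    (1 - fx) * fy * v[i0, j1] + fx * fy * v[i1, j1]
}
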