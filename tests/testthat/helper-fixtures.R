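# shared helpers: tiny lattices and an open (wall-free) geometry for physics
# tests, built in code at test time

emptyGeometry <- function(nx, ny, cell_size = 1) {
  arenaGeometry(matrix(OCC_EMPTY, nx, ny), cell_size = cell_size,
                lid_extent_y = 0, lid_x_range = c(1L, 0L),
                supply_cell = c(1L, 1L), block_size = 2L)
}

uniformField <- function(nx, ny, value = 40, cell_size = 1, dt = 0.25) {
  humidityField(matrix(value, nx, ny), cell_size, dt)
}

dryMoisture <- function(nx, ny, capacity = 2) {
  substrateMoisture(matrix(0, nx, ny), capacity)
}

# fast-converging small config for runner tests
tinyTrialConfig <- function(seed, kind = "still_wet", ...) {
  trialConfig(seed, condition = condition(kind),
              arena = list(nx = 21, ny = 31, wall_length = 10, wall_gap = 10,
                           block_size = 3),
              agent = agentParams(max_forward_y = 26),
              run = list(steps_per_action = 10, burn_in_steps = 800,
                         max_actions = 1500), ...)
}
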