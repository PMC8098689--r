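# Arena geometry: walls, deposited blocks, lid, adjacency and termination.

#' Occupancy codes
#'
#' Integer codes used in occupancy grids: `OCC_EMPTY` (0), `OCC_WALL` (1),
#' `OCC_BLOCK` (2).
#' @name occupancy-codes
#' @export
OCC_EMPTY <- 0L
#' @rdname occupancy-codes
#' @export
OCC_WALL <- 1L
#' @rdname occupancy-codes
#' @export
OCC_BLOCK <- 2L

#' Arena geometry
#'
#' Low-level constructor; most callers want [defaultArena()]. Holds the
#' occupancy lattice, the lid extent (cells with centres at y below
#' `lid_extent_y` inside the corridor span are covered), the front edge of
#' the initial walls, the block supply cell at the tunnel rear, and the
#' registry of deposited blocks.
#'
#' @param occupancy nx x ny integer matrix of occupancy codes.
#' @param cell_size Lattice spacing, cm.
#' @param lid_extent_y Lid cover extent along the tunnel axis, cm.
#' @param lid_x_range Integer `c(lo, hi)`: columns spanned by the covered
#'   corridor (the initial walls inclusive).
#' @param initial_wall_front_y Front edge of the initial walls, cm; the
#'   reference line for trigger distances.
#' @param supply_cell Integer `c(i, j)` cell of the block supply at the rear.
#' @param block_size Edge length of a standard block footprint, cells.
#' @param blocks Registry list of deposited blocks.
#' @return An object of class `arena_geometry`.
#' @export
arenaGeometry <- function(occupancy, cell_size = 1, lid_extent_y = 0,
                          lid_x_range = c(1L, nrow(occupancy)),
                          initial_wall_front_y = 0,
                          supply_cell = c(1L, 1L), block_size = 4L,
                          blocks = list()) {
  stopifnot(is.matrix(occupancy), cell_size > 0, lid_extent_y >= 0,
            length(lid_x_range) == 2, length(supply_cell) == 2,
            block_size >= 1)
  if (!all(occupancy %in% c(OCC_EMPTY, OCC_WALL, OCC_BLOCK))) {
    stop("occupancy must contain only EMPTY/WALL/BLOCK codes")
  }
  structure(list(occupancy = occupancy, cell_size = cell_size,
                 lid_extent_y = lid_extent_y,
                 lid_x_range = as.integer(lid_x_range),
                 initial_wall_front_y = initial_wall_front_y,
                 supply_cell = as.integer(supply_cell),
                 block_size = as.integer(block_size),
                 blocks = blocks),
            class = "arena_geometry")
}

#' Default arena: two parallel walls forming a short open tunnel
#'
#' A 35 x 55 cm arena (1 cm cells) with two 20 cm walls 18 cm apart whose
#' corridor opens toward +y; the transparent lid initially covers exactly the
#' walled tunnel, and the block supply sits at the rear of the corridor.
#'
#' @param nx,ny Arena size in cells.
#' @param cell_size Lattice spacing, cm.
#' @param wall_length Wall length along the tunnel axis, cm.
#' @param wall_gap Clear width between the walls, cm.
#' @param block_size Block footprint edge, cells.
#' @return An `arena_geometry`.
#' @export
defaultArena <- function(nx = 35, ny = 55, cell_size = 1, wall_length = 20,
                         wall_gap = 18, block_size = 3) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  wall_cells <- as.integer(round(wall_length / cell_size))
  gap_cells <- as.integer(round(wall_gap / cell_size))
  stopifnot(wall_cells >= 1, wall_cells < ny, gap_cells >= 2)
  iL <- as.integer(floor((nx - gap_cells) / 2))
  iR <- iL + gap_cells + 1L
  if (iL < 1 || iR > nx) stop("walls do not fit in the arena")
  occ <- matrix(OCC_EMPTY, nx, ny)
  occ[iL, 1:wall_cells] <- OCC_WALL
  occ[iR, 1:wall_cells] <- OCC_WALL
  supply <- c(iL + 1L + as.integer(ceiling(gap_cells / 2)), 2L)
  arenaGeometry(occ, cell_size = cell_size,
                lid_extent_y = wall_cells * cell_size,
                lid_x_range = c(iL, iR),
                initial_wall_front_y = wall_cells * cell_size,
                supply_cell = supply,
                block_size = as.integer(round(block_size / cell_size)))
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> %d x %d cells (%.0f x %.0f cm), %d blocks, lid to y = %.1f cm\n",
              nrow(x$occupancy), ncol(x$occupancy),
              nrow(x$occupancy) * x$cell_size, ncol(x$occupancy) * x$cell_size,
              length(x$blocks), x$lid_extent_y))
  invisible(x)
}

#' Lid cover mask
#'
#' Logical lattice of cells covered by the lid: cells within the corridor
#' span whose far edge lies at or behind `lid_extent_y`.
#'
#' @param geometry An `arena_geometry`.
#' @return Logical nx x ny matrix.
#' @export
coveredMask <- function(geometry) {
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  h <- geometry$cell_size
  covered_j <- (seq_len(ny) * h) <= geometry$lid_extent_y + 1e-9
  in_span <- seq_len(nx) >= geometry$lid_x_range[1] &
    seq_len(nx) <= geometry$lid_x_range[2]
  outer(in_span, covered_j, `&`)
}

#' Fan-swept half of the arena
#'
#' The fan blows across the arena from one side; its enhanced ambient
#' exchange applies to the half of the arena on that side (cells under the
#' lid are still protected).
#'
#' @param geometry An `arena_geometry`.
#' @param fan_side `"left"` or `"right"`.
#' @return Logical nx x ny matrix.
#' @export
fanMask <- function(geometry, fan_side) {
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  h <- geometry$cell_size
  mid <- nx * h / 2
  centers <- (seq_len(nx) - 0.5) * h
  cols <- if (identical(fan_side, "left")) centers <= mid + 1e-9
          else centers >= mid - 1e-9
  matrix(cols, nx, ny)
}

# 4-neighbours of cell (i, j) within the lattice
neighbours4 <- function(i, j, nx, ny) {
  out <- rbind(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
  out[out[, 1] >= 1 & out[, 1] <= nx & out[, 2] >= 1 & out[, 2] <= ny, ,
      drop = FALSE]
}

# is a footprint (n x 2 matrix of cells) 4-connected?
footprintConnected <- function(cells) {
  n <- nrow(cells)
  if (n <= 1) return(TRUE)
  key <- paste(cells[, 1], cells[, 2])
  seen <- logical(n)
  seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    nb <- cbind(cells[k, 1] + c(-1L, 1L, 0L, 0L),
                cells[k, 2] + c(0L, 0L, -1L, 1L))
    hit <- match(paste(nb[, 1], nb[, 2]), key)
    hit <- hit[!is.na(hit)]
    fresh <- hit[!seen[hit]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  all(seen)
}

#' Cells of a square block footprint
#'
#' @param anchor Integer `c(i, j)` of the footprint's low corner.
#' @param size Edge length in cells.
#' @return Matrix with one row per cell.
#' @export
footprintSquare <- function(anchor, size) {
  as.matrix(expand.grid(i = anchor[1] + seq_len(size) - 1L,
                        j = anchor[2] + seq_len(size) - 1L))
}

#' Place a block against existing structure
#'
#' The footprint must lie on empty cells and touch (4-adjacency) a wall or a
#' previously deposited block — the agent must affix its load to existing
#' material, as a termite attaches a soil pellet.
#'
#' @param geometry An `arena_geometry`.
#' @param footprint n x 2 integer matrix of cells; must be 4-connected.
#' @param cycle Deposition cycle index recorded in the block registry.
#' @return Updated geometry with the footprint marked `OCC_BLOCK`.
#' @export
placeBlock <- function(geometry, footprint, cycle = NA_integer_) {
  footprint <- matrix(as.integer(footprint), ncol = 2)
  occ <- geometry$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  if (any(footprint[, 1] < 1 | footprint[, 1] > nx |
          footprint[, 2] < 1 | footprint[, 2] > ny)) {
    stop("footprint outside the lattice")
  }
  if (!footprintConnected(footprint)) stop("footprint must be 4-connected")
  vals <- occ[footprint]
  if (any(vals != OCC_EMPTY)) stop("collision: footprint overlaps structure")
  attached <- FALSE
  for (k in seq_len(nrow(footprint))) {
    nb <- neighbours4(footprint[k, 1], footprint[k, 2], nx, ny)
    if (any(occ[nb] != OCC_EMPTY)) { attached <- TRUE; break }
  }
  if (!attached) stop("unattached deposition: footprint touches no structure")
  occ[footprint] <- OCC_BLOCK
  geometry$occupancy <- occ
  id <- length(geometry$blocks) + 1L
  geometry$blocks[[id]] <- list(id = id, cells = footprint,
                                cycle = as.integer(cycle))
  geometry
}

# flood fill over structure cells (occupancy > 0) from the initial walls;
# returns a logical matrix of the contiguous structure component
structureComponent <- function(geometry) {
  occ <- geometry$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  solid <- occ != OCC_EMPTY
  comp <- matrix(FALSE, nx, ny)
  seeds <- which(occ == OCC_WALL)
  comp[seeds] <- TRUE
  queue <- seeds
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- ((idx - 1L) %% nx) + 1L
    j <- ((idx - 1L) %/% nx) + 1L
    nb <- neighbours4(i, j, nx, ny)
    nb_idx <- (nb[, 2] - 1L) * nx + nb[, 1]
    fresh <- nb_idx[solid[nb_idx] & !comp[nb_idx]]
    comp[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  comp
}

#' Extend the lid to the furthest contiguous structure
#'
#' After each deposition cycle the lid is extended to the furthest y extent
#' of any structure contiguous with the initial walls; it never retracts.
#'
#' @param geometry An `arena_geometry`.
#' @return Updated geometry.
#' @export
extendLid <- function(geometry) {
  comp <- structureComponent(geometry)
  if (any(comp)) {
    far_j <- max(col(comp)[comp])
    geometry$lid_extent_y <- max(geometry$lid_extent_y,
                                 far_j * geometry$cell_size)
  }
  geometry
}

# Can a w x w square of empty cells slide (4-adjacent anchor moves) from a
# placement containing the supply cell to one touching the open front edge?
admitsWidth <- function(geometry, w) {
  occ <- geometry$occupancy
  nx <- nrow(occ); ny <- ncol(occ)
  if (w > nx || w > ny) return(FALSE)
  empty <- occ == OCC_EMPTY
  # summed-area table for fast all-empty square tests
  sat <- apply(apply(empty, 2, cumsum), 1, cumsum)  # sat[j, i] after transpose
  sat <- t(sat)
  sq <- function(i, j) {  # sum of empty over [i, i+w-1] x [j, j+w-1]
    i2 <- i + w - 1L; j2 <- j + w - 1L
    s <- sat[i2, j2]
    if (i > 1) s <- s - sat[i - 1L, j2]
    if (j > 1) s <- s - sat[i2, j - 1L]
    if (i > 1 && j > 1) s <- s + sat[i - 1L, j - 1L]
    s
  }
  na <- nx - w + 1L; nb <- ny - w + 1L
  ok <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) ok[i, j] <- sq(i, j) == w * w
  if (!any(ok)) return(FALSE)
  si <- geometry$supply_cell[1]; sj <- geometry$supply_cell[2]
  start <- matrix(FALSE, na, nb)
  ii <- max(1L, si - w + 1L):min(na, si)
  jj <- max(1L, sj - w + 1L):min(nb, sj)
  start[ii, jj] <- ok[ii, jj]
  if (!any(start)) return(FALSE)
  # BFS over admissible anchors
  seen <- start
  queue <- which(start)
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- ((idx - 1L) %% na) + 1L
    j <- ((idx - 1L) %/% na) + 1L
    if (j == nb) return(TRUE)  # square touches the open front edge
    nb4 <- neighbours4(i, j, na, nb)
    nb_idx <- (nb4[, 2] - 1L) * na + nb4[, 1]
    fresh <- nb_idx[ok[nb_idx] & !seen[nb_idx]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  any(seen[, nb])
}

#' Widest opening between the enclosure and the exterior
#'
#' The gap measure used by the closure rule: the bottleneck passage width
#' between the tunnel interior (the supply region) and the open exterior,
#' defined as the largest `w` for which a `w x w` square of empty cells can
#' slide from the supply cell out through the structure frontier to the
#' arena's front edge. An untouched 10 cm corridor gives 10; two blocks
#' leaving a 4 cm opening give 4; a sealed enclosure gives 0.
#'
#' @param geometry An `arena_geometry`.
#' @return Gap width in cm.
#' @export
maxGapWidth <- function(geometry) {
  nx <- nrow(geometry$occupancy); ny <- ncol(geometry$occupancy)
  for (w in rev(seq_len(min(nx, ny)))) {
    if (admitsWidth(geometry, w)) return(w * geometry$cell_size)
  }
  0
}

#' Termination check for a trial
#'
#' Building stops when no opening wider than the gap threshold remains
#' (closure) or when the block budget is spent. Closure takes precedence
#' when both conditions hold.
#'
#' @param geometry An `arena_geometry`.
#' @param blocks_placed Number of blocks deposited so far.
#' @param limits List with `gap_threshold` (cm) and `max_blocks`.
#' @return `"NONE"`, `"CLOSURE"` or `"BLOCK_LIMIT"`.
#' @export
checkTermination <- function(geometry, blocks_placed,
                             limits = list(gap_threshold = 5, max_blocks = 14)) {
  stopifnot(limits$gap_threshold > 0, limits$max_blocks >= 0)
  if (maxGapWidth(geometry) <= limits$gap_threshold + 1e-9) return("CLOSURE")
  if (blocks_placed >= limits$max_blocks) return("BLOCK_LIMIT")
  "NONE"
}
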