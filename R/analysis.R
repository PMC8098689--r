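# Analysis of trial results: trigger distances, condition comparison,
# trigger-point maps.

#' Signed trigger distances from the initial wall edge
#'
#' For each deposition event, the vertical (tunnel-axis) distance between
#' the front edge of the initial walls and the point where the sampled
#' humidity fell below threshold: positive beyond the walls (extension),
#' negative inside the tunnel. Forced depositions (travel-cap fallback) are
#' excluded by default.
#'
#' @param result A `trial_result`.
#' @param include_forced Include forced depositions? Default `FALSE`.
#' @return A data frame with columns `condition`, `cycle`, `distance` (cm).
#' @export
triggerDistances <- function(result, include_forced = FALSE) {
  stopifnot(inherits(result, "trial_result"))
  ev <- result$events
  if (!include_forced) ev <- ev[!ev$forced, , drop = FALSE]
  if (!nrow(ev)) {
    warning("no usable deposition events")
    return(data.frame(condition = character(0), cycle = integer(0),
                      distance = numeric(0)))
  }
  data.frame(condition = result$config$condition$kind,
             cycle = ev$cycle,
             distance = ev$trigger_y - result$geometry$initial_wall_front_y)
}

#' Pooled trigger distances for a batch
#'
#' @param results List of `trial_result` objects.
#' @param include_forced Include forced depositions? Default `FALSE`.
#' @return A data frame with a `trial` column added.
#' @export
batchDistances <- function(results, include_forced = FALSE) {
  rows <- lapply(seq_along(results), function(k) {
    d <- suppressWarnings(triggerDistances(results[[k]], include_forced))
    if (nrow(d)) d$trial <- k
    d
  })
  out <- do.call(rbind, rows[vapply(rows, nrow, 0L) > 0])
  if (is.null(out)) {
    out <- data.frame(condition = character(0), cycle = integer(0),
                      distance = numeric(0), trial = integer(0))
  }
  out
}

#' Least-squares slope of trigger distance against cycle
#'
#' Positive slope means the trigger point moves outward over the trial —
#' the tunnel is being extended.
#'
#' @param result A `trial_result` with at least two usable events.
#' @return Slope in cm per cycle.
#' @export
extensionSlope <- function(result) {
  d <- triggerDistances(result)
  if (nrow(d) < 2) stop("need at least two usable events for a slope")
  unname(stats::coef(stats::lm(distance ~ cycle, data = d))[2])
}

#' Two-sample comparison of trigger distances
#'
#' Student's two-sample t-test with pooled variance (the conventional
#' independent-sample t-test; Welch's correction available via
#' `welch = TRUE`), two-tailed.
#'
#' @param a,b Numeric vectors of distances, each of length >= 2.
#' @param welch Use Welch's unequal-variance form? Default `FALSE`.
#' @return List with `t`, `df`, and the two-tailed `p`.
#' @export
compareConditions <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) stop("degenerate samples")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Map of deposition trigger points over the arena
#'
#' All trigger points of one or more trials plotted on the arena raster,
#' coloured by cycle index, with the final structure and the initial wall
#' edge drawn for reference.
#'
#' @param results A `trial_result` or list of them.
#' @param include_forced Plot forced depositions too? Default `FALSE`.
#' @return A ggplot object.
#' @export
triggerMap <- function(results, include_forced = FALSE) {
  if (inherits(results, "trial_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  geo <- results[[1]]$geometry
  h <- geo$cell_size
  occ_union <- Reduce(`|`, lapply(results, function(r) {
    r$geometry$occupancy != OCC_EMPTY
  }))
  idx <- which(occ_union, arr.ind = TRUE)
  struct_df <- data.frame(x = (idx[, 1] - 0.5) * h, y = (idx[, 2] - 0.5) * h)
  pts <- do.call(rbind, lapply(seq_along(results), function(k) {
    ev <- results[[k]]$events
    if (!include_forced) ev <- ev[!ev$forced, , drop = FALSE]
    if (!nrow(ev)) return(NULL)
    data.frame(x = ev$trigger_x, y = ev$trigger_y, cycle = ev$cycle,
               trial = factor(k))
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = struct_df,
                       ggplot2::aes(x = x, y = y),
                       width = h, height = h, fill = "grey35") +
    ggplot2::geom_hline(yintercept = geo$initial_wall_front_y,
                        colour = "darkgreen", linetype = 2) +
    ggplot2::coord_fixed(xlim = c(0, nrow(geo$occupancy) * h),
                         ylim = c(0, ncol(geo$occupancy) * h)) +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", colour = "cycle") +
    ggplot2::theme_minimal()
  if (is.null(pts)) {
    warning("no trigger points to plot")
    return(p)
  }
  p + ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = x, y = y,
                                       colour = cycle),
                          shape = 4, size = 2, stroke = 1.2) +
    ggplot2::scale_colour_viridis_c()
}
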