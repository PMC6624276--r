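#' Population killing curve
#'
#' Cumulative fraction of cells dead at each imaging frame: a cell with
#' `death_time <= t` counts as dead at frame `t` (death exactly at a frame is
#' counted at that frame); censored cells count as alive at every frame. When
#' the experiment has several replicate positions, per-position curves and
#' their pointwise standard deviation are included, matching the mean +/- SD
#' presentation of population killing curves across replicate microscopy
#' positions.
#'
#' @param experiment A `cell_experiment`.
#' @return An object of class `killing_curve`: list with `time_grid`,
#'   `dead_fraction`, `by_position` (matrix, one column per position, or
#'   `NULL` for a single position), and `sd_across_positions`.
#' @examples
#' ex <- simulate_experiment(sim_config(seed = 1))
#' kc <- killing_curve(ex)
#' plot(kc)
#' @export
killing_curve <- function(experiment) {
  stopifnot(inherits(experiment, "cell_experiment"))
  cells <- experiment$cells
  if (nrow(cells) == 0L) stop("experiment has no cells")
  grid <- experiment$time_grid

  overall <- cum_dead_fraction(cells$death_time, cells$censored, grid)
  positions <- sort(unique(cells$position_id))
  by_position <- NULL
  sd_pos <- rep(0, length(grid))
  if (length(positions) > 1L) {
    by_position <- vapply(positions, function(p) {
      sel <- cells$position_id == p
      cum_dead_fraction(cells$death_time[sel], cells$censored[sel], grid)
    }, numeric(length(grid)))
    colnames(by_position) <- positions
    sd_pos <- apply(by_position, 1L, stats::sd)
  }
  structure(
    list(time_grid = grid, dead_fraction = overall,
         by_position = by_position, sd_across_positions = sd_pos),
    class = "killing_curve"
  )
}

# cumulative dead fraction on the frame grid; censored cells never die
cum_dead_fraction <- function(death_time, censored, grid) {
  n <- length(death_time)
  obs <- death_time[!censored]
  idx <- round(obs / (grid[2L] - grid[1L]))   # death times lie on the grid
  counts <- tabulate(idx, nbins = length(grid) - 1L)
  c(0, cumsum(counts)) / n
}

#' @export
print.killing_curve <- function(x, ...) {
  cat("Killing curve:", length(x$time_grid), "frames, final dead fraction",
      sprintf("%.3f", x$dead_fraction[length(x$dead_fraction)]), "\n")
  invisible(x)
}

#' @export
plot.killing_curve <- function(x, ...,
                               xlab = "Time (min)",
                               ylab = "Fraction of cells dead",
                               main = "Population killing curve") {
  graphics::plot(x$time_grid, x$dead_fraction, type = "n", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  if (!is.null(x$by_position)) {
    lo <- pmax(x$dead_fraction - x$sd_across_positions, 0)
    hi <- pmin(x$dead_fraction + x$sd_across_positions, 1)
    graphics::polygon(c(x$time_grid, rev(x$time_grid)), c(lo, rev(hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  graphics::lines(x$time_grid, x$dead_fraction, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Per-bin cumulative-death matrix (fate heatmap)
#'
#' The heatmap underlying the decile analysis: row `i`, column `t` holds the
#' cumulative dead fraction at frame `t` among the cells of bin `i` (bins
#' ordered low to high covariate). Every row is non-decreasing in time and the
#' bin-size-weighted mean of the rows reproduces the overall killing curve.
#'
#' @param experiment A `cell_experiment`.
#' @param bins A [rank_and_bin()] / [random_grouping()] assignment covering
#'   all cells of the experiment.
#' @return A numeric matrix of class `fate_matrix` (`n_bins` rows, one column
#'   per frame, dimnames bin index / time in minutes) with attributes
#'   `time_grid`, `bin_sizes`, `covariate_name`.
#' @export
fate_matrix <- function(experiment, bins) {
  stopifnot(inherits(experiment, "cell_experiment"),
            inherits(bins, "bin_assignment"))
  cells <- experiment$cells
  if (!all(cells$cell_id %in% names(bins$bin))) {
    stop("bin assignment does not cover all cells")
  }
  if (any(bins$sizes == 0L)) stop("bin with zero cells")
  grid <- experiment$time_grid
  bin_of <- bins$bin[cells$cell_id]
  m <- t(vapply(seq_len(bins$n_bins), function(i) {
    sel <- bin_of == i
    cum_dead_fraction(cells$death_time[sel], cells$censored[sel], grid)
  }, numeric(length(grid))))
  dimnames(m) <- list(bin = seq_len(bins$n_bins), time_min = grid)
  structure(m, class = c("fate_matrix", "matrix"),
            time_grid = grid, bin_sizes = bins$sizes,
            covariate_name = bins$covariate_name)
}

#' @export
print.fate_matrix <- function(x, ...) {
  cat(sprintf("Fate matrix: %d bins x %d frames (cumulative dead fraction, '%s')\n",
              nrow(x), ncol(x), attr(x, "covariate_name")))
  print(round(unclass(x)[, seq(1L, ncol(x), length.out = min(8L, ncol(x)))], 3))
  invisible(x)
}

#' @export
plot.fate_matrix <- function(x, ...,
                             xlab = "Time (min)",
                             ylab = "Covariate bin (low to high)",
                             main = "Cumulative dead fraction by bin") {
  grid <- attr(x, "time_grid")
  graphics::image(grid, seq_len(nrow(x)), t(unclass(x)), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = xlab, ylab = ylab, main = main, ...)
  invisible(x)
}

#' Export a fate matrix as TSV
#'
#' First column `bin_index`, remaining columns one per frame, labeled
#' `t<minutes>`.
#'
#' @param matrix A `fate_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fate_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "fate_matrix"))
  grid <- attr(matrix, "time_grid")
  df <- data.frame(bin_index = seq_len(nrow(matrix)), unclass(matrix),
                   check.names = FALSE)
  names(df) <- c("bin_index", paste0("t", grid))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
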