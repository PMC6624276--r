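#' Construct a single-cell time-kill experiment
#'
#' Bundles a table of single cells (one row per cell: initial covariates and a
#' possibly censored death time) with the imaging frame grid on which death
#' times were scored. This is the container every analysis function in the
#' package consumes, whether the cells came from [simulate_experiment()] or
#' from a real time-lapse movie via [read_cell_table()].
#'
#' @param cells A data frame with columns `cell_id`, `position_id`,
#'   `initial_fluorescence`, `initial_size`, `growth_rate`, `death_time`,
#'   `censored`. `death_time` is in minutes and must be `NA` exactly where
#'   `censored` is `TRUE` (a censored cell was still alive at the final frame).
#' @param time_grid Ordered vector of frame times in minutes, starting at 0
#'   with a constant spacing (the frame interval). Every observed death time
#'   must lie on this grid.
#' @param config A `sim_config` object, or `NULL` for real data.
#' @param provenance Free-text note on where the cells came from.
#'
#' @return An object of class `cell_experiment`: a list with elements `cells`,
#'   `time_grid`, `config`, `provenance`.
#' @seealso [simulate_experiment()], [read_cell_table()], [fate_information()]
#' @export
experiment <- function(cells, time_grid, config = NULL, provenance = "") {
  stopifnot(is.data.frame(cells))
  required <- c("cell_id", "position_id", "initial_fluorescence",
                "initial_size", "growth_rate", "death_time", "censored")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0L) {
    stop("cells is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cells <- cells[required]
  cells$cell_id <- as.character(cells$cell_id)
  cells$position_id <- as.character(cells$position_id)
  cells$censored <- as.logical(cells$censored)

  if (anyDuplicated(cells$cell_id)) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    stop("duplicate cell_id: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(time_grid) < 2L) stop("time_grid needs at least two frames")
  dt <- diff(time_grid)
  if (time_grid[1L] != 0 || any(abs(dt - dt[1L]) > 1e-9) || dt[1L] <= 0) {
    stop("time_grid must start at 0 with a constant positive frame interval")
  }
  if (any(is.na(cells$death_time) != cells$censored)) {
    stop("death_time must be NA exactly for censored cells")
  }
  obs <- cells$death_time[!cells$censored]
  if (length(obs) > 0L) {
    if (any(obs <= 0)) stop("observed death times must be > 0")
    on_grid <- vapply(obs, function(t) any(abs(time_grid - t) < 1e-9), logical(1L))
    if (!all(on_grid)) {
      stop("death time(s) off the frame grid: ",
           paste(utils::head(obs[!on_grid], 5L), collapse = ", "))
    }
  }
  structure(
    list(cells = cells, time_grid = as.numeric(time_grid),
         config = config, provenance = provenance),
    class = "cell_experiment"
  )
}

#' @export
print.cell_experiment <- function(x, ...) {
  n <- nrow(x$cells)
  npos <- length(unique(x$cells$position_id))
  ncens <- sum(x$cells$censored)
  cat("Single-cell time-kill experiment\n")
  cat(sprintf("  %d cells across %d position(s); %d censored (alive at movie end)\n",
              n, npos, ncens))
  cat(sprintf("  frame grid: 0 to %g min, every %g min (%d frames)\n",
              max(x$time_grid), x$time_grid[2L] - x$time_grid[1L],
              length(x$time_grid)))
  if (!is.null(x$config)) {
    cat(sprintf("  simulated: link_shape = %s, link_strength = %g, seed = %d\n",
                x$config$link_shape, x$config$link_strength, x$config$seed))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.cell_experiment <- function(object, ...) {
  cells <- object$cells
  print(object)
  cat("\nInitial fluorescence (a.u.):\n")
  print(summary(cells$initial_fluorescence))
  obs <- cells$death_time[!cells$censored]
  if (length(obs)) {
    cat("\nObserved death times (min):\n")
    print(summary(obs))
  }
  invisible(object)
}

frame_interval <- function(experiment) {
  experiment$time_grid[2L] - experiment$time_grid[1L]
}
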