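#' Time for a killing curve to reach a given dead fraction
#'
#' First frame at which the cumulative dead fraction reaches `fraction`.
#' Returns `NA` (unreached) if the curve never attains it, e.g. when many
#' cells are censored.
#'
#' @param curve A `killing_curve`, or a numeric vector of cumulative dead
#'   fractions accompanied by `time_grid`.
#' @param fraction Target dead fraction, in `(0, 1]` (default 0.5).
#' @param time_grid Frame times; only needed when `curve` is a bare vector.
#' @return Time in minutes, or `NA` if unreached.
#' @export
time_to_fraction_dead <- function(curve, fraction = 0.5, time_grid = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  if (inherits(curve, "killing_curve")) {
    time_grid <- curve$time_grid
    curve <- curve$dead_fraction
  }
  if (is.null(time_grid) || length(time_grid) != length(curve)) {
    stop("time_grid must accompany a bare dead-fraction vector")
  }
  hit <- which(curve >= fraction - 1e-12)
  if (length(hit) == 0L) return(NA_real_)
  time_grid[hit[1L]]
}

# Savitzky-Golay smoothing across bin index; window 1 is the identity filter
sg_smooth <- function(x, window, polyorder) {
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window <= polyorder) stop("Savitzky-Golay window must exceed polyorder")
  if (window == 1L) return(x)
  if (length(x) < window) {
    warning("fewer bins (", length(x), ") than the smoothing window (",
            window, "); returning unsmoothed values")
    return(x)
  }
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Spread of killing times across covariate bins
#'
#' For each bin of a fate matrix, finds the time to reach a target dead
#' fraction (50% by default), smooths those crossing times across the bin
#' index with a Savitzky-Golay filter, and reports the spread (max minus min
#' of the smoothed values) — the difference in time to 50% killing between
#' the fastest- and slowest-dying bins. Bins that never reach the target are
#' excluded from the smoothing and spread, with a warning.
#'
#' @param matrix A `fate_matrix`.
#' @param fraction Target dead fraction (default 0.5).
#' @param window Savitzky-Golay window length across bins (odd; default 5).
#' @param polyorder Savitzky-Golay polynomial order (default 2; must be less
#'   than `window`).
#' @return An object of class `decile_spread`: list with
#'   `time_to_half_by_bin` (minutes per bin, `NA` where unreached),
#'   `smoothed` (same length, `NA` where unreached), `spread` (minutes),
#'   `fraction`, `window`, `polyorder`.
#' @export
decile_spread <- function(matrix, fraction = 0.5, window = 5L,
                          polyorder = 2L) {
  stopifnot(inherits(matrix, "fate_matrix"))
  grid <- attr(matrix, "time_grid")
  crossing <- unname(apply(unclass(matrix), 1L, time_to_fraction_dead,
                           fraction = fraction, time_grid = grid))
  reached <- !is.na(crossing)
  if (!any(reached)) {
    warning("no bin reaches the target dead fraction; spread undefined")
    return(structure(list(time_to_half_by_bin = crossing,
                          smoothed = crossing, spread = NA_real_,
                          fraction = fraction, window = as.integer(window),
                          polyorder = as.integer(polyorder)),
                     class = "decile_spread"))
  }
  if (!all(reached)) {
    warning(sum(!reached), " bin(s) never reach ",
            round(100 * fraction), "% death; excluded from the spread")
  }
  smoothed <- rep(NA_real_, length(crossing))
  smoothed[reached] <- sg_smooth(crossing[reached], as.integer(window),
                                 as.integer(polyorder))
  structure(
    list(time_to_half_by_bin = crossing,
         smoothed = smoothed,
         spread = max(smoothed, na.rm = TRUE) - min(smoothed, na.rm = TRUE),
         fraction = fraction,
         window = as.integer(window),
         polyorder = as.integer(polyorder)),
    class = "decile_spread"
  )
}

#' @export
print.decile_spread <- function(x, ...) {
  cat(sprintf("Killing-time spread across %d bins (target %g%% dead)\n",
              length(x$time_to_half_by_bin), 100 * x$fraction))
  cat("  raw crossing times (min):",
      paste(ifelse(is.na(x$time_to_half_by_bin), "unreached",
                   x$time_to_half_by_bin), collapse = " "), "\n")
  cat(sprintf("  smoothed spread (Savitzky-Golay, window %d, order %d): %g min\n",
              x$window, x$polyorder, x$spread))
  invisible(x)
}

#' Export a decile spread as TSV plus JSON summary
#'
#' @param spread A `decile_spread`.
#' @param path Output TSV path (columns `bin_index`, `time_to_half_min`,
#'   `smoothed_min`).
#' @param json_path Optional JSON summary path (spread and filter
#'   parameters).
#' @return `path`, invisibly.
#' @export
write_decile_spread <- function(spread, path, json_path = NULL) {
  stopifnot(inherits(spread, "decile_spread"))
  utils::write.table(
    data.frame(bin_index = seq_along(spread$time_to_half_by_bin),
               time_to_half_min = spread$time_to_half_by_bin,
               smoothed_min = spread$smoothed),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(spread_min = spread$spread, fraction = spread$fraction,
           sg_window = spread$window, sg_polyorder = spread$polyorder),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Promoter summary statistics: mean expression and noise
#'
#' Arithmetic mean and coefficient of variation (sd / mean) of initial
#' fluorescence — the promoter's expression strength and noise. The CV uses
#' the population standard deviation (divide by N) by default.
#'
#' @param experiment A `cell_experiment`.
#' @param population_sd Use the population (divide-by-N) standard deviation
#'   (default `TRUE`); `FALSE` uses the sample (N - 1) form.
#' @return List with `mean` and `cv`.
#' @export
promoter_statistics <- function(experiment, population_sd = TRUE) {
  stopifnot(inherits(experiment, "cell_experiment"))
  x <- experiment$cells$initial_fluorescence
  if (length(x) == 0L) stop("experiment has no cells")
  m <- mean(x)
  v <- if (population_sd) mean((x - m)^2) else stats::var(x)
  list(mean = m, cv = sqrt(v) / m)
}

#' Correlation of peak information with a promoter-level statistic
#'
#' Given per-promoter peak information values and a matching promoter-level
#' scalar (mean expression, CV, time-to-50%-death, ...), reports both the
#' Pearson and the Spearman correlation coefficient. If either input is
#' constant the correlation is undefined and both coefficients are `NA`.
#'
#' @param peaks Numeric vector of per-promoter peak information (bits).
#' @param stats Numeric vector, same length, of the promoter statistic.
#' @return List with `pearson` and `spearman`, plus `n`.
#' @export
cross_promoter_correlation <- function(peaks, stats) {
  if (length(peaks) != length(stats)) stop("peaks and stats lengths differ")
  if (length(peaks) < 3L) stop("need at least 3 promoters")
  if (anyNA(peaks) || anyNA(stats)) stop("missing values not allowed")
  degenerate <- stats::sd(peaks) == 0 || stats::sd(stats) == 0
  if (degenerate) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(peaks)))
  }
  list(pearson = stats::cor(peaks, stats, method = "pearson"),
       spearman = stats::cor(peaks, stats, method = "spearman"),
       n = length(peaks))
}
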