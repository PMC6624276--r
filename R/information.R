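#' Binary entropy in bits
#'
#' `H(p) = -p log2 p - (1 - p) log2 (1 - p)`, with the convention
#' `0 * log2 0 = 0`. Vectorized over `p`.
#'
#' @param p Probability (fraction of cells dead), in `[0, 1]`.
#' @return Entropy in bits, same length as `p`.
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
#' @export
binary_entropy <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

# core statistic from per-bin dead counts: H(p_overall) - (1/n) sum_i H(p_i).
# The conditional entropy is an unweighted average over bins, exactly as in
# the displayed decomposition; it coincides with the count-weighted
# conditional entropy only when bin sizes are equal (see mi_oracle).
mi_from_counts <- function(dead, sizes) {
  p <- sum(dead) / sum(sizes)
  if (p == 0 || p == 1) return(0)   # degenerate frames carry no information
  binary_entropy(p) - mean(binary_entropy(dead / sizes))
}

#' Mutual information between bins and binary state at one frame
#'
#' The information statistic `I(x_t, y) = H(x_t) - H(x_t | y)` at a single
#' frame: `H(x_t)` is the binary entropy of the overall dead fraction and
#' `H(x_t | y)` is the *unweighted* average of the per-bin binary entropies
#' over the `n` covariate bins. With equal-frequency bins this equals the
#' plug-in mutual information of the joint (bin, state) table (see
#' [mi_oracle()]); with unequal bin sizes the unweighted average differs,
#' and this function implements the unweighted form by design.
#'
#' Frames where all cells share one state return exactly 0 without computing
#' per-bin terms.
#'
#' @param states Logical vector, `TRUE` = dead at the frame; either named by
#'   `cell_id` (matched against the bin assignment) or given in the same
#'   order as `bins$bin`.
#' @param bins A `bin_assignment`.
#' @return Information in bits (0 <= value <= 1 for a binary state).
#' @examples
#' # five bins fully dead, five fully alive: the 1-bit maximum
#' b <- structure(list(n_bins = 10L, bin = rep(1:10, each = 10),
#'                     covariate_name = "x", sizes = rep(10L, 10)),
#'                class = "bin_assignment")
#' mi_at_time(rep(c(TRUE, FALSE), each = 50), b)
#' @export
mi_at_time <- function(states, bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  states <- align_states(states, bins)
  if (any(bins$sizes == 0L)) stop("bin with zero cells")
  dead <- vapply(seq_len(bins$n_bins),
                 function(i) sum(states[bins$bin == i]), numeric(1L))
  mi_from_counts(dead, bins$sizes)
}

align_states <- function(states, bins) {
  if (!is.logical(states) || anyNA(states)) {
    stop("states must be logical (TRUE = dead) with no missing values")
  }
  if (length(states) != length(bins$bin)) {
    stop("states length (", length(states), ") does not match cells in bins (",
         length(bins$bin), ")")
  }
  if (!is.null(names(states)) && !is.null(names(bins$bin))) {
    if (!setequal(names(states), names(bins$bin))) {
      stop("states names do not match the binned cell ids")
    }
    states <- states[names(bins$bin)]
  }
  states
}

#' Plug-in mutual information from the joint count table
#'
#' Independent cross-check for [mi_at_time()]: computes
#' `sum p(i, s) log2( p(i, s) / (p(i) p(s)) )` from the full joint counts over
#' (bin, alive/dead). Agrees with [mi_at_time()] to machine precision whenever
#' all bins have equal size; with unequal bins the two estimators differ
#' because [mi_at_time()] averages conditional entropies with equal bin
#' weights.
#'
#' @inheritParams mi_at_time
#' @return Mutual information in bits.
#' @export
mi_oracle <- function(states, bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  states <- align_states(states, bins)
  if (any(bins$sizes == 0L)) stop("bin with zero cells")
  joint <- table(factor(bins$bin, levels = seq_len(bins$n_bins)),
                 factor(states, levels = c(FALSE, TRUE)))
  p <- joint / sum(joint)
  pi_ <- rowSums(p)
  ps <- colSums(p)
  terms <- p * log2(p / outer(pi_, ps))
  sum(terms[p > 0])
}

# per-bin cumulative dead counts over the whole frame grid (bins x frames)
cum_dead_counts_by_bin <- function(experiment, bins) {
  cells <- experiment$cells
  grid <- experiment$time_grid
  step <- grid[2L] - grid[1L]
  bin_of <- bins$bin[cells$cell_id]
  t(vapply(seq_len(bins$n_bins), function(i) {
    sel <- bin_of == i & !cells$censored
    idx <- round(cells$death_time[sel] / step)
    c(0, cumsum(tabulate(idx, nbins = length(grid) - 1L)))
  }, numeric(length(grid))))
}

#' Information between covariate bins and cell fate over time
#'
#' Evaluates the information statistic at every frame of the movie: at frame
#' `t` each cell is scored dead (`death_time <= t`) or alive (including all
#' censored cells), and [mi_at_time()] is applied with the supplied bin
#' assignment. The trace's maximum is the peak information — the time point
#' at which the initial covariate is most informative about cell state. Ties
#' are resolved to the earliest frame.
#'
#' @param experiment A `cell_experiment`.
#' @param bins A `bin_assignment` covering all cells.
#' @return An object of class `information_trace`: list with `time_grid`,
#'   `info_bits`, `peak_bits`, `peak_time`, `n_bins`, `n_cells`,
#'   `covariate_name`.
#' @export
information_trace <- function(experiment, bins) {
  stopifnot(inherits(experiment, "cell_experiment"),
            inherits(bins, "bin_assignment"))
  if (!all(experiment$cells$cell_id %in% names(bins$bin))) {
    stop("bin assignment does not cover all cells")
  }
  if (any(bins$sizes == 0L)) stop("bin with zero cells")
  counts <- cum_dead_counts_by_bin(experiment, bins)
  info <- apply(counts, 2L, mi_from_counts, sizes = bins$sizes)
  peak_idx <- which.max(info)              # earliest frame at the maximum
  structure(
    list(time_grid = experiment$time_grid,
         info_bits = as.numeric(info),
         peak_bits = info[[peak_idx]],
         peak_time = experiment$time_grid[[peak_idx]],
         n_bins = bins$n_bins,
         n_cells = length(bins$bin),
         covariate_name = bins$covariate_name),
    class = "information_trace"
  )
}

#' @export
print.information_trace <- function(x, ...) {
  cat(sprintf("Information trace ('%s', %d bins, %d cells)\n",
              x$covariate_name, x$n_bins, x$n_cells))
  cat(sprintf("  peak %.4f bits at t = %g min\n", x$peak_bits, x$peak_time))
  invisible(x)
}

#' @export
plot.information_trace <- function(x, ...,
                                   xlab = "Time (min)",
                                   ylab = "Information (bits)",
                                   main = "Information between bins and cell fate") {
  graphics::plot(x$time_grid, x$info_bits, type = "l", lwd = 2,
                 col = "firebrick", ylim = c(0, max(1, x$peak_bits)),
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::points(x$peak_time, x$peak_bits, pch = 19, col = "firebrick")
  invisible(x)
}

#' Export an information trace as TSV plus JSON summary
#'
#' Writes a two-column TSV (`time_min`, `info_bits`) and, if `json_path` is
#' given, a JSON summary `{peak_bits, peak_time_min, n_bins, n_cells}`.
#'
#' @param trace An `information_trace`.
#' @param path Output TSV path.
#' @param json_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_information_trace <- function(trace, path, json_path = NULL) {
  stopifnot(inherits(trace, "information_trace"))
  utils::write.table(
    data.frame(time_min = trace$time_grid, info_bits = trace$info_bits),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(peak_bits = trace$peak_bits, peak_time_min = trace$peak_time,
           n_bins = trace$n_bins, n_cells = trace$n_cells),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Quantify how well an initial covariate forecasts cell fate
#'
#' The package's main entry point: bins the cells of an experiment into
#' equal-frequency groups on the named covariate ([rank_and_bin()]), builds
#' the per-bin cumulative-death matrix ([fate_matrix()]) and the information
#' trace ([information_trace()]), and returns them together as a fitted
#' analysis object. Works for initial fluorescence (the forecasting covariate
#' of interest) and equally for fluorescence-independent covariates such as
#' initial cell size or early growth rate.
#'
#' @param experiment A `cell_experiment`.
#' @param covariate Cell column to forecast from (default initial
#'   fluorescence).
#' @param n_bins Number of equal-frequency bins (default 10: deciles).
#' @return An object of class `fate_information`: list with `trace`
#'   (`information_trace`), `bins` (`bin_assignment`), `fate_matrix`,
#'   `killing_curve`, `covariate`, `n_bins`, `n_cells`.
#' @examples
#' ex <- simulate_experiment(sim_config(seed = 7))
#' fit <- fate_information(ex)
#' fit
#' summary(fit)
#' @export
fate_information <- function(experiment, covariate = "initial_fluorescence",
                             n_bins = 10L) {
  bins <- rank_and_bin(experiment, covariate = covariate, n_bins = n_bins)
  structure(
    list(trace = information_trace(experiment, bins),
         bins = bins,
         fate_matrix = fate_matrix(experiment, bins),
         killing_curve = killing_curve(experiment),
         covariate = covariate,
         n_bins = bins$n_bins,
         n_cells = nrow(experiment$cells)),
    class = "fate_information"
  )
}

#' @export
print.fate_information <- function(x, ...) {
  cat(sprintf("Fate-forecasting information analysis ('%s')\n", x$covariate))
  cat(sprintf("  %d cells, %d equal-frequency bins\n", x$n_cells, x$n_bins))
  cat(sprintf("  peak information: %.4f bits at t = %g min\n",
              x$trace$peak_bits, x$trace$peak_time))
  invisible(x)
}

#' @export
summary.fate_information <- function(object, ...) {
  print(object)
  kc <- object$killing_curve
  final <- kc$dead_fraction[length(kc$dead_fraction)]
  t50 <- time_to_fraction_dead(kc, 0.5)
  cat(sprintf("  final dead fraction: %.3f; time to 50%% death: %s\n",
              final, if (is.na(t50)) "unreached" else paste0(t50, " min")))
  fm <- object$fate_matrix
  cat(sprintf("  final per-bin dead fractions (bin 1 -> %d): %s\n",
              object$n_bins,
              paste(sprintf("%.2f", fm[, ncol(fm)]), collapse = " ")))
  invisible(object)
}

#' @export
plot.fate_information <- function(x, which = c("trace", "heatmap", "curve"),
                                  ...) {
  which <- match.arg(which)
  switch(which,
         trace = plot(x$trace, ...),
         heatmap = plot(x$fate_matrix, ...),
         curve = plot(x$killing_curve, ...))
  invisible(x)
}

#' Peak information as a function of bin count
#'
#' Recomputes the information analysis at several bin counts on the same data
#' to check that conclusions are not sensitive to the exact number of bins.
#'
#' @param experiment A `cell_experiment`.
#' @param bin_counts Integer vector of bin counts to evaluate.
#' @param covariate Cell column to bin on.
#' @return A data frame with columns `n_bins`, `peak_bits`, `peak_time`.
#' @export
bin_sensitivity <- function(experiment, bin_counts = c(5L, 10L, 20L),
                            covariate = "initial_fluorescence") {
  res <- lapply(bin_counts, function(k) {
    tr <- information_trace(experiment,
                            rank_and_bin(experiment, covariate, n_bins = k))
    data.frame(n_bins = k, peak_bits = tr$peak_bits, peak_time = tr$peak_time)
  })
  do.call(rbind, res)
}
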