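#' Assign cells to equal-frequency covariate bins
#'
#' Ranks cells by a scalar covariate (initial fluorescence by default) from
#' low to high and splits them into `n_bins` equal-count bins — the decile
#' construction when `n_bins = 10`, where each bin holds 10% of the cells.
#' Replicate positions are pooled before binning. When the cell count is not
#' divisible by `n_bins`, the remainder cells go to the lowest-index
#' (low-covariate) bins, so bin sizes differ by at most one. Ties in the
#' covariate are broken by the stable order of `cell_id`, making the
#' assignment deterministic.
#'
#' Because only ranks are used, the assignment is invariant under any strictly
#' monotone transform of the covariate.
#'
#' @param experiment A `cell_experiment`.
#' @param covariate Name of the cell column to bin on
#'   (e.g. `"initial_fluorescence"`, `"initial_size"`, `"growth_rate"`).
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @return An object of class `bin_assignment`: list with `n_bins`, `bin`
#'   (integer bin index 1..n_bins per cell, named by `cell_id`; 1 = lowest
#'   covariate values), `covariate_name`, and `sizes` (cells per bin).
#' @examples
#' ex <- simulate_experiment(sim_config(seed = 1))
#' table(rank_and_bin(ex)$bin)
#' @export
rank_and_bin <- function(experiment, covariate = "initial_fluorescence",
                         n_bins = 10L) {
  stopifnot(inherits(experiment, "cell_experiment"))
  cells <- experiment$cells
  if (!covariate %in% names(cells)) {
    stop("covariate '", covariate, "' not found in cell table")
  }
  x <- cells[[covariate]]
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("covariate '", covariate, "' must be finite and numeric for all cells")
  }
  n <- length(x)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds number of cells (", n, ")")

  ord <- order(x, cells$cell_id)           # stable tie-break by cell_id
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(n_bins), bin_sizes(n, n_bins))
  names(bin) <- cells$cell_id
  new_bin_assignment(bin, n_bins, covariate)
}

# equal-frequency sizes; remainder cells in the lowest-index bins
bin_sizes <- function(n, n_bins) {
  base <- n %/% n_bins
  rem <- n %% n_bins
  base + as.integer(seq_len(n_bins) <= rem)
}

new_bin_assignment <- function(bin, n_bins, covariate_name) {
  structure(
    list(n_bins = as.integer(n_bins),
         bin = bin,
         covariate_name = covariate_name,
         sizes = tabulate(bin, nbins = n_bins)),
    class = "bin_assignment"
  )
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat(sprintf("Equal-frequency bin assignment on '%s': %d cells in %d bins\n",
              x$covariate_name, length(x$bin), x$n_bins))
  cat("  bin sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Randomly group cells into equal-count bins
#'
#' The permutation-null counterpart of [rank_and_bin()]: the bin sizes are
#' identical to the ranked assignment on the same cell count, but membership
#' is a uniformly random (seeded) partition, independent of every covariate.
#' This is equivalent to randomizing the data order before dividing it into
#' tenths.
#'
#' @inheritParams rank_and_bin
#' @param seed Integer seed for the partition.
#' @return A `bin_assignment`.
#' @export
random_grouping <- function(experiment, n_bins = 10L, seed = 1L) {
  stopifnot(inherits(experiment, "cell_experiment"))
  n <- nrow(experiment$cells)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds number of cells (", n, ")")
  set.seed(seed)
  ord <- sample.int(n)
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(n_bins), bin_sizes(n, n_bins))
  names(bin) <- experiment$cells$cell_id
  new_bin_assignment(bin, n_bins, "random")
}

#' Export a bin assignment as CSV
#'
#' Columns `cell_id`, `bin_index` (1-based, 1 = lowest covariate bin).
#'
#' @param bins A `bin_assignment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bin_assignment <- function(bins, path) {
  stopifnot(inherits(bins, "bin_assignment"))
  writeLines(c("cell_id,bin_index",
               paste(names(bins$bin), bins$bin, sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}
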