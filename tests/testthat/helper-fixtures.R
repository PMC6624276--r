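# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

# Hand-built experiment from explicit death times (NA = censored).
# Fluorescence defaults to the cell order, so rank_and_bin bins follow the
# construction order.
make_experiment <- function(death_times, frame_interval = 5,
                            movie_length = NULL, fluor = NULL,
                            position = NULL, size = NULL, growth = NULL) {
  n <- length(death_times)
  if (is.null(movie_length)) {
    top <- max(c(death_times, frame_interval), na.rm = TRUE)
    movie_length <- ceiling(top / frame_interval) * frame_interval
  }
  cells <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    position_id = if (is.null(position)) "p01" else position,
    initial_fluorescence = if (is.null(fluor)) as.numeric(seq_len(n)) else fluor,
    initial_size = if (is.null(size)) rep(3, n) else size,
    growth_rate = if (is.null(growth)) rep(0.02, n) else growth,
    death_time = as.numeric(death_times),
    censored = is.na(death_times),
    stringsAsFactors = FALSE
  )
  experiment(cells, seq(0, movie_length, by = frame_interval))
}

# Cells dying one per frame in exact fluorescence-rank order: the proportional
# death construction whose information trace is the parabolic arc peaking at
# the theoretical maximum of 1 bit at half-death.
rank_order_experiment <- function(n = 100, frame_interval = 5) {
  make_experiment(frame_interval * seq_len(n), frame_interval = frame_interval)
}

# Equal-bin assignment built directly (bypasses rank_and_bin) for statistic
# unit tests: bin i holds cells (i-1)*size+1 ... i*size in order.
equal_bins <- function(n_cells, n_bins) {
  size <- n_cells / n_bins
  stopifnot(size == round(size))
  bin <- rep(seq_len(n_bins), each = size)
  names(bin) <- sprintf("c%04d", seq_len(n_cells))
  structure(list(n_bins = as.integer(n_bins), bin = bin,
                 covariate_name = "constructed",
                 sizes = rep(as.integer(size), n_bins)),
            class = "bin_assignment")
}

# states vector (TRUE = dead) from per-bin dead counts under equal_bins
states_from_counts <- function(dead_per_bin, bin_size) {
  st <- unlist(lapply(dead_per_bin, function(k) {
    rep(c(TRUE, FALSE), c(k, bin_size - k))
  }))
  names(st) <- sprintf("c%04d", seq_along(st))
  st
}
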