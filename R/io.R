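#' Write a cell table to CSV
#'
#' One row per cell with columns `cell_id`, `position_id`,
#' `initial_fluorescence`, `initial_size`, `growth_rate`, `death_time_min`,
#' `censored` (0/1). Censored cells have an empty `death_time_min` field.
#' Numeric fields are written at full double precision so that
#' `read_cell_table(write_cell_table(e))` reproduces the experiment
#' field-for-field and a second write is byte-identical.
#'
#' @param experiment A `cell_experiment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "cell_experiment"))
  cells <- experiment$cells
  num <- function(x) {
    out <- ifelse(is.na(x), "", sprintf("%.17g", x))
    # keep integers clean (17 significant digits prints them exactly anyway)
    out
  }
  lines <- c(
    "cell_id,position_id,initial_fluorescence,initial_size,growth_rate,death_time_min,censored",
    paste(cells$cell_id, cells$position_id,
          num(cells$initial_fluorescence), num(cells$initial_size),
          num(cells$growth_rate), num(cells$death_time),
          as.integer(cells$censored), sep = ",")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Inverse of [write_cell_table()]. The CSV does not carry the imaging frame
#' grid, so it is supplied here: `frame_interval` in minutes and, optionally,
#' `movie_length` (defaults to the largest observed death time, rounded up to
#' the grid).
#'
#' @param path CSV path as written by [write_cell_table()] (or external data
#'   in the same layout).
#' @param frame_interval Minutes between frames.
#' @param movie_length Movie length in minutes, or `NULL` to infer.
#' @param provenance Free-text provenance note; defaults to the file path.
#' @return A `cell_experiment`.
#' @export
read_cell_table <- function(path, frame_interval = 5, movie_length = NULL,
                            provenance = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty cell table: ", path)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  expected <- c("cell_id", "position_id", "initial_fluorescence",
                "initial_size", "growth_rate", "death_time_min", "censored")
  if (!identical(header, expected)) {
    stop("line 1: unexpected header; expected ",
         paste(expected, collapse = ","))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  # a trailing empty death_time field drops under strsplit; pad it back
  fields[n_fields == 6L] <- lapply(fields[n_fields == 6L], function(f) c(f, ""))
  bad <- which(!(lengths(fields) == 7L))
  if (length(bad) > 0L) {
    stop("line ", bad[1L] + 1L, ": expected 7 comma-separated fields, got ",
         n_fields[bad[1L]])
  }
  m <- do.call(rbind, fields)
  parse_num <- function(col, name, allow_empty = FALSE) {
    x <- m[, col]
    out <- suppressWarnings(as.numeric(x))
    if (allow_empty) out[x == ""] <- NA_real_
    bad <- which(is.na(out) & x != "")
    if (length(bad) > 0L) {
      stop("line ", bad[1L] + 1L, ": cannot parse ", name, " value '",
           x[bad[1L]], "'")
    }
    if (!allow_empty && anyNA(out)) {
      stop("line ", which(is.na(out))[1L] + 1L, ": missing ", name)
    }
    out
  }
  cells <- data.frame(
    cell_id = m[, 1L],
    position_id = m[, 2L],
    initial_fluorescence = parse_num(3L, "initial_fluorescence"),
    initial_size = parse_num(4L, "initial_size"),
    growth_rate = parse_num(5L, "growth_rate"),
    death_time = parse_num(6L, "death_time_min", allow_empty = TRUE),
    censored = parse_num(7L, "censored") != 0,
    stringsAsFactors = FALSE
  )
  if (is.null(movie_length)) {
    obs <- cells$death_time[!cells$censored]
    movie_length <- if (length(obs)) {
      ceiling(max(obs) / frame_interval) * frame_interval
    } else frame_interval
  }
  experiment(cells, seq(0, movie_length, by = frame_interval),
             provenance = provenance %||% path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a simulation config as YAML
#'
#' The YAML file mirrors [sim_config()] field-for-field.
#'
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
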