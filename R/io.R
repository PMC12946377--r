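## Readers/writers: feeding schedules, record tables, run configurations.
## Plain comma-separated text throughout; numbers stored at 10 significant
## digits (below model tolerance, above round-trip noise).

#' Read a feeding schedule
#'
#' Reads a CSV with columns `day`, `feed_per_individual_g`, `feed_label`,
#' validates it (days contiguous from 1, non-negative masses, labels
#' resolvable against the feed-type table) and attaches the feed energy
#' density and pellet weight. Validation errors name the offending file
#' line.
#'
#' @param path Path to the schedule CSV.
#' @param feed_table Feed-type table (see [feed_types()]).
#' @return A validated schedule data frame with resolved feed columns.
#' @export
read_schedule <- function(path, feed_table = feed_types()) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("day", "feed_per_individual_g", "feed_label")
  if (!all(req %in% names(df)))
    stop("schedule must have columns: ", paste(req, collapse = ", "))
  # file line = data row + header line
  line <- function(i) i + 1L
  day <- suppressWarnings(as.integer(df$day))
  if (anyNA(day))
    stop("non-integer day at line ", line(which(is.na(day))[1]))
  exp_day <- seq_len(nrow(df))
  if (!identical(day, exp_day)) {
    bad <- which(day != exp_day)[1]
    stop("schedule days must be contiguous from 1; line ", line(bad),
         " has day ", day[bad], ", expected ", exp_day[bad])
  }
  mass <- suppressWarnings(as.numeric(df$feed_per_individual_g))
  if (anyNA(mass))
    stop("malformed feed mass at line ", line(which(is.na(mass))[1]))
  if (any(mass < 0))
    stop("negative feed mass at line ", line(which(mass < 0)[1]))
  unknown <- !(df$feed_label %in% feed_table$label)
  if (any(unknown))
    stop("unknown feed label '", df$feed_label[which(unknown)[1]],
         "' at line ", line(which(unknown)[1]))
  df$day <- day
  df$feed_per_individual_g <- mass
  resolve_schedule(df, feed_table)
}

#' @rdname read_schedule
#' @param schedule A schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  out <- schedule[, c("day", "feed_per_individual_g", "feed_label")]
  out$feed_per_individual_g <- formatC(out$feed_per_individual_g,
                                       digits = 10, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

record_cols <- c("day", "id", "W_g", "FL_cm", "G_J", "E_J", "V_cm3",
                 "S_g", "Nf")

#' Write / read daily record tables
#'
#' The per-individual per-day record table (columns `day`, `id`, `W_g`,
#' `FL_cm`, `G_J`, `E_J`, `V_cm3`, `S_g`, `Nf`) is stored as CSV with
#' numeric fields at 10 significant digits; writing is deterministic, so
#' two identical simulations produce byte-identical files. Malformed rows
#' are rejected on read with their row index.
#'
#' @param records A record data frame (e.g. `sim$records`).
#' @param path File path.
#' @return `write_records` returns the path invisibly; `read_records` the
#'   validated data frame.
#' @export
write_records <- function(records, path) {
  stopifnot(all(record_cols %in% names(records)))
  out <- records[, record_cols]
  for (col in c("W_g", "FL_cm", "G_J", "E_J", "V_cm3", "S_g"))
    out[[col]] <- formatC(out[[col]], digits = 10, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!all(record_cols %in% names(df)))
    stop("records must have columns: ", paste(record_cols, collapse = ", "))
  if (nrow(df) == 0)
    return(data.frame(day = integer(), id = integer(), W_g = numeric(),
                      FL_cm = numeric(), G_J = numeric(), E_J = numeric(),
                      V_cm3 = numeric(), S_g = numeric(), Nf = integer()))
  for (col in record_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("malformed value in column '", col, "' at row ",
           which(is.na(v))[1])
    df[[col]] <- v
  }
  df$day <- as.integer(df$day)
  df$id <- as.integer(df$id)
  df$Nf <- as.integer(df$Nf)
  df
}

#' Read a run configuration
#'
#' Reads a YAML configuration and returns a [simulation_config()]. The
#' schedule is given either as a file reference
#' (`schedule: {file: path.csv}`, relative paths resolved against the
#' configuration file) or inline as a generator spec
#' (`schedule: {pattern: constant_g, grams: 0.1, n_days: 30}` and
#' likewise for `percent_bw`/`table`). Any other top-level key matching a
#' [simulation_config()] argument is passed through; `tank`, `behavior`
#' and `deb` accept maps of overrides to the respective defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schedule)) stop("config must define a schedule")
  sch <- cfg$schedule
  schedule <- if (!is.null(sch$file)) {
    f <- sch$file
    if (!file.exists(f))
      f <- file.path(dirname(path), sch$file)
    read_schedule(f)
  } else {
    if (is.null(sch$pattern)) stop("schedule needs 'file' or 'pattern'")
    do.call(make_schedule, sch[setdiff(names(sch), character())])
  }
  args <- list(schedule = schedule)
  for (key in c("n_individuals", "temperature_K", "n_days",
                "feed_multiplier", "seed", "fl_mean", "fl_sd",
                "reserve_fraction", "substeps"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  if (!is.null(cfg$tank)) args$tank <- do.call(tank_geometry, cfg$tank)
  if (!is.null(cfg$behavior))
    args$behavior <- do.call(behavior_params, cfg$behavior)
  if (!is.null(cfg$deb)) args$deb <- do.call(deb_params, cfg$deb)
  do.call(simulation_config, args)
}
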