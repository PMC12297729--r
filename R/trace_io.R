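#' Protocolized sweep families
#'
#' A `sweep_set` bundles a family of uniformly sampled traces recorded under
#' one protocol: membrane voltage in current clamp, transmembrane current in
#' voltage clamp, or fluorescence intensity. Each sweep may carry a stimulus
#' step (onset, duration, level, pre-step level); stimulus-free sweeps carry
#' `NULL`. Time is kept implicit: sample `i` of every sweep is at
#' `(i - 1) / sampling_rate` seconds.
#'
#' @param mode one of `"current_clamp"`, `"voltage_clamp"`, `"fluorescence"`.
#' @param unit unit of the trace values: `"mV"`, `"pA"` or `"au"`
#'   (arbitrary fluorescence).
#' @param sampling_rate samples per second, > 0.
#' @param values numeric matrix, one column per sweep; column names are sweep
#'   labels.
#' @param steps list with one element per sweep: either `NULL` or a list with
#'   `onset_time` (s), `duration` (s), `level` and `pre_level` (pA in current
#'   clamp, mV in voltage clamp).
#' @param cell_id identifier for the recorded cell.
#' @param capacitance cell capacitance in pF, or `NA`. Required for
#'   current-density analysis in voltage clamp.
#' @param group_label free-text group tag (e.g. `"stimulated"`).
#' @param metadata free-form list; generators store ground truth here.
#'
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(mode, unit, sampling_rate, values, steps = NULL,
                      cell_id = NA_character_, capacitance = NA_real_,
                      group_label = NA_character_, metadata = list()) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sweep", seq_len(ncol(values)))
  if (is.null(steps)) steps <- rep(list(NULL), ncol(values))
  cell_id <- as.character(cell_id)
  capacitance <- as.numeric(capacitance)
  group_label <- as.character(group_label)
  x <- structure(list(
    mode = mode, unit = unit, sampling_rate = sampling_rate,
    values = values, steps = steps, cell_id = cell_id,
    capacitance = capacitance, group_label = group_label,
    metadata = metadata
  ), class = "sweep_set")
  validate_sweep_set(x)
}

#' Validate a sweep_set
#'
#' Checks mode/unit, positivity of the sampling rate, finiteness of all
#' values, and that each stimulus step fits inside the trace.
#'
#' @param x a `sweep_set`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_sweep_set <- function(x) {
  stopifnot(inherits(x, "sweep_set"))
  if (!x$mode %in% c("current_clamp", "voltage_clamp", "fluorescence"))
    stop("unknown mode: ", x$mode)
  if (!x$unit %in% c("mV", "pA", "au"))
    stop("unknown unit: ", x$unit)
  if (!is.numeric(x$sampling_rate) || length(x$sampling_rate) != 1L ||
      x$sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!is.matrix(x$values) || nrow(x$values) < 1L || ncol(x$values) < 1L)
    stop("values must be a non-empty matrix")
  bad <- which(!is.finite(x$values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at row %d, sweep '%s'",
                 bad[1L, 1L], colnames(x$values)[bad[1L, 2L]]))
  if (length(x$steps) != ncol(x$values))
    stop("steps must have one entry per sweep")
  dur <- nrow(x$values) / x$sampling_rate
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    if (is.null(st)) next
    need <- c("onset_time", "duration", "level", "pre_level")
    if (!all(need %in% names(st)))
      stop("step ", i, " is missing fields: ",
           paste(setdiff(need, names(st)), collapse = ", "))
    if (st$onset_time < 0 || st$duration <= 0)
      stop("step ", i, ": onset_time must be >= 0 and duration > 0")
    if (st$onset_time + st$duration > dur + 1e-9)
      stop("step ", i, " extends beyond the trace (", dur, " s)")
  }
  if (!is.na(x$capacitance) && x$capacitance <= 0)
    stop("capacitance must be positive when given")
  invisible(x)
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s, %d sweep(s) x %d samples @ %g Hz [%s]\n",
              x$mode, ncol(x$values), nrow(x$values), x$sampling_rate, x$unit))
  if (!is.na(x$cell_id)) cat("  cell:", x$cell_id, "\n")
  if (!is.na(x$group_label)) cat("  group:", x$group_label, "\n")
  n_stim <- sum(!vapply(x$steps, is.null, logical(1L)))
  cat(sprintf("  %d sweep(s) with a stimulus step\n", n_stim))
  invisible(x)
}

#' Number of sweeps in a sweep_set
#' @param x a `sweep_set`.
#' @return integer count.
#' @export
n_sweeps <- function(x) ncol(x$values)

#' Sample times of a sweep_set
#' @param x a `sweep_set`.
#' @return numeric vector of times in seconds.
#' @export
sweep_times <- function(x) (seq_len(nrow(x$values)) - 1) / x$sampling_rate

protocol_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".protocol.json")
}

#' Write a sweep_set to the native exchange format
#'
#' The exchange format is a comma-delimited sweep table (`time` column in
#' seconds plus one column per sweep, printed at full double precision) and a
#' JSON sidecar `<name>.protocol.json` carrying mode, unit, sampling rate,
#' per-sweep stimulus steps, capacitance, group label and metadata.
#' [read_sweepset()] inverts the pair bit-identically.
#'
#' @param s a valid `sweep_set`.
#' @param path path of the CSV table to write; the sidecar path is derived
#'   from it.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(s, path) {
  validate_sweep_set(s)
  if (ncol(s$values) < 1L) stop("refusing to write an empty sweep list")
  labs <- colnames(s$values)
  tt <- sweep_times(s)
  lines <- c(
    paste(c("time", labs), collapse = ","),
    vapply(seq_along(tt), function(i) {
      paste(sprintf("%.17g", c(tt[i], s$values[i, ])), collapse = ",")
    }, character(1L))
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  desc <- list(
    mode = s$mode, unit = s$unit, time_unit = "s",
    sampling_rate = s$sampling_rate,
    sweeps = lapply(seq_along(labs), function(i) {
      st <- s$steps[[i]]
      c(list(label = labs[i]), if (!is.null(st)) list(step = st))
    }),
    cell_id = s$cell_id, capacitance = s$capacitance,
    group_label = s$group_label, metadata = s$metadata
  )
  jsonlite::write_json(desc, protocol_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a sweep_set from the native exchange format
#'
#' Reads a delimited sweep table (one `time` column, one column per sweep)
#' plus its `<name>.protocol.json` sidecar. The time base must be uniform to
#' a relative tolerance of 1e-6 and is checked against the descriptor's
#' sampling rate; files may declare time in ms via the descriptor's
#' `time_unit` and are converted to seconds on read.
#'
#' @param path path of the CSV sweep table.
#' @param format_hint reserved for alternative container formats; only
#'   `"csv"` is built in.
#' @return a validated `sweep_set`.
#' @export
read_sweepset <- function(path, format_hint = "csv") {
  if (!identical(format_hint, "csv"))
    stop("unsupported format_hint: ", format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  pp <- protocol_path(path)
  if (!file.exists(pp))
    stop("format error: missing protocol descriptor ", pp)
  desc <- jsonlite::read_json(pp, simplifyVector = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(tab)[1L], "time"))
    stop("format error: first column must be 'time'")
  tu <- if (is.null(desc$time_unit)) "s" else desc$time_unit
  tt <- tab[[1L]] * switch(tu, s = 1, ms = 1e-3,
                           stop("unknown time_unit: ", tu))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("validation error: NaN/missing value at row %d, column '%s'",
                 bad[1L, 1L], colnames(vals)[bad[1L, 2L]]))
  if (length(tt) < 2L) stop("validation error: need at least 2 samples")
  dt <- diff(tt)
  if (max(abs(dt - dt[1L])) > 1e-6 * abs(dt[1L]))
    stop("validation error: non-uniform time base (first irregularity near row ",
         which.max(abs(dt - dt[1L])) + 1L, ")")
  fs <- desc$sampling_rate
  if (is.null(fs)) fs <- 1 / dt[1L]
  if (abs(1 / fs - dt[1L]) > 1e-6 / fs)
    stop("validation error: time column disagrees with declared sampling_rate")
  labs <- vapply(desc$sweeps, function(sw) sw$label, character(1L))
  if (!identical(labs, colnames(vals)))
    stop("format error: descriptor sweep labels do not match table columns")
  steps <- lapply(desc$sweeps, function(sw) {
    if (is.null(sw$step)) NULL else
      lapply(sw$step, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  })
  as_scalar <- function(v, proto) {
    if (is.null(v) || (length(v) == 1L && is.null(v[[1L]]))) proto else
      if (is.character(proto)) as.character(v) else as.numeric(v)
  }
  sweep_set(
    mode = desc$mode, unit = desc$unit, sampling_rate = fs, values = vals,
    steps = steps,
    cell_id = as_scalar(desc$cell_id, NA_character_),
    capacitance = as_scalar(desc$capacitance, NA_real_),
    group_label = as_scalar(desc$group_label, NA_character_),
    metadata = if (is.null(desc$metadata)) list() else desc$metadata
  )
}
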