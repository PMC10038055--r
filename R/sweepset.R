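#' Sweep set: aligned current sweeps on a uniform time base
#'
#' The universal exchange object of the pipeline.  `sweeps` is an
#' `n_sweeps x n_samples` matrix of membrane current in pA; inward current
#' is negative throughout (physiological convention).  `time` is a strictly
#' uniform grid in ms with spacing `1/sample_rate_khz`.
#'
#' @param time numeric ms vector.
#' @param sweeps numeric matrix, one row per sweep, in pA.
#' @param protocol the generating [voltage_protocol()].
#' @param capacitance_pf whole-cell capacitance in pF (used by per-pF
#'   normalizations; must be > 0 when those are requested).
#' @param series_resistance_mohm optional series resistance, MOhm.
#' @param charge_carrier list with `ion` ("Ca" or "Ba") and `conc_mm`.
#' @param leak_subtracted one of "none", "p4", "offline".
#' @param filter_cutoff_khz optional low-pass cutoff already applied, kHz.
#' @param annotations named list of free-form character metadata.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(time, sweeps, protocol, capacitance_pf = NA_real_,
                      series_resistance_mohm = NA_real_,
                      charge_carrier = list(ion = "Ca", conc_mm = 15),
                      leak_subtracted = c("none", "p4", "offline"),
                      filter_cutoff_khz = NA_real_,
                      annotations = list()) {
  leak_subtracted <- match.arg(leak_subtracted)
  sweeps <- as.matrix(sweeps)
  storage.mode(sweeps) <- "double"
  s <- structure(
    list(time = as.numeric(time), sweeps = sweeps, protocol = protocol,
         capacitance_pf = as.numeric(capacitance_pf)[1],
         series_resistance_mohm = as.numeric(series_resistance_mohm)[1],
         charge_carrier = charge_carrier,
         leak_subtracted = leak_subtracted,
         filter_cutoff_khz = as.numeric(filter_cutoff_khz)[1],
         annotations = annotations),
    class = "sweep_set")
  validate_sweepset(s)
  s
}

validate_sweepset <- function(s) {
  if (!inherits(s, "sweep_set")) stop("not a sweep_set")
  if (nrow(s$sweeps) < 1 || ncol(s$sweeps) < 2) stop("empty sweep matrix")
  if (length(s$time) != ncol(s$sweeps))
    stop("time length does not match sample count")
  if (anyNA(s$sweeps)) stop("sweeps contain missing values")
  validate_protocol(s$protocol)
  if (length(s$protocol$sweep_levels) != nrow(s$sweeps))
    stop("protocol sweep_levels count (", length(s$protocol$sweep_levels),
         ") does not match number of sweeps (", nrow(s$sweeps), ")")
  dt <- 1 / s$protocol$sample_rate_khz
  dev <- max(abs(s$time - (s$time[1] + (seq_along(s$time) - 1) * dt)))
  tol <- 1e-6 * max(1, max(abs(s$time)))
  if (dev > tol)
    stop(sprintf("non-uniform time grid: max deviation %.3g ms", dev))
  invisible(TRUE)
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g kHz (%s, %g mM)\n",
              nrow(x$sweeps), ncol(x$sweeps), x$protocol$sample_rate_khz,
              x$charge_carrier$ion, x$charge_carrier$conc_mm))
  cat(sprintf("  protocol %s | Cm %g pF | leak: %s\n",
              x$protocol$name, x$capacitance_pf, x$leak_subtracted))
  invisible(x)
}

#' @export
dim.sweep_set <- function(x) dim(x$sweeps)

#' Window one protocol epoch out of every sweep
#'
#' Boundaries fall exactly on the epoch sample indices (0-based, half-open
#' `[start, end)`), so consecutive epochs partition each sweep with no
#' overlap and no gap.  `step_level` is the epoch level, or the sweep's own
#' test potential for a per-sweep (`NA`-level) epoch.
#'
#' @param s a `sweep_set`.
#' @param epoch_index 1-based epoch index into the protocol.
#' @return list of `sweep_segment` objects (fields `sweep_index`,
#'   `start_ms`, `end_ms`, `time_ms`, `values`, `step_level`).
#' @export
segment <- function(s, epoch_index) {
  validate_sweepset(s)
  p <- s$protocol
  if (epoch_index < 1 || epoch_index > nrow(p$epochs))
    stop("epoch_index out of range: ", epoch_index)
  ns <- epoch_samples(p)
  if (sum(ns) > ncol(s$sweeps))
    stop("protocol epochs extend beyond the recorded window")
  i0 <- epoch_starts(p)[epoch_index]           # 0-based
  i1 <- i0 + ns[epoch_index]
  idx <- (i0 + 1L):i1
  lapply(seq_len(nrow(s$sweeps)), function(k) {
    lev <- p$epochs$level_mv[epoch_index]
    if (is.na(lev)) lev <- p$sweep_levels[k]
    structure(list(sweep_index = k,
                   start_ms = s$time[i0 + 1L],
                   end_ms = s$time[i0 + 1L] + ns[epoch_index] / p$sample_rate_khz,
                   time_ms = s$time[idx] - s$time[i0 + 1L],
                   values = s$sweeps[k, idx],
                   sample_rate_khz = p$sample_rate_khz,
                   step_level = lev),
              class = "sweep_segment")
  })
}

#' Read / write the plain-text sweep exchange format ("CSV-S")
#'
#' Header lines `# key=value` (required: `sample_rate_khz`,
#' `capacitance_pf`, `charge_carrier` as `ion:conc_mm`, `protocol_name`),
#' then a column header `time_ms,sweep_000,...`, then comma-separated
#' numeric rows.  Numbers are written as scientific notation with 9
#' significant digits, "." decimal separator, LF line endings; the same
#' `sweep_set` always serializes to identical bytes, and write-read-write
#' round trips are byte-identical.  Metadata keys absent from a file stay
#' absent in the object (never silently defaulted).
#'
#' Reading reconstructs the protocol from embedded `protocol.*` keys when
#' present; otherwise a single-epoch stand-in protocol spanning the whole
#' trace is built so that windowing still works.
#'
#' @param path file path.
#' @return `read_sweepset` returns a `sweep_set`; `write_sweepset` returns
#'   `path` invisibly.
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  if (length(hdr) && any(diff(hdr) != 1L))
    stop("format error: header lines must precede all data (line ",
         hdr[which(diff(hdr) != 1L)[1] + 1L], ")")
  meta <- list()
  for (ln in lines[hdr]) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1) stop("format error: malformed header line: ", ln)
    meta[[substr(body, 1, eq - 1)]] <- substr(body, eq + 1, nchar(body))
  }
  need <- c("sample_rate_khz", "capacitance_pf", "charge_carrier",
            "protocol_name")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("format error: missing required header key(s): ",
         paste(miss, collapse = ", "))
  body <- lines[-hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("format error: no data rows")
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (cols[1] != "time_ms")
    stop("format error: first column must be time_ms (line: ", body[1], ")")
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nc <- vapply(rows, length, 1L)
  if (any(nc != length(cols))) {
    bad <- which(nc != length(cols))[1]
    stop("format error: row ", bad, " has ", nc[bad], " fields, expected ",
         length(cols))
  }
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
              ncol = length(cols), byrow = TRUE)
  if (anyNA(m)) stop("format error: non-numeric value in data rows")
  time <- m[, 1]
  sweeps <- t(m[, -1, drop = FALSE])
  rate <- as.numeric(meta$sample_rate_khz)
  dt <- 1 / rate
  dev <- max(abs(diff(time) - dt))
  if (dev > 1e-6 * max(1, max(abs(time))))
    stop(sprintf("grid error: non-uniform time grid, max spacing deviation %.3g ms",
                 dev))
  cc <- strsplit(meta$charge_carrier, ":", fixed = TRUE)[[1]]
  proto <- read_embedded_protocol(meta, time, rate, nrow(sweeps))
  ann_keys <- grep("^annotation\\.", names(meta), value = TRUE)
  ann <- stats::setNames(as.list(unlist(meta[ann_keys], use.names = FALSE)),
                         sub("^annotation\\.", "", ann_keys))
  sweep_set(time = time, sweeps = sweeps, protocol = proto,
            capacitance_pf = as.numeric(meta$capacitance_pf),
            series_resistance_mohm =
              if (is.null(meta$series_resistance_mohm)) NA_real_
              else as.numeric(meta$series_resistance_mohm),
            charge_carrier = list(ion = cc[1],
                                  conc_mm = if (length(cc) > 1)
                                    as.numeric(cc[2]) else NA_real_),
            leak_subtracted = if (is.null(meta$leak_subtracted)) "none"
                              else meta$leak_subtracted,
            filter_cutoff_khz = if (is.null(meta$filter_cutoff_khz)) NA_real_
                                else as.numeric(meta$filter_cutoff_khz),
            annotations = ann)
}

read_embedded_protocol <- function(meta, time, rate, n_sweeps) {
  if (!is.null(meta$protocol.epochs)) {
    parts <- strsplit(strsplit(meta$protocol.epochs, ",", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    lev <- vapply(parts, function(x)
      if (identical(tolower(x[1]), "test")) NA_real_ else as.numeric(x[1]), 0)
    dur <- vapply(parts, function(x) as.numeric(x[2]), 0)
    voltage_protocol(
      name = meta$protocol_name,
      holding_mv = as.numeric(meta$protocol.holding_mv),
      epochs = data.frame(level_mv = lev, duration_ms = dur),
      sweep_levels = as.numeric(
        strsplit(meta$protocol.sweep_levels, ",")[[1]]),
      sample_rate_khz = rate)
  } else {
    voltage_protocol(
      name = meta$protocol_name,
      holding_mv = 0,
      epochs = data.frame(level_mv = NA_real_,
                          duration_ms = length(time) / rate),
      sweep_levels = rep(0, n_sweeps),
      sample_rate_khz = rate)
  }
}

#' @rdname read_sweepset
#' @param s a `sweep_set`.
#' @export
write_sweepset <- function(s, path) {
  validate_sweepset(s)
  p <- s$protocol
  lev <- ifelse(is.na(p$epochs$level_mv), "test", fmt_num(p$epochs$level_mv))
  hdr <- c(
    paste0("# sample_rate_khz=", fmt_num(p$sample_rate_khz)),
    paste0("# capacitance_pf=", fmt_num(s$capacitance_pf)),
    paste0("# charge_carrier=", s$charge_carrier$ion, ":",
           fmt_num(s$charge_carrier$conc_mm)),
    paste0("# protocol_name=", p$name),
    paste0("# leak_subtracted=", s$leak_subtracted))
  if (!is.na(s$series_resistance_mohm))
    hdr <- c(hdr, paste0("# series_resistance_mohm=",
                         fmt_num(s$series_resistance_mohm)))
  if (!is.na(s$filter_cutoff_khz))
    hdr <- c(hdr, paste0("# filter_cutoff_khz=", fmt_num(s$filter_cutoff_khz)))
  hdr <- c(hdr,
           paste0("# protocol.holding_mv=", fmt_num(p$holding_mv)),
           paste0("# protocol.epochs=",
                  paste(lev, fmt_num(p$epochs$duration_ms), sep = ":",
                        collapse = ",")),
           paste0("# protocol.sweep_levels=",
                  paste(fmt_num(p$sweep_levels), collapse = ",")))
  if (length(s$annotations)) {
    keys <- sort(names(s$annotations))
    hdr <- c(hdr, paste0("# annotation.", keys, "=",
                         vapply(s$annotations[keys], as.character, "")))
  }
  colhdr <- paste(c("time_ms",
                    sprintf("sweep_%03d", seq_len(nrow(s$sweeps)) - 1L)),
                  collapse = ",")
  rows <- apply(cbind(s$time, t(s$sweeps)), 1,
                function(r) paste(fmt_num(r), collapse = ","))
  con <- file(path, open = "wb")                # LF endings on all platforms
  on.exit(close(con))
  writeLines(c(hdr, colhdr, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
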