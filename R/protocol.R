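#' Voltage-step protocol
#'
#' A `voltage_protocol` describes the epoch structure shared by every sweep
#' of a voltage-clamp family: a holding potential, an ordered list of
#' constant-voltage epochs, and the per-sweep test potentials.  An epoch
#' whose level is `NA` is stepped to the sweep's own test potential
#' (`sweep_levels`), so one protocol object generates the whole family.
#'
#' All durations are in ms, voltages in mV, and the sample rate in kHz, the
#' native units of whole-cell recordings.  Epoch boundaries must fall on
#' integer sample indices: `duration_ms * sample_rate_khz` integral.
#'
#' @param name protocol label (free text).
#' @param holding_mv holding potential in mV.
#' @param epochs data.frame with columns `level_mv` (mV; `NA` = per-sweep
#'   test level) and `duration_ms` (ms, > 0).
#' @param sweep_levels numeric vector of test potentials, one per sweep.
#' @param sample_rate_khz sampling rate in kHz (samples per ms).
#' @param inter_sweep_interval_ms nominal start-to-start interval between
#'   sweeps (metadata only; sweeps are simulated independently).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, holding_mv, epochs, sweep_levels,
                             sample_rate_khz,
                             inter_sweep_interval_ms = 0) {
  stopifnot(is.data.frame(epochs),
            all(c("level_mv", "duration_ms") %in% names(epochs)))
  p <- structure(
    list(name = as.character(name)[1],
         holding_mv = as.numeric(holding_mv)[1],
         epochs = data.frame(level_mv = as.numeric(epochs$level_mv),
                             duration_ms = as.numeric(epochs$duration_ms)),
         sweep_levels = as.numeric(sweep_levels),
         sample_rate_khz = as.numeric(sample_rate_khz)[1],
         inter_sweep_interval_ms = as.numeric(inter_sweep_interval_ms)[1]),
    class = "voltage_protocol")
  validate_protocol(p)
  p
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s\n", x$name))
  cat(sprintf("  holding %g mV | %d sweeps | %g kHz\n",
              x$holding_mv, length(x$sweep_levels), x$sample_rate_khz))
  lev <- ifelse(is.na(x$epochs$level_mv), "test",
                sprintf("%g", x$epochs$level_mv))
  cat(sprintf("  epochs: %s\n",
              paste(sprintf("%s mV/%g ms", lev, x$epochs$duration_ms),
                    collapse = " -> ")))
  invisible(x)
}

validate_protocol <- function(p) {
  if (!inherits(p, "voltage_protocol")) stop("not a voltage_protocol")
  if (!is.finite(p$sample_rate_khz) || p$sample_rate_khz <= 0)
    stop("sample_rate_khz must be > 0")
  if (nrow(p$epochs) < 1) stop("protocol needs at least one epoch")
  if (any(!is.finite(p$epochs$duration_ms)) || any(p$epochs$duration_ms <= 0))
    stop("all epoch durations must be > 0")
  ns <- p$epochs$duration_ms * p$sample_rate_khz
  if (any(abs(ns - round(ns)) > 1e-6))
    stop("epoch durations must be integral in samples ",
         "(duration_ms * sample_rate_khz not an integer)")
  if (length(p$sweep_levels) < 1) stop("protocol needs at least one sweep level")
  if (any(!is.finite(p$sweep_levels))) stop("sweep_levels must be finite")
  invisible(TRUE)
}

## per-epoch sample counts and 0-based start indices (half-open windows)
epoch_samples <- function(p) as.integer(round(p$epochs$duration_ms *
                                                p$sample_rate_khz))
epoch_starts <- function(p) c(0L, cumsum(epoch_samples(p)))[seq_len(nrow(p$epochs))]
protocol_n_samples <- function(p) sum(epoch_samples(p))

## ms -> 0-based sample index, ties toward the earlier sample
ms_to_sample <- function(t_ms, rate_khz) as.integer(ceiling(t_ms * rate_khz - 0.5))

#' Per-sample command voltage of one sweep
#'
#' @param p a `voltage_protocol`.
#' @param sweep sweep index (1-based).
#' @return numeric vector of mV, one value per sample.
#' @export
voltage_trace <- function(p, sweep) {
  validate_protocol(p)
  if (sweep < 1 || sweep > length(p$sweep_levels)) stop("sweep index out of range")
  lev <- p$epochs$level_mv
  lev[is.na(lev)] <- p$sweep_levels[sweep]
  rep(lev, epoch_samples(p))
}

#' Standard step-family protocols
#'
#' Convenience constructors for the protocols used throughout:
#' `protocol_iv()` a square test pulse from holding to a grid of test
#' potentials (50-ms pulse from -89 mV by default; a 300-ms pulse with a
#' 10-mV grid gives the r250 family); `protocol_ssi()` a pre-conditioning
#' reference test pulse, a long conditioning epoch at the per-sweep level,
#' and a post-conditioning test pulse; `protocol_nsfa()` a strong
#' depolarization followed by a repolarizing tail step, repeated at a single
#' level; `protocol_long5s()` a single 5-s pulse.
#'
#' @param v_from,v_to,dv test-potential grid (mV).
#' @param pulse_ms test-pulse duration (ms).
#' @param holding_mv holding potential (mV).
#' @param sample_rate_khz sampling rate (kHz).
#' @param pre_ms,post_ms holding epochs flanking the pulse (ms).
#' @return a `voltage_protocol`.
#' @export
protocol_iv <- function(v_from = -80, v_to = 70, dv = 5, pulse_ms = 50,
                        holding_mv = -89, sample_rate_khz = 50,
                        pre_ms = 5, post_ms = 5) {
  if (dv <= 0) stop("dv must be > 0")
  if (v_to < v_from) stop("v_to must be >= v_from")
  voltage_protocol(
    name = sprintf("iv_%gms", pulse_ms),
    holding_mv = holding_mv,
    epochs = data.frame(level_mv = c(holding_mv, NA, holding_mv),
                        duration_ms = c(pre_ms, pulse_ms, post_ms)),
    sweep_levels = seq(v_from, v_to, by = dv),
    sample_rate_khz = sample_rate_khz)
}

#' @rdname protocol_iv
#' @param cond_levels conditioning potentials (mV), one per sweep.
#' @param cond_ms conditioning duration (ms); 5000 ms by default so the
#'   inactivation gate reaches steady state.
#' @param test_level potential of the reference/test pulses (mV).
#' @param test_ms test-pulse duration (ms).
#' @param gap_ms holding gap between reference pulse and conditioning (ms).
#' @export
protocol_ssi <- function(cond_levels, cond_ms = 5000, test_level,
                         test_ms = 50, holding_mv = -89,
                         sample_rate_khz = 20, pre_ms = 10, gap_ms = 50,
                         post_ms = 10) {
  p <- voltage_protocol(
    name = "ssi",
    holding_mv = holding_mv,
    epochs = data.frame(
      level_mv = c(holding_mv, test_level, holding_mv, NA, test_level,
                   holding_mv),
      duration_ms = c(pre_ms, test_ms, gap_ms, cond_ms, test_ms, post_ms)),
    sweep_levels = cond_levels,
    sample_rate_khz = sample_rate_khz)
  attr(p, "pre_test_epoch") <- 2L
  attr(p, "post_test_epoch") <- 5L
  p
}

#' @rdname protocol_iv
#' @param step_mv,step_ms activating depolarization (mV, ms).
#' @param tail_mv,tail_ms repolarizing tail step (mV, ms).
#' @param n_sweeps number of identical sweeps in the family.
#' @export
protocol_nsfa <- function(step_mv = 41, step_ms = 10, tail_mv = -49,
                          tail_ms = 10, holding_mv = -79,
                          sample_rate_khz = 50, pre_ms = 2, post_ms = 2,
                          n_sweeps = 1) {
  p <- voltage_protocol(
    name = "nsfa_tail",
    holding_mv = holding_mv,
    epochs = data.frame(
      level_mv = c(holding_mv, step_mv, tail_mv, holding_mv),
      duration_ms = c(pre_ms, step_ms, tail_ms, post_ms)),
    sweep_levels = rep(step_mv, n_sweeps),
    sample_rate_khz = sample_rate_khz)
  attr(p, "tail_epoch") <- 3L
  p
}

#' @rdname protocol_iv
#' @param level_mv pulse potential (mV).
#' @export
protocol_long5s <- function(level_mv, holding_mv = -89,
                            sample_rate_khz = 20, pre_ms = 10,
                            post_ms = 10) {
  voltage_protocol(
    name = "long5s",
    holding_mv = holding_mv,
    epochs = data.frame(level_mv = c(holding_mv, NA, holding_mv),
                        duration_ms = c(pre_ms, 5000, post_ms)),
    sweep_levels = level_mv,
    sample_rate_khz = sample_rate_khz)
}

#' Read / write a protocol configuration file
#'
#' Flat `key=value` text: `name`, `holding_mv`, `sample_rate_khz`,
#' `inter_sweep_interval_ms`, `epochs` as comma-separated
#' `level_mv:duration_ms` tokens (`test` for the per-sweep level), and
#' `sweep_levels` as a comma-separated list.
#'
#' @param path file path.
#' @return `read_protocol` returns a `voltage_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, 1L) < 2L)
  if (length(bad))
    stop("malformed protocol line ", bad[1], ": ", lines[bad[1]])
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  get <- function(k, required = TRUE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (required) stop("protocol file missing key: ", k)
      return(NA_character_)
    }
    vals[i]
  }
  toks <- strsplit(get("epochs"), ",", fixed = TRUE)[[1]]
  parts <- strsplit(trimws(toks), ":", fixed = TRUE)
  lev <- vapply(parts, function(x)
    if (identical(tolower(x[1]), "test")) NA_real_ else as.numeric(x[1]), 0)
  dur <- vapply(parts, function(x) as.numeric(x[2]), 0)
  isi <- get("inter_sweep_interval_ms", required = FALSE)
  voltage_protocol(
    name = get("name"),
    holding_mv = as.numeric(get("holding_mv")),
    epochs = data.frame(level_mv = lev, duration_ms = dur),
    sweep_levels = as.numeric(strsplit(get("sweep_levels"), ",")[[1]]),
    sample_rate_khz = as.numeric(get("sample_rate_khz")),
    inter_sweep_interval_ms = if (is.na(isi)) 0 else as.numeric(isi))
}

#' @rdname read_protocol
#' @param p a `voltage_protocol`.
#' @export
write_protocol <- function(p, path) {
  validate_protocol(p)
  lev <- ifelse(is.na(p$epochs$level_mv), "test",
                fmt_num(p$epochs$level_mv))
  lines <- c(
    paste0("name=", p$name),
    paste0("holding_mv=", fmt_num(p$holding_mv)),
    paste0("sample_rate_khz=", fmt_num(p$sample_rate_khz)),
    paste0("inter_sweep_interval_ms=", fmt_num(p$inter_sweep_interval_ms)),
    paste0("epochs=", paste(lev, fmt_num(p$epochs$duration_ms),
                            sep = ":", collapse = ",")),
    paste0("sweep_levels=", paste(fmt_num(p$sweep_levels), collapse = ",")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

## fixed decimal formatting used by all text writers (bit-exact round trips)
fmt_num <- function(x) sprintf("%.8e", x)
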