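#' Laminar LFP container
#'
#' Multichannel local field potential recorded along a linear probe. Channel 1
#' is by convention the most superficial site and channel index increases with
#' depth; sites are equally spaced (`spacing_um`, default 50 um). Sample `k`
#' of any channel is at session time `t0 + (k - 1) / fs` seconds, on the same
#' clock as all spike times.
#'
#' @param samples numeric matrix `[n_channels x n_timepoints]`, microvolts.
#' @param fs sampling rate, Hz.
#' @param spacing_um inter-channel spacing, micrometres.
#' @param t0 session time of the first sample, seconds.
#' @return object of class `laminar_lfp`.
#' @export
laminar_lfp <- function(samples, fs, spacing_um = 50, t0 = 0) {
  samples <- as.matrix(samples)
  x <- structure(
    list(samples = samples, fs = as.numeric(fs),
         spacing_um = as.numeric(spacing_um), t0 = as.numeric(t0),
         channel0_position = "superficial"),
    class = "laminar_lfp")
  validate_laminar_lfp(x)
}

validate_laminar_lfp <- function(x) {
  if (nrow(x$samples) < 3) stop("laminar_lfp: need n_channels >= 3")
  if (!is.numeric(x$fs) || x$fs <= 0) stop("laminar_lfp: fs must be > 0")
  if (x$spacing_um <= 0) stop("laminar_lfp: spacing_um must be > 0")
  if (anyNA(x$samples) || any(!is.finite(x$samples)))
    stop("laminar_lfp: missing or non-finite samples")
  x
}

#' @export
print.laminar_lfp <- function(x, ...) {
  cat(sprintf("<laminar_lfp> %d channels x %d samples @ %g Hz, spacing %g um, t0 = %g s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$spacing_um, x$t0))
  invisible(x)
}

#' Spike train set
#'
#' Named list mapping unit id to a strictly increasing vector of spike times
#' (seconds, session clock).
#'
#' @param spikes named list of numeric vectors.
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes = list()) {
  stopifnot(is.list(spikes))
  if (length(spikes) > 0 && is.null(names(spikes)))
    stop("spike_train_set: spike lists must be named by unit_id")
  x <- structure(list(spikes = spikes), class = "spike_train_set")
  validate_spike_train_set(x)
}

validate_spike_train_set <- function(x) {
  for (id in names(x$spikes)) {
    t <- x$spikes[[id]]
    if (length(t) && any(t < 0))
      stop(sprintf("spike_train_set: negative spike times for unit %s", id))
    if (length(t) > 1 && any(diff(t) <= 0))
      stop(sprintf("spike_train_set: non-increasing spike times for unit %s", id))
  }
  x
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat(sprintf("<spike_train_set> %d units, %d spikes total\n",
              length(x$spikes), sum(n)))
  invisible(x)
}

#' Per-unit metadata
#'
#' Mean multichannel spike waveform plus derived laminar/classification
#' fields. Fields not yet computed by the pipeline (`trough_to_peak_ms`,
#' `depth_channel`, `relative_depth_um`, `cell_class`) may be `NA`.
#'
#' @param unit_id character or integer id.
#' @param mean_waveform matrix `[n_channels x n_wave_samples]`, microvolts.
#' @param wave_fs waveform sampling rate, Hz.
#' @param area recording area, `"AC"` or `"MGB"`.
#' @param quality isolation-distance-like quality scalar, >= 0.
#' @param trough_to_peak_ms trough-to-peak duration, ms.
#' @param depth_channel channel index (1-based) of the somatic estimate.
#' @param relative_depth_um depth relative to the thalamic recipient layer,
#'   positive toward the pia.
#' @param cell_class one of NS, BS1, BS2, BS3, BS4, MGB, unclassified.
#' @return object of class `unit_meta`.
#' @export
unit_meta <- function(unit_id, mean_waveform, wave_fs, area = "AC",
                      quality = Inf, trough_to_peak_ms = NA_real_,
                      depth_channel = NA_integer_,
                      relative_depth_um = NA_real_,
                      cell_class = NA_character_) {
  x <- structure(
    list(unit_id = as.character(unit_id),
         mean_waveform = as.matrix(mean_waveform),
         wave_fs = as.numeric(wave_fs), area = area,
         quality = as.numeric(quality),
         trough_to_peak_ms = as.numeric(trough_to_peak_ms),
         depth_channel = as.integer(depth_channel),
         relative_depth_um = as.numeric(relative_depth_um),
         cell_class = as.character(cell_class)),
    class = "unit_meta")
  validate_unit_meta(x)
}

.CELL_CLASSES <- c("NS", "BS1", "BS2", "BS3", "BS4", "MGB", "unclassified")

validate_unit_meta <- function(x) {
  if (!x$area %in% c("AC", "MGB")) stop("unit_meta: area must be AC or MGB")
  if (!is.na(x$quality) && x$quality < 0) stop("unit_meta: quality must be >= 0")
  if (!is.na(x$trough_to_peak_ms) && x$trough_to_peak_ms <= 0)
    stop("unit_meta: trough_to_peak_ms must be > 0")
  if (!is.na(x$cell_class) && !x$cell_class %in% .CELL_CLASSES)
    stop(sprintf("unit_meta: unknown cell_class '%s'", x$cell_class))
  x
}

#' Collection of unit metadata
#'
#' @param units list of [unit_meta()] objects.
#' @return object of class `unit_set`.
#' @export
unit_set <- function(units = list()) {
  stopifnot(all(vapply(units, inherits, logical(1), "unit_meta")))
  ids <- vapply(units, function(u) u$unit_id, character(1))
  if (anyDuplicated(ids)) stop("unit_set: duplicate unit_id")
  names(units) <- ids
  structure(list(units = units), class = "unit_set")
}

#' @export
print.unit_set <- function(x, ...) {
  cat(sprintf("<unit_set> %d units (%s)\n", length(x$units),
              paste(names(table(units_df(x)$area)), collapse = ", ")))
  invisible(x)
}

#' @export
length.unit_set <- function(x) length(x$units)

#' Scalar summary of a unit set as a data frame
#'
#' @param units a [unit_set()].
#' @return data.frame with one row per unit (waveforms omitted).
#' @export
units_df <- function(units) {
  stopifnot(inherits(units, "unit_set"))
  do.call(rbind, lapply(units$units, function(u)
    data.frame(unit_id = u$unit_id, area = u$area, quality = u$quality,
               trough_to_peak_ms = u$trough_to_peak_ms,
               depth_channel = u$depth_channel,
               relative_depth_um = u$relative_depth_um,
               cell_class = u$cell_class, stringsAsFactors = FALSE)))
}

#' Event table
#'
#' Timestamped stimulation and stimulus events. Kinds: `bf_on`/`bf_off`
#' (basal-forebrain stimulation bounds), `click` (single click),
#' `train_onset`/`train_offset` (click-train bounds; onsets carry `train_hz`).
#' `block_kind` marks whether the containing trial block pairs sounds with BF
#' stimulation (`stim`) or not (`no_stim`).
#'
#' @param df data.frame with columns `time_s`, `kind` and optionally
#'   `level_db`, `train_hz`, `block_id`, `block_kind`.
#' @return object of class `event_table` (a data.frame).
#' @export
event_table <- function(df) {
  need <- c("time_s", "kind")
  opt <- c("level_db", "train_hz", "block_id", "block_kind")
  if (!all(need %in% names(df))) stop("event_table: need columns time_s, kind")
  for (cn in opt) if (!cn %in% names(df))
    df[[cn]] <- rep(if (cn %in% c("level_db", "train_hz")) NA_real_
                    else NA_character_, nrow(df))
  df <- df[, c(need, opt)]
  class(df) <- c("event_table", "data.frame")
  validate_event_table(df)
}

validate_event_table <- function(df) {
  kinds <- c("bf_on", "bf_off", "click", "train_onset", "train_offset")
  if (!all(df$kind %in% kinds))
    stop(sprintf("event_table: unknown kind '%s'",
                 setdiff(df$kind, kinds)[1]))
  if (is.unsorted(df$time_s)) stop("event_table: times must be non-decreasing")
  on <- df$time_s[df$kind == "bf_on"]; off <- df$time_s[df$kind == "bf_off"]
  if (length(on) != length(off) || (length(on) && any(off <= on)))
    stop("event_table: every bf_on needs a matching later bf_off")
  to <- df$kind == "train_onset"
  if (any(to) && anyNA(df$train_hz[to]))
    stop("event_table: train_onset rows must carry train_hz")
  df
}

#' Labeled state epochs
#'
#' @param df data.frame with columns `t_start`, `t_end`, `label` where label
#'   is one of `synchronized`, `desynchronized`, `up_state`.
#' @return object of class `state_epochs` (a data.frame).
#' @export
state_epochs <- function(df = data.frame(t_start = numeric(0),
                                         t_end = numeric(0),
                                         label = character(0))) {
  stopifnot(all(c("t_start", "t_end", "label") %in% names(df)))
  df <- df[, c("t_start", "t_end", "label")]
  class(df) <- c("state_epochs", "data.frame")
  validate_state_epochs(df)
}

validate_state_epochs <- function(df) {
  if (!all(df$label %in% c("synchronized", "desynchronized", "up_state")))
    stop("state_epochs: unknown label")
  if (any(df$t_end <= df$t_start)) stop("state_epochs: t_end must exceed t_start")
  for (lab in unique(df$label)) {
    e <- df[df$label == lab, ]
    e <- e[order(e$t_start), ]
    if (nrow(e) > 1 && any(e$t_start[-1] < e$t_end[-nrow(e)]))
      stop(sprintf("state_epochs: overlapping '%s' epochs", lab))
  }
  df
}

#' Session container
#'
#' @param lfp a [laminar_lfp()].
#' @param spikes a [spike_train_set()].
#' @param units a [unit_set()].
#' @param events an [event_table()].
#' @return object of class `session`.
#' @export
session <- function(lfp, spikes, units, events) {
  stopifnot(inherits(lfp, "laminar_lfp"), inherits(spikes, "spike_train_set"),
            inherits(units, "unit_set"), inherits(events, "event_table"))
  structure(list(lfp = lfp, spikes = spikes, units = units, events = events),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  print(x$lfp); print(x$spikes)
  cat(sprintf("<events> %d rows, %d bf stimulations, %d clicks, %d trains\n",
              nrow(x$events), sum(x$events$kind == "bf_on"),
              sum(x$events$kind == "click"),
              sum(x$events$kind == "train_onset")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Canonical on-disk session format: float32 binaries with JSON sidecars for
# signals, UTF-8 TSV (header line) for tabular components.

num_fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))

write_tsv <- function(df, path) {
  df2 <- df
  for (cn in names(df2)) if (is.numeric(df2[[cn]])) df2[[cn]] <- num_fmt(df2[[cn]])
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a session to a directory
#'
#' Canonical layout: `lfp.bin` (row-major float32, channels x samples) with
#' `lfp.json` sidecar; `spikes.tsv`; `waveforms.bin`/`waveforms.json`;
#' `units.tsv`; `events.tsv`. Signals are stored as float32; reading back
#' reproduces them to float32 precision and all text fields exactly.
#'
#' @param s a [session()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  stopifnot(inherits(s, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lfp <- s$lfp
  con <- file(file.path(path, "lfp.bin"), "wb")
  writeBin(as.numeric(t(lfp$samples)), con, size = 4L)
  close(con)
  jsonlite::write_json(
    list(fs = lfp$fs, n_channels = nrow(lfp$samples),
         n_samples = ncol(lfp$samples), spacing_um = lfp$spacing_um,
         t0 = lfp$t0, channel0_position = lfp$channel0_position),
    file.path(path, "lfp.json"), auto_unbox = TRUE, digits = NA)

  sp <- s$spikes$spikes
  spikes_df <- if (length(sp)) {
    data.frame(unit_id = rep(names(sp), vapply(sp, length, integer(1))),
               time_s = unlist(sp, use.names = FALSE))
  } else data.frame(unit_id = character(0), time_s = numeric(0))
  write_tsv(spikes_df, file.path(path, "spikes.tsv"))

  un <- s$units$units
  if (length(un)) {
    nc <- nrow(un[[1]]$mean_waveform); nw <- ncol(un[[1]]$mean_waveform)
    stopifnot(all(vapply(un, function(u)
      nrow(u$mean_waveform) == nc && ncol(u$mean_waveform) == nw, logical(1))))
    con <- file(file.path(path, "waveforms.bin"), "wb")
    for (u in un) writeBin(as.numeric(t(u$mean_waveform)), con, size = 4L)
    close(con)
    jsonlite::write_json(
      list(wave_fs = un[[1]]$wave_fs, n_channels = nc, n_wave_samples = nw,
           unit_ids = names(un)),
      file.path(path, "waveforms.json"), auto_unbox = TRUE, digits = NA)
  } else {
    writeBin(numeric(0), file.path(path, "waveforms.bin"), size = 4L)
    jsonlite::write_json(list(wave_fs = NA, n_channels = 0,
                              n_wave_samples = 0, unit_ids = character(0)),
                         file.path(path, "waveforms.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  udf <- if (length(un)) units_df(s$units) else
    data.frame(unit_id = character(0), area = character(0),
               quality = numeric(0), trough_to_peak_ms = numeric(0),
               depth_channel = integer(0), relative_depth_um = numeric(0),
               cell_class = character(0))
  write_tsv(udf, file.path(path, "units.tsv"))
  write_tsv(as.data.frame(s$events), file.path(path, "events.tsv"))
  invisible(path)
}

#' Read a session from a directory
#'
#' Inverse of [write_session()]. All invariants are re-validated on load; a
#' missing component file raises an error naming the file and an invariant
#' violation raises a validation error naming the offending record.
#'
#' @param path session directory.
#' @return a [session()].
#' @export
read_session <- function(path) {
  need <- c("lfp.bin", "lfp.json", "spikes.tsv", "waveforms.bin",
            "waveforms.json", "units.tsv", "events.tsv")
  for (f in need) if (!file.exists(file.path(path, f)))
    stop(sprintf("missing component: %s", f))
  meta <- jsonlite::read_json(file.path(path, "lfp.json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  dat <- readBin(file.path(path, "lfp.bin"), numeric(), n = n, size = 4L)
  if (length(dat) != n) stop("lfp.bin: truncated payload")
  lfp <- laminar_lfp(matrix(dat, nrow = meta$n_channels, byrow = TRUE),
                     fs = meta$fs, spacing_um = meta$spacing_um, t0 = meta$t0)

  spdf <- read_tsv(file.path(path, "spikes.tsv"))
  sp <- if (nrow(spdf)) split(spdf$time_s, as.character(spdf$unit_id)) else list()
  sp <- lapply(sp, as.numeric)
  spikes <- spike_train_set(sp)

  wmeta <- jsonlite::read_json(file.path(path, "waveforms.json"),
                               simplifyVector = TRUE)
  udf <- read_tsv(file.path(path, "units.tsv"))
  units <- list()
  if (length(wmeta$unit_ids)) {
    per <- wmeta$n_channels * wmeta$n_wave_samples
    wdat <- readBin(file.path(path, "waveforms.bin"), numeric(),
                    n = per * length(wmeta$unit_ids), size = 4L)
    for (i in seq_along(wmeta$unit_ids)) {
      id <- as.character(wmeta$unit_ids[i])
      w <- matrix(wdat[((i - 1) * per + 1):(i * per)],
                  nrow = wmeta$n_channels, byrow = TRUE)
      row <- udf[as.character(udf$unit_id) == id, ]
      if (nrow(row) != 1) stop(sprintf("units.tsv: missing record for unit %s", id))
      units[[i]] <- unit_meta(
        id, w, wmeta$wave_fs, area = row$area, quality = row$quality,
        trough_to_peak_ms = row$trough_to_peak_ms,
        depth_channel = row$depth_channel,
        relative_depth_um = row$relative_depth_um,
        cell_class = if (is.na(row$cell_class)) NA_character_ else row$cell_class)
    }
  }
  ev <- read_tsv(file.path(path, "events.tsv"))
  ev$block_id <- as.character(ev$block_id)
  ev$block_kind <- as.character(ev$block_kind)
  session(lfp, spikes, unit_set(units), event_table(ev))
}

#' Filter units by isolation quality
#'
#' Keeps units whose quality value meets the threshold (inclusive); default
#' threshold 20, the conventional isolation-distance cutoff for well-isolated
#' single units. Order is preserved.
#'
#' @param units a [unit_set()].
#' @param min_quality inclusive threshold.
#' @return filtered [unit_set()].
#' @export
filter_units <- function(units, min_quality = 20) {
  stopifnot(inherits(units, "unit_set"))
  keep <- vapply(units$units, function(u) u$quality >= min_quality, logical(1))
  unit_set(unname(units$units[keep]))
}
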