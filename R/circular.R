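#' Extract spike phases relative to click-train cycles
#'
#' For every train presentation, spikes from 50 ms after the first click
#' onset (excluding the initial onset transient, which would otherwise
#' inflate phase locking) until the end of the 1 s train are mapped to phase
#' `2*pi*((t - onset) mod T) / T`, with `T = 1 / train_hz` the inter-click
#' interval and phase 0 at click onset. Phases are pooled over presentations.
#'
#' @param t_spikes spike times of one unit, seconds.
#' @param train_onsets onsets of presentations of one train frequency, s.
#' @param train_hz click rate of the train, Hz.
#' @param exclusion_ms initial exclusion window, ms.
#' @param train_len_s train duration, seconds.
#' @return list (`phases` in [0, 2*pi), `n`, `train_hz`, `T`).
#' @export
extract_phases <- function(t_spikes, train_onsets, train_hz,
                           exclusion_ms = 50, train_len_s = 1) {
  if (!is.finite(train_hz) || train_hz <= 0)
    stop("extract_phases: unknown train frequency")
  T <- 1 / train_hz
  eps <- 1e-9  # guard the window edges against float round-off
  ph <- unlist(lapply(train_onsets, function(o) {
    d <- t_spikes - o
    d <- d[d >= exclusion_ms / 1000 - eps & d < train_len_s - eps]
    2 * pi * ((d %% T) / T)
  }))
  if (is.null(ph)) ph <- numeric(0)
  list(phases = ph %% (2 * pi), n = length(ph), train_hz = train_hz, T = T)
}

#' Vector strength of a phase sample
#'
#' Length of the mean resultant vector,
#' `VS = sqrt((sum cos)^2 + (sum sin)^2) / n`: 1 for perfect phase locking,
#' 0 for uniform phases.
#'
#' @param phases numeric vector of phases, radians.
#' @return VS in [0, 1]; NA for an empty sample.
#' @export
vector_strength <- function(phases) {
  n <- length(phases)
  if (n == 0) return(NA_real_)
  sqrt(sum(cos(phases))^2 + sum(sin(phases))^2) / n
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * VS^2`; the p-value uses the standard finite-sample approximation
#' `p = exp(-Z) * (1 + (2 Z - Z^2) / (4 n))`, clipped to [0, 1]. Significant
#' phase locking is conventionally declared at p < 0.01.
#'
#' @param phases numeric vector of phases, radians (n >= 2).
#' @return list (`n`, `vs`, `z`, `p`); all NA when n < 2.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n < 2)
    return(list(n = n, vs = NA_real_, z = NA_real_, p = NA_real_))
  vs <- vector_strength(phases)
  z <- n * vs^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(n = n, vs = vs, z = z, p = min(max(p, 0), 1))
}

#' State summary of vector-strength modulation
#'
#' From a per-(unit, frequency, state) vector-strength table, computes the
#' modulation index of VS per unit and train frequency (dropped when either
#' state's VS is missing) and, per cell class and frequency, the difference
#' in the fraction of significantly phase-locked units (Rayleigh p < 0.01)
#' between the desynchronized and synchronized states. Units with fewer than
#' 2 phase-sample spikes in a state are excluded from that state's fraction;
#' non-significant units with n >= 2 count in the denominator.
#'
#' @param vs_tbl data.frame with columns `unit_id`, `cell_class`, `train_hz`,
#'   `state`, `n`, `vs`, `p`.
#' @param alpha significance level for the Rayleigh test.
#' @return list of data.frames `mi` (unit_id, cell_class, train_hz, mi) and
#'   `fraction` (cell_class, train_hz, frac_sync, frac_desync, dfraction).
#' @export
vs_state_summary <- function(vs_tbl, alpha = 0.01) {
  s <- vs_tbl[vs_tbl$state == "synchronized", ]
  d <- vs_tbl[vs_tbl$state == "desynchronized", ]
  key <- function(x) paste(x$unit_id, x$train_hz)
  m <- match(key(s), key(d))
  ok <- !is.na(m) & !is.na(s$vs) & !is.na(d$vs[m])
  mi <- data.frame(unit_id = s$unit_id[ok], cell_class = s$cell_class[ok],
                   train_hz = s$train_hz[ok],
                   mi = modulation_index(s$vs[ok], d$vs[m][ok]),
                   stringsAsFactors = FALSE)
  frac_one <- function(g) mean(g$p[g$n >= 2] < alpha, na.rm = TRUE)
  rows <- list()
  for (cl in unique(vs_tbl$cell_class)) for (hz in unique(vs_tbl$train_hz)) {
    gs <- s[s$cell_class == cl & s$train_hz == hz & s$n >= 2, ]
    gd <- d[d$cell_class == cl & d$train_hz == hz & d$n >= 2, ]
    if (nrow(gs) == 0 && nrow(gd) == 0) next
    fs <- if (nrow(gs)) mean(gs$p < alpha, na.rm = TRUE) else NA_real_
    fd <- if (nrow(gd)) mean(gd$p < alpha, na.rm = TRUE) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cell_class = cl, train_hz = hz, frac_sync = fs, frac_desync = fd,
      dfraction = fd - fs, stringsAsFactors = FALSE)
  }
  list(mi = mi, fraction = do.call(rbind, rows))
}
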