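#' Trough-to-peak duration of a mean spike waveform
#'
#' Time from the global trough (minimum) to the subsequent maximum of the
#' mean waveform on a single channel, in milliseconds. This waveform width
#' separates narrow-spiking (putative fast-spiking interneurons) from
#' broad-spiking (putative pyramidal) units.
#'
#' @param wave numeric vector, the mean waveform on the depth channel.
#' @param wave_fs waveform sampling rate, Hz.
#' @return trough-to-peak time, ms.
#' @export
trough_to_peak <- function(wave, wave_fs) {
  wave <- as.numeric(wave)
  if (length(wave) < 3 || diff(range(wave)) == 0)
    stop("trough_to_peak: non-biphasic waveform")
  i_tr <- which.min(wave)
  if (i_tr >= length(wave)) stop("trough_to_peak: non-biphasic waveform")
  after <- wave[(i_tr + 1L):length(wave)]
  i_pk <- i_tr + which.max(after)
  if (wave[i_pk] <= wave[i_tr]) stop("trough_to_peak: non-biphasic waveform")
  (i_pk - i_tr) / wave_fs * 1000
}

#' Classify a unit from waveform width and laminar depth
#'
#' Thalamic (MGB) units keep class `MGB` regardless of width. Cortical units
#' with trough-to-peak < 0.55 ms are narrow-spiking (`NS`) at any depth;
#' broader units are binned by depth relative to the thalamic recipient
#' layer: `BS1` 0..200 um, `BS2` -300..0 um, `BS3` -700..-300 um, `BS4`
#' -1100..-700 um (roughly layers 2/3, 3/4, 5 and 6). Shared bin edges go to
#' the bin whose lower edge they are (half-open bins), so every depth inside
#' [-1100, 200] maps to exactly one class; broad units outside the bins are
#' `unclassified`. Width exactly 0.55 ms counts as broad-spiking.
#'
#' @param ttp_ms trough-to-peak duration, ms.
#' @param relative_depth_um depth relative to the recipient layer, um
#'   (positive toward the pia). Ignored for NS and MGB units.
#' @param area `"AC"` or `"MGB"`.
#' @return cell class string.
#' @export
classify_unit <- function(ttp_ms, relative_depth_um, area = "AC") {
  stopifnot(is.finite(ttp_ms))
  if (area == "MGB") return("MGB")
  if (ttp_ms < 0.55) return("NS")
  d <- relative_depth_um
  if (!is.finite(d)) return("unclassified")
  if (d >= 0 && d <= 200) "BS1"
  else if (d >= -300 && d < 0) "BS2"
  else if (d >= -700 && d < -300) "BS3"
  else if (d >= -1100 && d < -700) "BS4"
  else "unclassified"
}

#' Classify every unit in a set
#'
#' Fills `trough_to_peak_ms` (measured on the depth channel, estimating the
#' depth channel first if absent) and `cell_class` for each unit.
#'
#' @param units a [unit_set()] with `relative_depth_um` filled for AC units.
#' @return [unit_set()] with classification fields filled.
#' @export
classify_units <- function(units) {
  stopifnot(inherits(units, "unit_set"))
  out <- lapply(units$units, function(u) {
    if (is.na(u$depth_channel))
      u$depth_channel <- estimate_unit_depth(u$mean_waveform)
    u$trough_to_peak_ms <-
      trough_to_peak(u$mean_waveform[u$depth_channel, ], u$wave_fs)
    u$cell_class <- classify_unit(u$trough_to_peak_ms, u$relative_depth_um,
                                  u$area)
    u
  })
  unit_set(unname(out))
}
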