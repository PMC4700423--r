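# Polynomial rolling hash of a string; used to stamp outputs with the
# resolved config.
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' Materialises every stage parameter with its default so a run can be
#' stamped with the exact configuration it used. Unknown keys are rejected.
#'
#' @param ... named overrides; `sim` takes a [sim_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = sim_config(),
    min_quality = 20,
    psd = psd_params(),
    spont_window_s = 3,
    desync_len_s = 10,
    csd_window_ms = c(0, 50),
    onset_window_ms = c(0, 100),
    mst_window_ms = c(80, 200),
    psth_window_ms = c(-50, 300),
    psth_kernel_ms = 5,
    corr_bin_ms = 1, corr_kernel_ms = 5,
    mua_bin_ms = 1, mua_kernel_ms = 10,
    up_mask_pre_s = 8,
    up_window_ms = 200,
    up_post_rule = "all",
    rayleigh_alpha = 0.01,
    exclusion_ms = 50,
    deep_offset_ch = 8,
    stages = c("csd", "classify", "states", "spectra", "evoked", "phase"))
  ov <- list(...)
  for (k in names(ov)) {
    if (!k %in% names(cfg)) stop(sprintf("run_config: unknown key '%s'", k))
    cfg[[k]] <- ov[[k]]
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Spontaneous-analysis epochs: only the dedicated spontaneous-period BF
# stimulations (block_id "spont") define the 3 s before/after windows; the
# per-trial stimulations of the evoked blocks are excluded.
spont_epochs <- function(events, cfg) {
  ev <- events[!is.na(events$block_id) & events$block_id == "spont", ,
               drop = FALSE]
  if (nrow(ev) == 0) ev <- events
  define_state_epochs(event_table(as.data.frame(ev)), cfg$spont_window_s,
                      cfg$desync_len_s)
}

#' Run the full analysis pipeline on a session
#'
#' Executes, in dependency order: LFP preprocessing, CSD and recipient-layer
#' alignment, unit depth estimation and classification, state-epoch
#' construction and UP-state detection, spectral depth profiles and
#' band-power modulation indices, evoked onset statistics
#' (mean/variance/Fano modulation), mean spike time, normalized PSTHs,
#' spontaneous-rate and UP-vs-desynchronized modulation, pairwise spike-count
#' correlations, and click-train phase locking. Returns a structured report;
#' when `out` is given, writes the stage tables plus `report.json`, stamped
#' with the resolved configuration hash and seed.
#'
#' @param config a [run_config()].
#' @param sim result of [simulate_session()]; simulated from
#'   `config$sim`/`config$seed` when NULL.
#' @param out output directory, or NULL to skip writing.
#' @param verbose log one line per stage.
#' @return report list (invisibly identical to the written `report.json`).
#' @export
run_pipeline <- function(config = run_config(), sim = NULL, out = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  if (is.null(sim)) sim <- simulate_session(config$sim, config$seed)
  ses <- sim$session
  gt <- sim$ground_truth
  report <- list(seed = config$seed,
                 config_hash = config_hash(jsonlite::toJSON(unclass(config),
                                                     auto_unbox = TRUE,
                                                     force = TRUE)))

  lfp <- preprocess_lfp(ses$lfp)
  pipeline_log(verbose, "preprocess", "%d channels at %g Hz",
               nrow(lfp$samples), lfp$fs)

  units <- filter_units(ses$units, config$min_quality)
  pipeline_log(verbose, "filter", "%d/%d units pass quality >= %g",
               length(units), length(ses$units), config$min_quality)

  click_ev <- ses$events[ses$events$kind == "click", , drop = FALSE]
  recipient <- NA_integer_
  if ("csd" %in% stages) {
    csd <- compute_csd(smooth_depth(lfp))
    recipient <- find_recipient_channel(csd, click_ev$time_s,
                                        config$csd_window_ms)
    pipeline_log(verbose, "csd", "recipient channel %d", recipient)
  }
  report$recipient_channel <- recipient

  if ("classify" %in% stages) {
    if (is.na(recipient)) stop("classify: missing recipient channel (csd stage not run)")
    units <- unit_set(lapply(units$units, function(u) {
      u$depth_channel <- estimate_unit_depth(u$mean_waveform); u
    }))
    units <- assign_relative_depths(units, recipient, lfp$spacing_um)
    units <- classify_units(units)
    pipeline_log(verbose, "classify", "%s",
                 paste(names(table(units_df(units)$cell_class)), collapse = " "))
  }
  udf <- units_df(units)
  report$n_units <- nrow(udf)
  ac_ids <- udf$unit_id[udf$area == "AC"]
  mgb_ids <- udf$unit_id[udf$area == "MGB"]

  epochs <- NULL; up_epochs <- NULL
  if ("states" %in% stages) {
    epochs <- spont_epochs(ses$events, config)
    spont_bf <- ses$events[!is.na(ses$events$block_id) &
                             ses$events$block_id == "spont", , drop = FALSE]
    mask_iv <- data.frame(
      t_start = c(spont_bf$time_s[spont_bf$kind == "bf_on"] - config$up_mask_pre_s,
                  spont_bf$time_s[spont_bf$kind == "bf_off"]),
      t_end = c(spont_bf$time_s[spont_bf$kind == "bf_on"],
                spont_bf$time_s[spont_bf$kind == "bf_off"] + config$desync_len_s))
    mua <- compute_mua(ses$spikes, ac_ids, config$mua_bin_ms,
                       config$mua_kernel_ms, t_end = gt$duration_s)
    up_epochs <- detect_up_states(mua, mask_iv, post_ms = config$up_window_ms,
                                  post_rule = config$up_post_rule)
    report$up_states <- list(n_detected = nrow(up_epochs),
                             threshold_hz = attr(up_epochs, "threshold"))
    pipeline_log(verbose, "states", "%d spont epochs, %d UP states",
                 nrow(epochs), nrow(up_epochs))
  }

  spectra <- NULL
  if ("spectra" %in% stages) {
    if (is.null(epochs)) stop("spectra: missing epochs (states stage not run)")
    bp <- band_power_table(lfp, epochs, config$psd)
    bmi <- band_power_state_mi(bp)
    sup_ch <- seq_len(min(recipient, nrow(lfp$samples)))
    deep_ch <- seq(min(recipient + config$deep_offset_ch, nrow(lfp$samples)),
                   nrow(lfp$samples))
    grp_mi <- do.call(rbind, lapply(names(lfp_bands()), function(b) {
      data.frame(band = b,
                 superficial = mean(bmi$mi[bmi$band == b & bmi$channel %in% sup_ch]),
                 deep = mean(bmi$mi[bmi$band == b & bmi$channel %in% deep_ch]))
    }))
    spectra <- list(band_power = bp, band_mi = bmi, group_mi = grp_mi)
    report$band_mi <- grp_mi
    pipeline_log(verbose, "spectra", "delta deep MI %.2f, low-gamma sup MI %.2f",
                 grp_mi$deep[grp_mi$band == "delta"],
                 grp_mi$superficial[grp_mi$band == "low_gamma"])
  }

  spont <- NULL
  if (!is.null(epochs) && nrow(epochs)) {
    spont <- spontaneous_stats(ses$spikes, udf, epochs, up_epochs)
    report$spont_mi <- spont$class_mi
    report$up_vs_desync_mi <- spont$up_mi
    corr <- correlation_stats(ses$spikes, udf, epochs, config)
    report$correlations <- corr$summary
  } else corr <- NULL

  evoked <- NULL
  if ("evoked" %in% stages) {
    if (is.null(epochs)) stop("evoked: missing epochs (states stage not run)")
    evoked <- evoked_stats(ses$spikes, udf, ses$events, config)
    report$onset <- evoked$onset_summary
    report$mean_spike_time <- evoked$mst_summary
    pipeline_log(verbose, "evoked", "%d responsive units", evoked$n_responsive)
  }

  phase <- NULL
  if ("phase" %in% stages) {
    phase <- phase_stats(ses$spikes, udf, ses$events, config)
    report$vs <- phase$class_summary
    pipeline_log(verbose, "phase", "%d unit-frequency VS pairs",
                 nrow(phase$vs_tbl) / 2)
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    write_tsv(udf, file.path(out, "units.tsv"))
    if (!is.null(epochs))
      write_tsv(as.data.frame(rbind(epochs, up_epochs)),
                file.path(out, "epochs.tsv"))
    if (!is.null(spectra)) {
      write_tsv(spectra$band_power, file.path(out, "band_power.tsv"))
      write_tsv(spectra$band_mi, file.path(out, "band_power_mi.tsv"))
    }
    if (!is.null(evoked)) {
      write_tsv(evoked$onset_tbl, file.path(out, "onset_stats.tsv"))
      write_tsv(evoked$mi_tbl, file.path(out, "mi_onset.tsv"))
      write_tsv(evoked$mst_tbl, file.path(out, "mean_spike_time.tsv"))
    }
    if (!is.null(corr)) write_tsv(corr$pairs, file.path(out, "correlations.tsv"))
    if (!is.null(phase)) {
      write_tsv(phase$vs_tbl, file.path(out, "vs.tsv"))
      write_tsv(phase$summary$mi, file.path(out, "vs_mi.tsv"))
      write_tsv(phase$summary$fraction, file.path(out, "fraction_modulated.tsv"))
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(c(report, list(
    tables = list(spectra = spectra, evoked = evoked, corr = corr,
                  phase = phase, spont = spont, epochs = epochs,
                  up_epochs = up_epochs, units = udf))))
}

# Spontaneous firing rates per state and their modulation indices, plus the
# UP-state versus desynchronized comparison.
spontaneous_stats <- function(spikes, udf, epochs, up_epochs = NULL) {
  rate_in <- function(ts, iv) {
    tot <- sum(iv$t_end - iv$t_start)
    if (tot == 0) return(NA_real_)
    sum(vapply(seq_len(nrow(iv)), function(i)
      sum(in_window(ts, iv$t_start[i], iv$t_end[i])), numeric(1))) / tot
  }
  sync_iv <- epochs[epochs$label == "synchronized", ]
  des_iv <- epochs[epochs$label == "desynchronized", ]
  per_unit <- do.call(rbind, lapply(seq_len(nrow(udf)), function(i) {
    ts <- spikes$spikes[[udf$unit_id[i]]]
    rs <- rate_in(ts, sync_iv); rd <- rate_in(ts, des_iv)
    ru <- if (!is.null(up_epochs) && nrow(up_epochs)) rate_in(ts, up_epochs)
          else NA_real_
    data.frame(unit_id = udf$unit_id[i], cell_class = udf$cell_class[i],
               rate_sync = rs, rate_desync = rd, rate_up = ru,
               mi = modulation_index(rs, rd),
               up_mi = if (is.na(ru)) NA_real_ else up_vs_desync_index(ru, rd),
               stringsAsFactors = FALSE)
  }))
  agg <- function(col) {
    sp <- split(per_unit[[col]], per_unit$cell_class)
    do.call(rbind, lapply(names(sp), function(cl)
      data.frame(cell_class = cl, mean_mi = mean(sp[[cl]], na.rm = TRUE),
                 n = sum(!is.na(sp[[cl]])), stringsAsFactors = FALSE)))
  }
  list(per_unit = per_unit, class_mi = agg("mi"), up_mi = agg("up_mi"))
}

# Pairwise spike-count correlations over the spontaneous state windows,
# summarised by pair type.
correlation_stats <- function(spikes, udf, epochs, config) {
  ids <- udf$unit_id
  res <- list()
  mats <- list()
  for (st in c("synchronized", "desynchronized")) {
    iv <- epochs[epochs$label == st, ]
    mats[[st]] <- smoothed_count_matrix(spikes, ids, iv, config$corr_bin_ms,
                                        config$corr_kernel_ms)
  }
  pair_type <- function(i, j) {
    a1 <- udf$area[i]; a2 <- udf$area[j]
    if (a1 == "AC" && a2 == "AC") "AC-AC"
    else if (a1 == "MGB" && a2 == "MGB") "MGB-MGB" else "AC-MGB"
  }
  is_bs <- grepl("^BS", udf$cell_class)
  rows <- list()
  for (st in names(mats)) {
    cm <- suppressWarnings(cor(mats[[st]]))
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      r <- cm[i, j]
      if (is.na(r)) next
      cls <- if (is_bs[i] && is_bs[j]) "BS-BS"
             else if (!is_bs[i] && !is_bs[j]) "NSorMGB" else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        unit_i = ids[i], unit_j = ids[j], pair_type = pair_type(i, j),
        class_pair = cls, state = st, r = r, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  agg <- stats::aggregate(r ~ pair_type + state, pairs, mean)
  list(pairs = pairs, summary = agg)
}

# Evoked click statistics: onset-window trial counts (mean/var/Fano) per
# state, their modulation indices, mean spike time and normalized PSTHs.
evoked_stats <- function(spikes, udf, events, config) {
  es <- event_states(events, "click")
  resp <- responsive_filter(spikes, es$time_s, es$state,
                            config$onset_window_ms)
  onset_rows <- list(); mi_rows <- list(); mst_rows <- list()
  psth <- list()
  for (id in resp) {
    ts <- spikes$spikes[[id]]
    meta <- udf[udf$unit_id == id, ]
    tc <- trial_counts(ts, es$time_s, es$state, config$onset_window_ms)
    os <- onset_stats(tc)
    os$unit_id <- id; os$cell_class <- meta$cell_class; os$area <- meta$area
    onset_rows[[id]] <- os
    g <- function(col, st) os[[col]][os$state == st]
    mi_rows[[id]] <- data.frame(
      unit_id = id, cell_class = meta$cell_class, area = meta$area,
      mi_mu = modulation_index(g("mu", "synchronized"),
                               g("mu", "desynchronized")),
      mi_var = modulation_index(g("var", "synchronized"),
                                g("var", "desynchronized")),
      mi_fano = modulation_index(g("fano", "synchronized"),
                                 g("fano", "desynchronized")),
      stringsAsFactors = FALSE)
    for (st in c("synchronized", "desynchronized")) {
      on_st <- es$time_s[es$state == st]
      mst_rows[[paste(id, st)]] <- data.frame(
        unit_id = id, area = meta$area, cell_class = meta$cell_class,
        state = st,
        mst_ms = mean_spike_time(ts, on_st, config$mst_window_ms),
        stringsAsFactors = FALSE)
      p <- normalized_psth(ts, on_st, config$psth_window_ms,
                           kernel_ms = config$psth_kernel_ms)
      if (!is.null(p))
        psth[[paste(id, st)]] <- data.frame(
          unit_id = id, state = st, peak_latency_ms = p$peak_latency_ms)
    }
  }
  onset_tbl <- do.call(rbind, onset_rows)
  mi_tbl <- do.call(rbind, mi_rows)
  mst_tbl <- do.call(rbind, mst_rows)
  grp <- function(sel) {
    s <- mi_tbl[sel, , drop = FALSE]
    data.frame(n = nrow(s), mi_mu = mean(s$mi_mu, na.rm = TRUE),
               mi_var = mean(s$mi_var, na.rm = TRUE),
               mi_fano = mean(s$mi_fano, na.rm = TRUE))
  }
  onset_summary <- list(
    AC = grp(mi_tbl$area == "AC"), MGB = grp(mi_tbl$area == "MGB"),
    NS = grp(mi_tbl$cell_class == "NS"),
    BS = grp(grepl("^BS", mi_tbl$cell_class)))
  for (cl in c("BS1", "BS2", "BS3", "BS4"))
    onset_summary[[cl]] <- grp(mi_tbl$cell_class == cl)
  mst_area <- function(area) {
    s <- mst_tbl[mst_tbl$area == area, ]
    m <- tapply(s$mst_ms, s$state, mean, na.rm = TRUE)
    list(sync_ms = unname(m["synchronized"]),
         desync_ms = unname(m["desynchronized"]),
         diff_ms = unname(m["desynchronized"] - m["synchronized"]))
  }
  list(onset_tbl = onset_tbl, mi_tbl = mi_tbl, mst_tbl = mst_tbl,
       psth = do.call(rbind, psth), n_responsive = length(resp),
       onset_summary = onset_summary,
       mst_summary = list(AC = mst_area("AC"), MGB = mst_area("MGB")))
}

# Click-train phase locking: per (unit, frequency, state) vector strength
# and Rayleigh test, summarised per cell class.
phase_stats <- function(spikes, udf, events, config) {
  es <- event_states(events, "train_onset")
  rows <- list()
  for (id in udf$unit_id) {
    ts <- spikes$spikes[[id]]
    meta <- udf[udf$unit_id == id, ]
    for (hz in sort(unique(es$train_hz))) {
      for (st in c("synchronized", "desynchronized")) {
        on <- es$time_s[es$train_hz == hz & es$state == st]
        if (length(on) == 0) next
        ph <- extract_phases(ts, on, hz, config$exclusion_ms)
        rt <- rayleigh_test(ph$phases)
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = id, cell_class = meta$cell_class, area = meta$area,
          train_hz = hz, state = st, n = rt$n, vs = rt$vs, p = rt$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  vs_tbl <- do.call(rbind, rows)
  summ <- vs_state_summary(vs_tbl, config$rayleigh_alpha)
  cls_mi <- stats::aggregate(mi ~ cell_class, summ$mi, mean)
  area_map <- ifelse(cls_mi$cell_class == "MGB", "MGB", "AC")
  cls_mi$area <- area_map
  list(vs_tbl = vs_tbl, summary = summ, class_summary = cls_mi)
}
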