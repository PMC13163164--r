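#' Process one polysomnography recording into a trial table
#'
#' Runs the per-subject analysis chain: EEG band filtering and artifact
#' flagging, slow-oscillation and spindle detection, ECG filtering with
#' R-peak detection and LF/HF decomposition of instantaneous heart rate,
#' Hilbert phase extraction, STIM/UNSTIM trial construction with the
#' stage/artifact/arousal and evoked-SO inclusion rules, per-trial
#' response metrics, binary states and condition flags.
#'
#' @param recording a `psg_recording` (see [generate_recording()] or
#'   [read_recording()]).
#' @param min_trials minimum trials per condition side for the per-subject
#'   condition results (default 5).
#' @param do_spindles,do_hr,do_conditions stage switches; with `do_hr =
#'   FALSE` (or a missing/flat ECG) HR-dependent columns are NA and the
#'   SO-only analysis still proceeds.
#' @param max_latency_s evoked-SO latency bound (default 2.5 s).
#' @return list with `trials` (data.frame; one row per retained trial),
#'   `so_events`, `spindles`, `conditions` (per-subject condition
#'   results or NULL), `funnel` (named counts along the selection chain),
#'   `psd` (trial-aligned normalized PSD matrix and frequency grid).
#' @export
process_recording <- function(recording, min_trials = 5, do_spindles = TRUE,
                              do_hr = TRUE, do_conditions = TRUE,
                              max_latency_s = 2.5) {
  fs <- recording$fs_eeg
  filt <- filter_eeg(recording$eeg, fs)
  n <- length(recording$eeg)
  stage_per_sample <- recording$hypnogram[pmin(
    floor((seq_len(n) - 1L) / (30 * fs)) + 1L, length(recording$hypnogram))]
  n2n3_mask <- stage_per_sample %in% c("N2", "N3")

  so_events <- detect_slow_oscillations(filt$so_band, fs, filt$artifact_mask)
  spindles <- if (do_spindles && any(n2n3_mask & !filt$artifact_mask)) {
    detect_spindles(filt$spindle_band, filt$broadband, fs, n2n3_mask,
                    filt$artifact_mask)
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }

  hr <- NULL
  if (do_hr && !is.null(recording$ecg) && length(recording$ecg) > 0) {
    hr <- tryCatch({
      ecg_f <- zero_phase_bandpass(recording$ecg, 0.5,
                                   min(35, 0.45 * recording$fs_ecg),
                                   recording$fs_ecg)
      rp <- detect_r_peaks(ecg_f, recording$fs_ecg)
      decompose_hr(derive_instantaneous_hr(rp))
    }, error = function(e) {
      warnf("HR pipeline skipped: %s", conditionMessage(e))
      NULL
    })
  }

  # trial construction
  stim <- select_stim_tones(recording$tones_s, recording$hypnogram,
                            filt$artifact_mask, fs, recording$arousals,
                            recording$duration_s)
  unstim <- find_unstim_windows(recording$tones_s, recording$hypnogram,
                                filt$artifact_mask, fs, recording$arousals,
                                recording$duration_s)
  candidates <- rbind(stim, unstim)
  retained <- require_evoked_so(candidates, so_events, max_latency_s)
  funnel <- c(tones_total = length(recording$tones_s),
              stim_stage_artifact_pass = nrow(stim),
              stim_retained = sum(retained$is_stim),
              unstim_candidates = nrow(unstim),
              unstim_retained = sum(!retained$is_stim))

  if (nrow(retained) > 0) {
    retained$subject_id <- recording$subject_id
    retained <- compute_trial_responses(retained, filt$broadband, fs,
                                        spindles, hr)
    # instantaneous phases at (hypothetical) tone onsets
    so_phase <- phase_series(filt$so_band, fs, source = "EEG_SO")
    retained$phi_so <- phase_at(so_phase, retained$onset_s)
    if (!is.null(hr)) {
      rel_span <- range(hr$t_s[hr$reliable])
      lf_phase <- phase_series(hr$lf, hr$fs, t0 = hr$t_s[1], source = "HR_LF")
      hf_phase <- phase_series(hr$hf, hr$fs, t0 = hr$t_s[1], source = "HR_HF")
      inside <- retained$onset_s >= rel_span[1] & retained$onset_s <= rel_span[2]
      retained$phi_lf <- retained$phi_hf <- NA_real_
      if (any(inside)) {
        retained$phi_lf[inside] <- phase_at(lf_phase, retained$onset_s[inside])
        retained$phi_hf[inside] <- phase_at(hf_phase, retained$onset_s[inside])
      }
    } else {
      retained$phi_lf <- retained$phi_hf <- NA_real_
    }
    retained$state_so <- ifelse(is.na(retained$phi_so), NA,
                                classify_state(retained$phi_so))
    retained$state_lf <- ifelse(is.na(retained$phi_lf), NA,
                                classify_state(retained$phi_lf))
    retained$state_hf <- ifelse(is.na(retained$phi_hf), NA,
                                classify_state(retained$phi_hf))
    cond <- assign_conditions(retained$state_so, retained$state_lf,
                              retained$state_hf)
    colnames(cond) <- paste0("cond_", colnames(cond))
    retained <- cbind(retained, as.data.frame(cond))
  }

  conditions <- NULL
  if (do_conditions && nrow(retained) > 0) {
    conditions <- subject_condition_results(retained, filt$broadband, fs,
                                            min_trials = min_trials)
  }

  psd <- list(power = attr(retained, "psd_power"),
              freq = attr(retained, "psd_freq"),
              norm_constant = attr(retained, "norm_constant"))
  attr(retained, "psd_power") <- NULL
  attr(retained, "psd_freq") <- NULL

  list(trials = retained, so_events = so_events, spindles = spindles,
       conditions = conditions, funnel = funnel, psd = psd, hr = hr)
}

#' Simulate and process a synthetic cohort
#'
#' Generates `config$n_subjects` recordings and runs
#' [process_recording()] on each, returning the pooled trial table,
#' per-subject condition results, ERP accumulators and ground truth.
#'
#' @param config a [sim_config()].
#' @param ... passed to [process_recording()].
#' @param keep_ground_truth keep per-subject ground truth (default TRUE).
#' @param progress print one line per subject (default FALSE).
#' @return list with `trials`, `cond_table`, `erps` (per condition label:
#'   summed subject-mean waveforms and counts), `psd` (trial-aligned
#'   matrix), `funnel` (per-subject matrix), `ground_truth` (list).
#' @export
run_cohort <- function(config, ..., keep_ground_truth = TRUE,
                       progress = FALSE) {
  trials <- list(); cond <- list(); gt <- list(); funnel <- list()
  psd_mats <- list(); psd_freq <- NULL
  erps <- list()
  for (i in seq_len(config$n_subjects) - 1L) {
    sim <- generate_recording(config, i)
    res <- process_recording(sim$recording, ...)
    sid <- sim$recording$subject_id
    if (progress) cat(sid, ":", nrow(res$trials), "trials\n")
    if (nrow(res$trials) > 0) {
      trials[[sid]] <- res$trials
      if (!is.null(res$psd$power)) {
        psd_mats[[sid]] <- res$psd$power
        psd_freq <- res$psd$freq
      }
    }
    if (!is.null(res$conditions)) {
      cond[[sid]] <- res$conditions$table
      for (lab in names(res$conditions$erp)) {
        e <- res$conditions$erp[[lab]]
        if (is.null(erps[[lab]])) {
          erps[[lab]] <- list(t_s = e$t_s, stim = e$stim, unstim = e$unstim,
                              n = 1L)
        } else {
          erps[[lab]]$stim <- erps[[lab]]$stim + e$stim
          erps[[lab]]$unstim <- erps[[lab]]$unstim + e$unstim
          erps[[lab]]$n <- erps[[lab]]$n + 1L
        }
      }
    }
    funnel[[sid]] <- res$funnel
    if (keep_ground_truth) gt[[sid]] <- sim$ground_truth
  }
  for (lab in names(erps)) {
    erps[[lab]]$stim <- erps[[lab]]$stim / erps[[lab]]$n
    erps[[lab]]$unstim <- erps[[lab]]$unstim / erps[[lab]]$n
    erps[[lab]]$diff <- erps[[lab]]$stim - erps[[lab]]$unstim
  }
  list(trials = do.call(rbind, c(trials, list(make.row.names = FALSE))),
       cond_table = if (length(cond)) do.call(rbind, c(cond, list(make.row.names = FALSE))) else NULL,
       erps = erps,
       psd = list(power = if (length(psd_mats)) do.call(rbind, psd_mats) else NULL,
                  freq = psd_freq),
       funnel = do.call(rbind, funnel),
       ground_truth = gt)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: simulate the cohort, process every subject,
#' run the continuous phase analyses (SO amplitude, SWA and spindle
#' likelihood against EEG-SO / HR-LF / HR-HF phases, plus the HR response
#' against SO phase) and the multidimensional condition analysis, and
#' optionally write all result tables as CSV with a JSON manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param analysis_seed RNG seed for the Monte Carlo stages (default
#'   derived from `config$seed`).
#' @param min_trials,min_subjects,alpha inference parameters.
#' @param ... passed to [process_recording()] via [run_cohort()].
#' @return list with `cohort` (see [run_cohort()]), `continuous` (nested
#'   per metric/signal), `hr_by_so`, `conditions` (effect table,
#'   strategy comparisons, spectra), `funnel`.
#' @export
run_pipeline <- function(config, out_dir = NULL, analysis_seed = NULL,
                         min_trials = 5, min_subjects = 3, alpha = 0.05, ...) {
  if (is.null(analysis_seed)) analysis_seed <- (config$seed + 424243L) %% 2147483647L
  cohort <- run_cohort(config, min_trials = min_trials, ...)
  trials <- cohort$trials
  if (is.null(trials) || nrow(trials) == 0) stopf("pipeline stage 'trials': no retained trials")

  signals <- c("so", "lf", "hf")
  continuous <- list()
  for (metric in c("so_p2p_uv", "swa_norm", "spindle_flag")) {
    continuous[[metric]] <- list()
    for (sg in signals) {
      continuous[[metric]][[sg]] <- analyze_phase_responses(
        trials, sg, metric, min_trials = min_trials,
        min_subjects = min_subjects, alpha = alpha,
        seed = analysis_seed + match(sg, signals) * 131L +
          match(metric, c("so_p2p_uv", "swa_norm", "spindle_flag")) * 7L)
    }
  }
  hr_by_so <- if (any(is.finite(trials$hr_p2p_bpm))) {
    analyze_phase_responses(trials, "so", "hr_p2p_bpm",
                            min_trials = min_trials,
                            min_subjects = min_subjects, alpha = alpha,
                            seed = analysis_seed + 9999L)
  } else NULL

  conditions <- NULL
  if (!is.null(cohort$cond_table)) {
    effect_table <- strategy_effect_table(cohort$cond_table)
    pairs <- rbind(c("UUD", "U--"), c("UUD", "UU-"), c("UUD", "U-D"),
                   c("UU-", "U--"), c("U-D", "U--"),
                   c("-UD", "-U-"), c("-UD", "--D"), c("-U-", "--D"),
                   c("U--", "---"), c("UUD", "---"), c("-UD", "---"))
    comparisons <- compare_strategies(cohort$cond_table, pairs)
    spectra <- if (!is.null(cohort$psd$power)) {
      condition_spectra(trials, cohort$psd$power, cohort$psd$freq,
                        min_trials = min_trials)
    } else NULL
    conditions <- list(effect_table = effect_table,
                       comparisons = comparisons, spectra = spectra)
  }

  result <- list(cohort = cohort, continuous = continuous, hr_by_so = hr_by_so,
                 conditions = conditions, funnel = cohort$funnel,
                 config = config, analysis_seed = analysis_seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write pipeline result tables as CSV with a JSON manifest
#'
#' @param result output of [run_pipeline()].
#' @param out_dir target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$cohort$trials, "trials.csv")
  for (metric in names(result$continuous)) {
    for (sg in names(result$continuous[[metric]])) {
      a <- result$continuous[[metric]][[sg]]
      wr(a$contrasts, sprintf("contrasts_%s_by_%s.csv", metric, sg))
      wr(a$curve, sprintf("curve_%s_by_%s.csv", metric, sg))
      if (!is.null(a$pri)) wr(a$pri$tests, sprintf("pri_%s_by_%s.csv", metric, sg))
    }
  }
  if (!is.null(result$hr_by_so)) {
    wr(result$hr_by_so$contrasts, "contrasts_hr_p2p_by_so.csv")
    wr(result$hr_by_so$curve, "curve_hr_p2p_by_so.csv")
  }
  if (!is.null(result$conditions)) {
    wr(result$conditions$effect_table, "condition_effects.csv")
    wr(result$conditions$comparisons, "condition_comparisons.csv")
  }
  wr(as.data.frame(result$funnel), "funnel.csv")
  manifest <- list(
    package = "clasphase",
    r_version = as.character(getRversion()),
    seed = result$config$seed,
    analysis_seed = result$analysis_seed,
    n_subjects = result$config$n_subjects,
    duration_s = result$config$duration_s,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
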