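#' Tone-locked event-related potential
#'
#' Average of broadband EEG segments time-locked to the given onsets.
#'
#' @param onsets_s event onsets (s).
#' @param broadband broadband EEG (microvolts).
#' @param fs sampling rate (Hz).
#' @param window_s ERP window relative to onset (default `c(-2, 10)` s).
#' @return list with `t_s` (relative time) and `erp` (mean waveform), or
#'   NULL when no complete segment exists.
#' @export
condition_erp <- function(onsets_s, broadband, fs, window_s = c(-2, 10)) {
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  n <- length(broadband)
  acc <- numeric(length(rel))
  k <- 0L
  for (t0 in onsets_s) {
    idx <- round(t0 * fs) + 1L + rel
    if (idx[1] < 1L || idx[length(idx)] > n) next
    acc <- acc + broadband[idx]
    k <- k + 1L
  }
  if (k == 0L) return(NULL)
  list(t_s = rel / fs, erp = acc / k, n = k)
}

#' Peak-to-peak amplitude of an ERP within the post-onset search span
#'
#' @param erp an ERP from [condition_erp()].
#' @param span_s extrema search interval relative to onset (default 0-3 s).
#' @return max minus min of the ERP within the span (microvolts).
#' @export
erp_p2p <- function(erp, span_s = c(0, 3)) {
  sel <- erp$t_s >= span_s[1] & erp$t_s <= span_s[2]
  diff(range(erp$erp[sel]))
}

#' Per-subject condition results for one recording
#'
#' For every phase-locking condition, splits the subject's retained trials
#' into STIM and UNSTIM sets, computes tone-locked ERPs on the broadband
#' EEG (with the difference waveform STIM - UNSTIM), ERP peak-to-peak
#' amplitudes within the post-onset extrema span, trial-mean SO
#' amplitudes, and mean normalized SWA.
#'
#' @param trials the subject's retained trial table (with condition flag
#'   columns `cond_<label>` and responses).
#' @param broadband broadband EEG.
#' @param fs sampling rate.
#' @param specs condition set (default [condition_specs()]).
#' @param min_trials minimum trials per side for a condition (default 5).
#' @param window_s,span_s ERP window and extrema span.
#' @return list with `table` (one row per condition) and `erp` (named
#'   list of `list(t_s, stim, unstim, diff)` waveforms).
#' @export
subject_condition_results <- function(trials, broadband, fs,
                                      specs = condition_specs(),
                                      min_trials = 5,
                                      window_s = c(-2, 10), span_s = c(0, 3)) {
  rows <- list()
  erps <- list()
  for (j in seq_len(nrow(specs))) {
    lab <- specs$label[j]
    sel <- trials[[paste0("cond_", lab)]]
    st <- trials[sel & trials$is_stim, ]
    un <- trials[sel & !trials$is_stim, ]
    row <- data.frame(subject_id = trials$subject_id[1], label = lab,
                      n_stim = nrow(st), n_unstim = nrow(un),
                      stim_erp_p2p = NA_real_, unstim_erp_p2p = NA_real_,
                      diff_erp_p2p = NA_real_,
                      stim_so_amp = NA_real_, unstim_so_amp = NA_real_,
                      stim_swa = NA_real_, unstim_swa = NA_real_)
    if (nrow(st) >= min_trials && nrow(un) >= min_trials) {
      es <- condition_erp(st$onset_s, broadband, fs, window_s)
      eu <- condition_erp(un$onset_s, broadband, fs, window_s)
      if (!is.null(es) && !is.null(eu)) {
        ed <- list(t_s = es$t_s, erp = es$erp - eu$erp)
        row$stim_erp_p2p <- erp_p2p(es, span_s)
        row$unstim_erp_p2p <- erp_p2p(eu, span_s)
        row$diff_erp_p2p <- erp_p2p(ed, span_s)
        erps[[lab]] <- list(t_s = es$t_s, stim = es$erp, unstim = eu$erp,
                            diff = ed$erp)
      }
      row$stim_so_amp <- mean(st$so_p2p_uv)
      row$unstim_so_amp <- mean(un$so_p2p_uv)
      row$stim_swa <- mean(st$swa_norm)
      row$unstim_swa <- mean(un$swa_norm)
    }
    rows[[j]] <- row
  }
  list(table = do.call(rbind, rows), erp = erps)
}

#' Condition-level spectra
#'
#' Mean normalized PSD per condition, averaged over trials within subject
#' and then over subjects, separately for STIM and UNSTIM, with the
#' difference spectrum.
#'
#' @param trials cohort trial table with condition flags.
#' @param psd_power trials x frequencies matrix of normalized PSDs (rows
#'   aligned with `trials`).
#' @param freq frequency grid.
#' @param specs condition set.
#' @param min_trials minimum trials per subject per side.
#' @return named list per condition label: `freq`, `stim`, `unstim`,
#'   `diff` spectra (group means).
#' @export
condition_spectra <- function(trials, psd_power, freq,
                              specs = condition_specs(), min_trials = 5) {
  out <- list()
  subjects <- unique(trials$subject_id)
  for (j in seq_len(nrow(specs))) {
    lab <- specs$label[j]
    sel <- trials[[paste0("cond_", lab)]]
    s_list <- u_list <- list()
    for (sid in subjects) {
      ss <- sel & trials$is_stim & trials$subject_id == sid
      uu <- sel & !trials$is_stim & trials$subject_id == sid
      if (sum(ss) >= min_trials && sum(uu) >= min_trials) {
        s_list[[sid]] <- colMeans(psd_power[ss, , drop = FALSE])
        u_list[[sid]] <- colMeans(psd_power[uu, , drop = FALSE])
      }
    }
    if (length(s_list) > 0) {
      s_mean <- colMeans(do.call(rbind, s_list))
      u_mean <- colMeans(do.call(rbind, u_list))
      out[[lab]] <- list(freq = freq, stim = s_mean, unstim = u_mean,
                         diff = s_mean - u_mean)
    }
  }
  out
}

#' Compare phase-locking strategies across subjects
#'
#' For each requested pair of condition labels and each metric, the
#' per-subject difference is tested for normality with Shapiro-Wilk
#' (alpha = 0.05); a paired t-test is used when normality holds and a
#' Wilcoxon signed-rank test otherwise. Pairs with fewer than
#' `min_subjects` complete subjects are left untested.
#'
#' @param cond_table row-bound per-subject condition tables from
#'   [subject_condition_results()].
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   condition labels to compare.
#' @param metrics metric columns to compare (defaults to stimulated ERP
#'   peak-to-peak and SWA).
#' @param min_subjects minimum complete subjects (default 5).
#' @param shapiro_alpha normality-gate level (default 0.05).
#' @return data.frame: pair, metric, n, test used, statistic, p-value.
#' @export
compare_strategies <- function(cond_table, pairs,
                               metrics = c("stim_erp_p2p", "stim_swa"),
                               min_subjects = 5, shapiro_alpha = 0.05) {
  if (is.list(pairs) && !is.matrix(pairs)) pairs <- do.call(rbind, pairs)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    for (metric in metrics) {
      ta <- cond_table[cond_table$label == a, c("subject_id", metric)]
      tb <- cond_table[cond_table$label == b, c("subject_id", metric)]
      m <- merge(ta, tb, by = "subject_id", suffixes = c("_a", "_b"))
      m <- m[stats::complete.cases(m), ]
      d <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
      row <- data.frame(cond_a = a, cond_b = b, metric = metric,
                        n = length(d), test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        mean_diff = NA_real_)
      if (length(d) >= min_subjects) {
        row$mean_diff <- mean(d)
        normal <- if (stats::sd(d) == 0) TRUE else
          stats::shapiro.test(d)$p.value >= shapiro_alpha
        if (stats::sd(d) == 0) {
          row$test <- "paired t"; row$statistic <- 0
          row$p_value <- if (mean(d) == 0) 1 else 0
        } else if (normal) {
          tt <- stats::t.test(d)
          row$test <- "paired t"
          row$statistic <- unname(tt$statistic)
          row$p_value <- tt$p.value
        } else {
          wt <- stats::wilcox.test(d, exact = FALSE)
          row$test <- "wilcoxon"
          row$statistic <- unname(wt$statistic)
          row$p_value <- wt$p.value
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Strategy effect table (condition x metric grid)
#'
#' Produces the condition-level summary: group-mean stimulated and
#' unstimulated SO amplitudes (ERP peak-to-peak and trial-mean), SWA
#' expressed as a percentage of the unstimulated open-loop reference
#' (100 by definition), and enhancement deltas relative to open-loop
#' stimulation on the trial-mean SO amplitude.
#'
#' @param cond_table row-bound per-subject condition tables.
#' @param ref_label reference condition (default `"---"`, open loop).
#' @return data.frame, one row per condition, flagged `incomplete` when a
#'   condition is missing subjects entirely.
#' @export
strategy_effect_table <- function(cond_table, ref_label = "---") {
  labs <- unique(cond_table$label)
  ref_swa <- mean(cond_table$unstim_swa[cond_table$label == ref_label],
                  na.rm = TRUE)
  agg <- function(metric, lab) {
    mean(cond_table[[metric]][cond_table$label == lab], na.rm = TRUE)
  }
  out <- do.call(rbind, lapply(labs, function(lab) {
    data.frame(
      label = lab,
      n_subjects = sum(is.finite(cond_table$stim_so_amp[cond_table$label == lab])),
      n_stim = agg("n_stim", lab),
      n_unstim = agg("n_unstim", lab),
      stim_so_amp_erp = agg("stim_erp_p2p", lab),
      unstim_so_amp_erp = agg("unstim_erp_p2p", lab),
      stim_so_amp_trial = agg("stim_so_amp", lab),
      unstim_so_amp_trial = agg("unstim_so_amp", lab),
      stim_swa_pct = 100 * agg("stim_swa", lab) / ref_swa,
      unstim_swa_pct = 100 * agg("unstim_swa", lab) / ref_swa
    )
  }))
  ref_trial <- out$stim_so_amp_trial[out$label == ref_label]
  ref_erp <- out$stim_so_amp_erp[out$label == ref_label]
  out$so_enhancement_uv <- out$stim_so_amp_trial - ref_trial
  out$so_enhancement_erp_uv <- out$stim_so_amp_erp - ref_erp
  out$swa_enhancement_pct <- out$stim_swa_pct -
    out$stim_swa_pct[out$label == ref_label]
  out$incomplete <- out$n_subjects == 0
  out
}
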