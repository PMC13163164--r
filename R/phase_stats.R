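#' Mean-center responses within subjects
#'
#' Subtracts each subject's mean response. When `group` is supplied
#' (e.g. STIM vs UNSTIM), centering is performed within subject *and*
#' group, so that a constant offset between groups cannot masquerade as a
#' phase effect.
#'
#' @param values numeric responses.
#' @param subject subject identifier per value.
#' @param group optional grouping factor per value.
#' @return centered values.
#' @export
mean_center <- function(values, subject, group = NULL) {
  key <- if (is.null(group)) as.character(subject) else paste(subject, group)
  stats::ave(values, key, FUN = function(v) v - mean(v, na.rm = TRUE))
}

#' Gaussian Monte Carlo surrogate baseline for one phase bin
#'
#' Draws `n_draws` samples from a normal distribution with the empirical
#' mean and variance of the bin's UNSTIM responses. Requires at least two
#' values (variance defined); otherwise the bin is missing (`NULL`).
#' Consumes the current RNG stream.
#'
#' @param unstim_values UNSTIM responses in the bin (mean-centered).
#' @param n_draws number of surrogate draws (default 200).
#' @return numeric vector of draws, or `NULL` when the bin is missing.
#' @export
mc_baseline <- function(unstim_values, n_draws = 200) {
  unstim_values <- unstim_values[is.finite(unstim_values)]
  if (length(unstim_values) < 2) return(NULL)
  stats::rnorm(n_draws, mean(unstim_values), stats::sd(unstim_values))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control; `significant` flags satisfy `p_fdr < alpha`.
#'
#' @param p raw p-values in `[0, 1]` (NA allowed, propagated).
#' @param alpha FDR level (default 0.05).
#' @return list with `p_fdr` and `significant`.
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_fdr = adj, significant = !is.na(adj) & adj < alpha)
}

# Per-subject, per-bin response summaries with MC baselines.
# Returns a list keyed by subject, each with 24-vectors and a draws matrix.
bin_summaries <- function(trials, phi_col, value_col, grid = phase_bin_grid(),
                          n_draws = 200) {
  out <- list()
  for (sid in unique(trials$subject_id)) {
    tr <- trials[trials$subject_id == sid, ]
    ok <- is.finite(tr[[phi_col]]) & is.finite(tr[[value_col]])
    tr <- tr[ok, ]
    stim <- tr[tr$is_stim, ]
    unst <- tr[!tr$is_stim, ]
    sv <- stim[[value_col]] - mean(stim[[value_col]])
    uv <- unst[[value_col]] - mean(unst[[value_col]])
    sm <- if (nrow(stim)) bin_membership_matrix(stim[[phi_col]], grid) else
      matrix(FALSE, 0, nrow(grid))
    um <- if (nrow(unst)) bin_membership_matrix(unst[[phi_col]], grid) else
      matrix(FALSE, 0, nrow(grid))
    nb <- nrow(grid)
    s <- list(n_stim = colSums(sm), n_unstim = colSums(um),
              stim_mean = rep(NA_real_, nb), unstim_mean = rep(NA_real_, nb),
              unstim_sd = rep(NA_real_, nb), mc_mean = rep(NA_real_, nb),
              mc_draws = matrix(NA_real_, n_draws, nb),
              stim_flag = rep(NA_real_, nb), unstim_flag = rep(NA_real_, nb))
    has_flag <- "spindle_flag" %in% names(tr)
    for (b in seq_len(nb)) {
      if (s$n_stim[b] > 0) {
        s$stim_mean[b] <- mean(sv[sm[, b]])
        if (has_flag) s$stim_flag[b] <- mean(stim$spindle_flag[sm[, b]])
      }
      if (s$n_unstim[b] > 0 && has_flag) s$unstim_flag[b] <- mean(unst$spindle_flag[um[, b]])
      if (s$n_unstim[b] > 0) {
        vals <- uv[um[, b]]
        s$unstim_mean[b] <- mean(vals)
        if (length(vals) >= 2) {
          s$unstim_sd[b] <- stats::sd(vals)
          draws <- mc_baseline(vals, n_draws)
          s$mc_draws[, b] <- draws
          s$mc_mean[b] <- mean(draws)
        }
      }
    }
    out[[sid]] <- s
  }
  out
}

#' Per-bin STIM-MC vs UNSTIM-MC contrast tests
#'
#' For each subject and bin, the STIM-MC contrast is the bin's STIM mean
#' minus the mean of its Monte Carlo baseline draws, and likewise for
#' UNSTIM-MC. Per bin, the paired difference (STIM-MC) - (UNSTIM-MC) is
#' tested against zero across subjects with a one-sample t-test, and
#' p-values are corrected over bins with Benjamini-Hochberg.
#'
#' @param summaries output of the internal per-subject binning (see
#'   [analyze_phase_responses()]).
#' @param grid the phase-bin grid.
#' @param min_trials minimum STIM trials per subject-bin (default 5).
#' @param min_subjects minimum subjects per tested bin (default 3).
#' @param alpha FDR level.
#' @return data.frame per bin: `bin`, `center_deg`, `n_subjects`,
#'   `mean_contrast` (group mean paired difference), `stim_mc`,
#'   `unstim_mc`, `t_stat`, `p_raw`, `p_fdr`, `significant`, `tested`.
#' @export
bin_contrast_tests <- function(summaries, grid = phase_bin_grid(),
                               min_trials = 5, min_subjects = 3, alpha = 0.05) {
  nb <- nrow(grid)
  res <- data.frame(bin = grid$bin, center_deg = grid$center_deg,
                    n_subjects = 0L, mean_contrast = NA_real_,
                    stim_mc = NA_real_, unstim_mc = NA_real_,
                    t_stat = NA_real_, p_raw = NA_real_)
  for (b in seq_len(nb)) {
    d <- smc <- umc <- numeric(0)
    for (s in summaries) {
      if (s$n_stim[b] >= min_trials && is.finite(s$mc_mean[b])) {
        sc <- s$stim_mean[b] - s$mc_mean[b]
        uc <- s$unstim_mean[b] - s$mc_mean[b]
        d <- c(d, sc - uc); smc <- c(smc, sc); umc <- c(umc, uc)
      }
    }
    res$n_subjects[b] <- length(d)
    if (length(d) >= max(2, min_subjects)) {
      res$mean_contrast[b] <- mean(d)
      res$stim_mc[b] <- mean(smc)
      res$unstim_mc[b] <- mean(umc)
      if (stats::sd(d) == 0) {
        res$t_stat[b] <- 0; res$p_raw[b] <- 1
      } else {
        tt <- stats::t.test(d)
        res$t_stat[b] <- unname(tt$statistic)
        res$p_raw[b] <- tt$p.value
      }
    }
  }
  res$tested <- !is.na(res$p_raw)
  res$p_fdr <- NA_real_
  res$significant <- FALSE
  if (any(res$tested)) {
    bh <- benjamini_hochberg(res$p_raw[res$tested], alpha)
    res$p_fdr[res$tested] <- bh$p_fdr
    res$significant[res$tested] <- bh$significant
  }
  res
}

#' Pairwise Response Index
#'
#' For one subject, each bin's STIM-MC contrast distribution is the
#' vector of `stim_mean - mc_draw_k` values (one per Monte Carlo draw).
#' Every ordered pair of distinct bins is compared with Welch's
#' unequal-variance t-statistic; the PRI of a bin is the average sign of
#' its statistics over the comparisons with all other bins, in `[-1, 1]`.
#'
#' @param contrast_dists numeric matrix, draws x bins, of STIM-MC
#'   contrast values (NA columns = missing bins).
#' @return numeric vector of PRI values per bin (NA for missing bins).
#' @export
compute_pri <- function(contrast_dists) {
  nb <- ncol(contrast_dists)
  m <- colMeans(contrast_dists)
  v <- apply(contrast_dists, 2, stats::var)
  n <- nrow(contrast_dists)
  pri <- rep(NA_real_, nb)
  for (a in seq_len(nb)) {
    if (!is.finite(m[a])) next
    signs <- numeric(0)
    for (b in seq_len(nb)) {
      if (b == a || !is.finite(m[b])) next
      den <- sqrt(v[a] / n + v[b] / n)
      t_ab <- if (den == 0) 0 else (m[a] - m[b]) / den
      signs <- c(signs, sign(t_ab))
    }
    if (length(signs) > 0) pri[a] <- mean(signs)
  }
  pri
}

#' Group-level PRI tests
#'
#' Computes the per-subject PRI per bin from the Monte Carlo contrast
#' distributions, then tests the group PRI against zero per bin with
#' one-sample t-tests and BH-FDR.
#'
#' @inheritParams bin_contrast_tests
#' @return list with `pri` (subjects x bins matrix) and `tests`
#'   (per-bin data.frame as in [bin_contrast_tests()]).
#' @export
pri_tests <- function(summaries, grid = phase_bin_grid(), min_trials = 5,
                      min_subjects = 3, alpha = 0.05) {
  nb <- nrow(grid)
  pri_mat <- matrix(NA_real_, length(summaries), nb,
                    dimnames = list(names(summaries), NULL))
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    cd <- matrix(NA_real_, nrow(s$mc_draws), nb)
    for (b in seq_len(nb)) {
      if (s$n_stim[b] >= min_trials && all(is.finite(s$mc_draws[, b]))) {
        cd[, b] <- s$stim_mean[b] - s$mc_draws[, b]
      }
    }
    pri_mat[i, ] <- compute_pri(cd)
  }
  res <- data.frame(bin = grid$bin, center_deg = grid$center_deg,
                    n_subjects = colSums(is.finite(pri_mat)),
                    mean_pri = colMeans(pri_mat, na.rm = TRUE),
                    t_stat = NA_real_, p_raw = NA_real_)
  for (b in seq_len(nb)) {
    v <- pri_mat[is.finite(pri_mat[, b]), b]
    if (length(v) >= max(2, min_subjects)) {
      if (stats::sd(v) == 0) {
        res$t_stat[b] <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
        res$p_raw[b] <- if (mean(v) == 0) 1 else 0
      } else {
        tt <- stats::t.test(v)
        res$t_stat[b] <- unname(tt$statistic)
        res$p_raw[b] <- tt$p.value
      }
    }
  }
  res$tested <- !is.na(res$p_raw)
  res$p_fdr <- NA_real_; res$significant <- FALSE
  if (any(res$tested)) {
    bh <- benjamini_hochberg(res$p_raw[res$tested], alpha)
    res$p_fdr[res$tested] <- bh$p_fdr
    res$significant[res$tested] <- bh$significant
  }
  list(pri = pri_mat, tests = res)
}

#' Resampling null reference for spindle likelihood in one bin
#'
#' Repeatedly draws two-thirds of the bin's UNSTIM trials without
#' replacement and computes the spindle likelihood of each draw; the null
#' reference is the geometric mean over iterations, with iterations of
#' zero likelihood contributing `1/(2m)` (m = trials per draw) so the
#' geometric mean stays defined. Consumes the current RNG stream.
#'
#' @param spindle_flags logical vector of UNSTIM spindle flags in the bin
#'   (pooled across subjects).
#' @param n_resamples resampling iterations (default 200).
#' @param frac fraction drawn per iteration (default 2/3).
#' @return the null reference in `[0, 1]`, or NA with fewer than 3 trials.
#' @export
spindle_likelihood_null <- function(spindle_flags, n_resamples = 200,
                                    frac = 2 / 3) {
  n <- length(spindle_flags)
  if (n < 3) return(NA_real_)
  m <- max(1L, floor(frac * n))
  liks <- vapply(seq_len(n_resamples), function(i) {
    mean(spindle_flags[sample.int(n, m)])
  }, numeric(1))
  liks[liks == 0] <- 1 / (2 * m)
  exp(mean(log(liks)))
}

#' Per-bin spindle-likelihood tests against the resampling null
#'
#' Each subject's STIM and UNSTIM spindle likelihood in a bin is expressed
#' as a percentage of the bin's pooled UNSTIM resampling null; per bin the
#' STIM and UNSTIM relative likelihoods are compared across subjects with
#' Welch's unequal-variance t-test, BH-corrected over bins.
#'
#' @param trials trial table with `subject_id`, `is_stim`, `spindle_flag`
#'   and the phase column `phi_col`.
#' @param phi_col name of the phase column.
#' @param grid phase-bin grid.
#' @param min_trials minimum trials per subject-bin for a likelihood.
#' @param min_subjects minimum subjects per tested bin.
#' @param alpha FDR level.
#' @param n_resamples,frac resampling-null parameters.
#' @return data.frame per bin with the null reference, group mean relative
#'   likelihoods, Welch statistic and FDR-corrected p-values.
#' @export
spindle_likelihood_tests <- function(trials, phi_col, grid = phase_bin_grid(),
                                     min_trials = 5, min_subjects = 3,
                                     alpha = 0.05, n_resamples = 200,
                                     frac = 2 / 3) {
  trials <- trials[is.finite(trials[[phi_col]]) & !is.na(trials$spindle_flag), ]
  mem <- bin_membership_matrix(trials[[phi_col]], grid)
  nb <- nrow(grid)
  res <- data.frame(bin = grid$bin, center_deg = grid$center_deg,
                    null_reference = NA_real_, n_subjects = 0L,
                    stim_rel_mean = NA_real_, unstim_rel_mean = NA_real_,
                    t_stat = NA_real_, p_raw = NA_real_)
  subjects <- unique(trials$subject_id)
  for (b in seq_len(nb)) {
    in_bin <- mem[, b]
    null_ref <- spindle_likelihood_null(
      trials$spindle_flag[in_bin & !trials$is_stim], n_resamples, frac)
    res$null_reference[b] <- null_ref
    if (!is.finite(null_ref) || null_ref <= 0) next
    s_rel <- u_rel <- numeric(0)
    for (sid in subjects) {
      sel_s <- in_bin & trials$is_stim & trials$subject_id == sid
      sel_u <- in_bin & !trials$is_stim & trials$subject_id == sid
      if (sum(sel_s) >= min_trials && sum(sel_u) >= min_trials) {
        s_rel <- c(s_rel, 100 * mean(trials$spindle_flag[sel_s]) / null_ref)
        u_rel <- c(u_rel, 100 * mean(trials$spindle_flag[sel_u]) / null_ref)
      }
    }
    res$n_subjects[b] <- length(s_rel)
    if (length(s_rel) >= max(2, min_subjects)) {
      res$stim_rel_mean[b] <- mean(s_rel)
      res$unstim_rel_mean[b] <- mean(u_rel)
      if (stats::sd(s_rel) == 0 && stats::sd(u_rel) == 0) {
        res$t_stat[b] <- 0
        res$p_raw[b] <- 1
      } else {
        tt <- stats::t.test(s_rel, u_rel, var.equal = FALSE)
        res$t_stat[b] <- unname(tt$statistic)
        res$p_raw[b] <- tt$p.value
      }
    }
  }
  res$tested <- !is.na(res$p_raw)
  res$p_fdr <- NA_real_; res$significant <- FALSE
  if (any(res$tested)) {
    bh <- benjamini_hochberg(res$p_raw[res$tested], alpha)
    res$p_fdr[res$tested] <- bh$p_fdr
    res$significant[res$tested] <- bh$significant
  }
  res
}

#' Continuous phase-response analysis for one signal and metric
#'
#' Runs the full continuous-phase inference for one phase signal
#' (EEG SO, HR-LF or HR-HF) and one response metric: per-subject
#' mean-centering and 60/15-degree circular binning, Gaussian Monte Carlo
#' baselines from the UNSTIM responses, per-bin STIM-MC vs UNSTIM-MC
#' contrast tests with BH-FDR, the Pairwise Response Index, and (for the
#' spindle metric) the resampling-null likelihood tests. The preferred
#' phase readout is the bin centre maximising the group-mean
#' mean-centered STIM response.
#'
#' @param trials trial table (see [process_recording()]): one row per
#'   STIM/UNSTIM trial with phases and responses.
#' @param signal one of `"so"`, `"lf"`, `"hf"`.
#' @param metric response column, e.g. `"so_p2p_uv"`, `"swa_norm"`,
#'   `"hr_p2p_bpm"`, `"spindle_flag"`.
#' @param grid phase-bin grid.
#' @param n_draws Monte Carlo draws per bin (default 200).
#' @param min_trials,min_subjects inclusion thresholds.
#' @param alpha FDR level.
#' @param seed RNG seed for the Monte Carlo baselines.
#' @return list with `curve` (per-bin group response curve),
#'   `preferred_center_deg`, `anti_center_deg`, `extreme_diff`,
#'   `contrasts` (per-bin test table), `pri` (see [pri_tests()]), and
#'   `likelihood` (only for `metric = "spindle_flag"`).
#' @export
analyze_phase_responses <- function(trials, signal = c("so", "lf", "hf"),
                                    metric = "so_p2p_uv",
                                    grid = phase_bin_grid(), n_draws = 200,
                                    min_trials = 5, min_subjects = 3,
                                    alpha = 0.05, seed = 1L) {
  signal <- match.arg(signal)
  phi_col <- paste0("phi_", signal)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed %% 2147483647L)

  if (metric == "spindle_flag") {
    lik <- spindle_likelihood_tests(trials, phi_col, grid, min_trials,
                                    min_subjects, alpha)
    curve <- data.frame(bin = grid$bin, center_deg = grid$center_deg,
                        group_mean = lik$stim_rel_mean - lik$unstim_rel_mean,
                        n_subjects = lik$n_subjects)
    best <- which.max(curve$group_mean)
    worst <- which.min(curve$group_mean)
    return(list(curve = curve,
                preferred_center_deg = curve$center_deg[best],
                anti_center_deg = curve$center_deg[worst],
                extreme_diff = curve$group_mean[best] - curve$group_mean[worst],
                contrasts = lik, pri = NULL, likelihood = lik))
  }

  summaries <- bin_summaries(trials, phi_col, metric, grid, n_draws)
  contrasts <- bin_contrast_tests(summaries, grid, min_trials, min_subjects, alpha)
  pri <- pri_tests(summaries, grid, min_trials, min_subjects, alpha)

  # group STIM response curve (mean-centered within subject)
  nb <- nrow(grid)
  stim_mat <- t(vapply(summaries, function(s) {
    out <- s$stim_mean
    out[s$n_stim < min_trials] <- NA_real_
    out
  }, numeric(nb)))
  curve <- data.frame(bin = grid$bin, center_deg = grid$center_deg,
                      group_mean = colMeans(stim_mat, na.rm = TRUE),
                      n_subjects = colSums(is.finite(stim_mat)))
  curve$group_mean[curve$n_subjects < min_subjects] <- NA_real_
  best <- which.max(curve$group_mean)
  worst <- which.min(curve$group_mean)
  list(curve = curve,
       preferred_center_deg = curve$center_deg[best],
       anti_center_deg = curve$center_deg[worst],
       extreme_diff = curve$group_mean[best] - curve$group_mean[worst],
       contrasts = contrasts, pri = pri, likelihood = NULL)
}

#' Total angular extent of contiguous significant bins
#'
#' Length (degrees) of the largest contiguous arc of FDR-significant bin
#' centres, a descriptive summary of the "window of significant effects".
#'
#' @param tests a per-bin test table with `significant`.
#' @param grid the phase-bin grid.
#' @return arc length in degrees (0 when nothing is significant).
#' @export
significant_arc_deg <- function(tests, grid = phase_bin_grid()) {
  sig <- tests$significant[order(grid$left_deg)]
  if (!any(sig)) return(0)
  if (all(sig)) return(360)
  ext <- rep(sig, 2)                    # unwrap the circle
  r <- rle(ext)
  max(r$lengths[r$values]) * (grid$left_deg[2] - grid$left_deg[1])
}
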