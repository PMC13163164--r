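test_that("mean-centering removes subject (and group) means", {
  expect_equal(mean_center(c(10, 20, 30), rep("a", 3)), c(-10, 0, 10))
  expect_equal(mean_center(7, "a"), 0)
  v <- mean_center(c(1, 2, 10, 20), c("a", "a", "b", "b"))
  expect_equal(as.vector(tapply(v, c("a", "a", "b", "b"), sum)), c(0, 0))
  vg <- mean_center(c(1, 3, 10, 30), rep("a", 4), c("s", "s", "u", "u"))
  expect_equal(sum(vg[1:2]), 0)
  expect_equal(sum(vg[3:4]), 0)
})

test_that("Monte Carlo baselines reproduce the bin's Gaussian fit", {
  set.seed(61)
  expect_equal(mc_baseline(rep(4, 10)), rep(4, 200))
  draws <- mc_baseline(rnorm(50, 10, 2))
  expect_length(draws, 200)
  expect_lt(abs(mean(draws) - 10), 1)
  expect_null(mc_baseline(5))
})

test_that("Benjamini-Hochberg step-up rejects exactly the right hypotheses", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.04, 0.06), alpha = 0.05)
  expect_identical(bh$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(bh$p_fdr >= c(0.01, 0.02, 0.04, 0.06)))
  expect_true(all(benjamini_hochberg(rep(0.001, 8))$significant))
  expect_false(any(benjamini_hochberg(rep(0.9, 8))$significant))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted p monotone non-decreasing in raw-p rank
  set.seed(62)
  p <- runif(30)
  adj <- benjamini_hochberg(p)$p_fdr
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("PRI matches a brute-force Welch-sign oracle", {
  set.seed(63)
  # forced ordering: tight separated distributions
  cd <- cbind(rnorm(200, 0, 0.01), rnorm(200, 1, 0.01), rnorm(200, 2, 0.01))
  expect_equal(compute_pri(cd), c(-1, 0, 1))
  # identical constant distributions: all zeros
  expect_equal(compute_pri(matrix(5, 200, 4)), rep(0, 4))
  # random instances vs a literal double loop using stats::t.test
  for (rep_i in 1:5) {
    nb <- sample(3:6, 1)
    cd <- matrix(rnorm(20 * nb, sd = sample(1:3, 1)), 20, nb)
    got <- compute_pri(cd)
    oracle <- vapply(seq_len(nb), function(a) {
      s <- 0
      for (b in setdiff(seq_len(nb), a)) {
        s <- s + sign(stats::t.test(cd[, a], cd[, b],
                                    var.equal = FALSE)$statistic)
      }
      s / (nb - 1)
    }, numeric(1))
    expect_equal(got, unname(oracle), tolerance = 1e-12)
  }
  # antisymmetry: signed comparisons cancel over bins
  cd24 <- matrix(rnorm(200 * 24), 200, 24)
  pri <- compute_pri(cd24)
  expect_lt(abs(sum(pri)), 1e-9)
  expect_true(all(pri >= -1 & pri <= 1))
})

test_that("the spindle-likelihood resampling null behaves at the extremes", {
  set.seed(64)
  expect_equal(spindle_likelihood_null(rep(TRUE, 30)), 1)
  m <- floor(2 / 3 * 30)
  expect_equal(spindle_likelihood_null(rep(FALSE, 30)), 1 / (2 * m))
  null_mid <- spindle_likelihood_null(rep(c(TRUE, FALSE), 150))
  expect_true(null_mid >= 0.45 && null_mid <= 0.50)
  expect_true(is.na(spindle_likelihood_null(c(TRUE, FALSE))))
})

test_that("degenerate contrasts produce no significance", {
  trials <- data.frame(
    subject_id = rep(c("a", "b", "c", "d"), each = 40),
    is_stim = rep(c(TRUE, FALSE), 80),
    phi_so = rep(seq(-179, 180, length.out = 40), 4),
    so_p2p_uv = 150
  )
  a <- analyze_phase_responses(trials, "so", "so_p2p_uv", min_trials = 2,
                               seed = 3)
  tst <- a$contrasts[a$contrasts$tested, ]
  expect_gt(nrow(tst), 0)
  expect_false(any(tst$significant))
  expect_true(all(tst$t_stat == 0))
})

test_that("a bin-confined injected effect is detected and localized", {
  set.seed(65)
  subj <- sprintf("s%02d", 1:12)
  mk <- function(sid) {
    n_s <- 120; n_u <- 80
    phi <- runif(n_s + n_u, -180, 180 - 1e-9)
    stim <- rep(c(TRUE, FALSE), c(n_s, n_u))
    resp <- rnorm(n_s + n_u, 150, 15)
    boost <- stim & abs(circ_diff(phi, 75)) < 45
    resp[boost] <- resp[boost] + 30
    data.frame(subject_id = sid, is_stim = stim, phi_so = phi,
               so_p2p_uv = resp)
  }
  trials <- do.call(rbind, lapply(subj, mk))
  a <- analyze_phase_responses(trials, "so", "so_p2p_uv", seed = 99)
  expect_lt(abs(circ_diff(a$preferred_center_deg, 75)), 45)
  sig_centers <- a$contrasts$center_deg[a$contrasts$significant]
  expect_true(any(abs(circ_diff(sig_centers, 75)) <= 30))
  # mean-centering makes the anti-preferred side a significant *minimum*
  anti <- a$contrasts$significant & abs(circ_diff(a$contrasts$center_deg, -105)) < 45
  if (any(anti)) expect_true(all(a$contrasts$mean_contrast[anti] < 0))
  expect_gt(max(a$contrasts$mean_contrast, na.rm = TRUE), 0)
  # MC reproducibility end to end
  b <- analyze_phase_responses(trials, "so", "so_p2p_uv", seed = 99)
  expect_identical(a$contrasts, b$contrasts)
  expect_identical(a$pri$pri, b$pri$pri)
})

test_that("the significant-arc summary measures contiguous extent", {
  grid <- phase_bin_grid()
  tests <- data.frame(significant = rep(FALSE, 24))
  expect_equal(significant_arc_deg(tests, grid), 0)
  tests$significant[5:10] <- TRUE
  expect_equal(significant_arc_deg(tests, grid), 6 * 15)
  # wrap-around arc
  tests$significant[] <- FALSE
  tests$significant[c(1, 2, 23, 24)] <- TRUE
  expect_equal(significant_arc_deg(tests, grid), 4 * 15)
  tests$significant[] <- TRUE
  expect_equal(significant_arc_deg(tests, grid), 360)
})
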