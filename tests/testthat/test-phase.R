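test_that("corrected Hilbert phase follows the quadrature convention", {
  for (f in c(0.8, 0.1, 0.25)) {
    fs <- if (f > 0.5) 64 else 10
    t <- seq(0, 40 / f, by = 1 / fs)
    x <- sin(2 * pi * f * t)
    ph <- instantaneous_phase(x, fs)
    core <- seq_along(t) > length(t) * 0.1 & seq_along(t) < length(t) * 0.9
    true <- clasphase:::wrap_deg(360 * f * t)
    expect_lt(max(abs(circ_diff(ph[core], true[core]))), 2)
    # spot-check the three calibration points
    peaks <- which(abs(circ_diff(true, 90)) < 180 * f / fs)
    expect_lt(max(abs(circ_diff(ph[intersect(peaks, which(core))], 90))), 2)
    troughs <- which(abs(circ_diff(true, -90)) < 180 * f / fs)
    expect_lt(max(abs(circ_diff(ph[intersect(troughs, which(core))], -90))), 2)
    upzero <- which(abs(circ_diff(true, 0)) < 180 * f / fs)
    expect_lt(max(abs(circ_diff(ph[intersect(upzero, which(core))], 0))), 2)
  }
})

test_that("an all-zero signal has no phase", {
  expect_error(instantaneous_phase(numeric(100), 10), "zero")
})

test_that("phase lookup is nearest-sample with NA outside the span", {
  t <- seq(0, 60, by = 0.1)
  ps <- phase_series(sin(2 * pi * 0.25 * t), fs = 10, source = "HR_HF")
  # exactly on a grid point
  expect_equal(phase_at(ps, 12.3), ps$phase_deg[124])
  # 0.049 s past a grid point rounds back to it
  expect_equal(phase_at(ps, 12.349), ps$phase_deg[124])
  expect_warning(out <- phase_at(ps, c(5, 400)), "outside")
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("sampling bounds the phase lookup error on a pure tone", {
  fs <- 64; f <- 0.8
  t <- seq(0, 120, by = 1 / fs)
  ps <- phase_series(sin(2 * pi * f * t), fs = fs)
  set.seed(31)
  ev <- runif(100, 10, 110)
  got <- phase_at(ps, ev)
  true <- clasphase:::wrap_deg(360 * f * ev)
  expect_lt(max(abs(circ_diff(got, true))), 360 * f / fs + 2)
})

test_that("every phase lies in exactly four 60/15-degree bins", {
  grid <- phase_bin_grid()
  expect_equal(nrow(grid), 24)
  expect_identical(bin_membership(0), which(grid$left_deg %in% c(-60, -45, -30, -15)))
  m179 <- bin_membership(-179)
  expect_true(all(grid$left_deg[m179] %in% c(-180, 135, 150, 165)))
  set.seed(32)
  phis <- runif(1e4, -180, 180 - 1e-9)
  mm <- clasphase:::bin_membership_matrix(phis)
  expect_true(all(rowSums(mm) == 4))
  counts <- colSums(mm)
  expected <- 4e4 / 24
  expect_true(all(abs(counts - expected) < 5 * sqrt(expected)))
})

test_that("binary states follow the half-open convention", {
  expect_identical(classify_state(90), "U")
  expect_identical(classify_state(-90), "D")
  expect_identical(classify_state(0), "U")
  expect_identical(classify_state(-180), "D")
})

test_that("binary states are recoverable from the fine bins", {
  set.seed(33)
  phis <- runif(500, 0, 180 - 1e-9)   # upstate phases
  grid <- phase_bin_grid()
  for (p in phis[1:50]) {
    centers <- grid$center_deg[bin_membership(p, grid)]
    # all member-bin centres lie within the arc (-60, 240) around upstate
    d <- (centers + 60) %% 360
    expect_true(all(d > 0 & d < 300))
  }
})

test_that("condition assignment matches the eight-condition table", {
  m <- assign_conditions("U", "U", "D")
  expect_true(all(m[1, ]))
  m2 <- assign_conditions("D", "U", "D")
  expect_identical(unname(m2[1, ]), c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  # any tone always matches the open-loop condition
  set.seed(34)
  st <- matrix(sample(c("U", "D"), 300, replace = TRUE), ncol = 3)
  mm <- assign_conditions(st[, 1], st[, 2], st[, 3])
  expect_true(all(mm[, "---"]))
  # nesting: the triple-locked count never exceeds any parent
  n <- colSums(mm)
  expect_true(n["UUD"] <= min(n["UU-"], n["U-D"], n["-UD"]))
  expect_true(max(n[c("UU-", "U-D", "-UD")]) <= max(n[c("U--", "-U-", "--D")]))
  expect_true(all(n <= n["---"]))
})

test_that("time-shifting a sinusoid shifts event phases accordingly", {
  fs <- 64; f <- 0.8; dt <- 0.3
  t <- seq(0, 60, by = 1 / fs)
  ps1 <- phase_series(sin(2 * pi * f * t), fs)
  ps2 <- phase_series(sin(2 * pi * f * (t - dt)), fs)
  ev <- seq(10, 50, by = 0.9)
  d <- circ_diff(phase_at(ps1, ev), phase_at(ps2, ev))
  expect_lt(max(abs(circ_diff(d, 360 * f * dt))), 3)
})
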