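test_that("autocorrelation matches its definition and the direct oracle", {
  expect_equal(autocorrelation(c(1, 2, 3, 4), 1), c(1, 1 / 3),
               tolerance = 1e-12)
  set.seed(21)
  for (T in c(64, 500, 2000)) {
    x <- rnorm(T) + sin(2 * pi * (1:T) / 30)
    ac_fft <- autocorrelation(x, 50)
    ac_dir <- mcgica:::autocorrelation_direct(x, 50)
    expect_lt(max(abs(ac_fft - ac_dir)), 1e-10)
    expect_equal(ac_fft[1], 1, tolerance = 1e-12)
  }
  # sinusoid recurrence: Ac at one period is ~1 (within O(P/T))
  P <- 100; T <- 20000
  s <- sin(2 * pi * (1:T) / P)
  expect_gt(autocorrelation(s, P)[P + 1], 1 - 5 * P / T)
  expect_error(autocorrelation(rep(2, 100), 10), "constant")
  expect_error(autocorrelation(rnorm(50), 50), "max_lag")
})

test_that("AIP is the windowed variance of the autocorrelation", {
  expect_equal(aip(c(0.5, 0.5, 0.5, 0.5), c(0, 3), fs = 1), 0)
  expect_equal(aip(c(0, 0.5, 1.0), c(0, 2), fs = 1), 1 / 6)
  expect_error(aip(c(0, 0.5, 1.0), c(0, 5), fs = 1), "beyond")
  expect_error(aip(c(0, 0.5, 1.0), c(1, 1.2), fs = 1))  # < 2 lag samples
  # white noise: AIP stays at the sampling floor ~1/T on lags > 0
  set.seed(8)
  for (i in 1:20) {
    T <- 5000
    ac <- autocorrelation(rnorm(T), 400)
    expect_lt(aip(ac, c(0.05, 0.4), fs = 1000), 5 / T)
  }
})

test_that("IPR ranks heartbeat sources above tone and noise sources", {
  iv <- make_intervals()
  fs <- 1000
  max_lag <- round((iv$tau2 + 0.15) * fs)
  tone <- synth_pli(100, fs, 12)
  ipr_tone <- ipr(autocorrelation(tone, max_lag), iv, fs)
  expect_lt(ipr_tone, 2)
  expect_gt(ipr_tone, 0.5)    # cosine autocorrelation: both windows alike
  for (seed in 1:5) {
    hb <- synth_heartbeat(100, fs, seed = seed)$series
    ipr_hb <- ipr(autocorrelation(hb, max_lag), iv, fs)
    bwn <- synth_bwn(100, fs, c(0, 100), seed = seed)
    ipr_bwn <- ipr(autocorrelation(bwn, max_lag), iv, fs)
    expect_lt(ipr_bwn, 2)
    # the cardiac recurrence peak puts the heartbeat on top
    expect_gt(ipr_hb, 1.25)
    expect_gt(ipr_hb, ipr_bwn)
    expect_gt(ipr_hb, ipr_tone)
  }
  # after QRS-band ICA (the selection stage's actual input) the margin is
  # wide: the pipeline template carries an order-of-magnitude IPR
  res <- test_run("pli", 7, seed = 1)
  expect_gt(res$scores$table$ipr[res$scores$template_index], 5)
  # identical intervals give exactly 1
  iv_same <- make_intervals(); iv_same$tau3 <- iv_same$tau1
  iv_same$tau4 <- iv_same$tau2
  expect_equal(ipr(autocorrelation(hb, max_lag), iv_same, fs), 1)
})

test_that("template selection takes the largest finite IPR, ties low", {
  expect_identical(select_template(c(2.0, 50.0, 1.1)), 2L)
  expect_identical(select_template(7), 1L)
  expect_identical(select_template(c(5.0, 5.0)), 1L)
  expect_identical(select_template(c(Inf, 3, 4)), 3L)
  expect_error(select_template(c(Inf, NaN)), "finite")
})

test_that("cross-correlation matches the direct oracle and locates shifts", {
  set.seed(31)
  for (T in c(300, 2000)) {
    x <- rnorm(T); y <- 0.4 * x + rnorm(T)
    cc_fft <- cross_correlation(x, y, 40)
    cc_dir <- mcgica:::cross_correlation_direct(x, y, 40)
    expect_lt(max(abs(cc_fft - cc_dir)), 1e-10)
  }
  x <- rnorm(5000)
  expect_equal(unname(cross_correlation(x, x, 0)), 1, tolerance = 1e-12)
  # shifted copy: extremum at the shift lag
  s <- 17
  y <- c(rep(0, s), x[1:(5000 - s)])
  cc <- cross_correlation(x, y, 40)
  expect_identical(names(which.max(cc)), as.character(s))
  expect_gt(max(cc), 0.98)
  # independent white noise: everything below the sampling bound
  a <- rnorm(20000); b <- rnorm(20000)
  expect_lt(max(abs(cross_correlation(a, b, 300))), 0.05)
  expect_error(cross_correlation(rnorm(10), rnorm(11), 2), "equal length")
})

test_that("CFE takes the signed extremum within the delay window", {
  x <- synth_heartbeat(30, 1000, seed = 2)$series
  cc <- cross_correlation(x, x, 400)
  expect_equal(cfe(cc, 0.3, 1000), 1, tolerance = 1e-9)
  expect_error(cfe(cc, 0.5, 1000), "lag range")
  # asymmetric series: signed maximum, not max |R|
  r <- c(-0.9, -0.2, 0.1, 0.3, 0.05)   # lags -2..2
  expect_equal(cfe(r, 2, fs = 1), 0.3)
})

test_that("ranking keeps the top-N CFE components with stable ties", {
  sk <- rank_and_mask(c(1.0, 0.8, 0.05, 0.6), 2, 1L)
  expect_identical(which(sk$keep_mask), c(1L, 2L))
  expect_identical(sk$order[1:2], c(1L, 2L))
  expect_true(all(rank_and_mask(rep(0.5, 4), 4, 1L)$keep_mask))
  tie <- rank_and_mask(c(1.0, 0.5, 0.5), 2, 1L)
  expect_identical(which(tie$keep_mask), c(1L, 2L))
  expect_error(rank_and_mask(c(1, 0.5), 3, 1L), "N must lie")
})

test_that("scores are invariant to IC sign flips and positive rescaling", {
  iv <- make_intervals()
  fs <- 1000
  x <- synth_heartbeat(40, fs, seed = 3)$series + 0.05 * rnorm(40000)
  max_lag <- round((iv$tau2 + 0.15) * fs)
  base <- ipr(autocorrelation(x, max_lag), iv, fs)
  expect_equal(ipr(autocorrelation(-x, max_lag), iv, fs), base,
               tolerance = 1e-12)
  expect_equal(ipr(autocorrelation(3.7 * x, max_lag), iv, fs), base,
               tolerance = 1e-10)
  y <- synth_bwn(40, fs, c(0, 100), seed = 4)
  cc1 <- cfe(cross_correlation(x, y, 300), 0.3, fs)
  cc2 <- cfe(cross_correlation(x, 5 * y, 300), 0.3, fs)
  expect_equal(cc1, cc2, tolerance = 1e-12)
})

test_that("fragments of the same cardiac cycle score high CFE", {
  # split one heartbeat source into a QRS-only and a P/T-only stream: the
  # premise of template matching is that such fragments stay aligned
  fs <- 1000
  hb <- synth_heartbeat(60, fs, seed = 6)
  x <- hb$series
  qrs <- numeric(length(x)); rest <- numeric(length(x))
  for (r in hb$r_truth) {
    i <- max(1, r - 60):min(length(x), r + 60)
    qrs[i] <- x[i]
  }
  rest <- x - qrs
  cc <- cross_correlation(qrs, rest, 350)
  expect_gt(cfe(cc, 0.33, fs), 0.5)
})

test_that("end-to-end scoring flags the cardiac template and excludes noise", {
  res <- test_run("pli", 7, seed = 1)
  sc <- test_scene("pli", 7, seed = 1)
  idc <- identify_scene_components(res$ica, sc)
  expect_false(res$scores$keep_mask[idc$interference_ic])
  expect_true(res$scores$keep_mask[idc$heartbeat_ic])
  expect_equal(res$scores$table$cfe[res$scores$template_index], 1)
  expect_identical(sum(res$scores$keep_mask), res$n_retained)
  tab <- res$scores$table
  fin <- is.finite(tab$ipr)
  expect_identical(which.max(replace(tab$ipr, !fin, -Inf)),
                   res$scores$template_index)
})
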