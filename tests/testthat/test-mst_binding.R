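cfg <- mst_config()

test_that("normalize_trace sets the cold-window mean to 1", {
  tm <- seq(0, 40, by = 0.05)
  tr <- mst_trace(1e-6, tm, rep(400, length(tm)), cfg)
  n <- normalize_trace(tr)
  expect_true(all(n$fluorescence == 1))

  f <- ifelse(tm < 5, 400, 380)
  n2 <- normalize_trace(mst_trace(1e-6, tm, f, cfg))
  expect_equal(n2$fluorescence[tm >= 5][1], 0.95)

  # generator round trip: cold mean exactly 1 after normalization
  s <- gen_mst_series(1e-6, seed = 3)
  n3 <- normalize_trace(s$traces[[1]])
  expect_equal(mean(n3$fluorescence[n3$time_s < 5]), 1, tolerance = 1e-12)

  expect_error(normalize_trace(mst_trace(1e-6, tm, -f, cfg)),
               "non-positive")
})

test_that("readout extraction matches the closed-form trace model", {
  tm <- seq(0, 40, by = 0.05)
  fb <- 0.37
  tr <- mst_trace(1e-6, tm, mst_trace_model(tm, fb, cfg), cfg,
                  normalized = TRUE)
  expect_equal(extract_readout(tr, "tjump"),
               mst_trace_model(5 + 1.25, fb, cfg))
  expect_equal(extract_readout(tr, "backdiffusion"),
               mst_trace_model(5 + 30 + 2.5, fb, cfg))
  w <- tm[tm >= 34 & tm < 35]
  expect_equal(extract_readout(tr, "thermophoresis"),
               mean(mst_trace_model(w, fb, cfg)))

  # flat normalized trace: all readouts 1
  flat <- mst_trace(1e-6, tm, rep(1, length(tm)), cfg, normalized = TRUE)
  for (ro in c("tjump", "thermophoresis", "backdiffusion"))
    expect_equal(extract_readout(flat, ro), 1)

  # unnormalized trace refused; time out of range fails
  expect_error(extract_readout(mst_trace(1e-6, tm, rep(400, length(tm)), cfg)),
               "normalized")
})

test_that("readout extraction is stable under subsampling to 10 Hz", {
  s <- gen_mst_series(1e-6, seed = 11)
  tr <- normalize_trace(s$traces[[4]])
  sub <- tr
  keep <- seq(1, length(tr$time_s), by = 2)  # 20 Hz -> 10 Hz
  sub$time_s <- tr$time_s[keep]
  sub$fluorescence <- tr$fluorescence[keep]
  for (ro in c("tjump", "thermophoresis", "backdiffusion"))
    expect_lt(abs(extract_readout(tr, ro) - extract_readout(sub, ro)),
              3 * 0.002)
})

test_that("fraction_bound: limits, depletion quadratic, monotonicity", {
  expect_equal(fraction_bound(0, 5e-9, 1e-6), 0)
  # half saturation at L = kd when T << kd
  expect_equal(fraction_bound(1e-6, 1e-12, 1e-6), 0.5, tolerance = 1e-6)
  # T = 0 uses the limit form
  expect_equal(fraction_bound(2e-6, 0, 1e-6), 2 / 3)

  # independent oracle: numeric root of free-ligand mass balance
  T_c <- 10e-9; L <- 1e-6; kd <- 1e-6
  root <- uniroot(function(cplx)
    (T_c - cplx) * (L - cplx) - kd * cplx,
    c(0, min(T_c, L)), tol = 1e-18)$root
  expect_equal(fraction_bound(L, T_c, kd), root / T_c, tolerance = 1e-9)

  # monotone non-decreasing in L, non-increasing in kd, bounded
  L_grid <- 10^seq(-9, -4, length.out = 40)
  fb <- fraction_bound(L_grid, 5e-9, 1e-6)
  expect_true(all(diff(fb) >= 0))
  expect_true(all(fb >= 0 & fb <= 1))
  kds <- 10^seq(-8, -4, length.out = 20)
  fbk <- vapply(kds, function(k) fraction_bound(1e-6, 5e-9, k), numeric(1))
  expect_true(all(diff(fbk) <= 0))

  # agrees with the non-depleting hyperbola when T <= kd/100 (deviation
  # measured on the fraction-bound scale; the relative deviation approaches
  # T/kd at low saturation)
  hyp <- L_grid / (L_grid + 1e-6)
  expect_true(all(abs(fraction_bound(L_grid, 1e-8, 1e-6) - hyp) < 0.005))
})

test_that("noiseless isotherm round-trips Kd to 1e-6 relative", {
  for (kd in c(0.21e-6, 1e-6, 15.5e-6)) {
    s <- gen_mst_series(kd, noise_sd = 0, seed = 1)
    for (ro in c("tjump", "thermophoresis")) {
      f <- fit_isotherm(s, ro)
      expect_equal(f$flag, "ok")
      expect_lt(abs(f$kd_M - kd) / kd, 1e-6)
    }
  }
})

test_that("fit agrees with an exhaustive log-grid minimizer", {
  s <- gen_mst_series(2e-6, seed = 7)
  f <- fit_isotherm(s, "tjump")
  # independent oracle: profile RSS over a dense kd grid, plateaus by
  # linear least squares at each grid point
  traces <- lapply(s$traces, normalize_trace)
  L <- vapply(traces, `[[`, numeric(1), "ligand_conc_M")
  y <- vapply(traces, extract_readout, numeric(1), readout = "tjump")
  grid <- 10^seq(-9, -3, length.out = 2000)
  rss <- vapply(grid, function(kd) {
    fb <- fraction_bound(L, s$labeled_conc_M, kd)
    sum(lm.fit(cbind(1, fb), y)$residuals^2)
  }, numeric(1))
  kd_grid <- grid[which.min(rss)]
  step <- grid[2] / grid[1]
  expect_lt(abs(log(f$kd_M / kd_grid)), 2 * log(step))
})

test_that("fitted Kd is invariant to affine rescaling of the readout axis", {
  s <- gen_mst_series(1e-6, seed = 5)
  f0 <- fit_isotherm(s, "thermophoresis")
  s2 <- s
  s2$traces <- lapply(s$traces, function(tr) {
    tr <- normalize_trace(tr)
    tr$fluorescence <- 3.7 * tr$fluorescence - 1.2
    tr$normalized <- TRUE   # already on an affine-normalized scale
    tr
  })
  f2 <- fit_isotherm(s2, "thermophoresis")
  expect_equal(f2$kd_M, f0$kd_M, tolerance = 1e-5)
  expect_equal(f2$amplitude, 3.7 * f0$amplitude, tolerance = 1e-4)
})

test_that("parameter recovery within 25% at 1% noise across the Kd range", {
  # thermophoresis readout (the canonical MST signal; averaged over the
  # last second, so per-sample noise is suppressed); the series is
  # titrated to ~90% saturation as in practice
  for (kd in c(0.1e-6, 1e-6, 30e-6)) {
    fits <- vapply(1:20, function(sd) {
      s <- gen_mst_series(kd, noise_sd = 0.01, seed = sd,
                          top_conc_M = max(40e-6, 10 * kd))
      fit_isotherm(s, "thermophoresis", check_irregular = FALSE)$kd_M
    }, numeric(1))
    expect_lt(abs(median(fits, na.rm = TRUE) - kd) / kd, 0.25)
  }
})

test_that("no_binding flag fires on zero-amplitude series", {
  hits <- vapply(1:20, function(sd) {
    s <- gen_mst_series(1e-6, flat = TRUE, seed = sd)
    fit_isotherm(s, "tjump")$flag == "no_binding"
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("aggregation mode trips the irregularity screen; clean does not", {
  s <- gen_mst_series(0.5e-6, aggregation_mode = TRUE, seed = 2)
  d <- detect_irregularity(s)
  expect_true(d$irregular)
  expect_gt(d$roughness_ratio, 5)

  clean <- gen_mst_series(0.5e-6, seed = 2)
  expect_false(detect_irregularity(clean)$irregular)

  # thermophoresis n.d. while the T-jump still fits
  f_th <- fit_isotherm(s, "thermophoresis")
  expect_equal(f_th$flag, "irregular")
  expect_true(is.na(f_th$kd_M))
  f_tj <- fit_isotherm(s, "tjump")
  expect_equal(f_tj$flag, "ok")
  expect_false(is.na(f_tj$kd_M))
})

test_that("classify_binding labels non-binders and builds the Kd table", {
  flat_fits <- lapply(c("tjump", "thermophoresis", "backdiffusion"),
    function(ro) fit_isotherm(gen_mst_series(1e-6, flat = TRUE, seed = 4,
                                             rna_id = "FLAT"), ro))
  cls <- classify_binding(flat_fits)
  expect_false(cls$binder)
  expect_equal(cls$table$kd_tjump_uM, "n.d.")

  s <- gen_mst_series(0.87e-6, seed = 4, rna_id = "BINDER")
  fits <- list(fit_isotherm(s, "tjump"))
  expect_true(classify_binding(fits)$binder)
  tab <- kd_table(list(flat_fits, fits))
  expect_equal(dim(tab), c(2L, 4L))
  expect_true(is.na(tab$kd_thermophoresis_uM[2]))
})
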