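# Localizer GLM, ROI selection, HDR averaging, nonlinear HRF fitting.

test_that("localizer finds the active region and collapses under onset permutation", {
  ev <- make_hrf_design(seed = 1)          # full 30-trial protocol
  act <- default_active_mask(small_grid)
  b <- gaussian_smooth(
    simulate_bold(ev, active_mask = act, betas = c(red = 1.2, green = 1.2),
                  grid = small_grid, seed = 2), 0.8)
  z <- localizer_glm(b, ev)
  expect_gte(mean(z[act] > 3.1), 0.9)       # sensitivity on generator truth
  # misaligned onsets destroy the separation
  ev2 <- ev
  ev2$onset <- (ev$onset + 13) %% max(ev$onset)
  ev2 <- ev2[order(ev2$onset), ]
  z2 <- localizer_glm(b, ev2)
  expect_lt(mean(z2[act] > 3.1), 0.5)
  expect_lt(median(z2[act]), median(z[act]) / 2)
  expect_error(localizer_glm(b, transform(ev, trial_type = "blue")),
               "red/green")
})

test_that("suprathreshold rate under the null matches the nominal tail", {
  ev <- small_hrf_events(n_trials = 6, seed = 3)
  hits <- sapply(1:20, function(s) {
    b <- simulate_bold(ev, active_mask = default_active_mask(small_grid),
                       betas = c(red = 0, green = 0),
                       noise = noise_spec(ar1_coefficient = 0,
                                          drift_amplitude = 0),
                       grid = small_grid, seed = 400 + s)
    z <- localizer_glm(b, ev)
    c(n = length(z), k = sum(z > 3.1))
  })
  rate <- sum(hits["k", ]) / sum(hits["n", ])
  # one-sided 0.001 tail, Monte-Carlo slack (2560 voxel draws)
  expect_lt(rate, 0.004)
})

test_that("ROI selection thresholds the z map and errors when empty", {
  z <- array(c(-2, 0, 2, 4), dim = c(2, 2, 1))
  m <- select_roi(z, 3)
  expect_equal(sum(m), 1)
  expect_equal(sum(select_roi(z, -Inf)), 4)
  expect_error(select_roi(z, 10), "no activated voxels")
  ev <- make_hrf_design(seed = 1)
  act <- default_active_mask(small_grid)
  b <- gaussian_smooth(
    simulate_bold(ev, active_mask = act, betas = c(red = 1.2, green = 1.2),
                  grid = small_grid, seed = 2), 0.8)
  roi <- select_roi(localizer_glm(b, ev), 3.1)
  jacc <- sum(roi & act) / sum(roi | act)
  expect_gte(jacc, 0.5)
})

test_that("noiseless forward model round-trips through HDR extraction", {
  ev <- small_hrf_events(n_trials = 8, seed = 5)
  act <- default_active_mask(small_grid)
  b <- simulate_bold(ev, active_mask = act, betas = c(red = 1, green = 1),
                     noise = tiny_noise(), grid = small_grid, seed = 6)
  hdr <- extract_average_hdr(list(b), list(ev), act, epoch = 28)
  model <- hrf_response(canonical_hrf("pigeon"), 2, dt = 0.01)
  pred <- approx(curve_times(model), model$values, curve_times(hdr))$y
  expect_gt(cor(hdr$values, pred), 0.999)
  # two identical runs: same mean, zero SEM
  hdr2 <- extract_average_hdr(list(b, b), list(ev, ev), act, epoch = 28)
  expect_equal(hdr2$values, hdr$values, tolerance = 1e-12)
  expect_true(all(hdr2$sem == 0))
  expect_error(extract_average_hdr(list(b), list(ev), array(FALSE, small_grid)),
               "empty")
})

test_that("averaged percent-signal peak sits in the calibrated 0.8-1.5% window", {
  ev <- small_hrf_events(n_trials = 8, seed = 7)
  act <- default_active_mask(small_grid)
  b <- simulate_bold(ev, active_mask = act, betas = c(red = 1.2, green = 1.2),
                     noise = tiny_noise(), grid = small_grid, seed = 8)
  hdr <- extract_average_hdr(list(b), list(ev), act, epoch = 28)
  pk <- max(hdr$values)
  expect_gte(pk, 0.8)
  expect_lte(pk, 1.5)
})

test_that("fitting a noiseless pigeon curve recovers the generating parameters", {
  truep <- canonical_hrf("pigeon")
  tt <- seq(0, 30, by = 0.5)
  y <- avihrf:::hrf_model_at(c(A = 1, alpha1 = truep$alpha1,
                               alpha2 = truep$alpha2, beta1 = truep$beta1,
                               beta2 = truep$beta2, c = truep$c),
                             tt, 2)
  fit <- fit_hrf(sampled_curve(y, dt = 0.5, t0 = 0), seed = 1)
  est <- unlist(fit$params)
  expect_equal(est[["alpha1"]], 7.71, tolerance = 1e-3)
  expect_equal(est[["alpha2"]], 11.48, tolerance = 1e-2)
  expect_equal(est[["beta1"]], 1.74, tolerance = 1e-3)
  expect_equal(est[["beta2"]], 0.74, tolerance = 1e-3)
  expect_equal(est[["c"]], 0.25, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  # CIs bracket the estimates
  expect_true(all(fit$ci95[, 1] <= est[rownames(fit$ci95)] + 1e-9))
  expect_true(all(fit$ci95[, 2] >= est[rownames(fit$ci95)] - 1e-9))
})

test_that("bounds excluding the truth pin the fit at a bound and flag it", {
  truep <- canonical_hrf("pigeon")
  tt <- seq(0, 30, by = 0.5)
  y <- avihrf:::hrf_model_at(c(A = 1, alpha1 = truep$alpha1,
                               alpha2 = truep$alpha2, beta1 = truep$beta1,
                               beta2 = truep$beta2, c = truep$c),
                             tt, 2)
  bb <- hrf_fit_bounds()
  bb$upper[["alpha1"]] <- 5     # truth 7.71 excluded
  fit <- fit_hrf(sampled_curve(y, dt = 0.5), bounds = bb,
                 init = hrf_params(4, 16, 1, 1, 1 / 6), seed = 2)
  expect_equal(unlist(fit$params)[["alpha1"]], 5, tolerance = 1e-6)
  expect_true(fit$at_bound[["alpha1"]])
})

test_that("multi-start RSS is non-increasing in the number of starts", {
  truep <- canonical_hrf("pigeon")
  tt <- seq(0, 30, by = 2)
  set.seed(11)
  y <- avihrf:::hrf_model_at(c(A = 1, alpha1 = truep$alpha1,
                               alpha2 = truep$alpha2, beta1 = truep$beta1,
                               beta2 = truep$beta2, c = truep$c), tt, 2) +
    rnorm(length(tt), sd = 0.03)
  cv <- sampled_curve(y, dt = 2)
  r1 <- fit_hrf(cv, n_starts = 1, seed = 5)$rss
  r5 <- fit_hrf(cv, n_starts = 5, seed = 5)$rss
  r10 <- fit_hrf(cv, n_starts = 10, seed = 5)$rss
  expect_lte(r5, r1 + 1e-12)
  expect_lte(r10, r5 + 1e-12)
})

test_that("fitted pigeon-data features reproduce the in-vivo peak-time window", {
  truep <- canonical_hrf("pigeon")
  tt <- seq(0, 30, by = 2)
  set.seed(21)
  y <- avihrf:::hrf_model_at(c(A = 1, alpha1 = truep$alpha1,
                               alpha2 = truep$alpha2, beta1 = truep$beta1,
                               beta2 = truep$beta2, c = truep$c), tt, 2) +
    rnorm(length(tt), sd = 0.025)
  fit <- fit_hrf(sampled_curve(y, dt = 2), seed = 3)
  f <- hdr_features(hrf_response(fit$params, 2))
  expect_gte(f$T, 4.0)
  expect_lte(f$T, 6.0)
})
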