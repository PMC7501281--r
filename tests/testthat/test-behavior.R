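# Mandibulation detection, trial classification, SDT statistics.

test_that("detector finds known bursts precisely and cancels common-mode artifacts", {
  set.seed(31)
  fs <- 1000
  n <- fs * 60
  sig <- rnorm(n, sd = 0.02)
  ref <- rnorm(n, sd = 0.02)
  bt <- seq(2, 56, by = 6)            # 10 well-separated bursts
  burst <- avihrf:::mandib_burst(fs)
  for (b in bt) {
    i0 <- floor(b * fs) + 1L
    idx <- i0:(i0 + length(burst) - 1L)
    sig[idx] <- sig[idx] + burst
  }
  det <- detect_mandibulations(piezo_trace(sig, ref, fs))
  expect_equal(length(det), 10)
  expect_lt(max(abs(det - bt)), 0.02)
  # identical artifact on both channels: the differential cancels it
  art <- avihrf:::mandib_burst(fs, freq = 35, dur = 0.08, amplitude = 5)
  s2 <- r2 <- rnorm(n, sd = 0.02)
  for (b in bt) {
    i0 <- floor(b * fs) + 1L
    idx <- i0:(i0 + length(art) - 1L)
    s2[idx] <- s2[idx] + art
    r2[idx] <- r2[idx] + art
  }
  expect_equal(length(detect_mandibulations(piezo_trace(s2, r2, fs))), 0)
  expect_error(detect_mandibulations(piezo_trace(sig, ref, 40)), ">= 50")
})

test_that("noise floor stays under one false event per minute", {
  fp <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 250 * 120
    tr <- piezo_trace(rnorm(n, sd = 0.03), rnorm(n, sd = 0.03), fs = 250)
    length(detect_mandibulations(tr)) / 2
  })
  expect_lt(mean(fp), 1)
})

test_that("trial classification implements the Hit/Miss/CR/FA taxonomy", {
  ev <- make_discrimination_design(small_task_spec(4, rest = 40), seed = 1)
  go <- ev$onset[ev$trial_type == "splus"]
  nogo <- ev$onset[ev$trial_type == "sminus"]
  mand <- c(go[1] + 0.3, nogo[1] + 0.5, nogo[2] + 2.5)  # last one post-window
  oc <- classify_trials(ev, mand)
  expect_equal(oc$label[ev$onset == go[1]], "Hit")
  expect_equal(oc$rt_s[ev$onset == go[1]], 0.3)
  expect_equal(oc$label[ev$onset == nogo[1]], "FA")
  expect_equal(oc$label[ev$onset == nogo[2]], "CR")   # event after window
  expect_true(all(oc$label[ev$trial_type == "splus"][-1] == "Miss"))
  # exact partition
  expect_equal(sum(oc$label %in% c("Hit", "Miss")), sum(ev$trial_type == "splus"))
  expect_equal(sum(oc$label %in% c("CR", "FA")), sum(ev$trial_type == "sminus"))
  expect_true(all(na.omit(oc$rt_s) >= 0 & na.omit(oc$rt_s) <= 2))
})

test_that("d-prime follows the inverse-normal definition with log-linear correction", {
  # chance performance
  oc <- data.frame(label = c(rep("Hit", 5), rep("Miss", 5),
                             rep("FA", 5), rep("CR", 5)))
  s <- sdt_summary(oc, correction = "none")
  expect_equal(s$d_prime, 0)
  # hit 0.84 / fa 0.16: d' = 2 qnorm(0.84) (frozen from the inverse normal)
  oc2 <- data.frame(label = c(rep("Hit", 84), rep("Miss", 16),
                              rep("FA", 16), rep("CR", 84)))
  s2 <- sdt_summary(oc2, correction = "none")
  expect_equal(s2$d_prime, 2 * qnorm(0.84), tolerance = 1e-12)
  expect_equal(s2$d_prime, 1.989, tolerance = 1e-3)
  # perfect hit rate with 72 trials stays finite under the correction
  oc3 <- data.frame(label = c(rep("Hit", 72), rep("FA", 10), rep("CR", 62)))
  s3 <- sdt_summary(oc3)
  expect_true(is.finite(s3$d_prime))
  expect_equal(s3$d_prime,
               qnorm(72.5 / 73) - qnorm(10.5 / 73), tolerance = 1e-12)
  expect_error(sdt_summary(data.frame(label = rep("Hit", 3))), "at least one")
})

test_that("d-prime is antisymmetric under swapping hit and FA rates", {
  mk <- function(h, f) data.frame(label = c(rep("Hit", h), rep("Miss", 100 - h),
                                            rep("FA", f), rep("CR", 100 - f)))
  a <- sdt_summary(mk(80, 20))$d_prime
  b <- sdt_summary(mk(20, 80))$d_prime
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("ROC points sit above the diagonal for competent synthetic cohorts", {
  pts <- lapply(1:8, function(s) {
    ev <- make_discrimination_design(small_task_spec(), seed = s)
    pz <- simulate_piezo(ev, behavior_spec(), sampling_rate = 100,
                         seed = 50 + s)
    oc <- classify_trials(ev, detect_mandibulations(pz))
    roc_point(sdt_summary(oc))
  })
  expect_true(all(vapply(pts, `[[`, logical(1), "above_diagonal")))
  # chance performance sits on the diagonal
  oc <- data.frame(label = c(rep("Hit", 5), rep("Miss", 5),
                             rep("FA", 5), rep("CR", 5)))
  p0 <- roc_point(sdt_summary(oc))
  expect_equal(p0$hit, p0$fa)
})

test_that("peristimulus histogram conserves event mass and peaks at the Go latency", {
  ev <- make_discrimination_design(small_task_spec(), seed = 60)
  h0 <- peristimulus_histogram(ev, numeric(0))
  expect_true(all(h0$splus == 0) && all(h0$sminus == 0))
  # mass conservation inside the window
  go <- ev$onset[ev$trial_type == "splus"][1:5]
  mand <- go + 0.9
  h <- peristimulus_histogram(ev, mand, bin = 0.2, window = c(-2, 10))
  expect_equal(sum(h$splus), 5)
  # latency structure: pooled hits concentrate near 0.9 s
  lat <- unlist(lapply(1:6, function(s) {
    evs <- make_discrimination_design(small_task_spec(), seed = 70 + s)
    pz <- simulate_piezo(evs, behavior_spec(hit_rate = 1, fa_rate = 0,
                                            spontaneous_rate = 0,
                                            reward_burst_rate = 0),
                         sampling_rate = 100, seed = 80 + s)
    tm <- attr(pz, "truth")$mandib_times
    hh <- peristimulus_histogram(evs, tm, bin = 0.3, window = c(0, 2))
    hh$bin_start[which.max(hh$splus)]
  }))
  expect_lt(abs(mean(lat) + 0.15 - 0.9), 0.3)
})

test_that("simulate-detect-classify round trip recovers true labels almost surely", {
  ag <- sapply(1:5, function(s) {
    ev <- make_discrimination_design(small_task_spec(), seed = s)
    pz <- simulate_piezo(ev, behavior_spec(), sampling_rate = 250,
                         seed = 90 + s)
    oc <- classify_trials(ev, detect_mandibulations(pz))
    mean(oc$label == attr(pz, "truth")$label)
  })
  expect_gte(mean(ag), 0.99)
})
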