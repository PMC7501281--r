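# Design matrix construction, OLS fitting, contrasts, cluster inference.

mk_outcome_labels <- function(ev, seed = 1) {
  set.seed(seed)
  ifelse(ev$trial_type == "splus",
         ifelse(runif(nrow(ev)) < 0.9, "Hit", "Miss"),
         ifelse(runif(nrow(ev)) < 0.1, "FA", "CR"))
}

test_that("design matrix carries 7 task + 6 motion + intercept columns", {
  ev <- make_discrimination_design(small_task_spec(), seed = 1)
  lab <- mk_outcome_labels(ev)
  # ensure all four outcomes present
  lab[ev$trial_type == "splus"][1:2] <- c("Hit", "Miss")
  lab[ev$trial_type == "sminus"][1:2] <- c("CR", "FA")
  mt <- simulate_motion(attr(ev, "n_volumes"), seed = 2)
  X <- build_design_matrix(ev, lab, mandib_times = c(10, 30, 50), motion = mt)
  expect_equal(ncol(X), 7 + 6 + 1)
  expect_equal(attr(X, "task_columns"),
               c("Hit", "Miss", "CR", "FA", "reward", "post_reward",
                 "mandib_rest"))
  # nuisance columns demeaned
  expect_equal(unname(colMeans(X[, 8:13])), rep(0, 6), tolerance = 1e-12)
  expect_error(build_design_matrix(ev, lab[-1]), "match")
})

test_that("absent event types drop their columns with a warning, design stays full rank", {
  ev <- make_discrimination_design(small_task_spec(), seed = 3)
  lab <- ifelse(ev$trial_type == "splus", "Hit", "CR")   # no Miss/FA
  expect_warning(X <- build_design_matrix(ev, lab), "Miss, FA")
  expect_false(any(c("Miss", "FA") %in% colnames(X)))
  expect_equal(qr(X)$rank, ncol(X))
})

test_that("an isolated event's regressor matches the boxcar-convolution oracle", {
  ev <- make_discrimination_design(small_task_spec(), seed = 4)
  p <- canonical_hrf("pigeon")
  tr <- attr(ev, "tr")
  n_vol <- attr(ev, "n_volumes")
  on1 <- ev$onset[1]
  reg <- avihrf:::hrf_regressor(on1, 2, p, tr, n_vol)
  # oracle: exact gamma-CDF convolution of a 2 s boxcar, shifted to onset
  tvol <- (seq_len(n_vol) - 1) * tr
  oracle <- avihrf:::hrf_model_at(c(A = 1, alpha1 = p$alpha1,
                                    alpha2 = p$alpha2, beta1 = p$beta1,
                                    beta2 = p$beta2, c = p$c),
                                  tvol - on1, 2)
  # the regressor grid is dt = 0.1 s, so agreement is up to O(dt) error
  expect_gt(cor(reg, oracle), 0.999)
  expect_lt(max(abs(reg - oracle)), 0.03 * max(oracle))
})

test_that("OLS betas are exact on noiseless data and match the normal-equations oracle", {
  set.seed(5)
  n <- 60
  X <- cbind(hrf = rnorm(n), drift = seq_len(n) / n, intercept = 1)
  truth <- c(2, -1, 100)
  nvox <- 5
  Y <- sapply(seq_len(nvox), function(i) X %*% truth + rnorm(n, sd = i - 1))
  arr <- array(t(Y), dim = c(nvox, 1, 1, n))
  fit <- fit_glm(bold_series(arr, tr = 1, voxel_size = c(1, 1, 1)), X)
  # noiseless voxel: exact interpolation
  expect_equal(unname(fit$beta[, 1]), truth, tolerance = 1e-8)
  # all voxels: brute-force (X'X)^{-1} X'y
  oracle <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-8)
  # residuals orthogonal to the design
  res <- Y - X %*% fit$beta
  expect_lt(max(abs(t(X) %*% res)), 1e-6)
  expect_equal(fit$dof, n - 3)
  expect_error(fit_glm(bold_series(arr, tr = 1), cbind(X, X[, 1])),
               "rank deficient")
})

test_that("contrast z maps behave at the null and zero contrasts give zero", {
  set.seed(6)
  n <- 200
  nvox <- 500
  X <- cbind(a = rnorm(n), intercept = 1)
  Y <- matrix(rnorm(n * nvox, 100), n, nvox)
  arr <- array(t(Y), dim = c(nvox, 1, 1, n))
  fit <- fit_glm(bold_series(arr, tr = 1), X)
  z0 <- contrast_z(fit, c(0, 0))
  expect_true(all(z0 == 0))
  z <- contrast_z(fit, c(1, 0))
  # null calibration: P(z > 3.1) ~ 0.001
  expect_lt(mean(z > 3.1), 0.006)
  # z should be standard normal: sd near 1
  expect_equal(sd(z), 1, tolerance = 0.12)
  expect_error(contrast_z(fit, c(1, 0, 0)), "length")
})

test_that("named contrast presets weigh the published comparisons", {
  cols <- c("Hit", "Miss", "CR", "FA", "reward", "post_reward",
            "mandib_rest", "intercept")
  w <- contrast_preset("go_gt_nogo_plus_mandibulation", cols)
  expect_equal(sum(w), 0)
  expect_equal(unname(w[c("Hit", "Miss")]), c(0.5, 0.5))
  expect_equal(unname(w[c("CR", "FA", "mandib_rest")]), rep(-1 / 3, 3))
  w2 <- contrast_preset("nogo_gt_go", cols)
  expect_equal(unname(w2[c("CR", "FA", "Hit", "Miss")]),
               c(0.5, 0.5, -0.5, -0.5))
  w3 <- contrast_preset("mandibulation_gt_rest", cols)
  expect_equal(unname(w3[["mandib_rest"]]), 1)
  expect_error(contrast_preset("nogo_gt_go", cols[-1]), "absent")
})

test_that("contrast z maps are invariant to grand-mean scaling of the series", {
  ev <- small_hrf_events(n_trials = 6, seed = 7)
  b <- simulate_bold(ev, active_mask = default_active_mask(small_grid),
                     betas = c(red = 1, green = 1), grid = small_grid,
                     seed = 8)
  p <- canonical_hrf("pigeon")
  n_vol <- attr(ev, "n_volumes")
  X <- cbind(red = avihrf:::hrf_regressor(ev$onset[ev$trial_type == "red"],
                                          2, p, b$tr, n_vol),
             intercept = 1)
  z1 <- contrast_z(fit_glm(b, X), c(1, 0))
  z2 <- contrast_z(fit_glm(grand_mean_scale(b), X), c(1, 0))
  expect_equal(as.vector(z1), as.vector(z2), tolerance = 1e-8)
})

test_that("cluster labelling uses face connectivity and sizes sum to the mask", {
  m <- array(FALSE, dim = c(4, 4, 2))
  m[1:2, 1, 1] <- TRUE          # one face-connected pair
  m[4, 4, 2] <- TRUE            # an isolated voxel
  m[4, 4, 1] <- TRUE            # face-connected to it through z
  lab <- avihrf:::label_clusters(m)
  expect_equal(max(lab), 2)
  expect_equal(sort(tabulate(lab[lab > 0])), c(2, 2))
  # diagonal neighbours are NOT connected
  m2 <- array(FALSE, dim = c(3, 3, 1))
  m2[1, 1, 1] <- m2[2, 2, 1] <- TRUE
  expect_equal(max(avihrf:::label_clusters(m2)), 2)
})

test_that("cluster thresholding keeps true blobs, rejects spikes, handles empty maps", {
  dims <- c(10, 10, 3)
  set.seed(9)
  null_fun <- function(i) smooth_noise_map(dims)
  z <- smooth_noise_map(dims)
  z[3:6, 3:6, 2] <- 6           # a real 16-voxel blob
  z[9, 9, 1] <- 6               # an isolated spike
  res <- cluster_threshold(z, z_min = 3.1, alpha = 0.05,
                           null_fun = null_fun, n_permutations = 300,
                           seed = 10)
  expect_gte(nrow(res$clusters), 1)
  expect_true(any(res$clusters$size >= 16))
  expect_false(any(res$clusters$size == 1))   # spike rejected
  # all-subthreshold map: empty result, not an error
  res0 <- cluster_threshold(array(0, dims), z_min = 3.1,
                            null_fun = null_fun, n_permutations = 100,
                            seed = 11)
  expect_equal(nrow(res0$clusters), 0)
})

test_that("permutation critical extent is monotone non-increasing in alpha", {
  dims <- c(10, 10, 3)
  set.seed(12)
  null_fun <- function(i) smooth_noise_map(dims)
  z <- array(0, dims)
  crits <- sapply(c(0.01, 0.05, 0.2), function(a)
    cluster_threshold(z, alpha = a, null_fun = null_fun,
                      n_permutations = 200, seed = 13)$critical_extent)
  expect_true(all(diff(crits) <= 0))
})

test_that("group inference detects a common effect with identical maps flagged", {
  dims <- c(8, 8, 2)
  base <- array(0, dims)
  base[3:5, 3:5, 1] <- 1
  set.seed(14)
  maps <- lapply(1:8, function(i) base + array(rnorm(prod(dims), sd = 0.2),
                                               dims))
  res <- group_level(maps, n_permutations = 300, seed = 15)
  cm <- cluster_mask(res)
  expect_gte(sum(cm & (base > 0)) / sum(base > 0), 0.5)
  # identical maps: zero between-subject variance flagged, z capped
  same <- lapply(1:4, function(i) base)
  res2 <- group_level(same, n_permutations = 100, seed = 16)
  expect_true(any(attr(res2, "zero_variance")))
  expect_lte(max(res2$zmap), 38)
  expect_error(group_level(maps[1:2]), "at least 3")
})

test_that("a column orthogonal to data and contrast leaves the effect unchanged", {
  set.seed(17)
  n <- 100
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  X1 <- cbind(x = x, intercept = 1)
  # build a column orthogonal to y and to the contrast's span
  q <- qr.Q(qr(cbind(X1, y)))
  extra <- rnorm(n)
  extra <- extra - q %*% (t(q) %*% extra)
  X2 <- cbind(X1, extra = extra)
  arr <- array(rep(y, each = 1), dim = c(1, 1, 1, n))
  f1 <- fit_glm(bold_series(arr, tr = 1), X1)
  f2 <- fit_glm(bold_series(arr, tr = 1), X2)
  e1 <- drop(c(1, 0) %*% f1$beta)
  e2 <- drop(c(1, 0, 0) %*% f2$beta)
  expect_equal(e1, e2, tolerance = 1e-10)
})
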