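truth_params <- function() make_params(f_iso_max = 1200, alpha_opt_deg = 12, l_opt_mt = 0.32)

test_that("loss and gradient vanish at the generating parameters", {
  p <- truth_params()
  obs <- synth_force_observations(p, n = 25, noise_cv = 0, seed = 3)
  lg <- loss_and_gradient(p, obs, free = c("l_opt_f", "l_opt_mt"))
  expect_equal(lg$loss, 0, tolerance = 1e-20)
  expect_equal(unname(lg$gradient), c(0, 0), tolerance = 1e-12)
  expect_equal(lg$n_used, 25)
})

test_that("analytic loss gradient matches finite differences of the loss", {
  p <- truth_params()
  obs <- synth_force_observations(p, n = 30, noise_cv = 0.05, seed = 11)
  init <- make_params(
    f_iso_max = 1100, alpha_opt_deg = 15, l_opt_mt = 0.33, l_opt_f = 0.055
  )
  free <- c("f_iso_max", "l_opt_f", "alpha_opt", "l_opt_mt")
  lg <- loss_and_gradient(init, obs, free = free)
  for (w in free) {
    theta <- mtsens:::param_value(init, w)
    h <- 1e-6 * theta
    up <- loss_and_gradient(
      mtsens:::perturb_params(init, w, theta + h), obs, free
    )$loss
    dn <- loss_and_gradient(
      mtsens:::perturb_params(init, w, theta - h), obs, free
    )$loss
    expect_lt(rel_err(lg$gradient[[w]], (up - dn) / (2 * h)), 1e-4)
  }
})

test_that("doubling weights doubles the loss but not the minimizer", {
  p <- truth_params()
  obs <- synth_force_observations(p, n = 20, noise_cv = 0.03, seed = 5)
  init <- mtsens:::perturb_params(p, "l_opt_mt", p$l_opt_mt * 1.02)
  lg1 <- loss_and_gradient(init, obs, free = "l_opt_mt")
  obs2 <- dplyr::mutate(obs, weight = 2)
  lg2 <- loss_and_gradient(init, obs2, free = "l_opt_mt")
  expect_equal(lg2$loss, 2 * lg1$loss, tolerance = 1e-12)

  fit1 <- calibrate(init, obs, free = "l_opt_mt")
  fit2 <- calibrate(init, obs2, free = "l_opt_mt")
  expect_equal(fit1$params$l_opt_mt, fit2$params$l_opt_mt, tolerance = 1e-6)
})

test_that("calibration at the ground truth converges immediately", {
  p <- truth_params()
  obs <- synth_force_observations(p, n = 20, noise_cv = 0, seed = 2)
  fit <- calibrate(p, obs, free = c("l_opt_f", "l_opt_mt"))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 0)
  expect_equal(fit$loss, 0, tolerance = 1e-18)
})

test_that("noiseless observations recover fiber and tendon-side lengths", {
  p <- truth_params()
  obs <- synth_force_observations(p, l_norm_range = c(0.5, 1.4), n = 50, seed = 9)
  init <- make_params(
    f_iso_max = 1200, alpha_opt_deg = 12,
    l_opt_f = p$l_opt_f * 1.15, l_opt_mt = p$l_opt_mt * 1.03
  )
  fit <- calibrate(init, obs, free = c("l_opt_f", "l_opt_mt"), max_iter = 300)
  expect_lt(abs(fit$params$l_opt_mt / p$l_opt_mt - 1), 0.01)
  expect_lt(abs(fit$params$l_opt_f / p$l_opt_f - 1), 0.05)
  # monotone descent and the optimizer contract
  expect_true(all(diff(fit$trajectory$loss) <= 0))
  expect_lte(fit$loss, fit$trajectory$loss[1])
})

test_that("narrow length spans raise the identifiability flag", {
  p <- truth_params()
  obs <- synth_force_observations(p, l_norm_range = c(0.98, 1.02), n = 15, seed = 4)
  init <- mtsens:::perturb_params(p, "l_opt_f", p$l_opt_f * 1.05)
  fit <- calibrate(init, obs, free = c("l_opt_f", "l_opt_mt"), max_iter = 50)
  expect_true(any(grepl("identifiability", fit$flags)))
})

test_that("passive-only data leave the force capacity unidentifiable below slack", {
  # all observations on the slack side of the passive curve: zero force,
  # zero gradient in every direction that only rescales the active curve
  p <- make_params(alpha_opt_deg = 0)
  l_mt <- mtu_length_at_norm(p, seq(0.6, 0.95, length.out = 10))
  obs <- tibble::tibble(l_mt = l_mt, a = 0, f_obs = 0, weight = 1)
  fit <- calibrate(p, obs, free = "f_iso_max", max_iter = 10)
  expect_equal(fit$loss, 0)
  expect_true(fit$converged)
  # a mismatched capacity cannot be corrected by passive-only data
  init_off <- mtsens:::perturb_params(p, "f_iso_max", p$f_iso_max * 1.5)
  fit2 <- calibrate(init_off, obs, free = "f_iso_max", max_iter = 10)
  expect_equal(fit2$params$f_iso_max, init_off$f_iso_max, tolerance = 1e-9)
})

test_that("infeasible observations are excluded with a warning and errors are informative", {
  p <- make_params(alpha_opt_deg = 0)
  obs <- tibble::tibble(
    l_mt = c(p$l_sla_t - 0.001, mtu_length_at_norm(p, c(0.9, 1.1))),
    a = 1,
    f_obs = c(0, 500, 500),
    weight = 1
  )
  expect_warning(lg <- loss_and_gradient(p, obs, free = "l_opt_mt"), "infeasible")
  expect_equal(lg$n_excluded, 1)
  expect_equal(lg$n_used, 2)
  expect_error(
    loss_and_gradient(p, obs[0, ], free = "l_opt_mt"),
    "empty"
  )
  expect_error(
    loss_and_gradient(p, obs, free = "tendon"),
    "unknown free parameter"
  )
})

test_that("parameter recovery holds in median over seeded replicates", {
  # scaled-down version of the full recovery experiment (the acceptance test
  # runs the complete protocol): 6 noiseless and 6 noisy replicates
  p <- truth_params()
  errs <- purrr::map_dfr(1:6, function(s) {
    obs0 <- synth_force_observations(p, c(0.5, 1.4), n = 50, noise_cv = 0, seed = s)
    obs2 <- synth_force_observations(p, c(0.5, 1.4), n = 50, noise_cv = 0.02, seed = 100 + s)
    set.seed(s)
    init <- make_params(
      f_iso_max = 1200, alpha_opt_deg = 12,
      l_opt_f = p$l_opt_f * runif(1, 0.9, 1.1),
      l_opt_mt = p$l_opt_mt * runif(1, 0.98, 1.02)
    )
    f0 <- calibrate(init, obs0, free = c("l_opt_f", "l_opt_mt"), max_iter = 300)
    f2 <- calibrate(init, obs2, free = c("l_opt_f", "l_opt_mt"), max_iter = 300)
    tibble::tibble(
      e0_mt = abs(f0$params$l_opt_mt / p$l_opt_mt - 1),
      e0_f = abs(f0$params$l_opt_f / p$l_opt_f - 1),
      e2_mt = abs(f2$params$l_opt_mt / p$l_opt_mt - 1),
      e2_f = abs(f2$params$l_opt_f / p$l_opt_f - 1)
    )
  })
  expect_lt(median(errs$e0_mt), 0.01)
  expect_lt(median(errs$e0_f), 0.01)
  expect_lt(median(errs$e2_mt), 0.05)
  expect_lt(median(errs$e2_f), 0.05)
})

test_that("tidy and glance summarize a calibration fit", {
  p <- truth_params()
  obs <- synth_force_observations(p, n = 30, noise_cv = 0.02, seed = 8)
  init <- mtsens:::perturb_params(p, "l_opt_mt", p$l_opt_mt * 1.01)
  fit <- calibrate(init, obs, free = c("l_opt_f", "l_opt_mt"), max_iter = 100)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("l_opt_f", "l_opt_mt"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_lte(gl$loss_final, gl$loss_init)
})
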