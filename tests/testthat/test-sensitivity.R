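# Build a parameter set for one stratified-grid configuration.
config_params <- function(alpha_deg, ratio, sigma_volume = FALSE) {
  l_opt_f <- 0.05
  if (sigma_volume) {
    mt_params(
      l_opt_f = l_opt_f, alpha_opt = alpha_deg * pi / 180,
      l_opt_mt = ratio * l_opt_f, sigma = 61, volume = 250
    )
  } else {
    mt_params(
      f_iso_max = 1000, l_opt_f = l_opt_f, alpha_opt = alpha_deg * pi / 180,
      l_opt_mt = ratio * l_opt_f
    )
  }
}

test_that("every analytic derivative matches the finite-difference oracle on the stratified grid", {
  grid <- grid_configs()
  ids <- c("f_iso_max", "l_opt_f", "l_opt_f_pcsa", "alpha_opt", "l_opt_mt")
  worst <- stats::setNames(numeric(length(ids)), ids)
  n_checked <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- config_params(g$alpha_deg, g$ratio, sigma_volume = TRUE)
    l_mt <- mtu_length_at_norm(p, g$l_norm)
    if (is.na(l_mt) || l_mt <= p$l_sla_t) next # unreachable or folded fiber
    for (w in ids) {
      an <- mtsens:::analytic_gradient(w, p, l_mt, g$a)
      fd <- fd_gradient(p, l_mt, g$a, which = w)
      worst[w] <- max(worst[w], grad_mismatch(an, fd, w, p))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
  for (w in ids) expect_lt(worst[w], 1e-5)
})

test_that("fiber-length derivative vanishes at the optimal position and specializes at zero pennation", {
  p <- make_params(alpha_opt_deg = 25)
  expect_equal(dF_dlopt_fixed_pcsa(p, p$l_opt_mt, a = 1), 0)

  p0 <- make_params(alpha_opt_deg = 0)
  l_mt <- mtu_length_at_norm(p0, 1.2)
  g <- gradient_components(p0, l_mt, a = 1)
  expect_equal(
    dF_dlopt_fixed_pcsa(p0, l_mt, a = 1),
    -p0$f_iso_max * (l_mt - p0$l_opt_mt) * g$E2 / p0$l_opt_f^2,
    tolerance = 1e-12
  )
})

test_that("volume-coupled fiber-length derivative reduces to -F_iso_max/l_opt_f at the peak", {
  p <- make_params_sv(alpha_opt_deg = 0)
  expect_equal(
    dF_dlopt_volume_pcsa(p, p$l_opt_mt, a = 1),
    -p$f_iso_max / p$l_opt_f,
    tolerance = 1e-10
  )
  expect_error(
    dF_dlopt_volume_pcsa(make_params(), 0.4),
    "sigma"
  )
})

test_that("volume-coupled derivative satisfies the product-rule decomposition", {
  p <- make_params_sv(alpha_opt_deg = 20)
  l_mt <- mtu_length_at_norm(p, c(0.6, 0.9, 1.0, 1.25, 1.45))
  for (a in c(0, 0.5, 1)) {
    lhs <- dF_dlopt_volume_pcsa(p, l_mt, a)
    rhs <- -muscle_force(p, l_mt, a) / p$l_opt_f + dF_dlopt_fixed_pcsa(p, l_mt, a)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs), 1), 1e-10)
  }
})

test_that("pennation derivative is exactly zero at zero pennation and negative below optimum", {
  p0 <- make_params(alpha_opt_deg = 0)
  l_mt <- mtu_length_at_norm(p0, c(0.7, 1, 1.3))
  expect_equal(dF_dalpha_opt(p0, l_mt, a = 1), c(0, 0, 0))

  p <- make_params(alpha_opt_deg = 20)
  l_mt_short <- mtu_length_at_norm(p, 0.95)
  expect_lt(dF_dalpha_opt(p, l_mt_short, a = 1), 0)
  expect_lt(
    rel_err(
      dF_dalpha_opt(p, l_mt_short, a = 1),
      fd_gradient(p, l_mt_short, a = 1, which = "alpha_opt")
    ),
    1e-6
  )
})

test_that("tendon-side derivative reduces to the pure curve-shift term at zero pennation", {
  p0 <- make_params(alpha_opt_deg = 0)
  # at the active peak with no passive slope: stationary point, zero derivative
  l_at_opt <- mtu_length_at_norm(p0, 1)
  expect_equal(dF_dlopt_mt(p0, l_at_opt, a = 1), 0, tolerance = 1e-8)
  # ascending limb: E2 > 0, derivative is the negative curve-shift term
  l_short <- mtu_length_at_norm(p0, 0.8)
  g <- gradient_components(p0, l_short, a = 1)
  expect_gt(g$E2, 0)
  expect_equal(
    dF_dlopt_mt(p0, l_short, a = 1),
    -p0$f_iso_max * g$E2 / p0$l_opt_f,
    tolerance = 1e-12
  )
  expect_lt(dF_dlopt_mt(p0, l_short, a = 1), 0)
})

test_that("fd_gradient is exact on effectively quadratic inputs and converges at order 2", {
  # in a regime where the passive curve is inactive and the active curve is
  # locally smooth, halving h shrinks the central-difference error ~4x
  p <- make_params(alpha_opt_deg = 15)
  l_mt <- mtu_length_at_norm(p, 1.25)
  an <- dF_dlopt_mt(p, l_mt, a = 1)
  e1 <- abs(fd_gradient(p, l_mt, 1, which = "l_opt_mt", h = 1e-3 * p$l_opt_mt) - an)
  e2 <- abs(fd_gradient(p, l_mt, 1, which = "l_opt_mt", h = 5e-4 * p$l_opt_mt) - an)
  expect_equal(e1 / e2, 4, tolerance = 0.15)

  # central difference of a force linear in the parameter is exact: F ~ f_iso_max
  lin1 <- fd_gradient(p, l_mt, 1, which = "f_iso_max", h = 1)
  lin2 <- fd_gradient(p, l_mt, 1, which = "f_iso_max", h = 100)
  expect_equal(lin1, lin2, tolerance = 1e-10)
  expect_equal(lin1, muscle_force(p, l_mt, 1) / p$f_iso_max, tolerance = 1e-10)

  expect_error(fd_gradient(p, l_mt, 1, which = "nope"), "unknown parameter")
})

test_that("normalized derivatives satisfy first-order Taylor consistency", {
  p <- make_params_sv(alpha_opt_deg = 20)
  l_mt <- mtu_length_at_norm(p, 1.15)
  eps <- 1e-6
  for (w in c("f_iso_max", "l_opt_f", "l_opt_f_pcsa", "alpha_opt", "l_opt_mt")) {
    nd <- normalized_derivative(w, p, l_mt, a = 1)
    theta <- mtsens:::param_value(p, w)
    p_up <- mtsens:::perturb_params(p, w, theta * (1 + eps))
    df <- muscle_force(p_up, l_mt, 1) - muscle_force(p, l_mt, 1)
    expect_equal(df, nd * eps * p$f_iso_max, tolerance = 1e-4)
  }
  # zero-derivative case: unpennated fiber at the optimal position has a
  # stationary force, so the normalized tendon-side sensitivity is zero too
  p0 <- make_params(alpha_opt_deg = 0)
  expect_equal(
    normalized_derivative("l_opt_mt", p0, mtu_length_at_norm(p0, 1), 1), 0,
    tolerance = 1e-12
  )
  expect_equal(
    normalized_derivative("alpha_opt", p0, mtu_length_at_norm(p0, 1.1), 1), 0
  )
  expect_error(normalized_derivative("bogus", p, l_mt), "unknown parameter")
})

test_that("the tendon-side parameter dominates and pennation is least impactful", {
  grid <- unique(grid_configs()[, c("alpha_deg", "ratio")])
  for (i in seq_len(nrow(grid))) {
    p <- config_params(grid$alpha_deg[i], grid$ratio[i])
    r <- sensitivity_ranking(p,
      which = c("l_opt_mt", "l_opt_f", "alpha_opt"),
      l_norm_range = c(0.35, 1.5), a = 1
    )
    v <- stats::setNames(r$max_abs_normalized, r$parameter)
    expect_gt(v[["l_opt_mt"]], v[["l_opt_f"]])
    expect_gte(v[["l_opt_f"]], v[["alpha_opt"]])
    if (grid$alpha_deg[i] > 0) expect_gt(v[["l_opt_f"]], v[["alpha_opt"]])
  }
})

test_that("sweep reproduces the baseline at zero variation and scales linearly in force capacity", {
  p <- make_params(alpha_opt_deg = 15)
  sw <- sweep_force_curves(p, "f_iso_max", variations = c(-0.1, 0, 0.1))
  base <- sw[sw$parameter == "f_iso_max" & sw$variation == 0, ]
  direct <- muscle_force(p, base$l_mt, 1) / p$f_iso_max
  expect_equal(base$value, direct, tolerance = 1e-12)
  up <- sw[sw$parameter == "f_iso_max" & sw$variation == 0.1, ]
  dn <- sw[sw$parameter == "f_iso_max" & sw$variation == -0.1, ]
  expect_equal(up$value, 1.1 * base$value, tolerance = 1e-12)
  expect_equal(dn$value, 0.9 * base$value, tolerance = 1e-12)
  # reference bands present at +/-10% and +/-20%
  expect_setequal(
    unique(sw$variation[sw$parameter == "f_iso_max_band"]),
    c(-0.2, -0.1, 0.1, 0.2)
  )
})

test_that("volume-coupled +10% fiber-length variation divides the peak force by 1.1", {
  p <- make_params_sv(alpha_opt_deg = 0)
  sw <- sweep_force_curves(p, "l_opt_f_pcsa", variations = c(0, 0.1))
  expect_setequal(
    unique(sw$variation[sw$parameter == "l_opt_f_pcsa"]), c(0, 0.1)
  )
  # evaluate each curve at ITS own peak (l_norm = 1 of that fiber)
  peak0 <- muscle_force(p, mtu_length_at_norm(p, 1), 1) / p$f_iso_max
  p_up <- mtsens:::perturb_params(p, "l_opt_f_pcsa", p$l_opt_f * 1.1)
  peak_up <- muscle_force(p_up, mtu_length_at_norm(p_up, 1), 1) / p$f_iso_max
  expect_equal(peak_up, peak0 / 1.1, tolerance = 1e-10)
})

test_that("infeasible sweep variations are skipped with a warning", {
  p <- make_params(alpha_opt_deg = 10)
  expect_warning(
    sw <- sweep_force_curves(p, "l_opt_mt", variations = c(-0.9, 0)),
    "infeasible"
  )
  expect_false(-0.9 %in% sw$variation[sw$parameter == "l_opt_mt"])
  expect_true(0 %in% sw$variation[sw$parameter == "l_opt_mt"])
})

test_that("sensitivity grid matches pointwise calls, flags infeasible points, zeroes pennation row", {
  p <- make_params(alpha_opt_deg = 20)
  l_axis <- as.numeric(mtu_length_at_norm(p, c(0.7, 1.0, 1.3)))
  g <- sensitivity_grid(
    "l_opt_mt", p,
    param_axis = p$l_opt_mt * c(0.95, 1, 1.05), l_mt_axis = l_axis
  )
  expect_equal(nrow(g), 9)
  spot <- g[g$param_value == p$l_opt_mt, ]
  expect_equal(
    spot$value,
    normalized_derivative("l_opt_mt", p, l_axis, 1),
    tolerance = 1e-12
  )

  # pennation row at alpha -> 0 is (numerically) all zeros
  ga <- sensitivity_grid(
    "alpha_opt", p,
    param_axis = c(1e-12, 10 * pi / 180), l_mt_axis = l_axis
  )
  expect_equal(ga$value[ga$param_value == 1e-12], c(0, 0, 0), tolerance = 1e-9)

  # infeasible parameter values are NA and counted
  gbad <- sensitivity_grid(
    "l_opt_mt", p,
    param_axis = c(0.01, p$l_opt_mt), l_mt_axis = l_axis
  )
  expect_true(all(is.na(gbad$value[gbad$param_value == 0.01])))
  expect_gte(attr(gbad, "n_infeasible"), 3)
})
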