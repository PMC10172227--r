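test_that("fiber-length optimal scaling reproduces the classic rescales", {
  expect_equal(scale_fiber_length(40, 2.2, 2.8), 50.91, tolerance = 1e-3)
  expect_equal(scale_fiber_length(100, 2.12, 2.70), 127.36, tolerance = 1e-4)
  # the soleus-style elongation is about 27.4%, under the ~30% mark
  elong <- scale_fiber_length(100, 2.12, 2.70) / 100 - 1
  expect_equal(round(100 * elong, 1), 27.4)
  expect_lt(elong, 0.30)
  expect_equal(scale_fiber_length(55, 2.7, 2.7), 55) # identity
  expect_error(scale_fiber_length(-1, 2.2, 2.7), "positive")
})

test_that("pennation optimal scaling matches the soleus worked example and identities", {
  expect_equal(
    round(scale_pennation(28.3, 2.12, 2.7, degrees = TRUE), 1), 21.9
  )
  expect_equal(scale_pennation(0, 2.2, 2.7, degrees = TRUE), 0)
  expect_equal(scale_pennation(17, 2.7, 2.7, degrees = TRUE), 17)
  # monotone decreasing in the optimal sarcomere length
  vals <- vapply(
    seq(2.2, 3.2, by = 0.1),
    function(s) scale_pennation(25, 2.7, s, degrees = TRUE), numeric(1)
  )
  expect_true(all(diff(vals) < 0))
  expect_error(
    scale_pennation(80, 4.9, 2.2, degrees = TRUE),
    "constant-thickness"
  )
})

test_that("PCSA definitions conserve volume and apply the cosine projection", {
  expect_equal(pcsa_conventional(100, 10), 10)
  expect_equal(pcsa_conventional(500, 14.6), 34.25, tolerance = 1e-3)
  expect_equal(pcsa_conventional(200, 10), 2 * pcsa_conventional(100, 10))
  expect_equal(pcsa_projected(100, 10, 0), pcsa_conventional(100, 10))
  expect_equal(pcsa_projected(100, 10, 60 * pi / 180), 5, tolerance = 1e-12)
  expect_equal(pcsa_projected(100, 10, 21.9 * pi / 180), 9.28, tolerance = 1e-3)
  # exact volume conservation through scaling then PCSA
  l_opt <- scale_fiber_length(12.3, 2.41, 2.7)
  expect_equal(pcsa_conventional(321.7, l_opt) * l_opt, 321.7,
    tolerance = 1e-14
  )
})

test_that("projected/conventional PCSA ratio stays within the small-angle band below 20 deg", {
  alphas <- seq(0, 20, by = 0.5) * pi / 180
  ratio <- pcsa_projected(100, 10, alphas) / pcsa_conventional(100, 10)
  expect_true(all(ratio >= cos(20 * pi / 180) - 1e-12))
  expect_true(all(ratio <= 1))
})

test_that("maximal isometric force and specific-tension rescaling follow the worked numbers", {
  expect_equal(max_isometric_force(61, 10), 610)
  expect_equal(max_isometric_force(37, 20), 740)
  expect_error(max_isometric_force(0, 10), "positive")
  expect_equal(round(rescale_specific_tension(61, 2.8 / 2.2)), 78)
  expect_equal(rescale_specific_tension(40, 1), 40)
  expect_equal(rescale_specific_tension(25, 1.2), 30)
})

test_that("optimal-scaling uncertainty over the raw sarcomere range is 22.7%", {
  s <- seq(2.2, 3.2, by = 1e-4)
  worst <- max(abs(1 - 2.7 / s))
  expect_equal(worst, max(2.7 / 2.2 - 1, 1 - 2.7 / 3.2), tolerance = 1e-9)
  expect_equal(round(100 * worst, 1), 22.7)
  expect_lte(worst, 0.23)
})

test_that("tendon slack length follows the optimal-position subtraction", {
  expect_equal(tendon_slack_length(0.40, 0.05, 0), 0.35)
  expect_equal(tendon_slack_length(0.40, 0.05, 21.9 * pi / 180), 0.3536,
    tolerance = 1e-4
  )
  expect_error(tendon_slack_length(0.04, 0.05, 0), "shorter than projected")
  # round-trip: the optimal position realizes l_norm = 1
  p <- make_params(alpha_opt_deg = 21.9)
  expect_equal(normalized_fiber_length(p, p$l_opt_mt), 1, tolerance = 1e-12)
})

test_that("derive_dataset applies and logs each scaling step", {
  rec <- tibble::tibble(
    muscle = c("with_sarc", "no_sarc"),
    fiber_length_mm = c(40, 60),
    sarcomere_length_um = c(2.2, NA),
    pennation_deg = c(20, 10),
    volume_cm3 = c(300, 200),
    pcsa_cm2 = c(NA, NA),
    pcsa_kind = c(NA_character_, NA),
    mtu_length_opt_mm = c(250, 300),
    specific_tension_ncm2 = c(61, 61)
  )
  res <- derive_dataset(rec, derivation_config(l_s_opt = 2.7))
  expect_equal(nrow(res$params), 2)
  expect_equal(nrow(res$errors), 0)

  log1 <- res$log[res$log$muscle == "with_sarc", ]
  expect_true(any(grepl("fiber scaled", log1$note)))
  expect_true(any(grepl("pennation scaled", log1$note)))

  log2 <- res$log[res$log$muscle == "no_sarc", ]
  expect_true(any(grepl("optimal-at-rest", log2$note)))
  # unscaled values pass through
  expect_equal(res$params$l_opt_f_m[2], 0.060)
  expect_equal(res$params$alpha_opt_deg[2], 10)
  # scaled values follow the scalar operations
  expect_equal(res$params$l_opt_f_m[1], scale_fiber_length(40, 2.2, 2.7) / 1000)
  expect_equal(
    res$params$alpha_opt_deg[1],
    scale_pennation(20, 2.2, 2.7, degrees = TRUE)
  )
  # tendon slack from the optimal-position MTU length
  expect_equal(
    res$params$l_sla_t_m,
    res$params$l_opt_mt_m - res$params$l_opt_f_m * cos(res$params$alpha_opt_rad)
  )
})

test_that("derive_dataset prefers volume recomputation, collects errors, honours pcsa_mode", {
  rec <- tibble::tibble(
    muscle = c("both_pcsa", "bad_pennation", "projected"),
    fiber_length_mm = c(50, 50, 50),
    sarcomere_length_um = c(2.5, 2.5, 2.5),
    pennation_deg = c(15, 95, 25),
    volume_cm3 = c(400, 400, 400),
    pcsa_cm2 = c(70, NA, NA),
    pcsa_kind = c("conventional", NA, NA),
    mtu_length_opt_mm = c(NA, NA, NA),
    specific_tension_ncm2 = c(NA, NA, NA)
  )
  res <- derive_dataset(rec, derivation_config(pcsa_mode = "projected"))
  # bad pennation collected as an error, not dropped silently
  expect_equal(res$errors$muscle, "bad_pennation")
  expect_match(res$errors$problem, "pennation")
  # volume recomputation wins and discrepancy is logged
  expect_true(any(grepl("superseded", res$log$note[res$log$muscle == "both_pcsa"])))
  # projected mode uses the SCALED pennation angle by default
  row <- res$params[res$params$muscle == "projected", ]
  a_scaled <- scale_pennation(25 * pi / 180, 2.5, 2.7)
  expect_equal(
    row$pcsa_cm2,
    pcsa_projected(400, scale_fiber_length(50, 2.5, 2.7) / 10, a_scaled)
  )
  # legacy switch reproduces the fixed-pennation behavior
  res_legacy <- derive_dataset(
    rec,
    derivation_config(pcsa_mode = "projected", projected_uses_raw_pennation = TRUE)
  )
  row_l <- res_legacy$params[res_legacy$params$muscle == "projected", ]
  expect_equal(
    row_l$pcsa_cm2,
    pcsa_projected(400, scale_fiber_length(50, 2.5, 2.7) / 10, 25 * pi / 180)
  )
  expect_gt(row$pcsa_cm2, row_l$pcsa_cm2) # scaled angle is smaller, cos larger
})
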