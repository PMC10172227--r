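#' Intermediate quantities of the force partial derivatives
#'
#' The analytic partial derivatives of the rigid-tendon isometric force share
#' three intermediates: `E1 = f_pe + a * f_ce` (the total normalized fiber
#' force along the fiber), `E2 = d f_pe/d l_norm + a * d f_ce/d l_norm` (the
#' combined curve slope), and `E3 = (l_mt - l_sla_t)^2 +
#' (l_opt_f sin(alpha_opt))^2` (the squared fiber length, m^2).
#'
#' @inheritParams muscle_force
#' @return A tibble with columns `l_mt`, `l_norm`, `E1`, `E2`, `E3`.
#' @export
gradient_components <- function(params, l_mt, a = 1, curves = mt_curves()) {
  check_curves(curves)
  l_norm <- normalized_fiber_length(params, l_mt)
  tibble::tibble(
    l_mt = l_mt,
    l_norm = l_norm,
    E1 = curves$passive(l_norm) + a * curves$active(l_norm),
    E2 = curves$d_passive(l_norm) + a * curves$d_active(l_norm),
    E3 = (l_mt - params$l_sla_t)^2 + (params$l_opt_f * sin(params$alpha_opt))^2
  )
}

#' Analytic partial derivatives of isometric muscle force
#'
#' Closed-form partial derivatives of the rigid-tendon isometric Hill-type
#' force with respect to each musculotendon parameter, suitable as
#' calibration gradients. The differentiation convention throughout: the MTU
#' length at the optimal joint position (`l_opt_mt`) is the free tendon-side
#' parameter and the tendon slack length is always the dependent quantity
#' `l_opt_mt - l_opt_f cos(alpha_opt)`. Perturbing `l_opt_f` or `alpha_opt`
#' therefore also moves the slack length through that relation.
#'
#' * `dF_dlopt_fixed_pcsa()`: w.r.t. optimal fiber length with the maximal
#'   isometric force held fixed (PCSA obtained independently). N/m.
#' * `dF_dlopt_volume_pcsa()`: w.r.t. optimal fiber length when the force
#'   capacity is volume-coupled, `f_iso_max = sigma V / l_opt_f`, so shortening
#'   the fiber raises PCSA. Requires `sigma` and `volume` in `params`. N/m.
#' * `dF_dalpha_opt()`: w.r.t. optimal pennation angle. Carries an overall
#'   `sin(alpha_opt)` factor and vanishes identically at zero pennation
#'   (pennation has no first-order effect there). N/rad.
#' * `dF_dlopt_mt()`: w.r.t. the optimal-position MTU length (equivalently,
#'   the tendon slack length shift). No `sin(alpha_opt)` prefactor; at zero
#'   pennation it reduces to the pure curve-shift term
#'   `-f_iso_max * E2 / l_opt_f`. N/m.
#'
#' All are vectorized over `l_mt` and validated against the central
#' finite-difference oracle [fd_gradient()].
#'
#' @inheritParams muscle_force
#' @return Numeric vector of derivatives, one per `l_mt`.
#' @export
dF_dlopt_fixed_pcsa <- function(params, l_mt, a = 1, curves = mt_curves()) {
  g <- gradient_components(params, l_mt, a, curves)
  lf <- params$l_opt_f
  sa <- sin(params$alpha_opt)
  d <- l_mt - params$l_sla_t
  -params$f_iso_max * (l_mt - params$l_opt_mt) *
    (g$E1 * lf * sa^2 / g$E3^1.5 + g$E2 * d^2 / (g$E3 * lf^2))
}

#' @rdname dF_dlopt_fixed_pcsa
#' @export
dF_dlopt_volume_pcsa <- function(params, l_mt, a = 1, curves = mt_curves()) {
  if (is.null(params$sigma) || is.null(params$volume)) {
    stop("volume-coupled derivative needs `sigma` and `volume` in params",
      call. = FALSE
    )
  }
  g <- gradient_components(params, l_mt, a, curves)
  lf <- params$l_opt_f
  sa <- sin(params$alpha_opt)
  d <- l_mt - params$l_sla_t
  dmt <- l_mt - params$l_opt_mt
  # sigma V / l_opt_f in SI newtons equals the stored f_iso_max
  sigma_v <- params$f_iso_max * lf
  -(sigma_v / lf^2) * (
    g$E1 * (g$E3 * d + (lf * sa)^2 * dmt) / g$E3^1.5 +
      g$E2 * dmt * d^2 / (g$E3 * lf)
  )
}

#' @rdname dF_dlopt_fixed_pcsa
#' @export
dF_dalpha_opt <- function(params, l_mt, a = 1, curves = mt_curves()) {
  g <- gradient_components(params, l_mt, a, curves)
  lf <- params$l_opt_f
  sa <- sin(params$alpha_opt)
  ca <- cos(params$alpha_opt)
  d <- l_mt - params$l_sla_t
  dmt <- l_mt - params$l_opt_mt
  -params$f_iso_max * sa * (
    g$E1 * lf^2 * (lf + dmt * ca) / g$E3^1.5 +
      g$E2 * dmt * d / g$E3
  )
}

#' @rdname dF_dlopt_fixed_pcsa
#' @export
dF_dlopt_mt <- function(params, l_mt, a = 1, curves = mt_curves()) {
  g <- gradient_components(params, l_mt, a, curves)
  lf <- params$l_opt_f
  sa <- sin(params$alpha_opt)
  d <- l_mt - params$l_sla_t
  -params$f_iso_max * (
    g$E1 * (lf * sa)^2 / g$E3^1.5 + g$E2 * d^2 / (g$E3 * lf)
  )
}

# Canonical parameter ids for derivative dispatch.
mt_parameter_ids <- c(
  "f_iso_max", "l_opt_f", "l_opt_f_pcsa", "alpha_opt", "l_opt_mt"
)

# Dispatch an analytic derivative by parameter id.
analytic_gradient <- function(which, params, l_mt, a = 1, curves = mt_curves()) {
  switch(which,
    f_iso_max = muscle_force(params, l_mt, a, curves) / params$f_iso_max,
    l_opt_f = dF_dlopt_fixed_pcsa(params, l_mt, a, curves),
    l_opt_f_pcsa = dF_dlopt_volume_pcsa(params, l_mt, a, curves),
    alpha_opt = dF_dalpha_opt(params, l_mt, a, curves),
    l_opt_mt = dF_dlopt_mt(params, l_mt, a, curves),
    stop("unknown parameter id `", which, "`; one of: ",
      paste(mt_parameter_ids, collapse = ", "),
      call. = FALSE
    )
  )
}

# Rebuild params with parameter `which` set to `value`, re-deriving the
# dependent tendon slack length (l_opt_mt stays the free tendon parameter)
# and, for the volume-coupled id, the force capacity.
perturb_params <- function(params, which, value) {
  switch(which,
    f_iso_max = update_params(params, f_iso_max = value),
    l_opt_f = update_params(params, l_opt_f = value),
    l_opt_f_pcsa = update_params(params,
      l_opt_f = value,
      f_iso_max = params$f_iso_max * params$l_opt_f / value
    ),
    alpha_opt = update_params(params, alpha_opt = value),
    l_opt_mt = update_params(params, l_opt_mt = value),
    stop("unknown parameter id `", which, "`", call. = FALSE)
  )
}

# Model-variation counterpart of perturb_params: the four Hill parameters are
# independent quantities of Eq-1-style contraction dynamics, so a one-at-a-time
# sweep holds the TENDON SLACK LENGTH fixed when fiber length or pennation is
# varied (l_opt_mt is recomputed to keep l_sla_t constant). Only the
# tendon-side id itself moves the slack length. This differs from the
# derivative convention, where l_opt_mt is the free parameter and the slack
# length is re-derived.
perturb_params_fixed_slack <- function(params, which, value) {
  if (which %in% c("l_opt_f", "l_opt_f_pcsa", "alpha_opt")) {
    l_sla <- params$l_sla_t
    l_f <- if (which == "alpha_opt") params$l_opt_f else value
    alpha <- if (which == "alpha_opt") value else params$alpha_opt
    p <- perturb_params(params, which, value)
    update_params(p, l_opt_mt = l_sla + l_f * cos(alpha))
  } else {
    perturb_params(params, which, value)
  }
}

param_value <- function(params, which) {
  switch(which,
    f_iso_max = params$f_iso_max,
    l_opt_f = ,
    l_opt_f_pcsa = params$l_opt_f,
    alpha_opt = params$alpha_opt,
    l_opt_mt = params$l_opt_mt,
    stop("unknown parameter id `", which, "`", call. = FALSE)
  )
}

#' Central finite-difference oracle for the force derivatives
#'
#' O(h^2)-accurate central difference of [muscle_force()] with respect to one
#' musculotendon parameter, honouring the same differentiation convention as
#' the analytic derivatives (tendon slack length re-derived from the fixed
#' `l_opt_mt` when fiber length or pennation is perturbed; force capacity
#' re-derived for the volume-coupled id). Intended for tests and diagnostics,
#' not production gradients.
#'
#' If a perturbation leaves the feasible parameter region, the step is halved
#' once; if the region boundary still blocks one side (e.g. pennation at
#' exactly zero), an O(h^2) one-sided three-point formula is used on the
#' feasible side; only when no feasible stencil exists does the oracle error.
#'
#' @inheritParams muscle_force
#' @param which Parameter id: one of `"f_iso_max"`, `"l_opt_f"`,
#'   `"l_opt_f_pcsa"`, `"alpha_opt"`, `"l_opt_mt"`.
#' @param h Step size; default `1e-7` times the parameter magnitude (floored
#'   at 1 rad for the pennation angle and 1 mm for lengths so a zero-valued
#'   parameter still gets a usable step).
#' @return Numeric vector of derivative estimates, one per `l_mt`.
#' @export
fd_gradient <- function(params, l_mt, a = 1, curves = mt_curves(),
                        which = "l_opt_mt", h = NULL) {
  theta <- param_value(params, which)
  if (is.null(h)) {
    # 1e-7 x parameter magnitude, with an absolute floor so a zero pennation
    # angle still gets a step large enough to beat round-off cancellation
    h <- max(1e-7 * abs(theta), if (which == "alpha_opt") 1e-4 else 1e-10)
  }
  stopifnot(h > 0)
  force_at <- function(value) {
    muscle_force(perturb_params(params, which, value), l_mt, a, curves)
  }
  central <- function(step) {
    (force_at(theta + step) - force_at(theta - step)) / (2 * step)
  }
  one_sided <- function(step) {
    # second-order forward (step > 0) or backward (step < 0) difference
    (-3 * force_at(theta) + 4 * force_at(theta + step) -
      force_at(theta + 2 * step)) / (2 * step)
  }
  out <- tryCatch(central(h), error = function(e) e)
  if (inherits(out, "error")) {
    out <- tryCatch(central(h / 2), error = function(e) e)
  }
  if (inherits(out, "error")) {
    out <- tryCatch(one_sided(h), error = function(e) e)
  }
  if (inherits(out, "error")) {
    out <- tryCatch(one_sided(-h), error = function(e) {
      stop("finite-difference perturbation infeasible even after halving h: ",
        conditionMessage(e),
        call. = FALSE
      )
    })
  }
  out
}

#' Normalized (dimensionless) force sensitivity
#'
#' `(dF/d theta) * theta / f_iso_max`: the fractional change in force capacity
#' (in units of maximal isometric force) per fractional change in the
#' parameter. A value of 10 means that increasing the parameter by a small
#' fraction eps raises the estimated force at that muscle length by about
#' `10 * eps` of the maximal isometric force. This is the quantity mapped in
#' sensitivity heatmaps and the basis of the parameter-impact ranking.
#'
#' @inheritParams fd_gradient
#' @return Numeric vector, dimensionless.
#' @export
normalized_derivative <- function(which, params, l_mt, a = 1,
                                  curves = mt_curves()) {
  theta <- param_value(params, which)
  if (theta < 0) stop("parameter value must be nonnegative", call. = FALSE)
  analytic_gradient(which, params, l_mt, a, curves) * theta / params$f_iso_max
}

#' Force-length curve families under parameter variation
#'
#' Recomputes the normalized isometric force-length curve while one
#' musculotendon parameter is varied by given fractions, in the style of
#' conventional one-at-a-time sensitivity sweeps: maximal activation, rigid
#' tendon, normalized fiber lengths 0.35-1.50 by default. Reference bands at
#' +/-10% and +/-20% of the maximal isometric force are included for visual
#' comparison (`parameter = "f_iso_max_band"`).
#'
#' Forces are reported normalized by the baseline `f_iso_max`; for the
#' volume-coupled id the varied curves genuinely change amplitude. The curve
#' is evaluated over the baseline parameter's `l_norm` axis, i.e. at the MTU
#' lengths where the baseline fiber attains each normalized length, so curve
#' shifts under tendon-side variation are visible. Variations that make the
#' parameter infeasible are skipped with a warning.
#'
#' Coupling convention: the four Hill parameters are varied one at a time as
#' the independent model inputs they are — the tendon slack length stays fixed
#' while fiber length or pennation is varied, and only the tendon-side id
#' (`l_opt_mt`) shifts it. The analytic derivatives use the complementary
#' derivation-time convention (slack length re-derived from a fixed
#' `l_opt_mt`); see [dF_dlopt_fixed_pcsa()].
#'
#' @inheritParams fd_gradient
#' @param variations Numeric vector of fractional changes, e.g.
#'   `c(-0.1, 0, 0.1)`. `0` reproduces the baseline curve exactly.
#' @param l_norm_range Length-2 numeric, baseline normalized fiber-length
#'   span.
#' @param n_points Number of evaluation points.
#' @return A tibble of class `mt_sweep` with columns `parameter`, `variation`,
#'   `l_norm`, `l_mt`, `value` (force / baseline `f_iso_max`).
#' @export
sweep_force_curves <- function(params, which,
                               variations = c(-0.2, -0.1, 0, 0.1, 0.2),
                               l_norm_range = c(0.35, 1.5),
                               a = 1, curves = mt_curves(),
                               n_points = 200) {
  stopifnot(length(l_norm_range) == 2, l_norm_range[1] < l_norm_range[2])
  l_norm <- seq(l_norm_range[1], l_norm_range[2], length.out = n_points)
  l_mt <- mtu_length_at_norm(params, l_norm)
  keep <- !is.na(l_mt)
  if (!all(keep)) {
    warning(sum(!keep), " grid points below the geometric minimum ",
      "normalized length sin(alpha_opt) were dropped",
      call. = FALSE
    )
    l_norm <- l_norm[keep]
    l_mt <- l_mt[keep]
  }
  f0 <- params$f_iso_max

  pieces <- list()
  for (v in variations) {
    theta <- param_value(params, which)
    p_v <- tryCatch(
      perturb_params_fixed_slack(params, which, theta * (1 + v)),
      error = function(e) e
    )
    if (inherits(p_v, "error")) {
      warning("variation ", v, " infeasible for `", which, "`: ",
        conditionMessage(p_v), " (skipped)",
        call. = FALSE
      )
      next
    }
    force <- tryCatch(
      muscle_force(p_v, l_mt, a, curves),
      error = function(e) e
    )
    if (inherits(force, "error")) {
      warning("variation ", v, " gives infeasible fiber geometry (skipped)",
        call. = FALSE
      )
      next
    }
    pieces[[length(pieces) + 1]] <- tibble::tibble(
      parameter = which, variation = v,
      l_norm = l_norm, l_mt = l_mt, value = force / f0
    )
  }

  base <- muscle_force(params, l_mt, a, curves) / f0
  bands <- purrr::map(c(-0.2, -0.1, 0.1, 0.2), function(b) {
    tibble::tibble(
      parameter = "f_iso_max_band", variation = b,
      l_norm = l_norm, l_mt = l_mt, value = base * (1 + b)
    )
  })

  out <- dplyr::bind_rows(c(pieces, bands))
  class(out) <- c("mt_sweep", class(out))
  attr(out, "which") <- which
  attr(out, "activation") <- a
  out
}

#' Normalized-sensitivity heatmap grid
#'
#' Evaluates [normalized_derivative()] over a grid of parameter values
#' (vertical axis) and MTU lengths (horizontal axis), the tabular equivalent
#' of a sensitivity heatmap. Grid points where the perturbed parameter set or
#' fiber geometry is infeasible are flagged `NA` and counted in the
#' `n_infeasible` attribute.
#'
#' @param which Parameter id (see [fd_gradient()]).
#' @param params_template Baseline [mt_params()]; the grid replaces the chosen
#'   parameter with each `param_axis` value.
#' @param param_axis Strictly increasing vector of parameter values.
#' @param l_mt_axis Strictly increasing vector of MTU lengths (m).
#' @inheritParams muscle_force
#' @return A tibble of class `mt_sensitivity_grid` with columns `param_value`,
#'   `l_mt`, `l_norm`, `value`.
#' @export
sensitivity_grid <- function(which, params_template, param_axis, l_mt_axis,
                             a = 1, curves = mt_curves()) {
  stopifnot(
    length(param_axis) > 0, length(l_mt_axis) > 0,
    !is.unsorted(param_axis, strictly = TRUE),
    !is.unsorted(l_mt_axis, strictly = TRUE)
  )
  n_bad <- 0L
  rows <- purrr::map(param_axis, function(pv) {
    p <- tryCatch(
      perturb_params(params_template, which, pv),
      error = function(e) NULL
    )
    if (is.null(p)) {
      n_bad <<- n_bad + length(l_mt_axis)
      return(tibble::tibble(
        param_value = pv, l_mt = l_mt_axis,
        l_norm = NA_real_, value = NA_real_
      ))
    }
    val <- tryCatch(
      normalized_derivative(which, p, l_mt_axis, a, curves),
      error = function(e) rep(NA_real_, length(l_mt_axis))
    )
    ln <- tryCatch(
      normalized_fiber_length(p, l_mt_axis),
      error = function(e) rep(NA_real_, length(l_mt_axis))
    )
    n_bad <<- n_bad + sum(is.na(val))
    tibble::tibble(param_value = pv, l_mt = l_mt_axis, l_norm = ln, value = val)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mt_sensitivity_grid", class(out))
  attr(out, "which") <- which
  attr(out, "activation") <- a
  attr(out, "n_infeasible") <- n_bad
  out
}

#' Rank parameter impact by peak normalized sensitivity
#'
#' For each parameter id, the maximum absolute normalized sensitivity over a
#' normalized fiber-length span (restricted to geometrically reachable
#' lengths). Reproduces the qualitative impact ordering: the tendon-side
#' parameter (`l_opt_mt`, i.e. tendon slack length) dominates, optimal fiber
#' length is intermediate, and pennation is least impactful for angles within
#' the usual anatomical range.
#'
#' @inheritParams muscle_force
#' @param which Character vector of parameter ids to rank.
#' @param l_norm_range Normalized fiber-length span over which to take the
#'   maximum.
#' @param n_points Grid resolution.
#' @return Tibble with `parameter` and `max_abs_normalized`, sorted
#'   descending.
#' @export
sensitivity_ranking <- function(params,
                                which = c("l_opt_mt", "l_opt_f", "alpha_opt"),
                                l_norm_range = c(0.35, 1.5),
                                a = 1, curves = mt_curves(),
                                n_points = 200) {
  l_norm <- seq(l_norm_range[1], l_norm_range[2], length.out = n_points)
  l_mt <- mtu_length_at_norm(params, l_norm)
  l_mt <- l_mt[!is.na(l_mt) & l_mt > params$l_sla_t]
  vals <- purrr::map_dbl(which, function(w) {
    max(abs(normalized_derivative(w, params, l_mt, a, curves)))
  })
  dplyr::arrange(
    tibble::tibble(parameter = which, max_abs_normalized = vals),
    dplyr::desc(.data$max_abs_normalized)
  )
}
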