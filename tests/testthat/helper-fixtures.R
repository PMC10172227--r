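# Shared fixtures: parameter sets are built in code, never stored.

make_params <- function(f_iso_max = 1000, l_opt_f = 0.05,
                        alpha_opt_deg = 30, l_opt_mt = 0.40,
                        sigma = NULL, volume = NULL) {
  mt_params(
    f_iso_max = f_iso_max, l_opt_f = l_opt_f,
    alpha_opt = alpha_opt_deg * pi / 180, l_opt_mt = l_opt_mt,
    sigma = sigma, volume = volume
  )
}

# Volume-coupled variant: f_iso_max derived from sigma and volume.
make_params_sv <- function(l_opt_f = 0.05, alpha_opt_deg = 20,
                           l_opt_mt = 0.30, sigma = 61, volume = 250) {
  mt_params(
    l_opt_f = l_opt_f, alpha_opt = alpha_opt_deg * pi / 180,
    l_opt_mt = l_opt_mt, sigma = sigma, volume = volume
  )
}

# Independent constant-thickness geometry construction: given the invariant
# fiber "height" t = l_opt_f * sin(alpha_opt) and along-tendon extent d, solve
# for the pennation angle from the constraint that a fiber at angle alpha with
# projection d has height d * tan(alpha) = t. Solved numerically (uniroot)
# rather than via the closed form under test.
brute_force_pennation <- function(params, l_mt) {
  t <- params$l_opt_f * sin(params$alpha_opt)
  d <- l_mt - params$l_sla_t
  if (t == 0) {
    return(0)
  }
  stats::uniroot(
    function(alpha) d * tan(alpha) - t,
    interval = c(1e-12, pi / 2 - 1e-12), tol = 1e-14
  )$root
}

# Relative mismatch robust to zeros on both sides.
rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), 1e-9)
}

# Analytic/FD mismatch measured against the larger of the two values or a
# small fraction of the natural derivative scale for that parameter (so
# symmetry zeros, e.g. the pennation derivative at zero angle, compare against
# FD round-off noise on the right scale instead of 0/0).
grad_mismatch <- function(an, fd, which, params) {
  deriv_scale <- switch(which,
    f_iso_max = 1,
    alpha_opt = params$f_iso_max,
    params$f_iso_max / params$l_opt_f
  )
  abs(an - fd) / max(abs(an), abs(fd), 1e-3 * deriv_scale)
}

grid_configs <- function() {
  expand.grid(
    alpha_deg = c(0, 10, 20, 30),
    l_norm = c(0.5, 0.8, 1.0, 1.2, 1.4),
    a = c(0, 0.5, 1),
    ratio = c(3, 5, 10),
    KEEP.OUT.ATTRS = FALSE
  )
}
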