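#' Hill-type force-length characteristic curves
#'
#' Constructs the pair of dimensionless force-length curves used by the
#' rigid-tendon isometric muscle model, together with their analytic first
#' derivatives with respect to normalized fiber length. Both curves are
#' peak-normalized: the active curve equals 1 at optimal fiber length
#' (`l_norm = 1`) with zero slope there, and the passive curve rises from 0 at
#' the slack strain to 1 at the strain of maximal passive force.
#'
#' The default shapes are a Gaussian active curve,
#' `f_ce(l) = exp(-(l - 1)^2 / gamma)`, and an exponential passive curve
#' anchored at the conventional Millard-style strain defaults (passive force
#' developing at strain 0 and reaching the maximal isometric value at strain
#' 0.7): with `x = (l - 1 - e0) / (e_max - e0)`,
#' `f_pe = (exp(k x) - 1 - k x - (k x)^2 / 2) / (exp(k) - 1 - k - k^2 / 2)`
#' for `x > 0`, zero below. Subtracting the linear and quadratic terms makes
#' the passive value, slope and curvature all vanish at the slack point, so
#' the curve is twice continuously differentiable on the working range — a
#' property the analytic force gradients and their finite-difference
#' verification rely on. The curves are pluggable: any object with the same
#' fields can be passed wherever an `mt_curves` is accepted, so other curve
#' families can be injected.
#'
#' @param gamma Width of the Gaussian active curve (dimensionless, > 0).
#' @param k_passive Exponential shape factor of the passive curve (> 0).
#' @param strain_slack Normalized-fiber-length strain at which passive force
#'   begins to develop (default 0, i.e. at optimal fiber length).
#' @param strain_max Strain at which passive force reaches the maximal
#'   isometric value (default 0.7). Must exceed `strain_slack`.
#'
#' @return An object of class `mt_curves`: a list with vectorized functions
#'   `active`, `passive`, `d_active`, `d_passive` (all of `l_norm`) and the
#'   shape parameters.
#' @examples
#' cur <- mt_curves()
#' cur$active(1)            # 1 at optimal length
#' cur$passive(1.7)         # 1 at maximal passive strain
#' @export
mt_curves <- function(gamma = 0.45, k_passive = 4,
                      strain_slack = 0, strain_max = 0.7) {
  stopifnot(gamma > 0, k_passive > 0, strain_max > strain_slack)
  e0 <- strain_slack
  span <- strain_max - e0
  k <- k_passive
  denom <- expm1(k) - k - k^2 / 2

  active <- function(l_norm) exp(-(l_norm - 1)^2 / gamma)
  d_active <- function(l_norm) {
    -2 * (l_norm - 1) / gamma * exp(-(l_norm - 1)^2 / gamma)
  }
  passive <- function(l_norm) {
    x <- (l_norm - 1 - e0) / span
    out <- (expm1(k * x) - k * x - (k * x)^2 / 2) / denom
    out[x <= 0] <- 0
    out
  }
  d_passive <- function(l_norm) {
    x <- (l_norm - 1 - e0) / span
    out <- (k / span) * (expm1(k * x) - k * x) / denom
    out[x <= 0] <- 0
    out
  }

  structure(
    list(
      active = active, passive = passive,
      d_active = d_active, d_passive = d_passive,
      gamma = gamma, k_passive = k_passive,
      strain_slack = strain_slack, strain_max = strain_max
    ),
    class = "mt_curves"
  )
}

#' @export
print.mt_curves <- function(x, ...) {
  cat("<mt_curves>\n")
  cat(sprintf("  active:  Gaussian, width gamma = %g\n", x$gamma))
  cat(sprintf(
    "  passive: exponential, k = %g, slack strain = %g, max strain = %g\n",
    x$k_passive, x$strain_slack, x$strain_max
  ))
  invisible(x)
}

# Shared validation for injected curve objects.
check_curves <- function(curves) {
  need <- c("active", "passive", "d_active", "d_passive")
  if (!is.list(curves) || !all(need %in% names(curves))) {
    stop("`curves` must provide functions: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(curves)
}
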