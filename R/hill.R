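#' Pennation angle at a given MTU length
#'
#' Under the constant-muscle-thickness assumption, the fiber's perpendicular
#' "height" `l_opt_f * sin(alpha_opt)` is invariant, so the pennation angle at
#' any MTU length follows from the rigid-tendon fiber projection:
#' `alpha(l_mt) = atan2(l_opt_f * sin(alpha_opt), l_mt - l_sla_t)`.
#'
#' At the optimal joint position (`l_mt = l_opt_mt`) this returns exactly
#' `alpha_opt`, since the tendon slack length is defined from that position.
#'
#' @param params An [mt_params()] object.
#' @param l_mt MTU length(s), metres. Vectorized.
#' @return Pennation angle(s) in radians, in `[0, pi)`.
#' @export
pennation_at_length <- function(params, l_mt) {
  stopifnot(all(l_mt > 0))
  d <- l_mt - params$l_sla_t
  h <- params$l_opt_f * sin(params$alpha_opt)
  if (params$alpha_opt == 0 && any(d <= 0)) {
    stop("MTU shorter than slack tendon", call. = FALSE)
  }
  atan2(h, d)
}

#' Normalized fiber length at a given MTU length
#'
#' Rigid-tendon fiber length from the constant-thickness geometry:
#' `l_f = sqrt((l_mt - l_sla_t)^2 + (l_opt_f * sin(alpha_opt))^2)`, divided by
#' the optimal fiber length. This geometric form is algebraically identical to
#' the projection form `(l_mt - l_sla_t) / (l_opt_f * cos(alpha(l_mt)))`
#' wherever the latter is defined, but remains well behaved when the MTU
#' shortens past the slack length of a pennated muscle.
#'
#' @inheritParams pennation_at_length
#' @return Normalized fiber length(s), dimensionless.
#' @export
normalized_fiber_length <- function(params, l_mt) {
  stopifnot(all(l_mt > 0))
  d <- l_mt - params$l_sla_t
  h <- params$l_opt_f * sin(params$alpha_opt)
  if (params$alpha_opt == 0 && any(d <= 0)) {
    stop("fiber length nonpositive: MTU shorter than slack tendon",
      call. = FALSE
    )
  }
  sqrt(d^2 + h^2) / params$l_opt_f
}

#' Isometric rigid-tendon muscle force
#'
#' Hill-type muscle force with a rigid tendon and the force-velocity
#' multiplier fixed at unity (isometric analysis):
#' `F = f_iso_max * cos(alpha(l_mt)) * (f_pe(l_norm) + a * f_ce(l_norm)) * f_v`.
#'
#' The `f_v` argument is an extension hook for future force-velocity behavior;
#' it defaults to 1 and the isometric analysis in this package never varies it.
#'
#' @inheritParams pennation_at_length
#' @param a Activation level(s) in `[0, 1]`. Vectorized (recycled against
#'   `l_mt`).
#' @param curves An [mt_curves()] object (or compatible list).
#' @param f_v Force-velocity multiplier, fixed at 1 for isometric force.
#' @return Muscle force(s), newtons.
#' @examples
#' p <- mt_params(1000, 0.05, 30 * pi / 180, 0.40)
#' muscle_force(p, p$l_opt_mt, a = 1) # F_iso_max * cos(30 deg)
#' @export
muscle_force <- function(params, l_mt, a = 1, curves = mt_curves(), f_v = 1) {
  stopifnot(all(a >= 0), all(a <= 1))
  check_curves(curves)
  l_norm <- normalized_fiber_length(params, l_mt)
  alpha <- pennation_at_length(params, l_mt)
  params$f_iso_max * cos(alpha) *
    (curves$passive(l_norm) + a * curves$active(l_norm)) * f_v
}

#' MTU length that realizes a target normalized fiber length
#'
#' Inverts the rigid-tendon geometry: finds `l_mt` such that
#' `normalized_fiber_length(params, l_mt)` equals `l_norm`. Only normalized
#' lengths at or above `sin(alpha_opt)` are geometrically reachable under the
#' constant-thickness model (the fiber can never be shorter than its
#' perpendicular height); unreachable targets return `NA`.
#'
#' @inheritParams pennation_at_length
#' @param l_norm Target normalized fiber length(s).
#' @return MTU length(s), metres; `NA` where the target is unreachable.
#' @export
mtu_length_at_norm <- function(params, l_norm) {
  h <- params$l_opt_f * sin(params$alpha_opt)
  sq <- (l_norm * params$l_opt_f)^2 - h^2
  out <- params$l_sla_t + sqrt(pmax(sq, 0))
  out[sq < 0] <- NA_real_
  out
}
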