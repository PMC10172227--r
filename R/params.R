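#' Musculotendon parameter set
#'
#' Bundles the four Hill-type musculotendon parameters, plus the MTU length at
#' the optimal joint position that generates the tendon slack length. Internal
#' units are SI throughout: metres, newtons, radians. Degrees, N/cm^2 and cm^3
#' are accepted only at file boundaries (see [read_params_json()],
#' [read_architecture_csv()]).
#'
#' Tendon slack length is never stored independently: it is always the
#' dependent quantity `l_sla_t = l_opt_mt - l_opt_f * cos(alpha_opt)`, i.e. the
#' MTU length at the optimal joint position minus the projected optimal fiber
#' length. In this modeling context tendon slack length acts as a phase-shift
#' parameter fixing the joint position at which the fiber reaches optimal
#' length, rather than an anatomical tendon measurement.
#'
#' When specific tension `sigma` (N/cm^2) and muscle volume `volume` (cm^3)
#' are supplied, `f_iso_max` may be omitted and is computed as
#' `sigma * volume / (100 * l_opt_f)` (the conventional PCSA route, with
#' `l_opt_f` converted to cm); if supplied, it must agree with that product.
#'
#' @param f_iso_max Maximal isometric force (N). Optional when `sigma` and
#'   `volume` are both given.
#' @param l_opt_f Optimal fiber length (m).
#' @param alpha_opt Optimal pennation angle (rad), in `[0, pi/2)`.
#' @param l_opt_mt MTU length at the optimal joint position (m). Must exceed
#'   the projected fiber length `l_opt_f * cos(alpha_opt)`.
#' @param sigma Specific tension (N/cm^2), optional.
#' @param volume Muscle volume (cm^3), optional.
#' @param name Optional muscle name.
#'
#' @return An object of class `mt_params`.
#' @examples
#' p <- mt_params(
#'   f_iso_max = 1000, l_opt_f = 0.05,
#'   alpha_opt = 30 * pi / 180, l_opt_mt = 0.40
#' )
#' p$l_sla_t
#' @export
mt_params <- function(f_iso_max = NULL, l_opt_f, alpha_opt, l_opt_mt,
                      sigma = NULL, volume = NULL, name = NULL) {
  stopifnot(
    is.numeric(l_opt_f), length(l_opt_f) == 1, l_opt_f > 0,
    is.numeric(alpha_opt), length(alpha_opt) == 1,
    alpha_opt >= 0, alpha_opt < pi / 2,
    is.numeric(l_opt_mt), length(l_opt_mt) == 1, l_opt_mt > 0
  )
  if (!is.null(sigma)) stopifnot(is.numeric(sigma), sigma > 0)
  if (!is.null(volume)) stopifnot(is.numeric(volume), volume > 0)

  proj <- l_opt_f * cos(alpha_opt)
  if (l_opt_mt <= proj) {
    stop("optimal MTU length shorter than projected fiber", call. = FALSE)
  }

  f_from_sigma <- if (!is.null(sigma) && !is.null(volume)) {
    max_isometric_force(sigma, volume / (100 * l_opt_f))
  } else {
    NULL
  }
  if (is.null(f_iso_max)) {
    if (is.null(f_from_sigma)) {
      stop("supply `f_iso_max`, or both `sigma` and `volume`", call. = FALSE)
    }
    f_iso_max <- f_from_sigma
  } else {
    stopifnot(is.numeric(f_iso_max), f_iso_max > 0)
    if (!is.null(f_from_sigma) &&
      abs(f_iso_max - f_from_sigma) > 1e-9 * f_from_sigma) {
      stop(
        "`f_iso_max` inconsistent with sigma * volume / l_opt_f (",
        format(f_from_sigma), " N expected)",
        call. = FALSE
      )
    }
  }

  structure(
    list(
      name = name,
      f_iso_max = unname(f_iso_max),
      l_opt_f = unname(l_opt_f),
      alpha_opt = unname(alpha_opt),
      l_opt_mt = unname(l_opt_mt),
      l_sla_t = unname(l_opt_mt - proj),
      sigma = if (!is.null(sigma)) unname(sigma),
      volume = if (!is.null(volume)) unname(volume)
    ),
    class = "mt_params"
  )
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params>", if (!is.null(x$name)) x$name else "", "\n")
  cat(sprintf("  f_iso_max: %.6g N\n", x$f_iso_max))
  cat(sprintf("  l_opt_f:   %.6g m\n", x$l_opt_f))
  cat(sprintf(
    "  alpha_opt: %.6g rad (%.4g deg)\n",
    x$alpha_opt, x$alpha_opt * 180 / pi
  ))
  cat(sprintf("  l_opt_mt:  %.6g m\n", x$l_opt_mt))
  cat(sprintf("  l_sla_t:   %.6g m (dependent, phase-shift)\n", x$l_sla_t))
  if (!is.null(x$sigma)) {
    cat(sprintf(
      "  sigma: %.6g N/cm^2, volume: %.6g cm^3\n",
      x$sigma, x$volume
    ))
  }
  invisible(x)
}

# Rebuild a parameter set with some fields replaced; l_sla_t re-derived.
update_params <- function(params, ...) {
  repl <- list(...)
  args <- list(
    f_iso_max = params$f_iso_max, l_opt_f = params$l_opt_f,
    alpha_opt = params$alpha_opt, l_opt_mt = params$l_opt_mt,
    sigma = params$sigma, volume = params$volume, name = params$name
  )
  for (nm in names(repl)) args[[nm]] <- repl[[nm]]
  # Volume-coupled forces are re-derived by the caller when needed; a plain
  # field update must not trip the sigma/volume consistency check.
  if (!("f_iso_max" %in% names(repl)) || !("sigma" %in% names(repl))) {
    if (any(c("f_iso_max", "l_opt_f") %in% names(repl))) {
      args$sigma <- NULL
      args$volume <- NULL
      if (!is.null(params$sigma)) {
        # keep provenance of sigma/volume unless force consistency would break
        f_new <- if ("f_iso_max" %in% names(repl)) repl$f_iso_max else params$f_iso_max
        l_new <- if ("l_opt_f" %in% names(repl)) repl$l_opt_f else params$l_opt_f
        f_sv <- max_isometric_force(params$sigma, params$volume / (100 * l_new))
        if (abs(f_new - f_sv) <= 1e-9 * f_sv) {
          args$sigma <- params$sigma
          args$volume <- params$volume
        }
      }
    }
  }
  do.call(mt_params, args)
}

#' Read and write musculotendon parameter sets as JSON
#'
#' The on-disk schema uses boundary units (degrees for the pennation angle):
#' `{name, f_iso_max_N, l_opt_f_m, alpha_opt_deg, l_opt_mt_m, l_sla_t_m,
#' curve: {gamma, k_passive, strain_max}}`. On load, the tendon slack length is
#' recomputed from the stored `l_opt_mt_m`; a relative mismatch above 1e-6
#' against the stored `l_sla_t_m` is an error, so stale hand-edited files fail
#' loudly rather than silently shifting the force-length curve.
#'
#' @param params An `mt_params` object.
#' @param path File path.
#' @param curves Optional `mt_curves` whose shape parameters are embedded.
#' @return `read_params_json()` returns a list with elements `params`
#'   (`mt_params`) and `curves` (`mt_curves`). `write_params_json()` returns
#'   `path` invisibly.
#' @export
write_params_json <- function(params, path, curves = mt_curves()) {
  obj <- list(
    name = if (is.null(params$name)) "unnamed" else params$name,
    f_iso_max_N = params$f_iso_max,
    l_opt_f_m = params$l_opt_f,
    alpha_opt_deg = params$alpha_opt * 180 / pi,
    l_opt_mt_m = params$l_opt_mt,
    l_sla_t_m = params$l_sla_t,
    curve = list(
      gamma = curves$gamma,
      k_passive = curves$k_passive,
      strain_max = curves$strain_max
    )
  )
  if (!is.null(params$sigma)) {
    obj$sigma_ncm2 <- params$sigma
    obj$volume_cm3 <- params$volume
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("f_iso_max_N", "l_opt_f_m", "alpha_opt_deg", "l_opt_mt_m", "l_sla_t_m")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0) {
    stop("parameter JSON missing fields: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  params <- mt_params(
    f_iso_max = obj$f_iso_max_N,
    l_opt_f = obj$l_opt_f_m,
    alpha_opt = obj$alpha_opt_deg * pi / 180,
    l_opt_mt = obj$l_opt_mt_m,
    sigma = obj$sigma_ncm2,
    volume = obj$volume_cm3,
    name = obj$name
  )
  rel <- abs(params$l_sla_t - obj$l_sla_t_m) / params$l_sla_t
  if (!is.finite(rel) || rel > 1e-6) {
    stop(
      "stored l_sla_t_m (", format(obj$l_sla_t_m),
      ") disagrees with l_opt_mt - l_opt_f cos(alpha_opt) (",
      format(params$l_sla_t), ")",
      call. = FALSE
    )
  }
  curves <- if (!is.null(obj$curve)) {
    mt_curves(
      gamma = obj$curve$gamma,
      k_passive = obj$curve$k_passive,
      strain_max = obj$curve$strain_max
    )
  } else {
    mt_curves()
  }
  list(params = params, curves = curves)
}
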