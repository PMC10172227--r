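#' Synthetic muscle-architecture records with known ground truth
#'
#' Generates plausible lower-limb muscle architectures by first drawing the
#' ground-truth musculotendon parameters (optimal fiber length, optimal
#' pennation, volume, specific tension, optimal-position MTU length) and then
#' *inverse-scaling* them into raw measurements: a raw sarcomere length is
#' drawn in 2.0-3.2 um (the span of classic cadaveric reports), the raw fiber
#' length is the optimal length shrunk or stretched by the sarcomere ratio,
#' and the raw pennation follows the constant-thickness relation backwards.
#' Running the derivation pipeline with optimal scaling on therefore recovers
#' the ground truth exactly, which makes the generator an end-to-end oracle
#' for the derivation code.
#'
#' Default ranges emulate adult lower-limb muscles: optimal fiber length
#' 30-120 mm, pennation 0-30 degrees, volume 50-900 cm^3, specific tension
#' uniform at 61 N/cm^2 per record (a single value, but stored per record so
#' non-uniform tensions are expressible), optimal-position MTU length at 2.5-8
#' times the optimal fiber length.
#'
#' @param n_muscles Number of muscles (>= 1).
#' @param seed Integer seed; the same seed reproduces the same records.
#' @param l_s_opt Optimal sarcomere length used for the inverse construction
#'   (um).
#' @param sigma Specific tension assigned to every record (N/cm^2).
#' @return A list with `records` (architecture tibble in the CSV schema) and
#'   `truth` (tibble of ground-truth parameters per muscle, SI units).
#' @export
synth_architecture <- function(n_muscles, seed = 1, l_s_opt = 2.7, sigma = 61) {
  if (!is.numeric(n_muscles) || n_muscles < 1) {
    stop("`n_muscles` must be >= 1", call. = FALSE)
  }
  n <- as.integer(n_muscles)
  set.seed(as.integer(seed))

  l_opt_f_mm <- stats::runif(n, 30, 120)
  alpha_opt_deg <- stats::runif(n, 0, 30)
  volume_cm3 <- round(stats::runif(n, 50, 900), 1)
  ratio_mt <- stats::runif(n, 2.5, 8)
  l_opt_mt_mm <- l_opt_f_mm * ratio_mt
  l_s_raw <- stats::runif(n, 2.0, 3.2)

  # Inverse optimal scaling: raw values that scale back to the truth.
  fiber_raw_mm <- l_opt_f_mm * l_s_raw / l_s_opt
  sin_raw <- sin(alpha_opt_deg * pi / 180) * l_s_opt / l_s_raw
  stopifnot(all(sin_raw < 1))
  pennation_raw_deg <- asin(sin_raw) * 180 / pi

  alpha_opt_rad <- alpha_opt_deg * pi / 180
  truth <- tibble::tibble(
    muscle = sprintf("synth_%02d", seq_len(n)),
    f_iso_max_n = sigma * volume_cm3 / (l_opt_f_mm / 10),
    l_opt_f_m = l_opt_f_mm / 1000,
    alpha_opt_rad = alpha_opt_rad,
    l_opt_mt_m = l_opt_mt_mm / 1000,
    l_sla_t_m = l_opt_mt_mm / 1000 - l_opt_f_mm / 1000 * cos(alpha_opt_rad),
    volume_cm3 = volume_cm3,
    specific_tension_ncm2 = sigma,
    sarcomere_raw_um = l_s_raw
  )
  records <- tibble::tibble(
    muscle = truth$muscle,
    fiber_length_mm = fiber_raw_mm,
    sarcomere_length_um = l_s_raw,
    pennation_deg = pennation_raw_deg,
    volume_cm3 = volume_cm3,
    pcsa_cm2 = NA_real_,
    pcsa_kind = NA_character_,
    mtu_length_opt_mm = l_opt_mt_mm,
    specific_tension_ncm2 = sigma
  )
  list(records = records, truth = truth)
}

#' Synthetic force observations from known parameters
#'
#' Evaluates the rigid-tendon isometric force at MTU lengths spanning a
#' normalized fiber-length design and applies seeded multiplicative noise:
#' `F_obs = F * (1 + e)`, `e ~ N(0, noise_cv)`. With `noise_cv = 0` the
#' observations lie exactly on the model curve. Observed forces are floored at
#' zero (a force transducer cannot report negative tension).
#'
#' @param params Ground-truth [mt_params()].
#' @param l_norm_range Length-2 normalized fiber-length span of the design.
#' @param n Number of observations.
#' @param a Activation level(s), recycled.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed Integer seed.
#' @param curves An [mt_curves()] object.
#' @return A tibble of observations (`l_mt`, `a`, `f_obs`, `weight`).
#' @export
synth_force_observations <- function(params, l_norm_range = c(0.5, 1.4),
                                     n = 50, a = 1, noise_cv = 0, seed = 1,
                                     curves = mt_curves()) {
  stopifnot(noise_cv >= 0, n >= 1)
  set.seed(as.integer(seed))
  l_norm <- seq(l_norm_range[1], l_norm_range[2], length.out = n)
  l_mt <- mtu_length_at_norm(params, l_norm)
  if (anyNA(l_mt)) {
    stop("design includes normalized lengths below sin(alpha_opt): unreachable",
      call. = FALSE
    )
  }
  a <- rep_len(a, n)
  f <- muscle_force(params, l_mt, a, curves)
  noise <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else rep(0, n)
  tibble::tibble(
    l_mt = l_mt, a = a,
    f_obs = pmax(f * (1 + noise), 0),
    weight = 1
  )
}
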