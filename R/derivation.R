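#' Optimal scaling of fiber length by sarcomere length
#'
#' Fibers are serial chains of sarcomeres, so fiber length scales linearly
#' with sarcomere length. Raw fiber lengths measured at an arbitrary fixation
#' position are rescaled to the length the fiber would have at the optimal
#' sarcomere length: `l_f_raw * l_s_opt / l_s_raw`. Units of the fiber length
#' pass through unchanged; the two sarcomere lengths must share a unit.
#'
#' @param l_f_raw Raw fiber length(s) (any length unit).
#' @param l_s_raw Measured sarcomere length(s) (um).
#' @param l_s_opt Optimal sarcomere length (um, commonly 2.7; human estimates
#'   cluster in 2.6-2.8).
#' @return Scaled (optimal) fiber length, same unit as `l_f_raw`.
#' @examples
#' scale_fiber_length(40, 2.2, 2.8) # 50.91: the classic 2.8/2.2 rescale
#' @export
scale_fiber_length <- function(l_f_raw, l_s_raw, l_s_opt) {
  if (any(l_f_raw <= 0) || any(l_s_raw <= 0) || any(l_s_opt <= 0)) {
    stop("fiber and sarcomere lengths must be positive", call. = FALSE)
  }
  l_f_raw * l_s_opt / l_s_raw
}

#' Optimal scaling of pennation angle by sarcomere length
#'
#' Under the constant-muscle-thickness model, the fiber's perpendicular height
#' `l_f * sin(alpha)` is preserved as the fiber lengthens or shortens, and
#' fiber length is proportional to sarcomere length. Hence the pennation angle
#' at optimal fiber length follows from the measured angle and sarcomere
#' length: `alpha_opt = asin(l_s_meas * sin(alpha_meas) / l_s_opt)`.
#'
#' @param alpha_meas Measured pennation angle(s), radians (see
#'   `degrees` to pass degrees).
#' @param l_s_meas Measured sarcomere length(s) (um).
#' @param l_s_opt Optimal sarcomere length (um).
#' @param degrees If `TRUE`, `alpha_meas` is interpreted (and the result
#'   returned) in degrees. Default `FALSE` (radians).
#' @return Optimal pennation angle(s).
#' @examples
#' scale_pennation(28.3, 2.12, 2.7, degrees = TRUE) # 21.9 deg, soleus-style
#' @export
scale_pennation <- function(alpha_meas, l_s_meas, l_s_opt, degrees = FALSE) {
  if (any(l_s_meas <= 0) || any(l_s_opt <= 0)) {
    stop("sarcomere lengths must be positive", call. = FALSE)
  }
  a <- if (degrees) alpha_meas * pi / 180 else alpha_meas
  if (any(a < 0) || any(a >= pi / 2)) {
    stop("measured pennation must lie in [0, 90) degrees", call. = FALSE)
  }
  s <- l_s_meas * sin(a) / l_s_opt
  if (any(s > 1)) {
    stop("constant-thickness model violated: sin(alpha_opt) would exceed 1",
      call. = FALSE
    )
  }
  out <- asin(s)
  if (degrees) out * 180 / pi else out
}

#' Physiological cross-sectional area
#'
#' Conventional PCSA is muscle volume divided by optimal fiber length, the
#' cross-section perpendicular to the fibers; it conserves volume exactly
#' (`pcsa * l_opt_f = volume`). Projected (functional) PCSA additionally
#' multiplies by the cosine of the optimal pennation angle, approximating the
#' anatomical cross-section. Which definition should feed the maximal
#' isometric force is an open question in the field for strongly pennated
#' muscles; both are provided and neither is declared correct.
#'
#' @param volume Muscle volume(s) (cm^3).
#' @param l_opt_f Optimal fiber length(s) (cm).
#' @param alpha_opt Optimal pennation angle(s), radians.
#' @return Area(s) in cm^2.
#' @examples
#' pcsa_conventional(100, 10) # 10 cm^2
#' pcsa_projected(100, 10, 60 * pi / 180) # 5 cm^2
#' @export
pcsa_conventional <- function(volume, l_opt_f) {
  if (any(volume <= 0) || any(l_opt_f <= 0)) {
    stop("volume and fiber length must be positive", call. = FALSE)
  }
  volume / l_opt_f
}

#' @rdname pcsa_conventional
#' @export
pcsa_projected <- function(volume, l_opt_f, alpha_opt) {
  if (any(alpha_opt < 0) || any(alpha_opt >= pi / 2)) {
    stop("pennation must lie in [0, 90) degrees", call. = FALSE)
  }
  pcsa_conventional(volume, l_opt_f) * cos(alpha_opt)
}

#' Maximal isometric force from specific tension and PCSA
#'
#' `F_iso_max = sigma * PCSA`, with N/cm^2 times cm^2 giving newtons directly.
#'
#' @param sigma Specific tension(s) (N/cm^2).
#' @param pcsa Physiological cross-sectional area(s) (cm^2).
#' @return Force(s), newtons.
#' @export
max_isometric_force <- function(sigma, pcsa) {
  if (any(sigma <= 0) || any(pcsa <= 0)) {
    stop("specific tension and PCSA must be positive", call. = FALSE)
  }
  sigma * pcsa
}

#' Rescale a specific tension after optimal fiber-length scaling
#'
#' A specific tension tuned against PCSAs computed from unscaled (raw) fiber
#' lengths no longer reproduces the same forces once fiber lengths are scaled
#' to sarcomere optimality: scaling fibers up by a ratio `r` shrinks PCSA by
#' `1/r`, so the compensating specific tension is `sigma * r`. The classic
#' case is the 61 N/cm^2 tuned against raw-length PCSAs, which becomes 78
#' N/cm^2 once fibers are rescaled by 2.8/2.2.
#'
#' @param sigma Specific tension(s) (N/cm^2).
#' @param l_s_ratio Fiber-length scaling ratio (optimal / raw sarcomere
#'   length), dimensionless.
#' @return Rescaled specific tension(s) (N/cm^2).
#' @examples
#' rescale_specific_tension(61, 2.8 / 2.2) # 77.6 -> 78 to the nearest integer
#' @export
rescale_specific_tension <- function(sigma, l_s_ratio) {
  if (any(sigma <= 0) || any(l_s_ratio <= 0)) {
    stop("specific tension and ratio must be positive", call. = FALSE)
  }
  sigma * l_s_ratio
}

#' Tendon slack length from the optimal joint position
#'
#' `l_sla_t = l_opt_mt - l_opt_f * cos(alpha_opt)`: the MTU length at the
#' joint position of maximal active isometric force, minus the projected
#' optimal fiber length. Choosing `l_opt_mt` is equivalent to choosing the
#' joint position at which the fiber is optimal, which is why this parameter
#' behaves as a phase shift of the expressed force-length curve.
#'
#' @param l_opt_mt MTU length(s) at the optimal joint position (m).
#' @param l_opt_f Optimal fiber length(s) (m).
#' @param alpha_opt Optimal pennation angle(s), radians.
#' @return Tendon slack length(s) (m), strictly positive.
#' @export
tendon_slack_length <- function(l_opt_mt, l_opt_f, alpha_opt) {
  if (any(l_opt_mt <= 0) || any(l_opt_f <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  out <- l_opt_mt - l_opt_f * cos(alpha_opt)
  if (any(out <= 0)) {
    stop("optimal MTU length shorter than projected fiber", call. = FALSE)
  }
  out
}

#' Derivation configuration
#'
#' Options controlling how raw architecture records are turned into
#' musculotendon parameters.
#'
#' @param l_s_opt Optimal sarcomere length (um), default 2.7, constrained to
#'   `[2.2, 3.2]` (the span of raw sarcomere lengths reported across classic
#'   cadaveric datasets).
#' @param pcsa_mode `"conventional"` or `"projected"`.
#' @param pennation_scaling Scale measured pennation to the optimal angle via
#'   the constant-thickness relation when sarcomere length is available.
#' @param projected_uses_raw_pennation Compatibility switch: when `TRUE`,
#'   projected PCSA uses the raw measured pennation angle even if a scaled
#'   angle is available (the legacy "fixed pennation angle" simplification),
#'   for auditing older derivations. Default `FALSE` (use the scaled angle).
#' @param digits Rounding applied in the human-readable derivation log only;
#'   parameter values are never rounded.
#' @return A list of class `mt_derivation_config`.
#' @export
derivation_config <- function(l_s_opt = 2.7,
                              pcsa_mode = c("conventional", "projected"),
                              pennation_scaling = TRUE,
                              projected_uses_raw_pennation = FALSE,
                              digits = 4) {
  stopifnot(l_s_opt >= 2.2, l_s_opt <= 3.2)
  pcsa_mode <- match.arg(pcsa_mode)
  structure(
    list(
      l_s_opt = l_s_opt, pcsa_mode = pcsa_mode,
      pennation_scaling = isTRUE(pennation_scaling),
      projected_uses_raw_pennation = isTRUE(projected_uses_raw_pennation),
      digits = digits
    ),
    class = "mt_derivation_config"
  )
}

#' Derive musculotendon parameters for a table of architecture records
#'
#' Composes the individual derivation steps (optimal scaling of fiber length
#' and pennation, PCSA, maximal isometric force, tendon slack length) over a
#' table of raw per-muscle measurements, recording every applied or omitted
#' step in a per-muscle derivation log so that simplifications are auditable
#' rather than silent.
#'
#' Input columns follow the architecture CSV schema (see
#' [read_architecture_csv()]): `muscle`, `fiber_length_mm`,
#' `sarcomere_length_um`, `pennation_deg`, `volume_cm3`, `pcsa_cm2`,
#' `pcsa_kind`, `mtu_length_opt_mm`, `specific_tension_ncm2`. Optional values
#' are `NA`. Rules:
#'
#' * Sarcomere length present: fiber length is scaled to `l_s_opt`; pennation
#'   is scaled too when `pennation_scaling` is on. Absent: the raw values are
#'   used and the log flags the optimal-at-rest simplification.
#' * Both `pcsa_cm2` and `volume_cm3` present: the volume-based recomputation
#'   wins and the discrepancy against the reported PCSA is logged.
#' * Specific tension is per-record; a uniform tension is simply a constant
#'   column.
#' * `mtu_length_opt_mm` present: tendon slack length follows from the optimal
#'   joint position; absent: tendon-side parameters are `NA` and logged.
#'
#' @param records A data frame of architecture records (one row per muscle).
#' @param config A [derivation_config()].
#' @return A list with `params`: tibble of derived parameters (SI units plus
#'   `alpha_opt_deg` and `pcsa_cm2` for readability), `log`: tibble
#'   (`muscle`, `step`, `note`), and `errors`: tibble of per-record validation
#'   failures (`muscle`, `problem`) — collected, never silently dropped.
#' @export
derive_dataset <- function(records, config = derivation_config()) {
  stopifnot(is.data.frame(records))
  if (!"muscle" %in% names(records)) {
    stop("records must have a `muscle` column", call. = FALSE)
  }
  opt <- c(
    "fiber_length_mm", "sarcomere_length_um", "pennation_deg", "volume_cm3",
    "pcsa_cm2", "pcsa_kind", "mtu_length_opt_mm", "specific_tension_ncm2"
  )
  for (col in opt) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "pcsa_kind") NA_character_ else NA_real_
    }
  }

  logs <- list()
  errs <- list()
  rows <- list()
  dg <- config$digits
  note <- function(muscle, step, msg) {
    logs[[length(logs) + 1]] <<- tibble::tibble(
      muscle = muscle, step = step, note = msg
    )
  }

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    m <- r$muscle
    problem <- character()
    if (is.na(r$fiber_length_mm) || r$fiber_length_mm <= 0) {
      problem <- c(problem, "missing or nonpositive fiber_length_mm")
    }
    if (is.na(r$pennation_deg) || r$pennation_deg < 0 || r$pennation_deg >= 90) {
      problem <- c(problem, "pennation_deg missing or outside [0, 90)")
    }
    if (!is.na(r$sarcomere_length_um) &&
      (r$sarcomere_length_um < 1 || r$sarcomere_length_um > 5)) {
      problem <- c(problem, "sarcomere_length_um outside sanity bound 1-5 um")
    }
    if (length(problem) > 0) {
      errs[[length(errs) + 1]] <- tibble::tibble(
        muscle = m, problem = paste(problem, collapse = "; ")
      )
      next
    }

    has_sarc <- !is.na(r$sarcomere_length_um)
    alpha_raw <- r$pennation_deg * pi / 180

    if (has_sarc) {
      l_opt_f_mm <- scale_fiber_length(
        r$fiber_length_mm, r$sarcomere_length_um, config$l_s_opt
      )
      note(m, "fiber_length", sprintf(
        "fiber scaled %s -> %s mm (sarcomere %s -> %s um)",
        round(r$fiber_length_mm, dg), round(l_opt_f_mm, dg),
        r$sarcomere_length_um, config$l_s_opt
      ))
    } else {
      l_opt_f_mm <- r$fiber_length_mm
      note(
        m, "fiber_length",
        "no sarcomere length: raw fiber length used (optimal-at-rest simplification)"
      )
    }

    if (has_sarc && config$pennation_scaling) {
      alpha_opt <- scale_pennation(
        alpha_raw, r$sarcomere_length_um, config$l_s_opt
      )
      note(m, "pennation", sprintf(
        "pennation scaled %s -> %s deg",
        round(r$pennation_deg, dg), round(alpha_opt * 180 / pi, dg)
      ))
    } else {
      alpha_opt <- alpha_raw
      note(
        m, "pennation",
        if (has_sarc) {
          "pennation scaling off: raw angle used (optimal-at-rest simplification)"
        } else {
          "no sarcomere length: raw pennation used (optimal-at-rest simplification)"
        }
      )
    }

    # PCSA: volume-based recomputation wins when both are available.
    pcsa <- NA_real_
    if (!is.na(r$volume_cm3)) {
      alpha_for_pcsa <- if (config$projected_uses_raw_pennation) alpha_raw else alpha_opt
      pcsa <- switch(config$pcsa_mode,
        conventional = pcsa_conventional(r$volume_cm3, l_opt_f_mm / 10),
        projected = pcsa_projected(r$volume_cm3, l_opt_f_mm / 10, alpha_for_pcsa)
      )
      note(m, "pcsa", sprintf(
        "%s PCSA %s cm^2 from volume %s cm^3 / fiber %s cm%s",
        config$pcsa_mode, round(pcsa, dg), r$volume_cm3,
        round(l_opt_f_mm / 10, dg),
        if (config$pcsa_mode == "projected" && config$projected_uses_raw_pennation) {
          " (legacy: raw pennation in projection)"
        } else {
          ""
        }
      ))
      if (!is.na(r$pcsa_cm2)) {
        note(m, "pcsa", sprintf(
          "reported PCSA %s cm^2 superseded by volume-based value %s cm^2 (discrepancy %s%%)",
          r$pcsa_cm2, round(pcsa, dg),
          round(100 * (pcsa - r$pcsa_cm2) / r$pcsa_cm2, 2)
        ))
      }
    } else if (!is.na(r$pcsa_cm2)) {
      pcsa <- r$pcsa_cm2
      note(m, "pcsa", sprintf(
        "reported %s PCSA %s cm^2 used (no volume available)",
        ifelse(is.na(r$pcsa_kind), "unspecified-kind", r$pcsa_kind), pcsa
      ))
    } else {
      note(m, "pcsa", "no volume or reported PCSA: force capacity not derivable")
    }

    f_iso_max <- NA_real_
    if (!is.na(pcsa) && !is.na(r$specific_tension_ncm2)) {
      f_iso_max <- max_isometric_force(r$specific_tension_ncm2, pcsa)
      note(m, "f_iso_max", sprintf(
        "F_iso_max = %s N/cm^2 x %s cm^2 = %s N",
        r$specific_tension_ncm2, round(pcsa, dg), round(f_iso_max, dg)
      ))
    } else {
      note(m, "f_iso_max", "specific tension or PCSA missing: F_iso_max not derived")
    }

    l_sla_t_m <- NA_real_
    l_opt_mt_m <- NA_real_
    if (!is.na(r$mtu_length_opt_mm)) {
      l_opt_mt_m <- r$mtu_length_opt_mm / 1000
      l_sla_t_m <- tendon_slack_length(l_opt_mt_m, l_opt_f_mm / 1000, alpha_opt)
      note(m, "tendon", sprintf(
        "l_sla_t = %s m from optimal-position MTU length %s m",
        round(l_sla_t_m, 6), l_opt_mt_m
      ))
    } else {
      note(m, "tendon", "no optimal-position MTU length: tendon slack length not derived")
    }

    rows[[length(rows) + 1]] <- tibble::tibble(
      muscle = m,
      f_iso_max_n = f_iso_max,
      l_opt_f_m = l_opt_f_mm / 1000,
      alpha_opt_rad = alpha_opt,
      alpha_opt_deg = alpha_opt * 180 / pi,
      l_opt_mt_m = l_opt_mt_m,
      l_sla_t_m = l_sla_t_m,
      pcsa_cm2 = pcsa,
      specific_tension_ncm2 = r$specific_tension_ncm2
    )
  }

  list(
    params = if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(),
    log = if (length(logs)) dplyr::bind_rows(logs) else
      tibble::tibble(muscle = character(), step = character(), note = character()),
    errors = if (length(errs)) dplyr::bind_rows(errs) else
      tibble::tibble(muscle = character(), problem = character())
  )
}
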