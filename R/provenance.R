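# Closed vocabularies for provenance metadata and audit grades.
mt_simplifications <- c(
  "optimal_at_rest_fiber_length",
  "uniform_optimal_sarcomere_length",
  "fixed_pennation_angle",
  "inherited_fiber_length",
  "inherited_specific_tension",
  "uniform_specific_tension",
  "optimal_at_rest_pennation",
  "optimal_at_rest_tendon",
  "slack_at_rest"
)
mt_uncertainty_grades <- c("small", "considerable", "large")
mt_impact_grades <- c("neglectable", "considerable", "severe")
mt_tendon_modes <- c(
  "computed_at_measurement_position",
  "computed_at_calibrated_position",
  "measured_length"
)
mt_tension_sources <- c("same_cohort", "inherited", "uniform")

#' Provenance metadata for a dataset or model derivation
#'
#' Machine-checkable description of how a muscle's (or dataset's)
#' musculotendon parameters were derived: whether sarcomere length was
#' measured and used for optimal scaling, whether pennation was scaled, which
#' subject cohorts supplied fiber lengths vs. muscle volumes, where the
#' specific tension came from, and how the tendon slack length was set. All
#' booleans are explicit (no implicit defaults) and labels come from closed
#' vocabularies, so an audit is deterministic.
#'
#' @param sarcomere_measured Was sarcomere length measured?
#' @param fiber_scaled_to_optimal Was raw fiber length scaled to the optimal
#'   sarcomere length?
#' @param uniform_optimal_sarcomere Was a single optimal sarcomere length used
#'   across muscles?
#' @param pennation_scaled Was the measured pennation scaled to the optimal
#'   angle?
#' @param pennation_raw_used_in_projected_pcsa Was the raw (unscaled)
#'   pennation used in a projected PCSA computed from a scaled fiber length?
#' @param fiber_length_source_cohort,volume_source_cohort Cohort labels, e.g.
#'   `"elderly_cadaver"`, `"young_in_vivo"`.
#' @param specific_tension_source One of `"same_cohort"`, `"inherited"`,
#'   `"uniform"`.
#' @param tendon_mode One of `"computed_at_measurement_position"`,
#'   `"computed_at_calibrated_position"`, `"measured_length"`.
#' @param raw_pennation_deg,raw_sarcomere_um Raw measured values used by the
#'   grade qualifiers (may be `NA` when unknown).
#' @param label Optional free-text label for the dataset/model.
#' @return A list of class `mt_provenance`.
#' @export
provenance_metadata <- function(sarcomere_measured,
                                fiber_scaled_to_optimal,
                                uniform_optimal_sarcomere,
                                pennation_scaled,
                                pennation_raw_used_in_projected_pcsa,
                                fiber_length_source_cohort,
                                volume_source_cohort,
                                specific_tension_source,
                                tendon_mode,
                                raw_pennation_deg = NA_real_,
                                raw_sarcomere_um = NA_real_,
                                label = NULL) {
  bools <- list(
    sarcomere_measured = sarcomere_measured,
    fiber_scaled_to_optimal = fiber_scaled_to_optimal,
    uniform_optimal_sarcomere = uniform_optimal_sarcomere,
    pennation_scaled = pennation_scaled,
    pennation_raw_used_in_projected_pcsa = pennation_raw_used_in_projected_pcsa
  )
  for (nm in names(bools)) {
    if (!is.logical(bools[[nm]]) || length(bools[[nm]]) != 1 || is.na(bools[[nm]])) {
      stop("`", nm, "` must be a single TRUE/FALSE (booleans are explicit)",
        call. = FALSE
      )
    }
  }
  if (!specific_tension_source %in% mt_tension_sources) {
    stop("unknown specific_tension_source `", specific_tension_source,
      "`; allowed: ", paste(mt_tension_sources, collapse = ", "),
      call. = FALSE
    )
  }
  if (!tendon_mode %in% mt_tendon_modes) {
    stop("unknown tendon_mode `", tendon_mode, "`; allowed: ",
      paste(mt_tendon_modes, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    c(bools, list(
      fiber_length_source_cohort = as.character(fiber_length_source_cohort),
      volume_source_cohort = as.character(volume_source_cohort),
      specific_tension_source = specific_tension_source,
      tendon_mode = tendon_mode,
      raw_pennation_deg = as.numeric(raw_pennation_deg),
      raw_sarcomere_um = as.numeric(raw_sarcomere_um),
      label = label
    )),
    class = "mt_provenance"
  )
}

#' Read provenance metadata from YAML
#'
#' The YAML schema is versioned (`schema: mtsens-provenance-v1`) and maps
#' one-to-one onto [provenance_metadata()] fields.
#'
#' @param path Path to a YAML file.
#' @return An `mt_provenance` object.
#' @export
read_provenance_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "mtsens-provenance-v1")) {
    stop("expected `schema: mtsens-provenance-v1` in ", path, call. = FALSE)
  }
  provenance_metadata(
    sarcomere_measured = obj$sarcomere_measured,
    fiber_scaled_to_optimal = obj$fiber_scaled_to_optimal,
    uniform_optimal_sarcomere = obj$uniform_optimal_sarcomere,
    pennation_scaled = obj$pennation_scaled,
    pennation_raw_used_in_projected_pcsa = obj$pennation_raw_used_in_projected_pcsa,
    fiber_length_source_cohort = obj$fiber_length_source_cohort,
    volume_source_cohort = obj$volume_source_cohort,
    specific_tension_source = obj$specific_tension_source,
    tendon_mode = obj$tendon_mode,
    raw_pennation_deg = if (is.null(obj$raw_pennation_deg)) NA_real_ else obj$raw_pennation_deg,
    raw_sarcomere_um = if (is.null(obj$raw_sarcomere_um)) NA_real_ else obj$raw_sarcomere_um,
    label = obj$label
  )
}

#' Quantified qualifiers for audit grading
#'
#' The grading vocabulary attaches verbal qualifiers ("large pennation",
#' "sarcomere much different from optimal") to the escalation of uncertainty
#' grades. These are quantified with explicit, configurable thresholds:
#' pennation is "large" above 20 degrees (where the small-angle cosine
#' approximation starts to fail) and a sarcomere is "much different from
#' optimal" when the scaling ratio deviates from unity by more than 10%.
#'
#' @param metadata An `mt_provenance` object.
#' @param l_s_opt Optimal sarcomere length used as reference (um).
#' @param pennation_large_deg Threshold for "large pennation" (degrees).
#' @param sarcomere_far_rel Relative deviation `|1 - l_s_opt / raw|` above
#'   which the raw sarcomere counts as far from optimal.
#' @return A list with logical `pennation_large`, `sarcomere_far`, the inputs
#'   used, and the thresholds (echoed into reports).
#' @export
grade_thresholds <- function(metadata, l_s_opt = 2.7,
                             pennation_large_deg = 20,
                             sarcomere_far_rel = 0.10) {
  pen <- metadata$raw_pennation_deg
  sar <- metadata$raw_sarcomere_um
  list(
    pennation_large = !is.na(pen) && pen > pennation_large_deg,
    sarcomere_far = !is.na(sar) && abs(1 - l_s_opt / sar) > sarcomere_far_rel,
    raw_pennation_deg = pen,
    raw_sarcomere_um = sar,
    l_s_opt = l_s_opt,
    pennation_large_deg = pennation_large_deg,
    sarcomere_far_rel = sarcomere_far_rel
  )
}

finding <- function(simplification, parameter, uncertainty, impact, rationale) {
  stopifnot(
    simplification %in% mt_simplifications,
    uncertainty %in% mt_uncertainty_grades,
    impact %in% mt_impact_grades
  )
  tibble::tibble(
    simplification = simplification,
    parameter = parameter,
    uncertainty = uncertainty,
    impact = impact,
    rationale = rationale
  )
}

#' Audit a derivation against the nine-simplification taxonomy
#'
#' Deterministic rule evaluation over provenance metadata. Exactly nine
#' distinct simplifications can ever be reported (optimal-at-rest counts
#' separately for fiber length, pennation and tendon slack length). Each
#' triggered rule cites its metadata evidence, and the uncertainty/impact
#' grades escalate according to the quantified qualifiers from
#' [grade_thresholds()]. Fully scaled, same-cohort, calibrated-tendon metadata
#' produces an empty findings list.
#'
#' The report grades parameter-derivation uncertainty only; it is not a
#' statement about overall simulation accuracy, which also depends on
#' musculoskeletal geometry, moment arms and other model components outside
#' this scope.
#'
#' @param metadata An `mt_provenance` object (or path to a provenance YAML).
#' @param thresholds Optional result of [grade_thresholds()]; computed with
#'   defaults when `NULL`.
#' @return An object of class `mt_audit`: a tibble of findings
#'   (`simplification`, `parameter`, `uncertainty`, `impact`, `rationale`)
#'   with summary counts and the thresholds as attributes.
#' @export
audit <- function(metadata, thresholds = NULL) {
  if (is.character(metadata)) metadata <- read_provenance_yaml(metadata)
  if (!inherits(metadata, "mt_provenance")) {
    stop("`metadata` must be an mt_provenance object or a YAML path",
      call. = FALSE
    )
  }
  th <- if (is.null(thresholds)) grade_thresholds(metadata) else thresholds

  fs <- list()
  add <- function(f) fs[[length(fs) + 1]] <<- f

  # 1. optimal at rest (fiber length)
  if (!metadata$fiber_scaled_to_optimal) {
    unc <- if (th$sarcomere_far || is.na(th$raw_sarcomere_um)) "large" else "small"
    imp <- if (unc == "large") "severe" else "neglectable"
    add(finding(
      "optimal_at_rest_fiber_length", "optimal fiber length", unc, imp,
      paste0(
        "raw fiber length used as the optimal value without sarcomere scaling",
        if (is.na(th$raw_sarcomere_um)) {
          " (raw sarcomere length unknown, so the deviation from optimality is unbounded)"
        } else if (th$sarcomere_far) {
          sprintf(
            " (raw sarcomere %.3g um is far from the optimal %.3g um)",
            th$raw_sarcomere_um, th$l_s_opt
          )
        } else {
          sprintf(
            " (raw sarcomere %.3g um is close to the optimal %.3g um)",
            th$raw_sarcomere_um, th$l_s_opt
          )
        }
      )
    ))
  }

  # 2. uniform optimal sarcomere length
  if (metadata$fiber_scaled_to_optimal && metadata$uniform_optimal_sarcomere) {
    add(finding(
      "uniform_optimal_sarcomere_length", "optimal fiber length",
      "small", "neglectable",
      "a single optimal sarcomere length was applied to all muscles despite biomechanical differences; grades escalate if the muscle-specific optimum differs much from the chosen value or the muscle operates at extreme lengths"
    ))
  }

  # 3. fixed pennation angle (in projected PCSA)
  if (metadata$pennation_raw_used_in_projected_pcsa) {
    considerable <- th$pennation_large && th$sarcomere_far
    add(finding(
      "fixed_pennation_angle", "maximal isometric force (PCSA)",
      if (considerable) "considerable" else "small",
      if (considerable) "considerable" else "neglectable",
      paste0(
        "raw pennation used in projected PCSA while the fiber was scaled to optimal length",
        sprintf(
          " (raw pennation %.3g deg %s 20 deg; sarcomere ratio deviation %s %.0f%%)",
          th$raw_pennation_deg,
          if (th$pennation_large) ">" else "<=",
          if (th$sarcomere_far) ">" else "<=",
          100 * th$sarcomere_far_rel
        )
      )
    ))
  }

  # 4. inherited fiber length
  if (!identical(
    metadata$fiber_length_source_cohort,
    metadata$volume_source_cohort
  )) {
    add(finding(
      "inherited_fiber_length", "maximal isometric force (PCSA)",
      "considerable", "considerable",
      sprintf(
        "muscle volume from cohort `%s` divided by fiber length from cohort `%s`: fiber length is held unchanged across demographically different groups",
        metadata$volume_source_cohort, metadata$fiber_length_source_cohort
      )
    ))
  }

  # 5. inherited specific tension
  if (metadata$specific_tension_source == "inherited") {
    add(finding(
      "inherited_specific_tension", "maximal isometric force (specific tension)",
      "considerable", "considerable",
      "specific tension estimated on one group of subjects or muscles reused for another despite demographic or biomechanical differences"
    ))
  }

  # 6. uniform specific tension
  if (metadata$specific_tension_source == "uniform") {
    add(finding(
      "uniform_specific_tension", "maximal isometric force (specific tension)",
      "considerable", "considerable",
      "one specific tension applied to all muscles despite fiber-type and functional differences"
    ))
  }

  # 7. optimal at rest (pennation)
  if (!metadata$pennation_scaled) {
    considerable <- th$pennation_large && th$sarcomere_far
    add(finding(
      "optimal_at_rest_pennation", "pennation angle",
      if (considerable) "considerable" else "small",
      if (considerable) "considerable" else "neglectable",
      paste0(
        "pennation measured at the fixation position used as the optimal angle",
        sprintf(
          " (raw pennation %s; raw sarcomere %s)",
          if (is.na(th$raw_pennation_deg)) "unknown" else sprintf("%.3g deg", th$raw_pennation_deg),
          if (is.na(th$raw_sarcomere_um)) "unknown" else sprintf("%.3g um", th$raw_sarcomere_um)
        )
      )
    ))
  }

  # 8./9. tendon slack length
  if (metadata$tendon_mode == "computed_at_measurement_position") {
    add(finding(
      "optimal_at_rest_tendon", "tendon slack length",
      "large", "severe",
      "tendon slack length set so that fiber optimality occurs at the anatomical fixation position; severe for the entire range of motion unless that position happens to be the optimal joint position"
    ))
  }
  if (metadata$tendon_mode == "measured_length") {
    add(finding(
      "slack_at_rest", "tendon slack length",
      "large", "severe",
      "tendon length measured at the fixation position used directly as the slack length; severe for the entire range of motion even if the measurement uncertainty is small"
    ))
  }

  findings <- if (length(fs)) dplyr::bind_rows(fs) else finding(
    character(), character(), character(), character(), character()
  )[0, ]
  findings <- dplyr::arrange(findings, match(
    .data$simplification, mt_simplifications
  ))

  structure(
    findings,
    class = c("mt_audit", class(findings)),
    label = metadata$label,
    thresholds = th,
    summary = table(factor(findings$impact, levels = mt_impact_grades)),
    scope = paste(
      "Findings grade parameter-derivation uncertainty only;",
      "they are not a measure of overall simulation accuracy."
    )
  )
}

#' @export
print.mt_audit <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<mt_audit>", if (!is.null(lab)) lab else "", "\n")
  if (nrow(x) == 0) {
    cat("  no simplifications detected\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf(
        "  [%s] %s (%s)\n      uncertainty: %s, impact: %s\n      %s\n",
        i, x$simplification[i], x$parameter[i],
        x$uncertainty[i], x$impact[i], x$rationale[i]
      ))
    }
  }
  th <- attr(x, "thresholds")
  cat(sprintf(
    "  thresholds: pennation large > %g deg; sarcomere far > %g%% from %g um\n",
    th$pennation_large_deg, 100 * th$sarcomere_far_rel, th$l_s_opt
  ))
  cat(" ", attr(x, "scope"), "\n")
  invisible(x)
}

#' Serialize an audit report to JSON
#'
#' @param x An `mt_audit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(x, path) {
  th <- attr(x, "thresholds")
  obj <- list(
    label = attr(x, "label"),
    scope = attr(x, "scope"),
    thresholds = list(
      pennation_large_deg = th$pennation_large_deg,
      sarcomere_far_rel = th$sarcomere_far_rel,
      l_s_opt = th$l_s_opt
    ),
    summary = as.list(attr(x, "summary")),
    findings = as.data.frame(x)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
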