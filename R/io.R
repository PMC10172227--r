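# Architecture CSV schema: exact header names, boundary units
# (mm, um, degrees, cm^3, cm^2, N/cm^2).
architecture_columns <- c(
  "muscle", "fiber_length_mm", "sarcomere_length_um", "pennation_deg",
  "volume_cm3", "pcsa_cm2", "pcsa_kind", "mtu_length_opt_mm",
  "specific_tension_ncm2"
)

#' Read a muscle-architecture CSV
#'
#' UTF-8, comma-separated, `.` decimal, mandatory header row with the exact
#' columns `muscle, fiber_length_mm, sarcomere_length_um, pennation_deg,
#' volume_cm3, pcsa_cm2, pcsa_kind, mtu_length_opt_mm, specific_tension_ncm2`.
#' Empty optional cells load as `NA` (absent), never as zero. Lines starting
#' with `#` are comments (output files written by this package carry such a
#' header). Per-row validation problems are reported with the offending row
#' and column.
#'
#' @param path CSV path.
#' @return A tibble of architecture records with a `.row` column preserving
#'   source row numbers for error messages.
#' @export
read_architecture_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(
    path,
    n_max = 0, comment = "#", show_col_types = FALSE, progress = FALSE
  ))
  miss <- setdiff(architecture_columns, hdr)
  if (length(miss) > 0) {
    stop("architecture CSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      muscle = readr::col_character(),
      pcsa_kind = readr::col_character(),
      .default = readr::col_double()
    )
  )
  df$.row <- seq_len(nrow(df))
  probs <- character()
  chk <- function(cond, row, col, msg) {
    if (isTRUE(cond)) probs <<- c(probs, sprintf("row %d, %s: %s", row, col, msg))
  }
  for (i in seq_len(nrow(df))) {
    chk(
      !is.na(df$pennation_deg[i]) &&
        (df$pennation_deg[i] < 0 || df$pennation_deg[i] >= 90),
      i, "pennation_deg", "must be in [0, 90)"
    )
    for (col in c(
      "fiber_length_mm", "sarcomere_length_um", "volume_cm3",
      "pcsa_cm2", "mtu_length_opt_mm", "specific_tension_ncm2"
    )) {
      chk(
        !is.na(df[[col]][i]) && df[[col]][i] <= 0,
        i, col, "must be positive"
      )
    }
    chk(
      !is.na(df$pcsa_kind[i]) &&
        !df$pcsa_kind[i] %in% c("conventional", "projected"),
      i, "pcsa_kind", "must be `conventional` or `projected`"
    )
  }
  if (length(probs) > 0) {
    stop("invalid architecture CSV:\n  ", paste(probs, collapse = "\n  "),
      call. = FALSE
    )
  }
  df
}

# Standard comment header for numeric output files: version, seed, config hash.
output_header <- function(seed = NA, config = list()) {
  c(
    sprintf(
      "# mtsens %s",
      as.character(utils::packageVersion("mtsens"))
    ),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", rlang::hash(config))
  )
}

#' Write a tibble as CSV with a provenance comment header
#'
#' Every numeric output file carries a `#` comment header with the tool
#' version, the seed in effect, and a hash of the generating configuration,
#' so outputs are traceable to their inputs. Files written this way round-trip
#' through [read_architecture_csv()] and `readr::read_csv(comment = "#")`.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header (`NA` when no randomness).
#' @param config List describing the generating configuration (hashed).
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(x, path, seed = NA, config = list()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read force observations from CSV
#'
#' Columns: `mtu_length_m`, `activation`, `force_n`, optional `weight`
#' (default 1). Returned in the internal observation layout (`l_mt`, `a`,
#' `f_obs`, `weight`).
#'
#' @param path CSV path.
#' @return A tibble of observations.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  need <- c("mtu_length_m", "activation", "force_n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("observations CSV missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"weight" %in% names(df)) df$weight <- 1
  tibble::tibble(
    l_mt = df$mtu_length_m, a = df$activation,
    f_obs = df$force_n, weight = df$weight
  )
}
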