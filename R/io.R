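#' Read a force curve from a delimited text file
#'
#' Accepts comma- or tab-separated text with a header row naming the
#' columns: `time_ms,force_nN` for a relaxation curve or
#' `z_nm,force_nN` for a loading curve. Lines starting with `#` are
#' comments; the decimal mark is `.`. The curve kind is inferred from
#' the header.
#'
#' @param path Path to the file.
#' @return An [afm_curve()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' sc <- tmv_scenario()
#' write_force_curve(generate_relaxation_curve(sc$solid, sc$contact), tf)
#' read_force_curve(tf)
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) < 2) abort_format("file has no data rows.")
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[1], delim, fixed = TRUE)[[1]])
  accepted <- c("time_ms,force_nN (relaxation)", "z_nm,force_nN (loading)")
  if (length(header) != 2 || header[2] != "force_nN" ||
      !header[1] %in% c("time_ms", "z_nm")) {
    abort_format(sprintf(
      "unrecognized header '%s'; accepted headers: %s.",
      paste(header, collapse = delim), paste(accepted, collapse = "; ")
    ))
  }
  df <- readr::read_delim(
    I(paste(lines, collapse = "\n")),
    delim = delim, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  )
  kind <- if (header[1] == "time_ms") "relaxation" else "loading"
  if (any(diff(df[[1]]) <= 0)) {
    abort_data(sprintf("the %s column must be strictly increasing.", header[1]))
  }
  afm_curve(df[[1]], df[[2]], kind = kind, id = basename(path))
}

#' Write a force curve to a delimited text file
#'
#' Writes the canonical on-disk format read back by
#' [read_force_curve()] (comma-separated, unit-bearing headers, full
#' double precision so a write-read round trip is lossless well
#' beyond 12 significant digits).
#'
#' @param curve An [afm_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  if (!inherits(curve, "afm_curve")) abort_data("`curve` must be an afm_curve.")
  readr::write_csv(tibble::as_tibble(curve), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' The JSON run configuration collects everything the pipeline needs
#' beyond the curves themselves: contact geometry (`R_nm`, `k_nN_nm`,
#' optional `D0_nm`), adhesion as exactly one of `w_nN_nm` or
#' `pull_off_nN` (with optional `adhesion_convention`, `"dmt"` or
#' `"jkr"`), Poisson ratios `v1` / `v2`, and optional fit
#' (`fit_method`, `plateau_fraction`) and simulation (`noise_sd`,
#' `noise_model`, `seed`) settings.
#'
#' @param path Path to a JSON file.
#' @return A validated named list with a `$contact`
#'   ([contact_config()]) element attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("config file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list as parsed from the JSON config.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) abort_format("config must be a JSON object.")
  req_pos <- function(field) {
    val <- cfg[[field]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0) {
      abort_format(sprintf("config field `%s` must be a single positive number.", field))
    }
    val
  }
  R <- req_pos("R_nm")
  k <- req_pos("k_nN_nm")
  has_w <- !is.null(cfg$w_nN_nm)
  has_fc <- !is.null(cfg$pull_off_nN)
  if (has_w == has_fc) {
    abort_format("config must give exactly one adhesion specification: `w_nN_nm` or `pull_off_nN`.")
  }
  convention <- cfg$adhesion_convention %||% "dmt"
  if (!convention %in% c("dmt", "jkr")) {
    abort_format("`adhesion_convention` must be \"dmt\" or \"jkr\".")
  }
  D0 <- cfg$D0_nm %||% NA_real_
  contact <- contact_config(
    R = R, k = k, D0 = D0,
    w = if (has_w) cfg$w_nN_nm else NULL,
    pull_off = if (has_fc) cfg$pull_off_nN else NULL,
    convention = convention
  )
  v1 <- cfg$v1 %||% 0.380829
  v2 <- cfg$v2 %||% v1
  for (v in c(v1, v2)) {
    if (!is.numeric(v) || v <= -1 || v >= 0.5) {
      abort_format("Poisson ratios in the config must lie in (-1, 0.5).")
    }
  }
  fit_method <- cfg$fit_method %||% "least_squares"
  if (!fit_method %in% c("least_squares", "three_point")) {
    abort_format("`fit_method` must be \"least_squares\" or \"three_point\".")
  }
  noise_sd <- cfg$noise_sd %||% 0
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort_format("`noise_sd` must be non-negative.")
  }
  cfg$contact <- contact
  cfg$v1 <- v1
  cfg$v2 <- v2
  cfg$fit_method <- fit_method
  cfg$noise_sd <- noise_sd
  cfg$plateau_fraction <- cfg$plateau_fraction %||% 0.1
  cfg
}

#' Serialize a fit result to JSON
#'
#' Emits the fitted parameters with units, the goodness of fit, a
#' residual summary, QC flags, and (for relaxation fits) the
#' closed-form coefficient table Ar/Br/Cr/alpha/beta.
#'
#' @param fit An `afm_fit`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_fit_json <- function(fit, path = NULL) {
  if (!inherits(fit, "afm_fit")) abort_data("`fit` must be an afm_fit.")
  payload <- fit_result_payload(fit)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(path)
}

fit_result_payload <- function(fit) {
  params <- lapply(names(fit$estimates), function(nm) {
    unit <- c(
      E1_GPa = "GPa", E2_GPa = "GPa", eta_GPa_ms = "GPa ms",
      E1s_GPa = "GPa", E_star_GPa = "GPa"
    )[[nm]]
    list(value = fit$estimates[[nm]], units = unit)
  })
  names(params) <- sub("_(GPa(_ms)?)$", "", names(fit$estimates))
  payload <- list(
    method = fit$method,
    parameters = params,
    r_squared = list(value = fit$r_squared, units = "dimensionless"),
    residuals = list(
      rmse = list(
        value = sqrt(mean(fit$residuals^2)),
        units = if (inherits(fit, "afm_loading_fit")) "nm" else "nN"
      ),
      max_abs = list(
        value = max(abs(fit$residuals)),
        units = if (inherits(fit, "afm_loading_fit")) "nm" else "nN"
      ),
      n = length(fit$residuals)
    ),
    warnings = as.list(fit$warnings)
  )
  if (inherits(fit, "afm_relaxation_fit")) {
    co <- relaxation_coefficients(fit$solid, fit$contact)
    payload$coefficients <- list(
      Ar = list(value = co$Ar, units = "GPa"),
      Br = list(value = co$Br, units = "GPa"),
      Cr = list(value = co$Cr, units = "GPa"),
      alpha = list(value = co$alpha, units = "1/ms"),
      beta = list(value = co$beta, units = "1/ms"),
      prefactor = list(value = co$prefactor, units = "nm^2")
    )
  }
  payload
}

`%||%` <- function(x, y) if (is.null(x)) y else x
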