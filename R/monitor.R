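#' Read an impedance spectrum from CSV
#'
#' Expects the project dialect: header `freq_hz,z_mod_ohm,z_phase_deg`, one
#' row per frequency, '.' decimal separator. Lines starting with `#` carry
#' `key=value` metadata (stage, electrode pair, amplitude_mV). Rows are sorted
#' ascending by frequency (with a message when reordering was needed);
#' duplicate frequencies are rejected. With `dialect = "eu"` the reader
#' accepts ';' separators and ',' decimals.
#'
#' @param path CSV file path.
#' @param dialect `"standard"` (`,` separator, `.` decimal) or `"eu"`
#'   (`;` separator, `,` decimal).
#' @return An `eis_spectrum`.
#' @export
read_spectrum_csv <- function(path, dialect = c("standard", "eu")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "eu") ";" else ","
  dec <- if (dialect == "eu") "," else "."
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines)
  metadata <- list()
  for (i in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", lines[i])
    if (grepl("=", kv, fixed = TRUE)) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      metadata[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
    }
  }
  body <- setdiff(seq_along(lines), meta_lines)
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(trimws(lines[body[1]]), sep, fixed = TRUE)[[1]]
  expected <- c("freq_hz", "z_mod_ohm", "z_phase_deg")
  if (!identical(trimws(header), expected)) {
    stop("malformed header at line ", body[1], " of ", path,
         ": expected 'freq_hz,z_mod_ohm,z_phase_deg'", call. = FALSE)
  }
  rows <- body[-1]
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  parse_num <- function(x) {
    if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  vals <- matrix(NA_real_, nrow = length(rows), ncol = 3)
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[k]]), sep, fixed = TRUE)[[1]]
    if (length(fields) != 3) {
      stop("malformed row at line ", rows[k], " of ", path,
           ": expected 3 fields", call. = FALSE)
    }
    v <- parse_num(fields)
    if (any(is.na(v))) {
      stop("non-numeric value at line ", rows[k], " of ", path, call. = FALSE)
    }
    vals[k, ] <- v
  }
  if (anyDuplicated(vals[, 1])) {
    stop("duplicate frequency value(s) in ", path, call. = FALSE)
  }
  bad <- which(vals[, 2] <= 0)
  if (length(bad)) {
    stop("non-positive magnitude at line ", rows[bad[1]], " of ", path,
         call. = FALSE)
  }
  if (is.unsorted(vals[, 1], strictly = TRUE)) {
    message("rows in ", basename(path), " were not frequency-sorted; sorting")
    vals <- vals[order(vals[, 1]), , drop = FALSE]
  }
  impedance_spectrum(vals[, 1], vals[, 2], vals[, 3], metadata = metadata)
}

#' Write an impedance spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()] (standard dialect): metadata as leading
#' `# key=value` lines, then the header and one row per frequency with 9
#' significant digits, so a write/read round trip preserves the spectrum to
#' better than 1e-9 relative.
#'
#' @param spectrum An `eis_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  check_spectrum(spectrum)
  md <- attr(spectrum, "metadata")
  lines <- character(0)
  if (length(md)) {
    lines <- sprintf("# %s=%s", names(md), vapply(md, as.character, ""))
  }
  lines <- c(lines, "freq_hz,z_mod_ohm,z_phase_deg",
             sprintf("%.10g,%.10g,%.10g", spectrum$freq_hz,
                     spectrum$z_mod_ohm, spectrum$z_phase_deg))
  writeLines(lines, path)
  invisible(path)
}

#' Monitoring run configuration
#'
#' @param spectra Named list (names among `"i"`-`"iv"`) of `eis_spectrum`
#'   objects or CSV paths.
#' @param assays Optional assay table (or CSV path) with the columns of
#'   [apparent_permeability()] plus `signal` and `role`; concentrations are
#'   obtained through the calibration curve.
#' @param calibration Optional standards table (or CSV path) with
#'   `conc_mg_ml`, `signal`; required when `assays` is given.
#' @param area_cm2 Sensing area for TEER normalisation.
#' @param crossover_hz,ratio_threshold Barrier-assessment settings.
#' @param fit [fit_config()] for the staged calibration.
#' @param seed Seed recorded in the report and used for fit multi-starts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spectra, assays = NULL, calibration = NULL,
                       area_cm2 = 2.35e-3, crossover_hz = 50,
                       ratio_threshold = 1.02, fit = fit_config(),
                       seed = 1L) {
  stopifnot(area_cm2 > 0)
  if (!is.null(assays) && is.null(calibration)) {
    stop("assays require a calibration table", call. = FALSE)
  }
  structure(list(spectra = spectra, assays = assays,
                 calibration = calibration, area_cm2 = area_cm2,
                 crossover_hz = crossover_hz,
                 ratio_threshold = ratio_threshold, fit = fit,
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_spectrum <- function(x) {
  if (is.character(x)) read_spectrum_csv(x) else { check_spectrum(x); x }
}

resolve_table <- function(x) {
  if (is.character(x)) tibble::as_tibble(utils::read.csv(x)) else
    tibble::as_tibble(x)
}

#' Run the end-to-end barrier monitoring pipeline
#'
#' Staged calibration (i -> iv) of the supplied spectra, TEER extraction from
#' the complete-model fit, barrier assessment of the stage-iv spectrum
#' against the cell-free stage-i control, and, when assay data is supplied,
#' calibration-curve inversion and permeability summary. Failures in one
#' section are recorded in the report's `errors` field and do not abort later
#' sections.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with sections `stages`, `teer`,
#'   `barrier`, `permeability`, `inputs`, `errors`, `session`.
#' @export
run_monitor <- function(config) {
  stopifnot(inherits(config, "run_config"))
  errors <- list()
  note <- function(section, e) {
    errors[[section]] <<- conditionMessage(e)
    NULL
  }

  spectra <- purrr::imap(config$spectra, function(x, nm) {
    tryCatch(resolve_spectrum(x), error = function(e) note(paste0("spectrum_", nm), e))
  })
  spectra <- purrr::compact(spectra)

  cfg <- config$fit
  cfg$seed <- config$seed
  fits <- tryCatch(
    withCallingHandlers(
      staged_calibration(spectra, base_config = cfg),
      warning = function(w) {
        errors[["staged_calibration_warning"]] <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }),
    error = function(e) note("staged_calibration", e))

  stage_summaries <- purrr::map(fits, function(f) {
    list(stage = f$stage,
         parameters = as.list(f$parameters),
         deviation_percent = f$deviation_percent,
         accepted = f$accepted,
         converged = f$converged,
         iterations = f$iterations)
  })

  teer <- NULL
  if (!is.null(fits[["iv"]])) {
    teer <- tryCatch({
      tr <- extract_teer(fits[["iv"]], config$area_cm2)
      as.list(tr)
    }, error = function(e) note("teer", e))
  }

  barrier <- NULL
  if (all(c("i", "iv") %in% names(spectra))) {
    barrier <- tryCatch(
      as.list(assess_barrier(spectra[["i"]], spectra[["iv"]],
                             crossover_hz = config$crossover_hz,
                             ratio_threshold = config$ratio_threshold)),
      error = function(e) note("barrier", e))
  }

  permeability <- NULL
  if (!is.null(config$assays)) {
    permeability <- tryCatch({
      assays <- resolve_table(config$assays)
      curve <- fit_calibration(resolve_table(config$calibration))
      assays$c_rec_mg_ml <- concentration_from_signal(curve, assays$signal)
      summ <- permeability_summary(assays)
      list(calibration = list(slope = curve$slope,
                              intercept = curve$intercept,
                              r_squared = curve$r_squared),
           per_sample = summ$per_sample,
           mean_barrier_cm_s = summ$mean_barrier,
           mean_control_cm_s = summ$mean_control,
           percent_reduction = summ$percent_reduction)
    }, error = function(e) note("permeability", e))
  }

  inputs <- purrr::imap(config$spectra, function(x, nm) {
    if (is.character(x)) {
      list(path = x, sha1 = digest::digest(file = x, algo = "sha1"))
    } else {
      list(path = NA, sha1 = digest::digest(bode_table(x), algo = "sha1"))
    }
  })

  cfg_for_hash <- config
  cfg_for_hash$spectra <- purrr::map(config$spectra, function(x) {
    if (is.character(x)) x else digest::digest(bode_table(x))
  })

  structure(list(
    stages = stage_summaries,
    teer = teer,
    barrier = barrier,
    permeability = permeability,
    inputs = inputs,
    errors = errors,
    session = list(package_version = as.character(utils::packageVersion("teerfit")),
                   seed = config$seed,
                   config_hash = digest::digest(cfg_for_hash, algo = "sha1"))
  ), class = "run_report")
}

#' Write a run report as deterministic JSON
#'
#' Keys are sorted and numbers written at full precision, so two runs on
#' identical inputs and seed produce byte-identical files. Absent sections
#' (e.g. no TEER because stage iv was missing) are written as explicit nulls.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- unclass(report)
  payload <- purrr::map(payload, function(x) {
    if (is.data.frame(x)) x else x
  })
  sections <- c("stages", "teer", "barrier", "permeability", "inputs",
                "errors", "session")
  for (s in sections) if (is.null(payload[[s]])) payload[s] <- list(NULL)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  # sort keys for byte-stable output
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x)) {
      x <- x[order(names(x))]
      lapply(x, sort_rec)
    } else if (is.list(x)) lapply(x, sort_rec) else x
  }
  writeLines(jsonlite::toJSON(sort_rec(parsed), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             path)
  invisible(path)
}
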