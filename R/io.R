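#' @title Cohort files, standards files and the pipeline driver
#' @name io
NULL

.cohort_columns <- c("subject_id", "visit", "sex", "age_years", "tsh_mU_L",
                     "ft3_pmol_L", "ft4_pmol_L", "disease_history",
                     "medication", "iodine_mg_d", "cohort_tag",
                     "contaminant_rule")

#' Read and write cohort CSV files
#'
#' The cohort schema is a UTF-8, decimal-point, newline-terminated CSV
#' with the exact header \code{subject_id, visit, sex, age_years,
#' tsh_mU_L, ft3_pmol_L, ft4_pmol_L, disease_history, medication,
#' iodine_mg_d, cohort_tag, contaminant_rule}.  Sex is encoded F/M;
#' empty \code{iodine_mg_d}/\code{contaminant_rule} fields are missing
#' values, not zeros.  Round-trips are lossless.
#'
#' @param path file path.
#' @param records a cohort data.frame (see \code{\link{generate_cohort}}).
#' @return \code{read_cohort}: the cohort data.frame;
#'   \code{write_cohort}: \code{path}, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  header <- gsub('"', "", strsplit(readLines(path, n = 1L), ",",
                                   fixed = TRUE)[[1]])
  if (!identical(header, .cohort_columns))
    stop("cohort file header mismatch; expected exactly: ",
         paste(.cohort_columns, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       contaminant_rule = "character",
                                       cohort_tag = "character",
                                       sex = "character"))
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex))
    stop(sprintf("parse error in column 'sex', line %d: '%s' (expected F or M)",
                 bad_sex[1] + 1L, df$sex[bad_sex[1]]), call. = FALSE)
  for (col in c("age_years", "tsh_mU_L", "ft3_pmol_L", "ft4_pmol_L")) {
    bad <- which(!is.finite(df[[col]]) | (col != "age_years" & df[[col]] <= 0))
    if (length(bad))
      stop(sprintf("parse error in column '%s', line %d: non-positive or missing value",
                   col, bad[1] + 1L), call. = FALSE)
  }
  df$contaminant_rule[df$contaminant_rule == ""] <- NA_character_
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols))
    stop("records lack cohort columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(records[, .cohort_columns], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.standards_format_version <- "1.0"

#' Serialize fitted standards to JSON and back
#'
#' Standards are stored as human-auditable JSON: format version, analyte,
#' sex, age domain and transform, link functions, knots, coefficient
#' vectors (or frozen constants) per parameter curve, fit metadata and
#' optional provenance.  Reading validates the schema and rejects files
#' with unknown top-level fields or an unsupported format version.
#'
#' @param std a \code{"centile_standard"}.
#' @param path file path.
#' @param provenance optional named list (e.g. input/config hashes, seed)
#'   stored verbatim.
#' @return \code{write_standard}: \code{path}, invisibly;
#'   \code{read_standard}: the \code{"centile_standard"}.
#' @export
write_standard <- function(std, path, provenance = NULL) {
  stopifnot(inherits(std, "centile_standard"))
  obj <- list(format_version = .standards_format_version,
              analyte = std$analyte, sex = std$sex,
              age_domain = std$age_domain, age_offset = std$age_offset,
              knots = std$knots, order = std$order, tau_max = std$tau_max,
              curves = std$curves,
              fit = c(std$fit[c("n", "logLik", "deviance",
                                "iterations", "converged")],
                      list(edf = as.list(std$fit$edf))),
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_standard
#' @export
read_standard <- function(path) {
  if (!file.exists(path)) stop("no such standards file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("format_version", "analyte", "sex", "age_domain", "age_offset",
             "knots", "order", "tau_max", "curves", "fit", "provenance")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stop("standards file has unknown fields (", paste(extra, collapse = ", "),
         "); refusing to guess their meaning", call. = FALSE)
  if (!identical(obj$format_version, .standards_format_version))
    stop("unsupported standards format version: ", obj$format_version,
         call. = FALSE)
  stopifnot(obj$analyte %in% c("fT3", "fT4", "TSH", "ratio"),
            obj$sex %in% c("female", "male"),
            length(obj$age_domain) == 2, length(obj$knots) > 8)
  curves <- lapply(obj$curves, function(cv) {
    stopifnot(cv$link %in% c("log", "identity"),
              !is.null(cv$coef) || !is.null(cv$fixed))
    cv
  })
  fit <- obj$fit
  fit$edf <- unlist(fit$edf)
  structure(list(analyte = obj$analyte, sex = obj$sex,
                 age_domain = as.numeric(obj$age_domain),
                 age_offset = obj$age_offset,
                 knots = as.numeric(obj$knots), order = as.integer(obj$order),
                 tau_max = obj$tau_max, curves = curves,
                 fit = fit, provenance = obj$provenance),
            class = "centile_standard")
}

#' Export percentile curves as a tidy CSV table
#'
#' One schema serves both fitted standards and generator truth surfaces,
#' so recovery can be checked by diffing two files: columns \code{age},
#' \code{sex}, \code{analyte}, \code{P}, \code{value}.
#'
#' @param stds a \code{\link{standard_set}} (or list of standards).
#' @param path file path; \code{NULL} returns the data.frame only.
#' @param percentiles percentiles to tabulate.
#' @param by age grid step in years.
#' @return the tidy data.frame, invisibly if written.
#' @export
write_curves <- function(stds, path = NULL,
                         percentiles = c(3, 10, 25, 50, 75, 90, 97),
                         by = 0.1) {
  if (inherits(stds, "centile_standard")) stds <- list(stds)
  out <- do.call(rbind, lapply(stds, function(std) {
    ages <- seq(std$age_domain[1], std$age_domain[2], by = by)
    do.call(rbind, lapply(percentiles, function(P)
      data.frame(age = ages, sex = std$sex, analyte = std$analyte, P = P,
                 value = percentile_curve(std, P, ages))))
  }))
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Percentile curves of the generator truth, in the same tidy schema
#'
#' @param cfg a \code{"generator_config"}.
#' @inheritParams write_curves
#' @param analytes analytes to tabulate.
#' @return the tidy data.frame.
#' @export
truth_curves <- function(cfg, percentiles = c(3, 10, 25, 50, 75, 90, 97),
                         by = 0.1, analytes = c("fT3", "fT4", "TSH", "ratio")) {
  out <- do.call(rbind, lapply(analytes, function(an)
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      ages <- seq(0, cfg$age_max, by = by)
      p <- true_params(an, ages, sx, cfg)
      do.call(rbind, lapply(percentiles, function(P)
        data.frame(age = ages, sex = sx, analyte = an, P = P,
                   value = qbcpe(P / 100, p$mu, p$sigma, p$nu, p$tau))))
    }))))
  rownames(out) <- NULL
  out
}

.md5_of_file <- function(path) unname(tools::md5sum(path))

#' Run the full simulate-clean-fit pipeline
#'
#' Generates (or reads) a cohort, applies the cleaning rules, fits one
#' standard per analyte and sex, and writes every artifact with
#' provenance (input hash, seed) to an output directory:
#' \code{cohort.csv}, \code{cleaning_report.json},
#' \code{standards/<analyte>_<sex>.json} and \code{curves.csv}.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the generator.
#' @param cfg a \code{"generator_config"}; ignored when \code{cohort_csv}
#'   is given.
#' @param cohort_csv optional path to an existing cohort CSV to use
#'   instead of simulating.
#' @param fit_cfg a \code{\link{fit_config}}.
#' @param analytes analytes to fit.
#' @param n_total cohort size when simulating (default: the full design).
#' @return invisibly, a list with the retained cohort, the
#'   \code{\link{standard_set}}, the cleaning report and the artifact
#'   paths.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         cfg = default_generator_config(),
                         cohort_csv = NULL,
                         fit_cfg = fit_config(),
                         analytes = c("fT3", "fT4", "TSH", "ratio"),
                         n_total = cfg$cohort$n_total) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "standards"), showWarnings = FALSE)

  if (is.null(cohort_csv)) {
    message("[simulate] generating cohort (seed ", seed, ")")
    cohort <- generate_cohort(cfg, seed = seed, n_total = n_total)
    cohort_csv <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, cohort_csv)
  } else {
    message("[simulate] reading cohort from ", cohort_csv)
    cohort <- read_cohort(cohort_csv)
  }
  input_hash <- .md5_of_file(cohort_csv)

  message("[clean] applying exclusion rules")
  cleaned <- apply_filters(cohort)
  message(sprintf("[clean] %d in -> %d retained", cleaned$report$n_input,
                  cleaned$report$n_retained))
  write_cleaning_report(cleaned$report,
                        file.path(out_dir, "cleaning_report.json"))

  stds <- list()
  for (an in analytes) for (sx in c("female", "male")) {
    message(sprintf("[fit] %s / %s", an, sx))
    std <- fit_standard(cleaned$retained, an, sx, fit_cfg)
    message(sprintf("[fit]   n=%d logLik=%.1f cycles=%d", std$fit$n,
                    std$fit$logLik, std$fit$iterations))
    prov <- list(input_md5 = input_hash, seed = seed,
                 fit_df = as.list(fit_cfg$df), nseg = fit_cfg$nseg)
    write_standard(std, file.path(out_dir, "standards",
                                  sprintf("%s_%s.json", an, sx)), prov)
    stds <- c(stds, list(std))
  }
  stds <- standard_set(stds)
  write_curves(stds, file.path(out_dir, "curves.csv"))

  invisible(list(retained = cleaned$retained, report = cleaned$report,
                 standards = stds,
                 paths = list(cohort = cohort_csv,
                              cleaning_report = file.path(out_dir, "cleaning_report.json"),
                              standards_dir = file.path(out_dir, "standards"),
                              curves = file.path(out_dir, "curves.csv"))))
}
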