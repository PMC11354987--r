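#' @title Percentile-threshold screening for thyroid hormone resistance
#'
#' @description
#' Thyroid-hormone-resistance syndromes (MCT8/SLC16A2 deficiency, THR-alpha
#' resistance, SECISBP2 deficiency) present with normal TSH and often
#' normal absolute free-hormone levels, but a shifted fT3/fT4 ratio.
#' Screening therefore places a patient's measurements on the age- and
#' sex-specific centile standards and classifies the ratio percentile:
#' elevated ratios point towards MCT8/THR-alpha patterns, reduced ratios
#' towards SECISBP2 patterns.  The output is a screening pattern, not a
#' diagnosis.
#' @name screening
NULL

#' Compute the fT3/fT4 ratio from canonical values
#'
#' Both inputs must already be in pmol/L (use \code{\link{to_canonical}});
#' the ratio is then dimensionless.
#'
#' @param ft3,ft4 positive free-hormone concentrations in pmol/L.
#' @return \code{ft3 / ft4}.
#' @examples
#' compute_ratio(7.05, 16.5)   # 0.4273, the birth-median ratio
#' @export
compute_ratio <- function(ft3, ft4) {
  if (any(!is.finite(ft3)) || any(!is.finite(ft4)) ||
      any(ft3 <= 0) || any(ft4 <= 0))
    stop("fT3 and fT4 must be positive canonical (pmol/L) values",
         call. = FALSE)
  ft3 / ft4
}

#' Classify a ratio percentile into a screening category
#'
#' Boundaries follow the published patterns: below the 3rd percentile is
#' \code{reduced} (SECISBP2-like); the 90th up to and including the 97th
#' is \code{borderline_elevated} ("at or above the 90th"); strictly above
#' the 97th is \code{elevated} (MCT8/THR-alpha-like); everything between
#' is \code{normal}.
#'
#' @param percentile ratio percentile(s) in (0, 100).
#' @return factor with ordered levels
#'   \code{reduced < normal < borderline_elevated < elevated}.
#' @export
classify_ratio <- function(percentile) {
  stopifnot(all(is.finite(percentile)))
  lv <- c("reduced", "normal", "borderline_elevated", "elevated")
  out <- ifelse(percentile < 3, "reduced",
         ifelse(percentile < 90, "normal",
         ifelse(percentile <= 97, "borderline_elevated", "elevated")))
  factor(out, levels = lv, ordered = TRUE)
}

#' A single patient measurement for screening
#'
#' @param age age in decimal years.
#' @param sex \code{"female"} or \code{"male"}.
#' @param tsh,ft3,ft4 \code{\link{quantity}} objects (any registered
#'   unit), or plain numbers taken to be in canonical units.
#' @param label optional free-text label.
#' @return a list of class \code{"patient_measurement"}.
#' @export
patient_measurement <- function(age, sex = c("female", "male"),
                                tsh, ft3, ft4, label = NULL) {
  sex <- match.arg(sex)
  as_q <- function(x, analyte) {
    if (inherits(x, "thyro_quantity")) {
      if (x$analyte != analyte)
        stop("quantity is for ", x$analyte, ", expected ", analyte,
             call. = FALSE)
      x
    } else quantity(x, analyte, .canonical_unit[[analyte]])
  }
  structure(list(age = age, sex = sex,
                 tsh = as_q(tsh, "TSH"), ft3 = as_q(ft3, "fT3"),
                 ft4 = as_q(ft4, "fT4"), label = label),
            class = "patient_measurement")
}

.std_key <- function(analyte, sex) paste(analyte, sex, sep = ".")

#' Assemble a set of standards for screening
#'
#' @param ... \code{"centile_standard"} objects (any order); one per
#'   analyte/sex pair, covering at least fT3, fT4 and ratio for the sexes
#'   to be screened.
#' @return a named list of class \code{"standard_set"} keyed by
#'   \code{analyte.sex}.
#' @export
standard_set <- function(...) {
  stds <- list(...)
  if (length(stds) == 1 && is.list(stds[[1]]) &&
      !inherits(stds[[1]], "centile_standard"))
    stds <- stds[[1]]
  stopifnot(all(vapply(stds, inherits, TRUE, "centile_standard")))
  names(stds) <- vapply(stds, function(s) .std_key(s$analyte, s$sex), "")
  structure(stds, class = "standard_set")
}

#' Screen one patient against fitted centile standards
#'
#' Converts the measurements to canonical units, recomputes the fT3/fT4
#' ratio from the converted values, evaluates per-analyte SDS and
#' percentiles against the patient's age/sex standards, and classifies
#' the ratio percentile (\code{\link{classify_ratio}}).  TSH above
#' 10 mU/L does not abort screening but attaches a prominent flag: such
#' patients fall outside the reference population of the ratio chart
#' (primary hypothyroidism pattern), so the ratio category must not be
#' interpreted as a resistance screen.
#'
#' @param m a \code{\link{patient_measurement}}.
#' @param standards a \code{\link{standard_set}} containing fT3, fT4 and
#'   ratio standards (TSH optional) for the patient's sex, whose age
#'   domains cover the patient's age; ages outside the domain are an
#'   error, never extrapolated.
#' @return a list of class \code{"screening_result"}: canonical values,
#'   \code{ratio}, per-analyte \code{sds} and \code{percentile},
#'   \code{category}, and \code{flags}.
#' @export
screen_patient <- function(m, standards) {
  stopifnot(inherits(m, "patient_measurement"),
            inherits(standards, "standard_set"))
  can <- c(tsh = convert(m$tsh, "mU/L")$value,
           ft3 = convert(m$ft3, "pmol/L")$value,
           ft4 = convert(m$ft4, "pmol/L")$value)
  ratio <- compute_ratio(can[["ft3"]], can[["ft4"]])

  need <- c("fT3", "fT4", "ratio")
  have <- names(standards)
  vals <- c(fT3 = can[["ft3"]], fT4 = can[["ft4"]], TSH = can[["tsh"]],
            ratio = ratio)
  sds <- percentile <- c()
  for (an in c(need, if (.std_key("TSH", m$sex) %in% have) "TSH")) {
    key <- .std_key(an, m$sex)
    if (!key %in% have)
      stop("no ", an, " standard for sex ", m$sex, " in the standard set",
           call. = FALSE)
    std <- standards[[key]]
    sds[an] <- sds_of(std, m$age, vals[[an]])
    percentile[an] <- percentile_of(std, m$age, vals[[an]])
  }

  flags <- character(0)
  if (can[["tsh"]] > 10)
    flags <- c(flags, paste("TSH > 10 mU/L: primary hypothyroidism",
                            "pattern - ratio screening not applicable"))

  structure(list(age = m$age, sex = m$sex, label = m$label,
                 canonical = can, ratio = ratio,
                 sds = sds, percentile = percentile,
                 category = classify_ratio(percentile[["ratio"]]),
                 flags = flags),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening result%s: %s, %.2f y\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              x$sex, x$age))
  cat(sprintf("  TSH %.3g mU/L | fT3 %.3g pmol/L | fT4 %.3g pmol/L | ratio %.4f\n",
              x$canonical[["tsh"]], x$canonical[["ft3"]],
              x$canonical[["ft4"]], x$ratio))
  for (an in names(x$sds))
    cat(sprintf("  %-5s SDS %+6.2f  percentile %6.2f\n",
                an, x$sds[[an]], x$percentile[[an]]))
  cat("  ratio category:", as.character(x$category), "\n")
  for (f in x$flags) cat("  !! ", f, "\n")
  invisible(x)
}

#' Screen a table of patients
#'
#' @param patients a data.frame with columns \code{age_years}, \code{sex}
#'   (female/male), \code{tsh_mU_L}, \code{ft3_pmol_L}, \code{ft4_pmol_L}
#'   (canonical units), e.g. from \code{\link{generate_patients}}.
#' @param standards a \code{\link{standard_set}}.
#' @return a data.frame with the ratio, per-analyte SDS/percentile,
#'   category and TSH flag per patient.
#' @export
screen_table <- function(patients, standards) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    r <- screen_patient(
      patient_measurement(p$age_years, p$sex, p$tsh_mU_L, p$ft3_pmol_L,
                          p$ft4_pmol_L,
                          label = if ("label" %in% names(patients)) p$label),
      standards)
    data.frame(label = if (is.null(r$label)) NA_character_ else r$label,
               age_years = r$age, sex = r$sex, ratio = r$ratio,
               ratio_sds = r$sds[["ratio"]],
               ratio_percentile = r$percentile[["ratio"]],
               ft3_percentile = r$percentile[["fT3"]],
               ft4_percentile = r$percentile[["fT4"]],
               category = as.character(r$category),
               tsh_flag = length(r$flags) > 0)
  })
  do.call(rbind, rows)
}
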