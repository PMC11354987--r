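#' Exclusion rules for the reference population
#'
#' Before centile estimation, raw cohort records are cleaned by removing
#' measurement occasions from individuals who cannot serve as thyroid
#' reference subjects.  Four rules are applied, in this fixed order, and
#' each removed record is attributed to the first rule it fails:
#'
#' \enumerate{
#'   \item \code{disease_history}: any history of thyroid disease;
#'   \item \code{tsh_gt_10}: TSH strictly above 10 mU/L;
#'   \item \code{medication}: medication affecting thyroid hormone
#'     metabolism (e.g. L-thyroxine, iodine);
#'   \item \code{iodine_gt_1.08}: urinary iodine excretion strictly above
#'     1.08 mg/d.
#' }
#'
#' "Above" is read strictly, so boundary values (TSH = 10 mU/L,
#' iodine = 1.08 mg/d) are retained.  Missing iodine excretion does not
#' exclude (the oldest sub-cohort lacks it).  Records, not subjects, are
#' the unit of analysis: repeated visits of one child are filtered
#' independently.
#'
#' @param records a cohort data.frame in canonical units, as produced by
#'   \code{\link{generate_cohort}} or \code{\link{read_cohort}} (columns
#'   \code{tsh_mU_L}, \code{disease_history}, \code{medication},
#'   \code{iodine_mg_d} are used).
#' @return a list of class \code{"cleaning_result"} with elements
#'   \code{retained} (data.frame of surviving records), \code{rejected}
#'   (data.frame with an extra column \code{failed_rule}), and
#'   \code{report}, a \code{"cleaning_report"} with counts \code{n_input},
#'   \code{n_retained} and \code{n_removed_per_rule}.
#' @examples
#' cfg <- default_generator_config()
#' coh <- generate_cohort(cfg, seed = 1, n_total = 500)
#' res <- apply_filters(coh)
#' res$report
#' @export
apply_filters <- function(records) {
  required <- c("tsh_mU_L", "disease_history", "medication", "iodine_mg_d")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("cohort records lack required canonical-unit columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  rules <- c("disease_history", "tsh_gt_10", "medication", "iodine_gt_1.08")
  fails <- cbind(
    disease_history  = records$disease_history %in% TRUE |
                       records$disease_history %in% 1,
    tsh_gt_10        = !is.na(records$tsh_mU_L) & records$tsh_mU_L > 10,
    medication       = records$medication %in% TRUE | records$medication %in% 1,
    `iodine_gt_1.08` = !is.na(records$iodine_mg_d) & records$iodine_mg_d > 1.08
  )
  first_fail <- apply(fails, 1L, function(f) {
    i <- which(f)
    if (length(i)) rules[i[1L]] else NA_character_
  })

  keep <- is.na(first_fail)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$failed_rule <- first_fail[!keep]
  n_per_rule <- vapply(rules, function(r) sum(first_fail == r, na.rm = TRUE),
                       integer(1))

  report <- structure(
    list(n_input = nrow(records), n_retained = sum(keep),
         n_removed_per_rule = n_per_rule),
    class = "cleaning_report")
  stopifnot(report$n_input == report$n_retained + sum(n_per_rule))

  structure(list(retained = records[keep, , drop = FALSE],
                 rejected = rejected, report = report),
            class = "cleaning_result")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cohort cleaning report\n")
  cat(sprintf("  records in:  %d\n  retained:    %d\n", x$n_input, x$n_retained))
  for (r in names(x$n_removed_per_rule))
    cat(sprintf("  removed (%s): %d\n", r, x$n_removed_per_rule[[r]]))
  invisible(x)
}

#' @export
print.cleaning_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Export a cleaning report as JSON
#'
#' @param report a \code{"cleaning_report"}.
#' @param path file path to write to.
#' @return \code{path}, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(
    list(n_input = report$n_input, n_retained = report$n_retained,
         n_removed_per_rule = as.list(report$n_removed_per_rule)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
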