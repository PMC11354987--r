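#' @title Synthetic cohort and patient-profile generation
#'
#' @description Draws reference-population records and pathological
#' patient profiles from the calibrated truth surfaces
#' (see \link{synthetic_truth}).
#' @name synthetic_cohort
NULL

## visit-count law on {1..8}: 1 + beta-binomial(kmax-1, a, b), moment-matched
## to the target mean and SD.  A plain shifted binomial cannot reach the
## target overdispersion (max SD ~1.03 at mean 2.3), the beta-binomial can.
.visit_betabin_shape <- function(mean, sd, kmax = 8L) {
  n <- kmax - 1L
  pi <- (mean - 1) / n
  stopifnot(pi > 0, pi < 1)
  v <- sd^2
  rho <- (v / (n * pi * (1 - pi)) - 1) / (n - 1)
  if (rho <= 0 || rho >= 1)
    stop("visit-count moments not attainable by a shifted beta-binomial",
         call. = FALSE)
  ab <- 1 / rho - 1
  c(a = pi * ab, b = (1 - pi) * ab)
}

.rvisits <- function(n, mean, sd, kmax = 8L) {
  sh <- .visit_betabin_shape(mean, sd, kmax)
  p <- stats::rbeta(n, sh["a"], sh["b"])
  1L + stats::rbinom(n, kmax - 1L, p)
}

## independent sub-streams derived from one master seed, so that e.g.
## changing the contamination fraction cannot perturb the hormone draws
.stream_seeds <- function(seed, k = 5L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

.draw_hormones <- function(age, sex, cfg) {
  out <- data.frame(tsh_mU_L = NA_real_, ft3_pmol_L = NA_real_,
                    ft4_pmol_L = NA_real_)[rep(1, length(age)), , drop = FALSE]
  rownames(out) <- NULL
  for (s in c("female", "male")) {
    i <- which(sex == s)
    if (!length(i)) next
    pr <- true_params("ratio", age[i], s, cfg)
    p4 <- true_params("fT4", age[i], s, cfg)
    pt <- true_params("TSH", age[i], s, cfg)
    ratio <- rbcpe(length(i), pr$mu, pr$sigma, pr$nu, pr$tau)
    ft4 <- rbcpe(length(i), p4$mu, p4$sigma, p4$nu, p4$tau)
    tsh <- rbcpe(length(i), pt$mu, pt$sigma, pt$nu, pt$tau)
    ## reference subjects must pass the TSH filter; redraw the (rare) tail
    while (any(bad <- tsh > 10))
      tsh[bad] <- rbcpe(sum(bad), pt$mu[bad], pt$sigma[bad], pt$nu[bad],
                        pt$tau[bad])
    out$tsh_mU_L[i] <- tsh
    out$ft4_pmol_L[i] <- ft4
    out$ft3_pmol_L[i] <- ratio * ft4   # within-record coupling of fT3 to fT4
  }
  out
}

#' Generate a synthetic reference cohort
#'
#' Emulates the structure of the pooled surveys behind the published
#' charts: a longitudinal 0-6 y sub-cohort (\code{LIFE} tag; children
#' with 1-8 visits each, visit counts moment-matched to mean 2.3 /
#' SD 1.51), a 3-17 y cross-sectional sub-cohort (\code{KIGGS_BASE})
#' and a 10-29 y cross-sectional sub-cohort (\code{KIGGS_W2}); sub-cohort
#' sizes are scaled so the clean record count and female record count hit
#' the configured totals exactly (defaults 23,522 and 11,325).  Labelled
#' contaminant records (one cleaning rule each) are appended on top.
#'
#' fT3 is generated as an independent ratio draw times the fT4 draw, so
#' the fT3/fT4 ratio itself is exactly BCPE-distributed at every age.
#' Urinary iodine excretion is present for the two pediatric sub-cohorts
#' and missing for the 10-29 y one.
#'
#' @param cfg a \code{"generator_config"}.
#' @param seed integer master seed; sub-streams for visits, ages, sexes,
#'   hormones and contamination are derived from it independently.
#' @param n_total clean record count (default from \code{cfg}); sub-cohort
#'   sizes and the female count are scaled proportionally.
#' @param contamination named per-rule fractions of \code{n_total}; use
#'   \code{c()} for a contaminant-free cohort.
#' @return a data.frame with columns \code{subject_id}, \code{visit},
#'   \code{sex} (F/M), \code{age_years}, \code{tsh_mU_L},
#'   \code{ft3_pmol_L}, \code{ft4_pmol_L}, \code{disease_history},
#'   \code{medication}, \code{iodine_mg_d}, \code{cohort_tag},
#'   \code{contaminant_rule} (NA for clean records).
#' @export
generate_cohort <- function(cfg, seed, n_total = cfg$cohort$n_total,
                            contamination = cfg$contamination) {
  stopifnot(inherits(cfg, "generator_config"), n_total >= 50)
  co <- cfg$cohort
  scale <- n_total / co$n_total
  n_life_children <- max(1L, round(co$life_children * scale))
  n_female_target <- round(co$n_female * scale)
  ss <- .stream_seeds(seed, 5L)

  ## stream 1: visit counts
  set.seed(ss[1])
  visits <- .rvisits(n_life_children, co$visit_mean, co$visit_sd,
                     co$visit_range[2])
  n_life <- sum(visits)
  if (n_life >= n_total)
    stop("cohort too small for the longitudinal sub-cohort", call. = FALSE)
  n_kiggs <- n_total - n_life
  n_base <- round(n_kiggs * co$base_share)
  n_w2 <- n_kiggs - n_base

  ## stream 2: ages (longitudinal children: sorted visit ages)
  set.seed(ss[2])
  life_child <- rep(seq_len(n_life_children), visits)
  age_life <- unlist(lapply(visits, function(v)
    sort(stats::runif(v, co$life_age[1], co$life_age[2]))))
  age_base <- stats::runif(n_base, co$base_age[1], co$base_age[2])
  age_w2 <- stats::runif(n_w2, co$w2_age[1], co$w2_age[2])

  ## stream 3: sexes, with the overall female record count exact
  set.seed(ss[3])
  p_f <- n_female_target / n_total
  sex_child <- ifelse(stats::runif(n_life_children) < p_f, "female", "male")
  sex_life <- sex_child[life_child]
  f_life <- sum(sex_life == "female")
  f_kiggs <- n_female_target - f_life
  if (f_kiggs < 0 || f_kiggs > n_kiggs)
    stop("cannot reach the target female count with this sub-cohort draw",
         call. = FALSE)
  f_base <- min(n_base, max(0L, round(f_kiggs * n_base / n_kiggs)))
  f_w2 <- f_kiggs - f_base
  if (f_w2 > n_w2) { f_base <- f_base + (f_w2 - n_w2); f_w2 <- n_w2 }
  sex_base <- sample(c(rep("female", f_base), rep("male", n_base - f_base)))
  sex_w2 <- sample(c(rep("female", f_w2), rep("male", n_w2 - f_w2)))

  age <- c(age_life, age_base, age_w2)
  sex <- c(sex_life, sex_base, sex_w2)
  tag <- c(rep("LIFE", n_life), rep("KIGGS_BASE", n_base),
           rep("KIGGS_W2", n_w2))
  subject_id <- c(sprintf("LIFE%05d", life_child),
                  sprintf("KB%06d", seq_len(n_base)),
                  sprintf("KW%06d", seq_len(n_w2)))
  visit <- c(unlist(lapply(visits, seq_len)), rep(1L, n_kiggs))

  ## stream 4: hormone values and iodine excretion
  set.seed(ss[4])
  horm <- .draw_hormones(age, sex, cfg)
  iodine <- rep(NA_real_, n_total)
  ped <- tag != "KIGGS_W2"
  io <- stats::rlnorm(sum(ped), log(0.12), 0.5)
  while (any(bad <- io > 1.08))            # clean records pass the iodine rule
    io[bad] <- stats::rlnorm(sum(bad), log(0.12), 0.5)
  iodine[ped] <- io

  clean <- data.frame(subject_id = subject_id, visit = visit,
                      sex = ifelse(sex == "female", "F", "M"),
                      age_years = age, horm,
                      disease_history = 0L, medication = 0L,
                      iodine_mg_d = iodine, cohort_tag = tag,
                      contaminant_rule = NA_character_,
                      stringsAsFactors = FALSE)

  ## stream 5: labelled contaminants, appended on top of the clean records
  set.seed(ss[5])
  cont <- NULL
  if (length(contamination)) {
    n_rule <- round(unlist(contamination) * n_total)
    n_rule <- n_rule[n_rule > 0]
    if (length(n_rule)) {
      nc <- sum(n_rule)
      age_c <- stats::runif(nc, 0, cfg$age_max)
      sex_c <- ifelse(stats::runif(nc) < p_f, "female", "male")
      hc <- .draw_hormones(age_c, sex_c, cfg)
      rule <- rep(names(n_rule), n_rule)
      cont <- data.frame(subject_id = sprintf("CONT%05d", seq_len(nc)),
                         visit = 1L,
                         sex = ifelse(sex_c == "female", "F", "M"),
                         age_years = age_c, hc,
                         disease_history = as.integer(rule == "disease_history"),
                         medication = as.integer(rule == "medication"),
                         iodine_mg_d = NA_real_, cohort_tag = "CONTAM",
                         contaminant_rule = rule, stringsAsFactors = FALSE)
      cont$tsh_mU_L[rule == "tsh_gt_10"] <-
        stats::runif(sum(rule == "tsh_gt_10"), 10.5, 25)
      cont$iodine_mg_d[rule == "iodine_gt_1.08"] <-
        stats::runif(sum(rule == "iodine_gt_1.08"), 1.2, 3.0)
    }
  }
  out <- rbind(clean, cont)
  rownames(out) <- NULL
  out
}

.profile_specs <- list(
  MCT8_severe = list(ft3 = c(3, 5),     ft4 = c(-2, 0),       age = c(0.9, 12)),
  MCT8_mild   = list(ft3 = c(1.5, 2.5), ft4 = c(-1.5, -0.5),  age = c(0.9, 12)),
  THRA        = list(ft3 = c(1, 1.8),   ft4 = c(-1.8, -1),    age = c(0.9, 12)),
  THRA_cterm  = list(ft3 = c(0.3, 0.4), ft4 = c(-0.55, -0.5), age = c(0.9, 12)),
  SECISBP2    = list(ft3 = c(-1.5, 0),  ft4 = c(2, 4),        age = c(0.9, 12)),
  CP_control  = list(age = c(1.3, 16.7))
)

#' Names of the available synthetic patient profiles
#' @return character vector of profile names.
#' @export
patient_profiles <- function() names(.profile_specs)

#' Generate synthetic patient measurements for a screening profile
#'
#' Pathological profiles are defined as SDS-offset zones relative to the
#' truth surfaces, never in absolute units: free-hormone SDS offsets are
#' drawn uniformly from the profile's zone and mapped through the truth
#' quantile functions of fT3 and fT4 at the patient's age and sex.
#' \code{MCT8_severe} places fT3 at +3 to +5 SDS with fT4 at -2 to 0;
#' \code{MCT8_mild} is a milder variant; \code{THRA} stays inside the
#' marginal normal bands (fT3 +1 to +1.8, fT4 -1.8 to -1) yet has a
#' clearly elevated ratio; \code{THRA_cterm} targets a ratio around the
#' 90th-97th band; \code{SECISBP2} has elevated fT4 (+2 to +4) with
#' low-normal fT3.  \code{CP_control} draws from the reference population
#' itself (independent N(0,1) SDS for the ratio and fT4, fT3 derived), so
#' its ratio percentile is uniform by construction.  TSH is always drawn
#' from the normal truth surface (thyroid-hormone-resistance syndromes
#' present with normal TSH).
#'
#' @param profile one of \code{\link{patient_profiles}}.
#' @param n number of patients.
#' @param cfg a \code{"generator_config"}.
#' @param seed integer seed.
#' @return a data.frame with columns \code{label}, \code{age_years},
#'   \code{sex} (female/male), \code{tsh_mU_L}, \code{ft3_pmol_L},
#'   \code{ft4_pmol_L} (canonical units).
#' @export
generate_patients <- function(profile, n, cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"), n >= 1)
  if (!profile %in% names(.profile_specs))
    stop("unknown profile '", profile, "'; available: ",
         paste(names(.profile_specs), collapse = ", "), call. = FALSE)
  sp <- .profile_specs[[profile]]
  set.seed(seed)
  age <- stats::runif(n, sp$age[1], sp$age[2])
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  ft3 <- ft4 <- tsh <- numeric(n)
  for (s in c("female", "male")) {
    i <- which(sex == s)
    if (!length(i)) next
    p3 <- true_params("fT3", age[i], s, cfg)
    p4 <- true_params("fT4", age[i], s, cfg)
    pt <- true_params("TSH", age[i], s, cfg)
    if (identical(profile, "CP_control")) {
      pr <- true_params("ratio", age[i], s, cfg)
      ratio <- qbcpe(stats::pnorm(stats::rnorm(length(i))),
                     pr$mu, pr$sigma, pr$nu, pr$tau)
      ft4[i] <- qbcpe(stats::pnorm(stats::rnorm(length(i))),
                      p4$mu, p4$sigma, p4$nu, p4$tau)
      ft3[i] <- ratio * ft4[i]
    } else {
      s3 <- stats::runif(length(i), sp$ft3[1], sp$ft3[2])
      s4 <- stats::runif(length(i), sp$ft4[1], sp$ft4[2])
      ft3[i] <- qbcpe(stats::pnorm(s3), p3$mu, p3$sigma, p3$nu, p3$tau)
      ft4[i] <- qbcpe(stats::pnorm(s4), p4$mu, p4$sigma, p4$nu, p4$tau)
    }
    tsh[i] <- qbcpe(stats::pnorm(stats::rnorm(length(i))),
                    pt$mu, pt$sigma, pt$nu, pt$tau)
  }
  data.frame(label = profile, age_years = age, sex = sex,
             tsh_mU_L = tsh, ft3_pmol_L = ft3, ft4_pmol_L = ft4,
             stringsAsFactors = FALSE)
}
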