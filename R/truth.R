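#' @title Parametric truth surfaces for the synthetic cohort
#'
#' @description
#' The real survey data behind published pediatric thyroid centile charts
#' are access-restricted, so validation of the fitting pipeline runs on a
#' synthetic cohort drawn from fully known ("truth") age- and sex-specific
#' BCPE parameter surfaces.  The surfaces are calibrated so that their
#' centiles hit the published anchor values exactly:
#' fT3 median 7.05 pmol/L at birth declining to 4.7 pmol/L in adulthood,
#' fT4 median 16.5 declining to 12.5 pmol/L, fT3/fT4-ratio medians with
#' sex-specific pubertal peaks at 11.2 y (girls) and 13.3 y (boys), a
#' maximal male ratio 97th centile of 0.59 and a minimal female ratio 3rd
#' centile of 0.27 (at 17 y).
#'
#' Structurally, every median declines from its birth anchor to an adult
#' plateau reached at 22 y via a C2-smooth (quintic smoothstep) decay.
#' The ratio median adds a compactly supported pubertal bump per sex; the
#' female ratio dispersion adds a late-pubertal bump so that the 3rd
#' centile attains its minimum at 17 y.  fT3 is defined as ratio x fT4
#' (the generator draws the ratio and fT4 independently and multiplies),
#' so the ratio chart is exactly BCPE-distributed; the fT3 surface is the
#' implied product, with dispersion combined in quadrature.
#'
#' @name synthetic_truth
NULL

## quintic smoothstep (C2 at both ends) and its derivative
.s5 <- function(x) x^3 * (10 - 15 * x + 6 * x^2)
.s5d <- function(x) 30 * x^2 * (1 - x)^2

## decay from 1 at age 0 to exactly 0 at the plateau age (default 22 y)
.decay <- function(t, plateau = 22) {
  x <- pmin(pmax(t / plateau, 0), 1)
  1 - .s5(x)
}
.decay_d <- function(t, plateau = 22) {
  x <- t / plateau
  ifelse(x <= 0 | x >= 1, 0, -.s5d(x) / plateau)
}

## compactly supported tricube-like bump kernel (1 - u^2)^3: K(0) = 1,
## K and its first two derivatives vanish at |u| = 1 (C2 overall), with
## gentle shoulders that smooth fits can track
.bumpK <- function(u) {
  out <- numeric(length(u))
  i <- abs(u) < 1
  out[i] <- (1 - u[i]^2)^3
  out
}
.bumpK_d <- function(u) {
  out <- numeric(length(u))
  i <- abs(u) < 1
  out[i] <- -6 * u[i] * (1 - u[i]^2)^2
  out
}

#' Published anchor values used to calibrate the synthetic truth
#'
#' @return a named list of anchors: birth/adult medians for fT3 and fT4
#'   (pmol/L), sex-specific pubertal peak ages of the ratio median
#'   (years), the maximal male ratio 97th centile, the minimal female
#'   ratio 3rd centile, and the age (years) at which the female minimum
#'   occurs.
#' @export
default_anchors <- function() {
  list(ft3_birth = 7.05, ft3_adult = 4.7,
       ft4_birth = 16.5, ft4_adult = 12.5,
       peak_age_female = 11.2, peak_age_male = 13.3,
       ratio_p97_male_max = 0.59,
       ratio_p3_female_min = 0.27, ratio_p3_female_min_age = 17)
}

.ratio_mu <- function(t, sex, cfg) {
  r <- cfg$ratio
  b <- r$bump[[sex]]
  r$adult + r$amp * .decay(t, cfg$plateau_age) + b$h * .bumpK((t - b$c) / b$w)
}
.ratio_mu_d <- function(t, sex, cfg) {
  r <- cfg$ratio
  b <- r$bump[[sex]]
  r$amp * .decay_d(t, cfg$plateau_age) + b$h / b$w * .bumpK_d((t - b$c) / b$w)
}
.ratio_sigma <- function(t, sex, cfg) {
  r <- cfg$ratio
  s <- r$sigma0 + numeric(length(t))
  if (sex == "female" && !is.null(r$sigma_bump_female)) {
    sb <- r$sigma_bump_female
    s <- s + sb$s * .bumpK((t - sb$c) / sb$w)
  }
  s
}
.ratio_sigma_d <- function(t, sex, cfg) {
  r <- cfg$ratio
  if (sex == "female" && !is.null(r$sigma_bump_female)) {
    sb <- r$sigma_bump_female
    sb$s / sb$w * .bumpK_d((t - sb$c) / sb$w)
  } else numeric(length(t))
}
.ft4_mu <- function(t, cfg) cfg$ft4$adult + cfg$ft4$amp * .decay(t, cfg$plateau_age)
.tsh_mu <- function(t, cfg) cfg$tsh$adult + cfg$tsh$amp * .decay(t, cfg$plateau_age)

#' Evaluate the truth BCPE parameters of the synthetic population
#'
#' @param analyte one of \code{"fT3"}, \code{"fT4"}, \code{"TSH"},
#'   \code{"ratio"}.
#' @param age decimal ages in years, within \code{[0, cfg$age_max]}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param cfg a generator configuration, see
#'   \code{\link{default_generator_config}}.
#' @return a data.frame with one row per age and columns \code{mu},
#'   \code{sigma}, \code{nu}, \code{tau}.
#' @export
true_params <- function(analyte = c("fT3", "fT4", "TSH", "ratio"),
                        age, sex = c("female", "male"), cfg) {
  analyte <- match.arg(analyte)
  sex <- match.arg(sex)
  stopifnot(inherits(cfg, "generator_config"))
  if (any(age < 0 | age > cfg$age_max))
    stop(sprintf("age out of range [0, %g]", cfg$age_max), call. = FALSE)
  switch(analyte,
    ratio = data.frame(mu = .ratio_mu(age, sex, cfg),
                       sigma = .ratio_sigma(age, sex, cfg),
                       nu = cfg$ratio$nu, tau = cfg$ratio$tau),
    fT4 = data.frame(mu = .ft4_mu(age, cfg),
                     sigma = cfg$ft4$sigma + numeric(length(age)),
                     nu = cfg$ft4$nu, tau = cfg$ft4$tau),
    fT3 = data.frame(mu = .ratio_mu(age, sex, cfg) * .ft4_mu(age, cfg),
                     sigma = sqrt(.ratio_sigma(age, sex, cfg)^2 +
                                  cfg$ft4$sigma^2),
                     nu = 1, tau = 2),
    TSH = data.frame(mu = .tsh_mu(age, cfg),
                     sigma = cfg$tsh$sigma + numeric(length(age)),
                     nu = cfg$tsh$nu, tau = cfg$tsh$tau))
}

#' Calibrate the synthetic truth surfaces to the published anchors
#'
#' One-dimensional root finding (nested where a location and a height
#' interact) determines, in order: the female and male pubertal bump
#' centers (so the ratio median is stationary exactly at the published
#' peak ages), the male bump height (so the male ratio 97th centile at
#' its peak equals the published maximum), and the female dispersion
#' bump (height and center, so the female ratio 3rd centile attains the
#' published minimum exactly at its published age).  Every solved
#' constraint holds to better than 1e-6.
#'
#' @param anchors a named anchor list, see \code{\link{default_anchors}}.
#' @param contamination named fractions of injected contaminant records
#'   per cleaning rule.
#' @param sigma0 baseline relative dispersion of the ratio.
#' @param ft4_sigma relative dispersion of fT4.
#' @param bump_height_female height of the female pubertal ratio-median
#'   bump (the male height is solved from the 97th-centile anchor).
#' @param bump_width_female,bump_width_male,sigma_bump_width half-widths
#'   (years) of the pubertal median bumps and of the female dispersion
#'   bump.
#' @return an object of class \code{"generator_config"}.
#' @export
calibrate_generator <- function(anchors = default_anchors(),
                                contamination = c(
                                  disease_history = 0.010,
                                  tsh_gt_10 = 0.005,
                                  medication = 0.010,
                                  `iodine_gt_1.08` = 0.005),
                                sigma0 = 0.075, ft4_sigma = 0.12,
                                bump_height_female = 0.045,
                                bump_width_female = 5,
                                bump_width_male = 7,
                                sigma_bump_width = 5) {
  a <- anchors
  r_birth <- a$ft3_birth / a$ft4_birth
  r_adult <- a$ft3_adult / a$ft4_adult
  if (!(a$ft3_birth > a$ft3_adult && a$ft4_birth > a$ft4_adult &&
        r_birth > r_adult))
    stop("calibration error: anchors violate the declining-median ",
         "constraint (birth anchors must exceed adult anchors, for the ",
         "ratio as well)", call. = FALSE)

  cfg <- structure(list(
    age_max = 29, plateau_age = 22,
    ft4 = list(adult = a$ft4_adult, amp = a$ft4_birth - a$ft4_adult,
               sigma = ft4_sigma, nu = 0.6, tau = 2),
    ratio = list(adult = r_adult, amp = r_birth - r_adult,
                 sigma0 = sigma0, nu = 1, tau = 2,
                 bump = list(female = list(h = bump_height_female,
                                           w = bump_width_female, c = NA),
                             male = list(h = NA, w = bump_width_male, c = NA)),
                 sigma_bump_female = list(s = NA, w = sigma_bump_width, c = NA)),
    tsh = list(adult = 1.5, amp = 1.0, sigma = 0.35, nu = 0, tau = 2),
    cohort = list(n_total = 23522, n_female = 11325,
                  life_children = 2287, visit_range = c(1L, 8L),
                  visit_mean = 2.3, visit_sd = 1.51,
                  life_age = c(0, 6), base_age = c(3, 17),
                  w2_age = c(10, 29),
                  base_share = 12836 / (12836 + 2971)),
    contamination = contamination,
    anchors = a), class = "generator_config")

  ## bump center making the ratio median stationary at the target peak age.
  ## K' rises from 0 at the bump center to its maximum at |u*| ~ 0.76 of the
  ## half-width; restricting the center to within |u*| half-widths right of
  ## the peak selects the root where K'' < 0, i.e. a local maximum.
  u_star <- stats::optimize(function(u) -.bumpK_d(u), c(-1, 0), tol = 1e-8)$minimum
  solve_center <- function(sex, peak) {
    b <- cfg$ratio$bump[[sex]]
    f <- function(ctr) {
      cfg$ratio$bump[[sex]]$c <<- ctr
      .ratio_mu_d(peak, sex, cfg)
    }
    lo <- peak + 1e-9; hi <- peak + abs(u_star) * b$w
    if (f(lo) * f(hi) > 0)
      stop(sprintf("calibration error: cannot place the %s pubertal peak at ",
                   sex), peak, " y (bump height too small for the baseline ",
           "slope)", call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }

  ## female mu bump: fixed height, solved center
  cfg$ratio$bump$female$c <- solve_center("female", a$peak_age_female)

  ## male mu bump: height from the P97 anchor, center re-solved per height
  male_p97 <- function(h) {
    cfg$ratio$bump$male$h <<- h
    cfg$ratio$bump$male$c <<- solve_center("male", a$peak_age_male)
    p <- true_params("ratio", a$peak_age_male, "male", cfg)
    qbcpe(0.97, p$mu, p$sigma, p$nu, p$tau)
  }
  ## smallest height for which the stationarity equation is solvable:
  ## h/w * max K' must exceed the baseline slope at the peak
  kd_max <- .bumpK_d(u_star)
  h_min <- with(cfg$ratio, abs(amp * .decay_d(a$peak_age_male, cfg$plateau_age)) *
                  bump$male$w / kd_max) * 1.05
  h_root <- tryCatch(
    stats::uniroot(function(h) male_p97(h) - a$ratio_p97_male_max,
                   c(h_min, 0.4), tol = 1e-10)$root,
    error = function(e)
      stop("calibration error: male ratio 97th-centile anchor ",
           a$ratio_p97_male_max, " is not attainable with the configured ",
           "dispersion (", conditionMessage(e), ")", call. = FALSE))
  male_p97(h_root)  # leave cfg at the solution

  ## female dispersion bump: center from stationarity of the 3rd centile
  ## at the anchor age, height from its value there
  t_min <- a$ratio_p3_female_min_age
  z03 <- .pe_quantile(0.03, cfg$ratio$tau)
  solve_sigma_center <- function(s) {
    cfg$ratio$sigma_bump_female$s <<- s
    f <- function(ctr) {
      cfg$ratio$sigma_bump_female$c <<- ctr
      .ratio_mu_d(t_min, "female", cfg) *
        (1 + z03 * .ratio_sigma(t_min, "female", cfg)) +
        .ratio_mu(t_min, "female", cfg) * z03 *
          .ratio_sigma_d(t_min, "female", cfg)
    }
    lo <- t_min - abs(u_star) * cfg$ratio$sigma_bump_female$w; hi <- t_min - 1e-9
    if (f(lo) * f(hi) > 0)
      stop("calibration error: cannot place the female 3rd-centile minimum ",
           "at ", t_min, " y", call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  female_p3 <- function(s) {
    cfg$ratio$sigma_bump_female$c <<- solve_sigma_center(s)
    p <- true_params("ratio", t_min, "female", cfg)
    qbcpe(0.03, p$mu, p$sigma, p$nu, p$tau)
  }
  s_root <- tryCatch(
    stats::uniroot(function(s) female_p3(s) - a$ratio_p3_female_min,
                   c(0.01, 0.3), tol = 1e-10)$root,
    error = function(e)
      stop("calibration error: female ratio 3rd-centile anchor ",
           a$ratio_p3_female_min, " is not attainable (",
           conditionMessage(e), ")", call. = FALSE))
  female_p3(s_root)  # leave cfg at the solution

  ## all bump supports must sit inside (0, plateau age)
  supp_ok <- with(cfg$ratio, c(
    bump$female$c - bump$female$w > 0,
    bump$female$c + bump$female$w < cfg$plateau_age,
    bump$male$c + bump$male$w < cfg$plateau_age,
    sigma_bump_female$c + sigma_bump_female$w < cfg$plateau_age))
  if (!all(supp_ok))
    stop("calibration error: a pubertal bump extends beyond the adult ",
         "plateau age; adult anchors would be violated", call. = FALSE)
  cfg
}

#' Default generator configuration (published study conditions)
#'
#' Calibrates the truth surfaces to \code{\link{default_anchors}} and the
#' published cohort structure: 23,522 records (11,325 female), a
#' longitudinal 0-6 y sub-cohort of 2,287 children with 1-8 visits each
#' (mean 2.3, SD 1.51), a 3-17 y cross-sectional sub-cohort and a
#' 10-29 y cross-sectional sub-cohort.
#'
#' @inheritParams calibrate_generator
#' @return a \code{"generator_config"}.
#' @export
default_generator_config <- function(anchors = default_anchors()) {
  calibrate_generator(anchors)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  cohort: %d records (%d female), ages 0-%g y\n",
              x$cohort$n_total, x$cohort$n_female, x$age_max))
  cat(sprintf("  ratio bumps: female h=%.4f c=%.3f w=%g | male h=%.4f c=%.3f w=%g\n",
              x$ratio$bump$female$h, x$ratio$bump$female$c, x$ratio$bump$female$w,
              x$ratio$bump$male$h, x$ratio$bump$male$c, x$ratio$bump$male$w))
  cat(sprintf("  female sigma bump: s=%.4f c=%.3f w=%g\n",
              x$ratio$sigma_bump_female$s, x$ratio$sigma_bump_female$c,
              x$ratio$sigma_bump_female$w))
  invisible(x)
}
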