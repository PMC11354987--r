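# Penalized BCPE fitting: parameter recovery, determinism, smoothing
# behaviour, and agreement with an independent Gaussian oracle in the
# nu = 1, tau = 2 special case.

make_flat_cohort <- function(n, mu = 5, sigma = 0.1, nu = 1, tau = 2,
                             seed = 1, sex = "F") {
  set.seed(seed)
  age <- runif(n, 0, 29)
  data.frame(subject_id = sprintf("S%06d", seq_len(n)), visit = 1L,
             sex = sex, age_years = age,
             tsh_mU_L = 2, ft3_pmol_L = 6,
             ft4_pmol_L = rbcpe(n, mu, sigma, nu, tau),
             disease_history = 0L, medication = 0L, iodine_mg_d = 0.2,
             cohort_tag = "SIM", contaminant_rule = NA_character_)
}

test_that("constant truth is recovered within 2 percent everywhere", {
  coh <- make_flat_cohort(2000, mu = 5, sigma = 0.1, seed = 10)
  # an age-constant target warrants modest curve flexibility
  std <- fit_standard(coh, "fT4", "female", fit_config(df_mu = 6, df_sigma = 4))
  g <- seq(0, 29, 0.5)
  expect_true(all(abs(percentile_curve(std, 50, g) / 5 - 1) < 0.02))
  p <- predict_params(std, g)
  expect_true(all(abs(p$sigma / 0.1 - 1) < 0.15))
})

test_that("refitting identical input gives identical coefficients", {
  coh <- make_flat_cohort(1500, seed = 2)
  s1 <- fit_standard(coh, "fT4", "female")
  s2 <- fit_standard(coh, "fT4", "female")
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$fit$deviance, s2$fit$deviance)
})

test_that("the 50th percentile curve is exactly the mu curve", {
  run <- default_run()
  std <- run$standards[["ratio.female"]]
  g <- seq(0, 29, 1)
  expect_equal(percentile_curve(std, 50, g), predict_params(std, g)$mu,
               tolerance = 1e-12)
})

test_that("P3/P97 bracket ~94 percent of the training records", {
  run <- default_run()
  for (std in run$standards) {
    sx <- if (std$sex == "female") "F" else "M"
    rows <- run$retained[run$retained$sex == sx, ]
    y <- switch(std$analyte, fT4 = rows$ft4_pmol_L, TSH = rows$tsh_mU_L,
                fT3 = rows$ft3_pmol_L,
                ratio = rows$ft3_pmol_L / rows$ft4_pmol_L)
    lo <- percentile_curve(std, 3, rows$age_years)
    hi <- percentile_curve(std, 97, rows$age_years)
    expect_gt(length(y), 1e4)
    # smoothing bias around the pubertal dispersion bump can widen the
    # band by up to ~2 points on the affected charts
    expect_equal(mean(y > lo & y < hi), 0.94, tolerance = 0.02 / 0.94,
                 label = sprintf("coverage of %s %s", std$analyte, std$sex))
  }
})

test_that("percentile curves never cross", {
  run <- default_run()
  g <- seq(0, 29, 0.1)
  for (std in run$standards) {
    ps <- c(3, 10, 25, 50, 75, 90, 97)
    curves <- sapply(ps, function(P) percentile_curve(std, P, g))
    expect_true(all(apply(curves, 1, diff) > 0),
                label = paste("ordering for", std$analyte, std$sex))
  }
})

test_that("training SDS are approximately standard normal", {
  run <- default_run()
  std <- run$standards[["ratio.male"]]
  rows <- run$retained[run$retained$sex == "M", ]
  z <- sds_of(std, rows$age_years, rows$ft3_pmol_L / rows$ft4_pmol_L)
  expect_lt(abs(mean(z)), 0.03)
  expect_lt(abs(sd(z) - 1), 0.03)
})

test_that("stronger penalties reduce effective df and fitted likelihood", {
  coh <- make_flat_cohort(2500, seed = 5)
  coh$ft4_pmol_L <- coh$ft4_pmol_L * (1 + 0.2 * exp(-coh$age_years / 6))
  lo <- fit_standard(coh, "fT4", "female", fit_config(df_mu = 4))
  hi <- fit_standard(coh, "fT4", "female", fit_config(df_mu = 10))
  expect_lt(lo$fit$edf[["mu"]], hi$fit$edf[["mu"]])
  expect_lte(lo$fit$logLik, hi$fit$logLik)
})

test_that("frozen nu/tau fit matches an independent Gaussian oracle", {
  n <- 4000
  set.seed(77)
  age <- runif(n, 0, 29)
  mu_t <- 12.5 + 4 * exp(-age / 7)
  y <- rnorm(n, mu_t, 0.1 * mu_t)
  y <- pmax(y, 0.1)
  coh <- data.frame(subject_id = "s", visit = 1L, sex = "F",
                    age_years = age, tsh_mU_L = 2, ft3_pmol_L = 6,
                    ft4_pmol_L = y, disease_history = 0L, medication = 0L,
                    iodine_mg_d = 0.2, cohort_tag = "SIM",
                    contaminant_rule = NA_character_)
  std <- fit_standard(coh, "fT4", "female",
                      fit_config(nu_fixed = 1, tau_fixed = 2))

  # independent oracle: iterated weighted least squares on an unpenalized
  # (moderate-df) spline, normal location-scale with sd proportional to
  # the mean, identity link
  u <- sqrt(age + 0.05)
  X <- cbind(1, splines::bs(u, df = 9))
  m <- rep(mean(y), n); s <- 0.2
  for (it in 1:25) {
    w <- 1 / (s * m)^2
    beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
    m <- drop(X %*% beta)
    s <- sd((y - m) / m)
  }
  g <- seq(0.5, 28.5, 0.5)
  Xg <- cbind(1, predict(splines::bs(u, df = 9), sqrt(g + 0.05)))
  oracle_mu <- drop(Xg %*% beta)
  expect_true(all(abs(predict_params(std, g)$mu / oracle_mu - 1) < 0.01))
  expect_equal(mean(predict_params(std, g)$sigma), s, tolerance = 0.05)
})

test_that("full-pipeline recovery holds on the smooth monotone analyte", {
  run <- default_run()
  # ages from 3 months on: the exact birth boundary carries essentially no
  # data mass and is validated through the sex-averaged anchor criterion
  g <- seq(0.25, 29, 0.25)
  for (sx in c("female", "male")) {
    std <- run$standards[[paste0("fT4.", sx)]]
    tp <- true_params("fT4", g, sx, run$cfg)
    for (P in c(3, 50, 97)) {
      got <- percentile_curve(std, P, g)
      want <- qbcpe(P / 100, tp$mu, tp$sigma, tp$nu, tp$tau)
      expect_true(all(abs(got / want - 1) < 0.03),
                  label = sprintf("fT4 %s P%d within 3%%", sx, P))
    }
  }
})

test_that("degenerate inputs fail loudly", {
  coh <- make_flat_cohort(150)
  expect_error(fit_standard(coh, "fT4", "female"), "insufficient data")
  coh2 <- make_flat_cohort(300)
  expect_error(fit_standard(coh2, "fT4", "male"), "insufficient data")
  run <- default_run()
  std <- run$standards[["fT4.female"]]
  expect_error(percentile_curve(std, 50, 31), "domain")
  expect_error(percentile_curve(std, 50, -1), "domain")
  expect_error(percentile_curve(std, 101, 5))
})
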