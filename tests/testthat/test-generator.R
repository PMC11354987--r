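# Cohort structure, reproducibility, stream isolation, and the synthetic
# patient profiles.

test_that("the default cohort reproduces the published structure exactly", {
  run <- default_run()
  clean <- run$cohort[is.na(run$cohort$contaminant_rule), ]
  expect_equal(nrow(clean), 23522)
  expect_equal(sum(clean$sex == "F"), 11325)
  expect_equal(sum(clean$sex == "M"), 12197)
  life <- clean[clean$cohort_tag == "LIFE", ]
  expect_equal(length(unique(life$subject_id)), 2287)
  expect_true(all(life$age_years >= 0 & life$age_years <= 6))
  kb <- clean[clean$cohort_tag == "KIGGS_BASE", ]
  expect_true(all(kb$age_years >= 3 & kb$age_years <= 17))
  kw <- clean[clean$cohort_tag == "KIGGS_W2", ]
  expect_true(all(kw$age_years >= 10 & kw$age_years <= 29))
  expect_true(all(is.na(kw$iodine_mg_d)))         # no iodine in the oldest arm
  expect_true(all(!is.na(kb$iodine_mg_d)))
})

test_that("visit counts match the published moments", {
  run <- default_run()
  life <- run$cohort[run$cohort$cohort_tag == "LIFE", ]
  visits <- tapply(life$visit, life$subject_id, max)
  expect_true(all(visits >= 1 & visits <= 8))
  expect_equal(mean(visits), 2.3, tolerance = 0.1 / 2.3)
  expect_equal(sd(visits), 1.51, tolerance = 0.15 / 1.51)
  # repeated visits of one child have increasing ages
  kid <- life[life$subject_id == names(which.max(visits))[1], ]
  expect_true(all(diff(kid$age_years[order(kid$visit)]) > 0))
})

test_that("generation is seed-deterministic down to the CSV bytes", {
  cfg <- default_cfg()
  a <- generate_cohort(cfg, seed = 17, n_total = 2000)
  b <- generate_cohort(cfg, seed = 17, n_total = 2000)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(a, generate_cohort(cfg, seed = 18, n_total = 2000)))
})

test_that("contamination settings do not perturb the clean records", {
  cfg <- default_cfg()
  with_c <- generate_cohort(cfg, seed = 23, n_total = 2000)
  without <- generate_cohort(cfg, seed = 23, n_total = 2000,
                             contamination = c())
  clean <- with_c[is.na(with_c$contaminant_rule), ]
  rownames(clean) <- NULL
  expect_identical(clean[, setdiff(names(clean), "contaminant_rule")],
                   without[, setdiff(names(without), "contaminant_rule")])
})

test_that("drawn hormones follow the truth distribution at a fixed age", {
  cfg <- default_cfg()
  p <- true_params("ratio", 9, "male", cfg)
  set.seed(12)
  x <- rbcpe(1e5, p$mu, p$sigma, p$nu, p$tau)
  for (q in c(0.03, 0.5, 0.97))
    expect_equal(unname(quantile(x, q)),
                 qbcpe(q, p$mu, p$sigma, p$nu, p$tau), tolerance = 0.01)
})

test_that("resistance profiles sit where the clinic reports them", {
  cfg <- default_cfg()
  score_ratio <- function(p) {
    # ratio percentile under the truth standard at each patient's age/sex
    vapply(seq_len(nrow(p)), function(i) {
      tp <- true_params("ratio", p$age_years[i], p$sex[i], cfg)
      100 * pbcpe(p$ft3_pmol_L[i] / p$ft4_pmol_L[i],
                  tp$mu, tp$sigma, tp$nu, tp$tau)
    }, numeric(1))
  }
  marg <- function(p, an, col) {
    vapply(seq_len(nrow(p)), function(i) {
      tp <- true_params(an, p$age_years[i], p$sex[i], cfg)
      100 * pbcpe(p[[col]][i], tp$mu, tp$sigma, tp$nu, tp$tau)
    }, numeric(1))
  }

  thra <- generate_patients("THRA", 150, cfg, 31)
  # single hormones inside their own normal bands, ratio far outside
  expect_true(all(marg(thra, "fT3", "ft3_pmol_L") > 3 &
                  marg(thra, "fT3", "ft3_pmol_L") < 97))
  expect_true(all(marg(thra, "fT4", "ft4_pmol_L") > 3 &
                  marg(thra, "fT4", "ft4_pmol_L") < 97))
  expect_true(all(score_ratio(thra) > 97))

  mct8 <- generate_patients("MCT8_severe", 150, cfg, 32)
  expect_true(all(score_ratio(mct8) > 97))
  expect_true(all(marg(mct8, "fT3", "ft3_pmol_L") > 97))

  sec <- generate_patients("SECISBP2", 150, cfg, 33)
  expect_true(all(score_ratio(sec) < 3))
  expect_true(all(marg(sec, "fT4", "ft4_pmol_L") > 97))

  cterm <- generate_patients("THRA_cterm", 150, cfg, 34)
  expect_true(all(score_ratio(cterm) >= 90 & score_ratio(cterm) <= 97))

  # controls are population draws: ratio percentile uniform on (0, 100)
  ctl <- generate_patients("CP_control", 5000, cfg, 35)
  ks <- suppressWarnings(ks.test(score_ratio(ctl) / 100, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(generate_patients("no_such", 5, cfg, 1), "unknown profile")
})
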