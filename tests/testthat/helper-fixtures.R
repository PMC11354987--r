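# Shared fixtures, built once per test session.
#
# The "default run" is the full study-condition pipeline: the calibrated
# generator at its published design (23,522 records + contaminants),
# cleaning, and one fitted standard per chart analyte and sex.  Several
# test files interrogate it, so it is memoized.

DEFAULT_COHORT_SEED <- 20240806L

the_cache <- new.env(parent = emptyenv())

default_cfg <- function() {
  if (is.null(the_cache$cfg)) the_cache$cfg <- default_generator_config()
  the_cache$cfg
}

default_run <- function() {
  if (is.null(the_cache$run)) {
    cfg <- default_cfg()
    cohort <- generate_cohort(cfg, seed = DEFAULT_COHORT_SEED)
    cleaned <- apply_filters(cohort)
    stds <- list()
    for (an in c("fT3", "fT4", "TSH", "ratio"))
      for (sx in c("female", "male"))
        stds <- c(stds, list(fit_standard(cleaned$retained, an, sx)))
    the_cache$run <- list(cfg = cfg, cohort = cohort,
                          retained = cleaned$retained,
                          report = cleaned$report,
                          standards = standard_set(stds))
  }
  the_cache$run
}

# independently coded Box-Cox Cole-Green (LMS) density, no truncation:
# the tau = 2 special case oracle
dlms_oracle <- function(y, mu, sigma, nu) {
  z <- if (abs(nu) < 1e-12) log(y / mu) / sigma
       else ((y / mu)^nu - 1) / (nu * sigma)
  stats::dnorm(z) * y^(nu - 1) / (mu^nu * sigma)
}

# generic quantile by root finding on the cdf: the closed-form cross-check
qbcpe_root_oracle <- function(p, mu, sigma, nu, tau) {
  vapply(p, function(pp)
    stats::uniroot(function(y) pbcpe(y, mu, sigma, nu, tau) - pp,
                   c(mu * 1e-3, mu * 1e3), tol = 1e-12)$root,
    numeric(1))
}
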