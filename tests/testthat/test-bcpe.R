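# The BCPE distribution kernel: closed-form special cases, quadrature
# normalization under the no-truncation convention, inversion identities,
# and sampling behaviour.

test_that("nu = 1, tau = 2 reduces to the normal closed form", {
  mu <- 5; sigma <- 0.1
  expect_equal(dbcpe(mu, mu, sigma, 1, 2), 1 / (mu * sigma * sqrt(2 * pi)),
               tolerance = 1e-12)
  ys <- c(4.2, 4.8, 5, 5.3, 6.1)
  expect_equal(dbcpe(ys, mu, sigma, 1, 2),
               dnorm(ys, mu, mu * sigma), tolerance = 1e-12)
  expect_equal(pbcpe(3, 1, 1, 1, 2), pnorm(2), tolerance = 1e-12)
  expect_equal(qbcpe(pnorm(2), 1, 1, 1, 2), 3, tolerance = 1e-9)
})

test_that("tau = 2 matches an independently coded LMS (BCCG) density", {
  grid <- expand.grid(y = c(0.5, 2, 5, 9), mu = c(3, 5), sigma = c(0.08, 0.2),
                      nu = c(-1, 0, 0.5, 2))
  got <- with(grid, dbcpe(y, mu, sigma, nu, 2))
  want <- mapply(dlms_oracle, grid$y, grid$mu, grid$sigma, grid$nu)
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("density integrates to one minus the truncated mass", {
  for (nu in c(-1, 0, 0.5, 1, 2)) for (tau in c(1.5, 2, 3, 5))
    for (sigma in c(0.05, 0.1, 0.2)) {
      v <- integrate(function(y) dbcpe(y, 5, sigma, nu, tau), 1e-8, Inf,
                     rel.tol = 1e-10, subdivisions = 500L)$value
      m <- bcpe_truncation_mass(5, sigma, nu, tau)
      expect_equal(v, 1 - m, tolerance = 1e-6,
                   label = sprintf("integral at nu=%g tau=%g sigma=%g",
                                   nu, tau, sigma))
      # inside the fitting region the mass itself is negligible
      if (sigma * abs(nu) <= 0.1 && tau >= 2)
        expect_lt(m, 1e-6)
    }
})

test_that("cdf and quantile are mutual inverses", {
  params <- list(c(5, 0.1, 1, 2), c(5, 0.1, 0.5, 3), c(2, 0.2, -0.5, 1.5),
                 c(0.4, 0.08, 0, 2), c(10, 0.05, 2, 5))
  qs <- c(0.001, 0.03, 0.25, 0.5, 0.75, 0.97, 0.999)
  for (p in params) {
    expect_equal(pbcpe(qbcpe(qs, p[1], p[2], p[3], p[4]),
                       p[1], p[2], p[3], p[4]), qs, tolerance = 1e-8)
    ys <- qbcpe(c(0.1, 0.6, 0.9), p[1], p[2], p[3], p[4])
    expect_equal(qbcpe(pbcpe(ys, p[1], p[2], p[3], p[4]),
                       p[1], p[2], p[3], p[4]), ys, tolerance = 1e-8)
    # median is mu exactly under the no-truncation convention
    expect_equal(qbcpe(0.5, p[1], p[2], p[3], p[4]), p[1], tolerance = 1e-12)
    expect_equal(pbcpe(p[1], p[1], p[2], p[3], p[4]), 0.5, tolerance = 1e-12)
  }
})

test_that("closed-form quantile agrees with root finding on the cdf", {
  qs <- c(0.03, 0.2, 0.5, 0.9, 0.97)
  for (p in list(c(5, 0.1, 0.5, 3), c(2, 0.15, -1, 1.8), c(7, 0.08, 0, 2))) {
    expect_equal(qbcpe(qs, p[1], p[2], p[3], p[4]),
                 qbcpe_root_oracle(qs, p[1], p[2], p[3], p[4]),
                 tolerance = 1e-8)
  }
})

test_that("quantiles are strictly increasing and ordered across centiles", {
  qs <- c(0.03, 0.1, 0.25, 0.5, 0.75, 0.9, 0.97)
  v <- qbcpe(qs, 5, 0.12, 0.4, 2.5)
  expect_true(all(diff(v) > 0))
})

test_that("sampling is reproducible and matches its quantiles", {
  set.seed(99); x1 <- rbcpe(1e5, 5, 0.1, 1, 2)
  set.seed(99); x2 <- rbcpe(1e5, 5, 0.1, 1, 2)
  expect_identical(x1, x2)
  expect_equal(median(x1), 5, tolerance = 0.01 / 5)
  expect_equal(mean(x1 < qbcpe(0.97, 5, 0.1, 1, 2)), 0.97, tolerance = 0.005)
})

test_that("z-scores of draws are standard normal and monotone in y", {
  set.seed(7)
  x <- rbcpe(1e5, 5, 0.1, 0.5, 3)
  z <- zbcpe(x, 5, 0.1, 0.5, 3)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
  expect_equal(zbcpe(5, 5, 0.1, 0.5, 3), 0, tolerance = 1e-12)
  expect_equal(zbcpe(qbcpe(0.97, 5, 0.1, 0.5, 3), 5, 0.1, 0.5, 3),
               qnorm(0.97), tolerance = 1e-8)
  ys <- seq(3, 8, 0.1)
  expect_true(all(diff(zbcpe(ys, 5, 0.1, 0.5, 3)) > 0))
})

test_that("domain and parameter violations raise errors", {
  expect_error(dbcpe(-1, 5, 0.1), "y must be")
  expect_error(dbcpe(0, 5, 0.1), "y must be")
  expect_error(pbcpe(0, 5, 0.1), "q must be")
  expect_error(qbcpe(0, 5, 0.1), "strictly inside")
  expect_error(qbcpe(1, 5, 0.1), "strictly inside")
  expect_error(dbcpe(1, -5, 0.1), "mu must be")
  expect_error(dbcpe(1, 5, 0), "sigma must be")
  expect_error(dbcpe(1, 5, 0.1, 1, -2), "tau must be")
})
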