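#' @title Penalized maximum-likelihood centile estimation
#'
#' @description
#' \code{fit_standard} estimates age-varying BCPE parameter curves
#' \eqn{\mu(t), \sigma(t), \nu(t), \tau(t)} for one analyte and one sex by
#' penalized maximum likelihood, in the manner of GAMLSS reference-chart
#' fitting: each curve is a cubic P-spline (B-spline basis with a
#' second-order difference penalty) on a transformed age axis, and the
#' curves are updated cyclically by per-parameter penalized Newton steps
#' (an RS-type backfitting algorithm) until the global deviance is
#' stable.  Smoothness per curve is controlled by a target effective
#' degrees of freedom; the penalty weight is re-solved against the
#' current working weights in every cycle.
#'
#' Ages are fitted on \eqn{u = \sqrt{t + 0.05}} so that infancy, where
#' sampling is dense and the hormone curves steep, receives adequate
#' resolution; all user-facing evaluation is in years.
#'
#' @name centile_fit
NULL

#' Fitting configuration
#'
#' @param df_mu,df_sigma,df_nu,df_tau target effective degrees of freedom
#'   per parameter curve (including the constant).
#' @param nseg number of equal-width B-spline segments on the transformed
#'   age axis (basis dimension is \code{nseg + 3}).
#' @param age_offset offset in the \eqn{\sqrt{t + c}} age transform.
#' @param nu_fixed,tau_fixed freeze the skewness/tail curve at a constant
#'   (e.g. \code{nu_fixed = 1, tau_fixed = 2} for a penalized Gaussian
#'   location-scale fit).
#' @param tau_max ceiling for tau; heavy-tail parameters are weakly
#'   identified on moderate samples, so tau is frozen there (with a
#'   warning) rather than allowed to diverge.
#' @param tol relative global-deviance convergence tolerance.
#' @param maxit maximum number of backfitting cycles.
#' @return a list of class \code{"fit_config"}.
#' @export
fit_config <- function(df_mu = 10, df_sigma = 8, df_nu = 2, df_tau = 2,
                       nseg = 16, age_offset = 0.05,
                       nu_fixed = NULL, tau_fixed = NULL, tau_max = 15,
                       tol = 1e-6, maxit = 200) {
  structure(list(df = c(mu = df_mu, sigma = df_sigma, nu = df_nu,
                        tau = df_tau),
                 nseg = nseg, age_offset = age_offset,
                 nu_fixed = nu_fixed, tau_fixed = tau_fixed,
                 tau_max = tau_max, tol = tol, maxit = maxit),
            class = "fit_config")
}

## equally spaced cubic B-spline basis with exterior knots (P-spline setup)
.pspline_knots <- function(urange, nseg) {
  du <- diff(urange) / nseg
  seq(urange[1] - 3 * du, urange[2] + 3 * du, by = du)
}

.pspline_basis <- function(u, knots) {
  splines::splineDesign(knots, u, ord = 4, outer.ok = TRUE)
}

## effective df of the penalized smoother at the current working weights
.edf <- function(A, P, lam) {
  sum(diag(solve(A + lam * P, A)))
}

## solve the penalty weight whose effective df matches the target
.lambda_for_df <- function(A, P, target) {
  lo <- 1e-8; hi <- 1e10
  if (.edf(A, P, lo) <= target) return(lo)
  ## the edf cannot drop below the penalty null space (dimension 2); a
  ## target at or near that asymptote means maximal smoothing
  if (.edf(A, P, hi) >= target - 0.01) return(hi)
  r <- stats::uniroot(function(ll) .edf(A, P, exp(ll)) - target,
                      c(log(lo), log(hi)), tol = 1e-6)
  exp(r$root)
}

.analyte_values <- function(cohort, analyte) {
  switch(analyte,
         fT3 = cohort$ft3_pmol_L,
         fT4 = cohort$ft4_pmol_L,
         TSH = cohort$tsh_mU_L,
         ratio = cohort$ft3_pmol_L / cohort$ft4_pmol_L,
         stop("unknown analyte '", analyte, "'", call. = FALSE))
}

#' Fit a centile standard for one analyte and sex
#'
#' @param cohort a cleaned cohort data.frame (canonical units; see
#'   \code{\link{apply_filters}}).  The fT3/fT4 ratio is fitted directly
#'   on per-record \code{ft3/ft4} quotients as its own analyte.
#' @param analyte \code{"fT3"}, \code{"fT4"}, \code{"TSH"} or
#'   \code{"ratio"}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param config a \code{\link{fit_config}}.
#' @return an object of class \code{"centile_standard"}: the spline
#'   coefficient vectors, knots, links and age domain, plus fit metadata
#'   (n, effective df per curve, converged log-likelihood, deviance
#'   trace).  Query it with \code{\link{predict_params}},
#'   \code{\link{percentile_curve}}, \code{\link{sds_of}} and
#'   \code{\link{percentile_of}}.
#' @export
fit_standard <- function(cohort, analyte = c("fT3", "fT4", "TSH", "ratio"),
                         sex = c("female", "male"), config = fit_config()) {
  analyte <- match.arg(analyte)
  sex <- match.arg(sex)
  stopifnot(inherits(config, "fit_config"))
  sx <- if (sex == "female") "F" else "M"
  rows <- cohort$sex == sx
  y <- .analyte_values(cohort[rows, , drop = FALSE], analyte)
  age <- cohort$age_years[rows]
  ok <- !is.na(y) & !is.na(age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 200)
    stop(sprintf("insufficient data: %d %s records for sex %s (need >= 200)",
                 length(y), analyte, sex), call. = FALSE)
  if (any(y <= 0)) stop("analyte values must be positive", call. = FALSE)

  off <- config$age_offset
  domain <- c(0, ceiling(max(age)))   # charts run over whole years
  u <- sqrt(age + off)
  knots <- .pspline_knots(sqrt(domain + off), config$nseg)
  B <- .pspline_basis(u, knots)
  k <- ncol(B)
  P <- crossprod(diff(diag(k), differences = 2))

  links <- c(mu = "log", sigma = "log", nu = "identity", tau = "log")
  fixed <- list(mu = NULL, sigma = NULL,
                nu = config$nu_fixed, tau = config$tau_fixed)

  ## initialization: mu from a smoothed log-median, sigma from residual
  ## spread, nu = 1, tau = 2 (B-splines sum to one, so a constant
  ## coefficient vector is a constant curve)
  A0 <- crossprod(B)
  lam0 <- .lambda_for_df(A0, P, config$df[["mu"]])
  beta <- list(
    mu = solve(A0 + lam0 * P, crossprod(B, log(y))),
    sigma = NULL, nu = NULL, tau = NULL)
  sig0 <- max(0.01, stats::sd(log(y) - B %*% beta$mu))
  beta$sigma <- rep(log(sig0), k)
  beta$nu <- rep(1, k)
  beta$tau <- rep(log(2), k)

  eta_of <- function(nm) {
    if (!is.null(fixed[[nm]])) {
      val <- fixed[[nm]]
      rep(if (links[[nm]] == "log") log(val) else val, length(y))
    } else drop(B %*% beta[[nm]])
  }
  par_of <- function(nm, eta) {
    v <- if (links[[nm]] == "log") exp(eta) else eta
    if (nm == "tau") pmin(v, config$tau_max) else v
  }

  loglik <- function(e) {
    sum(dbcpe(y, par_of("mu", e$mu), par_of("sigma", e$sigma),
              par_of("nu", e$nu), par_of("tau", e$tau), log = TRUE))
  }
  loglik_vec <- function(e) {
    dbcpe(y, par_of("mu", e$mu), par_of("sigma", e$sigma),
          par_of("nu", e$nu), par_of("tau", e$tau), log = TRUE)
  }
  pen <- function(lams) {
    s <- 0
    for (nm in names(beta))
      if (is.null(fixed[[nm]]))
        s <- s + 0.5 * lams[[nm]] * drop(crossprod(beta[[nm]], P %*% beta[[nm]]))
    s
  }

  lams <- list(mu = lam0, sigma = lam0, nu = lam0, tau = lam0)
  eta <- list(mu = eta_of("mu"), sigma = eta_of("sigma"),
              nu = eta_of("nu"), tau = eta_of("tau"))
  gd_trace <- -2 * loglik(eta)
  h <- 1e-3
  edf_out <- c(mu = NA, sigma = NA, nu = NA, tau = NA)
  converged <- FALSE

  for (it in seq_len(config$maxit)) {
    for (nm in c("mu", "sigma", "nu", "tau")) {
      if (!is.null(fixed[[nm]])) next
      e_hi <- eta; e_hi[[nm]] <- eta[[nm]] + h
      e_lo <- eta; e_lo[[nm]] <- eta[[nm]] - h
      l0 <- loglik_vec(eta); l_hi <- loglik_vec(e_hi); l_lo <- loglik_vec(e_lo)
      g <- (l_hi - l_lo) / (2 * h)
      w <- -(l_hi - 2 * l0 + l_lo) / h^2
      w[!is.finite(w) | w < 1e-6] <- 1e-6
      g[!is.finite(g)] <- 0
      step <- pmin(pmax(g / w, -5), 5)        # damped working residual
      zwork <- eta[[nm]] + step
      A <- crossprod(B, w * B)
      lams[[nm]] <- .lambda_for_df(A, P, config$df[[nm]])
      rhs <- crossprod(B, w * zwork)
      beta_new <- solve(A + lams[[nm]] * P, rhs)

      obj_old <- loglik(eta) - pen(lams)
      beta_old <- beta[[nm]]
      beta[[nm]] <- beta_new
      eta[[nm]] <- eta_of(nm)
      halv <- 0
      while (loglik(eta) - pen(lams) < obj_old && halv < 12) {
        beta[[nm]] <- (beta[[nm]] + beta_old) / 2
        eta[[nm]] <- eta_of(nm)
        halv <- halv + 1
      }
      if (halv >= 12) {          # no improving step along this direction
        beta[[nm]] <- beta_old
        eta[[nm]] <- eta_of(nm)
      }
      edf_out[nm] <- .edf(A, P, lams[[nm]])
    }
    gd <- -2 * loglik(eta)
    gd_trace <- c(gd_trace, gd)
    if (abs(gd_trace[length(gd_trace) - 1] - gd) <
        config$tol * (abs(gd) + 0.1)) { converged <- TRUE; break }
  }
  if (!converged)
    stop("centile fit did not converge within ", config$maxit,
         " cycles; deviance trace: ",
         paste(signif(utils::tail(gd_trace, 8), 8), collapse = ", "),
         call. = FALSE)
  tm <- bcpe_truncation_mass(par_of("mu", eta$mu), par_of("sigma", eta$sigma),
                             par_of("nu", eta$nu), par_of("tau", eta$tau))
  if (any(tm > 1e-4))
    warning(sprintf(paste("fitted %s/%s standard leaves the no-truncation",
                          "fit region (max truncated mass %.2g); centiles",
                          "near the extremes may be biased"),
                    analyte, sex, max(tm)), call. = FALSE)
  if (any(par_of("tau", eta$tau) >= config$tau_max))
    warning("tau reached its ceiling (", config$tau_max,
            ") and was frozen there; heavy-tail parameter weakly identified",
            call. = FALSE)

  curves <- lapply(c("mu", "sigma", "nu", "tau"), function(nm) {
    if (!is.null(fixed[[nm]]))
      list(link = links[[nm]], fixed = fixed[[nm]])
    else
      list(link = links[[nm]], coef = as.numeric(beta[[nm]]))
  })
  names(curves) <- c("mu", "sigma", "nu", "tau")

  structure(list(
    analyte = analyte, sex = sex, age_domain = domain,
    age_offset = off, knots = as.numeric(knots), order = 4L,
    tau_max = config$tau_max, curves = curves,
    fit = list(n = length(y), edf = edf_out,
               logLik = -utils::tail(gd_trace, 1) / 2,
               deviance = utils::tail(gd_trace, 1),
               iterations = it, converged = converged,
               deviance_trace = as.numeric(gd_trace))),
    class = "centile_standard")
}

#' @export
print.centile_standard <- function(x, ...) {
  cat(sprintf("Centile standard: %s, %s, ages %.3g-%.4g y (n = %d)\n",
              x$analyte, x$sex, x$age_domain[1], x$age_domain[2], x$fit$n))
  cat(sprintf("  logLik %.2f after %d cycles; edf: mu %.2f, sigma %.2f, nu %s, tau %s\n",
              x$fit$logLik, x$fit$iterations,
              x$fit$edf[["mu"]], x$fit$edf[["sigma"]],
              if (is.null(x$curves$nu$coef)) "fixed" else sprintf("%.2f", x$fit$edf[["nu"]]),
              if (is.null(x$curves$tau$coef)) "fixed" else sprintf("%.2f", x$fit$edf[["tau"]])))
  invisible(x)
}

.check_domain <- function(std, age) {
  if (any(age < std$age_domain[1] - 1e-9 | age > std$age_domain[2] + 1e-9))
    stop(sprintf("age outside the standard's domain [%.3g, %.4g]; no extrapolation",
                 std$age_domain[1], std$age_domain[2]), call. = FALSE)
}

#' Evaluate the fitted BCPE parameter curves of a standard
#'
#' @param std a \code{"centile_standard"}.
#' @param age ages in years within the standard's domain.
#' @return data.frame with columns \code{mu}, \code{sigma}, \code{nu},
#'   \code{tau}, one row per age.
#' @export
predict_params <- function(std, age) {
  stopifnot(inherits(std, "centile_standard"))
  .check_domain(std, age)
  Bn <- .pspline_basis(sqrt(age + std$age_offset), std$knots)
  one <- function(nm) {
    cv <- std$curves[[nm]]
    if (!is.null(cv$fixed)) {
      rep(cv$fixed, length(age))
    } else {
      eta <- drop(Bn %*% cv$coef)
      v <- if (cv$link == "log") exp(eta) else eta
      if (nm == "tau") pmin(v, std$tau_max) else v
    }
  }
  data.frame(mu = one("mu"), sigma = one("sigma"),
             nu = one("nu"), tau = one("tau"))
}

#' Percentile curve of a fitted standard
#'
#' @param std a \code{"centile_standard"}.
#' @param P percentile in (0, 100), e.g. 3, 10, 25, 50, 75, 90, 97.
#' @param ages age grid (years) within the standard's domain.
#' @return numeric vector of analyte values, one per age.
#' @export
percentile_curve <- function(std, P, ages) {
  stopifnot(P > 0, P < 100)
  p <- predict_params(std, ages)
  qbcpe(P / 100, p$mu, p$sigma, p$nu, p$tau)
}

#' SDS and percentile of an individual value under a standard
#'
#' @param std a \code{"centile_standard"}.
#' @param age age in years within the standard's domain.
#' @param value positive analyte value(s) in canonical units.
#' @return \code{sds_of}: the standard deviation score
#'   \eqn{\Phi^{-1}(F(value))}; \code{percentile_of}: \eqn{100 F(value)}.
#' @export
sds_of <- function(std, age, value) {
  p <- predict_params(std, age)
  zbcpe(value, p$mu, p$sigma, p$nu, p$tau)
}

#' @rdname sds_of
#' @export
percentile_of <- function(std, age, value) {
  p <- predict_params(std, age)
  100 * pbcpe(value, p$mu, p$sigma, p$nu, p$tau)
}
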