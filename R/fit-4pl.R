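#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{r = bottom + (top - bottom) \frac{d^h}{d^h + IC_{50}^h}}
#' to percent response versus dose. For screening inhibition data the
#' asymptotes default to fixed `bottom = 0`, `top = 100`; pass `NA` to
#' estimate either from the data. Viability (MTT) curves, which fall with
#' dose, reuse the same machinery with `decreasing = TRUE` (the midpoint
#' `ic50` keeps its meaning as the half-effect concentration).
#'
#' The optimizer works on `log(ic50)` and `log(hill)` (positivity enforced by
#' construction) with multi-start initialization: `ic50` is seeded at the
#' dose bracketing the half response and `hill` at each of 0.5, 1, 2 and 4;
#' the start reaching the smallest residual sum of squares wins, ties going
#' to the smallest starting slope. A stalled optimizer is reported as
#' `converged = FALSE` rather than an error.
#'
#' @param formula model formula `response ~ dose`.
#' @param data data frame containing the variables in `formula`.
#' @param bottom,top fixed asymptote values (percent), or `NA` to estimate.
#' @param decreasing logical; `TRUE` for curves that fall with dose
#'   (viability), `FALSE` (default) for inhibition.
#' @param hill_starts numeric vector of Hill-slope starting values.
#'
#' @return An object of class `c("fourpl_fit", "fourpl")` with components
#'   `bottom`, `top`, `ic50`, `hill`, `rss`, `converged`, `se` (named vector
#'   of standard errors for the free parameters, ic50 via the delta method),
#'   `se_ic50`, `data`, `fitted.values`, `residuals`.
#' @examples
#' d <- data.frame(dose = c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16))
#' d$inhibition <- predict(fourpl(1.48, 1.292), dose = d$dose)
#' fit <- fit_4pl(inhibition ~ dose, d)
#' coef(fit)
#' ic_at_level(fit, 70)
#' @seealso [ic_at_level()], [build_ladder()], [predict.fourpl_fit()]
#' @export
fit_4pl <- function(formula, data, bottom = 0, top = 100,
                    decreasing = FALSE, hill_starts = c(0.5, 1, 2, 4)) {
  mf <- stats::model.frame(formula, data)
  response <- unname(stats::model.response(mf))
  if (ncol(mf) != 2L)
    stop("formula must be of the form response ~ dose")
  dose <- mf[[2L]]
  if (any(!is.finite(response)))
    stop("responses must be finite")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative")
  if (length(unique(dose)) < 4L)
    stop("at least 4 distinct doses are required to identify a 4PL curve")
  if (diff(range(response)) == 0)
    stop("all responses are equal; the curve is unidentifiable")

  est_bottom <- is.na(bottom)
  est_top <- is.na(top)

  # data-driven asymptote stand-ins for initialization
  b0 <- if (est_bottom) min(response) else bottom
  t0 <- if (est_top) max(response) else top
  if (!est_bottom && !est_top && b0 >= t0)
    stop("'bottom' must be less than 'top'")

  pred_par <- function(p) {
    b <- if (est_bottom) p[["bottom"]] else bottom
    tt <- if (est_top) p[["top"]] else top
    fourpl_effect(b, tt, exp(p[["lic50"]]), exp(p[["lhill"]]), dose,
                  decreasing = decreasing)
  }
  rss_par <- function(p) {
    r <- response - pred_par(p)
    sum(r * r)
  }

  # seed ic50 at the dose bracketing the half response
  half <- (b0 + t0) / 2
  ord <- order(dose)
  rmean <- tapply(response, dose, mean)
  dd <- as.numeric(names(rmean))
  rr <- as.numeric(rmean)
  if (decreasing) rr <- -rr + (b0 + t0) # reflect so rr rises with dose
  cross <- which(diff(sign(rr - half)) != 0)
  pos <- dd[dd > 0]
  ic50_start <- if (length(cross)) {
    lo <- max(dd[cross[1]], min(pos))
    hi <- dd[cross[1] + 1L]
    sqrt(lo * hi)
  } else {
    exp(mean(log(pos)))
  }

  best <- NULL
  for (h0 in sort(hill_starts)) {
    p0 <- c(lic50 = log(ic50_start), lhill = log(h0))
    if (est_bottom) p0 <- c(p0, bottom = b0)
    if (est_top) p0 <- c(p0, top = t0)
    res <- tryCatch(
      stats::optim(p0, rss_par, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12)
      best <- res # ties keep the earlier (smaller) hill start
  }

  if (is.null(best)) { # every start failed: report non-convergence
    par <- c(lic50 = log(ic50_start), lhill = 0)
    if (est_bottom) par <- c(par, bottom = b0)
    if (est_top) par <- c(par, top = t0)
    best <- list(par = par, value = rss_par(par), convergence = 1L)
  }

  p <- best$par
  fit_bottom <- if (est_bottom) p[["bottom"]] else bottom
  fit_top <- if (est_top) p[["top"]] else top
  ic50 <- exp(p[["lic50"]])
  hill <- exp(p[["lhill"]])
  fitted <- pred_par(p)
  resid <- response - fitted
  rss <- best$value
  n <- length(response)
  npar <- length(p)

  # standard errors from the Jacobian at the optimum (Gauss-Newton cov.)
  se <- rep(NA_real_, npar)
  names(se) <- names(p)
  if (n > npar) {
    pred_named <- function(q) { names(q) <- names(p); pred_par(q) }
    J <- tryCatch(numDeriv::jacobian(pred_named, p), error = function(e) NULL)
    if (!is.null(J)) {
      JtJ <- crossprod(J)
      cv <- tryCatch(solve(JtJ) * rss / (n - npar), error = function(e) NULL)
      if (!is.null(cv)) se[] <- sqrt(pmax(diag(cv), 0))
    }
  }
  se_ic50 <- unname(ic50 * se["lic50"]) # delta method off the log scale

  out <- list(
    bottom = fit_bottom, top = fit_top, ic50 = ic50, hill = hill,
    name = NULL,
    rss = rss, converged = identical(best$convergence, 0L),
    se = c(ic50 = se_ic50, hill = unname(hill * se["lhill"]),
           bottom = if (est_bottom) unname(se["bottom"]) else NA_real_,
           top = if (est_top) unname(se["top"]) else NA_real_),
    se_ic50 = se_ic50,
    decreasing = decreasing,
    fixed = c(bottom = !est_bottom, top = !est_top),
    data = data.frame(dose = dose, response = response),
    fitted.values = fitted, residuals = resid,
    call = match.call(), formula = formula
  )
  class(out) <- c("fourpl_fit", "fourpl")
  out
}

#' @export
print.fourpl_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic fit",
      if (x$decreasing) " (decreasing)", "\n", sep = "")
  print(signif(coef(x), digits))
  cat("rss:", signif(x$rss, digits),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.fourpl_fit <- function(object, ...) {
  est <- coef(object)
  tab <- cbind(Estimate = est,
               `Std. Error` = object$se[names(est)])
  n <- nrow(object$data)
  npar <- 2L + sum(!object$fixed)
  structure(list(coefficients = tab, rss = object$rss,
                 sigma = sqrt(object$rss / max(n - npar, 1L)),
                 n = n, converged = object$converged,
                 fixed = object$fixed, decreasing = object$decreasing,
                 call = object$call),
            class = "summary.fourpl_fit")
}

#' @export
print.summary.fourpl_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat("Call: "); print(x$call)
  fixed <- names(x$fixed)[x$fixed]
  if (length(fixed)) cat("Fixed:", paste(fixed, collapse = ", "), "\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "fixed")
  cat("Residual sum of squares:", signif(x$rss, digits),
      "on", x$n, "observations\n")
  cat("Residual std. error:", signif(x$sigma, digits), "\n")
  if (!x$converged) cat("Warning: optimizer did not report convergence\n")
  invisible(x)
}

#' Predict from a fitted 4PL curve
#'
#' @param object a [fit_4pl()] fit.
#' @param newdata optional data frame with a `dose` column; defaults to the
#'   fitting data.
#' @param dose alternatively a numeric dose vector.
#' @param ... unused.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, dose = NULL, ...) {
  if (is.null(dose)) {
    dose <- if (is.null(newdata)) object$data$dose else newdata$dose
    if (is.null(dose)) stop("'newdata' must contain a dose column")
  }
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative")
  fourpl_effect(object$bottom, object$top, object$ic50, object$hill, dose,
                decreasing = object$decreasing)
}

#' @export
fitted.fourpl_fit <- function(object, ...) object$fitted.values

#' @export
residuals.fourpl_fit <- function(object, ...) object$residuals

#' Simulate replicate responses from a fitted 4PL curve
#'
#' Draws Gaussian responses at the observed doses with standard deviation
#' equal to the residual standard error, the conventional parametric
#' bootstrap for a least-squares dose-response fit.
#'
#' @param object a [fit_4pl()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param ... unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.fourpl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- nrow(object$data)
  npar <- 2L + sum(!object$fixed)
  sigma <- sqrt(object$rss / max(n - npar, 1L))
  draw <- function() object$fitted.values + stats::rnorm(n, 0, sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    withr::with_seed(seed, replicate(nsim, draw()))
  }
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted 4PL curve
#'
#' Observed responses and the fitted curve on a log-dose axis (dose-0 points
#' are drawn at the left margin).
#'
#' @param x a [fit_4pl()] fit.
#' @param n number of curve evaluation points.
#' @param xlab,ylab,main usual graphical labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fourpl_fit <- function(x, n = 200,
                            xlab = "dose (µg/mL)",
                            ylab = "response (%)", main = NULL, ...) {
  d <- x$data
  pos <- d$dose[d$dose > 0]
  if (!length(pos)) stop("no positive doses to plot")
  lo <- min(pos) / 4
  dose_plot <- ifelse(d$dose == 0, lo, d$dose)
  grid <- exp(seq(log(lo), log(max(pos)), length.out = n))
  graphics::plot(dose_plot, d$response, log = "x",
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(grid, predict(x, dose = grid))
  graphics::abline(v = x$ic50, lty = 3)
  invisible(x)
}
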