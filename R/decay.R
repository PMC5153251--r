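#' Exponential-decay fit of the alkyl fragment series
#'
#' Fits `I(m) = A exp(-lambda m)` to the alkyl-series intensities by ordinary
#' least squares on the intensity scale (Levenberg--Marquardt, started from
#' the log-linear regression). The two lowest-mass present members are
#' excluded from fitting, since they are dominated by non-specific
#' fragmentation. Ions that sit far above the fitted envelope bias the fit,
#' so fitting is outlier-aware: fit, flag members whose intensity ratio
#' `I / I_hat >= tau`, refit without them, and repeat until the flagged set
#' is stable (at most `max_iter` rounds). Residual ratios are reported for
#' every present series member against the final fit, so enhanced ions keep
#' their full ratio even though they did not influence the fit.
#'
#' @param series data frame from [alkyl_series()] (columns `mz`, `intensity`,
#'   `present`), or any data frame with `mz` and `intensity`.
#' @param tau enhancement threshold used for outlier exclusion during
#'   fitting (default 3). Outlier flagging is seeded by a robust
#'   (M-estimator) regression on the log scale, so that strongly enhanced
#'   ions cannot drag the provisional envelope up far enough to hide below
#'   the threshold.
#' @param max_iter maximum fit/flag rounds (default 5).
#' @param drop_low number of lowest-mass members excluded from the fit
#'   domain (default 2).
#' @return An object of class `decay_fit` with components `A`, `lambda`,
#'   `series` (with fitted values and residual ratios), `domain`,
#'   `excluded` (m/z flagged as outliers), `flat` (TRUE when no decaying
#'   envelope could be established).
#' @examples
#' m <- 14 * (3:25) + 1
#' fit <- fit_decay(data.frame(mz = m, intensity = 1000 * exp(-0.02 * m)))
#' coef(fit)
#' @export
fit_decay <- function(series, tau = 3, max_iter = 5L, drop_low = 2L) {
  if (!all(c("mz", "intensity") %in% names(series))) {
    stop("series needs columns mz and intensity")
  }
  if (is.null(series$present)) series$present <- !is.na(series$intensity)
  obs <- series[series$present & series$intensity > 0, c("mz", "intensity")]
  obs <- obs[order(obs$mz), ]
  if (nrow(obs) - drop_low < 4L) {
    stop("need at least ", 4L + drop_low, " positive series members to fit")
  }
  fit_dom <- obs[-seq_len(drop_low), ]

  one_fit <- function(d) {
    # log-linear start, then OLS on the intensity scale
    start_fit <- stats::lm(log(intensity) ~ mz, data = d)
    start <- list(A = exp(stats::coef(start_fit)[[1]]),
                  lambda = -stats::coef(start_fit)[[2]])
    if (!is.finite(start$lambda) || start$lambda <= 0) start$lambda <- 1e-4
    minpack.lm::nlsLM(intensity ~ A * exp(-lambda * mz), data = d,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  # robust reference envelope on the log scale: enhanced ions are large
  # positive residuals there and get downweighted instead of absorbed, and
  # the envelope stays accurate across the whole mass range, where the
  # intensity-scale fit is dominated by the low-mass members. Flagging is
  # iterated against the re-fitted robust envelope until stable.
  robust_envelope <- function(d) {
    rob <- tryCatch(
      MASS::rlm(log(intensity) ~ mz, data = d, maxit = 50),
      error = function(e) stats::lm(log(intensity) ~ mz, data = d))
    c(A = exp(stats::coef(rob)[[1]]), lambda = -stats::coef(rob)[[2]])
  }
  env <- robust_envelope(fit_dom)
  excluded <- numeric(0)
  detect_ratio_dom <- rep(NA_real_, nrow(fit_dom))
  if (is.finite(env[["lambda"]]) && env[["lambda"]] > 0) {
    for (it in seq_len(max_iter)) {
      detect_ratio_dom <- fit_dom$intensity /
        (env[["A"]] * exp(-env[["lambda"]] * fit_dom$mz))
      new_excl <- fit_dom$mz[detect_ratio_dom >= tau]
      if (setequal(new_excl, excluded)) break
      excluded <- new_excl
      d <- fit_dom[!(fit_dom$mz %in% excluded), ]
      if (nrow(d) < 4L) break
      env <- robust_envelope(d)
    }
  }
  # reported parameters: OLS on the intensity scale over the clean members
  d <- fit_dom[!(fit_dom$mz %in% excluded), ]
  if (nrow(d) < 4L) stop("decay fit failed: too few members after exclusion")
  loglin <- stats::lm(log(intensity) ~ mz, data = d)
  loglin_lambda <- -stats::coef(loglin)[[2]]
  fit <- tryCatch(one_fit(d), error = function(e) e)
  if (inherits(fit, "error")) {
    if (loglin_lambda <= 1e-8) {
      # no decaying envelope to converge to: report the log-linear solution
      # and let the flat-spectrum guard below take over
      A <- exp(stats::coef(loglin)[[1]]); lambda <- loglin_lambda
    } else {
      stop("decay fit did not converge: ", conditionMessage(fit))
    }
  } else {
    cf <- stats::coef(fit)
    A <- cf[["A"]]; lambda <- cf[["lambda"]]
  }
  # decay rates of real alkyl envelopes are ~0.01-0.03 per Da; a fitted rate
  # indistinguishable from zero means no envelope at all
  flat <- !is.finite(lambda) || lambda <= 1e-8
  if (flat) {
    warning("flat spectrum: fitted decay rate is not positive")
  }
  series$fitted <- ifelse(series$present, A * exp(-lambda * series$mz),
                          NA_real_)
  series$ratio <- series$intensity / series$fitted
  series$detect_ratio <- ifelse(
    series$present,
    series$intensity / (env[["A"]] * exp(-env[["lambda"]] * series$mz)),
    NA_real_)
  structure(list(A = A, lambda = lambda, envelope = env, series = series,
                 domain = range(fit_dom$mz), excluded = sort(excluded),
                 flat = flat, tau = tau),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(A = object$A, lambda = object$lambda)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay fit> I(m) = %.4g * exp(-%.5g m), domain m/z %g..%g\n",
              x$A, x$lambda, x$domain[1], x$domain[2]))
  if (x$flat) cat("  WARNING: flat spectrum (lambda <= 0)\n")
  if (length(x$excluded)) {
    cat("  excluded as enhanced during fitting:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, mz = NULL, ...) {
  if (is.null(mz)) mz <- object$series$mz
  object$A * exp(-object$lambda * mz)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$series$intensity - object$series$fitted
}

#' @export
plot.decay_fit <- function(x, ...) {
  s <- x$series[x$series$present, ]
  graphics::plot(s$mz, s$intensity, type = "h", xlab = "m/z",
                 ylab = "intensity", ...)
  grid_mz <- seq(x$domain[1], x$domain[2], length.out = 200)
  graphics::lines(grid_mz, predict(x, grid_mz), col = 2)
  if (length(x$excluded)) {
    graphics::points(x$excluded,
                     s$intensity[match(x$excluded, s$mz)], col = 2, pch = 19)
  }
  invisible(x)
}

#' Ions standing above the fitted decay envelope
#'
#' Returns the series members whose intensity exceeds the decay envelope by
#' at least a factor `tau` -- the diagnostic signature of a methyl branch.
#' Detection ratios are taken against the robust reference envelope carried
#' by the fit (see [fit_decay()]); the result is monotone in `tau`: raising
#' the threshold can only shrink it.
#'
#' @param fit a [fit_decay()] result.
#' @param tau enhancement threshold (default: the one used for fitting).
#' @return A data frame with columns `mz` and `ratio`, sorted by m/z; empty
#'   when nothing stands out (e.g. a linear alkane) or when the fit is flat.
#' @export
enhanced_ions <- function(fit, tau = fit$tau) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$flat) {
    return(data.frame(mz = numeric(0), ratio = numeric(0)))
  }
  s <- fit$series
  keep <- s$present & s$mz >= fit$domain[1] & !is.na(s$detect_ratio) &
    s$detect_ratio >= tau
  out <- data.frame(mz = s$mz[keep], ratio = s$detect_ratio[keep])
  out[order(out$mz), ]
}
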