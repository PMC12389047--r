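#' @export
print.pkfit <- function(x, ...) {
  cat("Laplace NLME fit:", x$model$drug,
      sprintf("(%d subjects, %d observations)\n", x$n_subjects, x$n_obs))
  cat(sprintf("OFV: %.3f   convergence: %d %s\n", x$ofv, x$convergence,
              if (!is.null(x$message)) paste0("(", x$message, ")") else ""))
  cat("Thetas:\n"); print(round(x$theta, 4))
  cat("IIV (CV):", if (length(x$omega))
    paste(sprintf("%s=%.1f%%", names(x$omega), 100 * x$omega), collapse = ", ")
    else "none", "\n")
  cat(sprintf("Proportional error: %.1f%%\n", 100 * x$sigma))
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) object$coefficients

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$par), class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) {
  if (is.null(object$se)) stop("fit was run without standard errors")
  diag(object$se^2)
}

#' Summarise a Laplace NLME fit
#'
#' @param object,x A \code{\link{pkfit}}.
#' @param ... Unused.
#' @return data.frame with estimates, RSEs (where available) and, for IIV
#'   terms, eta shrinkage.
#' @export
summary.pkfit <- function(object, ...) {
  est <- c(object$coefficients, object$omega, sigma = object$sigma)
  scale <- c(rep("theta", length(object$coefficients)),
             rep("omega (SD)", length(object$omega)), "sigma (SD)")
  out <- data.frame(parameter = names(est), type = scale, estimate = est)
  out$rse_pct <- if (!is.null(object$rse)) object$rse else NA_real_
  out$shrinkage_pct <- NA_real_
  if (length(object$iiv))   # omega rows sit between the thetas and sigma
    out$shrinkage_pct[length(object$coefficients) + seq_along(object$iiv)] <-
      object$shrinkage
  rownames(out) <- NULL
  structure(list(table = out, ofv = object$ofv, drug = object$model$drug,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.pkfit")
}

#' @rdname summary.pkfit
#' @export
print.summary.pkfit <- function(x, ...) {
  cat("Laplace NLME fit:", x$drug,
      sprintf("(%d subjects, %d observations), OFV %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

# individual or population prediction per subject
.predict_subject <- function(fit, i, eta = NULL) {
  pred <- .pred_factory(fit$model, fit$subjects[[i]], fit$iiv)
  if (is.null(eta)) eta <- numeric(length(fit$iiv))
  pred(fit$theta, eta)
}

#' Predictions from a fitted model
#'
#' \code{"pred"} evaluates the model at eta = 0 (population prediction);
#' \code{"ipred"} at the empirical-Bayes eta modes (individual prediction).
#'
#' @param object A \code{\link{pkfit}}.
#' @param type \code{"ipred"} or \code{"pred"}.
#' @param ... Unused.
#' @return Numeric vector aligned with the modelled observations (rows with
#'   \code{EVID == 0 & MDV == 0}, in subject order).
#' @export
predict.pkfit <- function(object, type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  unlist(lapply(seq_along(object$subjects), function(i)
    .predict_subject(object, i,
                     if (type == "ipred") object$eta[i, ] else NULL)),
    use.names = FALSE)
}

#' @export
fitted.pkfit <- function(object, ...) predict.pkfit(object, "ipred")

#' Residuals of a fitted model
#'
#' \code{"cwres"} are conditional weighted residuals: the observation vector
#' is decorrelated with the first-order-approximated covariance at the eta
#' mode (linearising f in eta; error variance at the conditional
#' prediction). \code{"iwres"} are individual weighted residuals
#' \eqn{(y - f_i)/(\sigma f_i)}.
#'
#' @param object A \code{\link{pkfit}}.
#' @param type \code{"cwres"} or \code{"iwres"}.
#' @param ... Unused.
#' @export
residuals.pkfit <- function(object, type = c("cwres", "iwres"), ...) {
  type <- match.arg(type)
  if (type == "iwres") {
    f <- predict.pkfit(object, "ipred")
    y <- unlist(lapply(object$subjects, `[[`, "y"), use.names = FALSE)
    return((y - f) / (object$sigma * f))
  }
  unlist(lapply(seq_along(object$subjects), function(i)
    .cwres_subject(object, i)), use.names = FALSE)
}

.cwres_subject <- function(fit, i, h = 1e-4) {
  sub <- fit$subjects[[i]]
  d <- length(fit$iiv)
  pred <- .pred_factory(fit$model, sub, fit$iiv)
  if (d == 0L) {
    f0 <- pred(fit$theta, numeric(0))
    return((sub$y - f0) / (fit$sigma * f0))
  }
  eta <- fit$eta[i, ]
  fhat <- pred(fit$theta, eta)
  J <- matrix(0, length(fhat), d)
  for (k in seq_len(d)) {
    ek <- replace(numeric(d), k, h)
    J[, k] <- (pred(fit$theta, eta + ek) - pred(fit$theta, eta - ek)) / (2 * h)
  }
  V <- J %*% diag(fit$omega^2, d) %*% t(J) + diag(fit$sigma^2 * fhat^2,
                                                  length(fhat))
  mu <- fhat - as.vector(J %*% eta)
  L <- chol(V)
  as.vector(backsolve(L, sub$y - mu, transpose = TRUE))
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (PRED, eta = 0), individual
#' predictions (IPRED, at the eta modes) and conditional weighted residuals
#' (CWRES).
#'
#' @param fit A \code{\link{pkfit}}.
#' @return data.frame with columns \code{ID, TIME, DV, PRED, IPRED, CWRES}.
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "pkfit"))
  data.frame(
    ID = unlist(lapply(fit$subjects, function(s) rep(s$id, length(s$y))),
                use.names = FALSE),
    TIME = unlist(lapply(fit$subjects, `[[`, "t"), use.names = FALSE),
    DV = unlist(lapply(fit$subjects, `[[`, "y"), use.names = FALSE),
    PRED = predict.pkfit(fit, "pred"),
    IPRED = predict.pkfit(fit, "ipred"),
    CWRES = residuals.pkfit(fit, "cwres"))
}

#' Goodness-of-fit plots
#'
#' Four panels: CWRES vs time, CWRES vs PRED, DV vs PRED, DV vs IPRED.
#'
#' @param x A \code{\link{pkfit}}.
#' @param ... Passed to the panel plots.
#' @export
plot.pkfit <- function(x, ...) {
  g <- gof_table(x)
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(par(op))
  plot.default(g$TIME, g$CWRES, xlab = "Time (h)", ylab = "CWRES", ...)
  abline(h = 0, lty = 2)
  plot.default(g$PRED, g$CWRES, xlab = "PRED (mg/L)", ylab = "CWRES", ...)
  abline(h = 0, lty = 2)
  plot.default(g$PRED, g$DV, xlab = "PRED (mg/L)", ylab = "Observed (mg/L)", ...)
  abline(0, 1, lty = 2)
  plot.default(g$IPRED, g$DV, xlab = "IPRED (mg/L)", ylab = "Observed (mg/L)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

# simulate DV vectors for a set of prepared subjects under a model
.sim_subject_dv <- function(pred, theta, omega, sigma) {
  eta <- rnorm(length(omega), 0, omega)
  f <- pred(theta, eta)
  y <- f * (1 + rnorm(length(f), 0, sigma))
  while (sigma > 0 && any(bad <- y <= 0))    # resample eps, no point mass at 0
    y[bad] <- f[bad] * (1 + rnorm(sum(bad), 0, sigma))
  y
}

#' Simulate replicate datasets from a fitted model
#'
#' Redraws the random effects and the proportional residual error under the
#' fitted parameters, at each subject's own design (times, dose, covariates).
#'
#' @param object A \code{\link{pkfit}}.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of \code{nsim} data.frames shaped like the original data
#'   with simulated \code{DV}.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  preds <- lapply(object$subjects, .pred_factory,
                  model = object$model, iiv = object$iiv)
  omega <- object$omega
  obs_rows <- which(object$data$EVID == 0 & object$data$MDV == 0)
  lapply(seq_len(nsim), function(s) {
    dv <- unlist(lapply(preds, .sim_subject_dv, theta = object$theta,
                        omega = omega, sigma = object$sigma),
                 use.names = FALSE)
    out <- as.data.frame(object$data)
    out$DV[obs_rows] <- dv
    out
  })
}
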