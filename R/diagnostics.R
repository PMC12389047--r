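#' Visual predictive check
#'
#' Simulates replicate datasets under the model (random effects plus
#' proportional residual error) at the observed design, computes the
#' simulated percentiles per time bin together with their confidence
#' intervals, and overlays the observed percentiles. Binning is by the
#' nominal (exact) sampling times. Prediction correction is not applied:
#' the single-dose, single-dose-level design does not need it.
#'
#' @param data A \code{study_data} data.frame.
#' @param model A \code{\link{pk_model}} carrying the parameters to simulate
#'   from (e.g. \code{fit$model} after \code{\link{pkfit}}).
#' @param n_sim Number of simulated replicate datasets.
#' @param prob Percentiles to track (default 10/50/90th).
#' @param ci Confidence level of the simulated percentile bands.
#' @param iiv Parameters with IIV (default from the model's omega).
#' @param seed Optional seed.
#' @return Object of class \code{pk_vpc}: data.frame with columns
#'   \code{time, prob, observed, lower, upper, inside}.
#' @export
vpc <- function(data, model, n_sim = 1000, prob = c(0.1, 0.5, 0.9),
                ci = 0.95, iiv = names(model$omega), seed = NULL) {
  stopifnot(inherits(model, "pk_model"))
  if (!is.null(seed)) set.seed(seed)
  subjects <- .split_subjects(data)
  preds <- lapply(subjects, .pred_factory, model = model, iiv = iiv)
  omega <- model$omega[iiv]
  times <- unlist(lapply(subjects, `[[`, "t"))
  y_obs <- unlist(lapply(subjects, `[[`, "y"))
  bins <- sort(unique(times))
  pct <- function(y) vapply(bins, function(b)
    quantile(y[times == b], prob, names = FALSE), numeric(length(prob)))
  obs_pct <- pct(y_obs)                                  # prob x bins
  sim_pct <- array(NA_real_, c(length(prob), length(bins), n_sim))
  for (s in seq_len(n_sim)) {
    dv <- unlist(lapply(preds, .sim_subject_dv, theta = model$theta,
                        omega = omega, sigma = model$sigma))
    sim_pct[, , s] <- pct(dv)
  }
  alpha <- (1 - ci) / 2
  lower <- apply(sim_pct, c(1, 2), quantile, probs = alpha)
  upper <- apply(sim_pct, c(1, 2), quantile, probs = 1 - alpha)
  med <- apply(sim_pct, c(1, 2), median)
  out <- data.frame(
    time = rep(bins, each = length(prob)),
    prob = rep(prob, length(bins)),
    observed = as.vector(obs_pct),
    sim_median = as.vector(med),
    lower = as.vector(lower),
    upper = as.vector(upper))
  out$inside <- out$observed >= out$lower & out$observed <= out$upper
  structure(out, n_sim = n_sim, ci = ci, class = c("pk_vpc", "data.frame"))
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d simulations, %.0f%% CI; %d/%d observed percentiles inside\n",
              attr(x, "n_sim"), 100 * attr(x, "ci"), sum(x$inside), nrow(x)))
  print(as.data.frame(round(as.data.frame(x)[sapply(x, is.numeric)], 3)))
  invisible(x)
}

#' @export
plot.pk_vpc <- function(x, ...) {
  probs <- unique(x$prob)
  plot.default(range(x$time), range(c(x$lower, x$upper, x$observed)),
               type = "n", xlab = "Time (h)", ylab = "Concentration (mg/L)", ...)
  for (p in probs) {
    sub <- x[x$prob == p, ]
    polygon(c(sub$time, rev(sub$time)), c(sub$lower, rev(sub$upper)),
            col = adjustcolor("steelblue", 0.25), border = NA)
    lines(sub$time, sub$observed, type = "b", pch = 16)
  }
  mtext(sprintf("VPC (%d simulations)", attr(x, "n_sim")))
  invisible(x)
}

#' Nonparametric bootstrap of a fit
#'
#' Resamples subjects with replacement, refits each resample (started at the
#' original estimates), and reports medians and percentile confidence
#' intervals of all estimated parameters. Non-convergent resamples are
#' counted and excluded.
#'
#' @param fit A \code{\link{pkfit}}.
#' @param n_resamples Number of bootstrap resamples (2000 for full fidelity;
#'   a few hundred for exploratory use).
#' @param seed Optional seed.
#' @param ci Confidence level.
#' @return Object of class \code{pk_bootstrap}: a data.frame with the
#'   original estimate, bootstrap median and CI per parameter; the number of
#'   failed resamples is attached as an attribute.
#' @export
pk_bootstrap <- function(fit, n_resamples = 200, seed = NULL, ci = 0.95) {
  stopifnot(inherits(fit, "pkfit"))
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(fit$data$ID)
  start <- list(theta = fit$theta, omega = fit$omega, sigma = fit$sigma)
  ctrl <- fit$control
  ctrl$compute_se <- FALSE
  base_model <- update_pk_model(fit$model, theta = fit$theta,
                                omega = fit$omega, sigma = fit$sigma)
  draws <- list()
  n_failed <- 0L
  df <- as.data.frame(fit$data)
  for (b in seq_len(n_resamples)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      sub <- df[df$ID == take[k], ]
      sub$ID <- k
      sub
    })
    bdata <- do.call(rbind, pieces)
    bf <- tryCatch(
      pkfit(bdata, base_model, fixed = fit$fixed, iiv = fit$iiv,
            start = start, control = ctrl),
      error = function(e) NULL)
    if (is.null(bf) || !bf$converged) { n_failed <- n_failed + 1L; next }
    draws[[length(draws) + 1L]] <-
      c(bf$coefficients, bf$omega, sigma = bf$sigma)
  }
  if (length(draws) == 0) stop("no bootstrap resample converged")
  mat <- do.call(rbind, draws)
  alpha <- (1 - ci) / 2
  out <- data.frame(
    parameter = colnames(mat),
    estimate = c(fit$coefficients, fit$omega, sigma = fit$sigma),
    median = apply(mat, 2, median),
    lower = apply(mat, 2, quantile, probs = alpha),
    upper = apply(mat, 2, quantile, probs = 1 - alpha))
  rownames(out) <- NULL
  structure(out, n_resamples = n_resamples, n_failed = n_failed,
            class = c("pk_bootstrap", "data.frame"))
}

#' Stepwise covariate selection by OFV
#'
#' Forward selection / backward elimination on the covariate terms of the
#' structural model. A candidate enters when adding it drops the OFV by more
#' than \code{forward_dofv} (6.635, chi-square p < 0.01 on 1 df) and is
#' retained in the backward pass when its removal raises the OFV by at least
#' \code{backward_dofv} (10.83, p < 0.001). Candidate functional forms are
#' the ones appearing in the final models: a power of CE on CL
#' (\code{"cl_ce"}), a power of LBM on Q (\code{"q_lbm"}), an exponential of
#' centred WT on V2 (\code{"v2_wt"}).
#'
#' @param data A \code{study_data} data.frame.
#' @param model Base \code{\link{pk_model}}; candidate terms not already in
#'   its theta may be added.
#' @param candidates Character vector of candidate theta names.
#' @param fixed,iiv,start,control Passed to \code{\link{pkfit}} (standard
#'   errors are off by default here for speed).
#' @param forward_dofv,backward_dofv OFV thresholds.
#' @return List with \code{model} (final fitted model), \code{fit} (final
#'   \code{pkfit}), \code{selected} (added terms surviving elimination) and
#'   \code{trace} (data.frame logging every tested step).
#' @export
covariate_step <- function(data, model,
                           candidates = c("cl_ce", "q_lbm", "v2_wt"),
                           fixed = model$fixed, iiv = names(model$omega),
                           start = NULL,
                           control = pkfit_control(compute_se = FALSE),
                           forward_dofv = 6.635, backward_dofv = 10.83) {
  cand_start <- c(cl_ce = 0.1, q_lbm = 0.1, v2_wt = 0.01)
  cache <- new.env(parent = emptyenv())
  fit_one <- function(m) {
    key <- paste(sort(names(m$theta)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- pkfit(data, m, fixed = intersect(fixed, names(m$theta)),
               iiv = iiv, start = start, control = control)
    cache[[key]] <- f
    f
  }
  add_term <- function(m, term) {
    th <- c(m$theta, setNames(cand_start[[term]], term))
    update_pk_model(m, theta = th)
  }
  drop_term <- function(m, term)
    update_pk_model(m, theta = m$theta[setdiff(names(m$theta), term)])

  trace <- list()
  log_step <- function(phase, term, ofv_base, ofv_alt, action)
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, term = term, ofv_base = ofv_base, ofv_alt = ofv_alt,
      dofv = ofv_base - ofv_alt, action = action)

  cur <- model
  added <- character(0)
  repeat {
    avail <- setdiff(candidates, names(cur$theta))
    if (length(avail) == 0) break
    f_cur <- fit_one(cur)
    drops <- vapply(avail, function(term) {
      f2 <- fit_one(add_term(cur, term))
      log_step("forward", term, f_cur$ofv, f2$ofv, "tested")
      f_cur$ofv - f2$ofv
    }, 0)
    best <- which.max(drops)
    if (drops[best] > forward_dofv) {
      term <- avail[best]
      log_step("forward", term, f_cur$ofv, f_cur$ofv - drops[best], "added")
      cur <- add_term(cur, term)
      added <- c(added, term)
    } else break
  }
  # backward elimination on the candidate terms present in the model
  repeat {
    present <- intersect(candidates, names(cur$theta))
    if (length(present) == 0) break
    f_cur <- fit_one(cur)
    rises <- vapply(present, function(term) {
      f2 <- fit_one(drop_term(cur, term))
      log_step("backward", term, f_cur$ofv, f2$ofv, "tested")
      f2$ofv - f_cur$ofv
    }, 0)
    weakest <- which.min(rises)
    if (rises[weakest] < backward_dofv) {
      term <- present[weakest]
      log_step("backward", term, f_cur$ofv, f_cur$ofv + rises[weakest], "removed")
      cur <- drop_term(cur, term)
      added <- setdiff(added, term)
    } else break
  }
  final <- fit_one(cur)
  list(model = final$model, fit = final,
       selected = intersect(added, names(cur$theta)),
       trace = do.call(rbind, trace))
}
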