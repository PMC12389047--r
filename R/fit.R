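# Nonlinear mixed-effects estimation by the Laplace approximation.
#
# Marginal likelihood per subject: the integral over the log-normal random
# effects eta is approximated at the posterior mode eta_hat,
#   -2 log L_i = 2 g(eta_hat) - d log(2 pi) + log det H,
# where g(eta) = -log p(y | eta) - log p(eta) and H is the Hessian of g at
# the mode. The residual model is proportional with interaction: the error
# variance is evaluated at the conditional (eta-dependent) prediction,
# var(y_ij) = sigma^2 f(eta)^2. This mirrors FOCE-I's model; the
# approximation of the integral differs (Laplace at the mode rather than
# NONMEM's linearisation conventions).

.LOG2PI <- log(2 * pi)

# ---- dataset preparation ---------------------------------------------------

.split_subjects <- function(data) {
  req <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV", "CE", "WT", "LBM")
  if (!all(req %in% names(data)))
    stop("study dataset must contain columns ", paste(req, collapse = ", "))
  ids <- factor(data$ID, levels = unique(data$ID))  # keep appearance order
  lapply(split(as.data.frame(data), ids), function(sub) {
    dose <- sub[sub$EVID == 1, ]
    if (nrow(dose) != 1)
      stop("estimation supports single-dose subjects; subject ",
           sub$ID[1], " has ", nrow(dose), " dose events")
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    if (any(obs$TIME <= dose$TIME))
      stop("subject ", sub$ID[1], " has modelled observations at or before dosing")
    list(id = sub$ID[1],
         t = obs$TIME - dose$TIME, y = obs$DV,
         rate = dose$RATE, dur = dose$AMT / dose$RATE,
         ce = obs$CE[1], wt = obs$WT[1], lbm = obs$LBM[1])
  })
}

# prediction closure: f(theta named vector, eta plain vector ordered as iiv)
.pred_factory <- function(model, sub, iiv) {
  refs <- model$refs
  ce_r <- sub$ce / refs[["ce"]]
  lbm_r <- sub$lbm / refs[["lbm"]]
  wt_c <- sub$wt - refs[["wt"]]
  i_cl <- match("cl", iiv); i_v1 <- match("v1", iiv)
  i_q <- match("q", iiv); i_v2 <- match("v2", iiv)
  t <- sub$t; rate <- sub$rate; dur <- sub$dur
  function(th, eta) {
    cl <- th[["cl"]]
    if (!is.na(th["cl_ce"])) cl <- cl * ce_r^th[["cl_ce"]]
    q <- th[["q"]]
    if (!is.na(th["q_lbm"])) q <- q * lbm_r^th[["q_lbm"]]
    v2 <- th[["v2"]]
    if (!is.na(th["v2_wt"])) v2 <- v2 * exp(th[["v2_wt"]] * wt_c)
    v1 <- th[["v1"]]
    if (!is.na(i_cl)) cl <- cl * exp(eta[i_cl])
    if (!is.na(i_v1)) v1 <- v1 * exp(eta[i_v1])
    if (!is.na(i_q)) q <- q * exp(eta[i_q])
    if (!is.na(i_v2)) v2 <- v2 * exp(eta[i_v2])
    .conc1(t, cl, v1, q, v2, rate, dur)
  }
}

# -log p(y | f) for the proportional model, with interaction
.nll_data <- function(y, f, sigma) {
  if (any(f <= 0) || !all(is.finite(f))) return(Inf)
  v <- sigma^2 * f^2
  0.5 * sum((y - f)^2 / v + log(v) + .LOG2PI)
}

# d/df of the per-observation -log density (analytic)
.dnll_df <- function(y, f, sigma) {
  r <- y - f
  -r / (sigma^2 * f^2) - r^2 / (sigma^2 * f^3) + 1 / f
}

# Jacobian of the prediction vector wrt eta, central differences on f.
# f is an analytic function of eta, so this is smooth and deterministic --
# the inner-optimiser tolerance never leaks into the outer objective.
.pred_jac <- function(pred, theta, eta, h = 1e-5) {
  d <- length(eta)
  f0 <- pred(theta, eta)
  J <- matrix(0, length(f0), d)
  for (k in seq_len(d)) {
    ek <- replace(numeric(d), k, h)
    J[, k] <- (pred(theta, eta + ek) - pred(theta, eta - ek)) / (2 * h)
  }
  J
}

# Laplace -2 log L for one subject; warm is the starting eta
.laplace_subject <- function(pred, y, theta, omega, sigma, warm,
                             inner_rel_tol = 1e-12) {
  d <- length(omega)
  if (d == 0L) {
    f <- pred(theta, numeric(0))
    return(list(ofv = 2 * .nll_data(y, f, sigma), eta = numeric(0)))
  }
  g <- function(eta) {
    .nll_data(y, pred(theta, eta), sigma) +
      0.5 * sum(eta^2 / omega^2 + log(omega^2) + .LOG2PI)
  }
  grad <- function(eta) {
    f <- pred(theta, eta)
    J <- .pred_jac(pred, theta, eta)
    as.vector(crossprod(J, .dnll_df(y, f, sigma))) + eta / omega^2
  }
  hess <- function(eta) {
    h <- 1e-4
    H <- matrix(0, d, d)
    for (k in seq_len(d)) {
      ek <- replace(numeric(d), k, h)
      H[, k] <- (grad(eta + ek) - grad(eta - ek)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  # guarded Newton from the warm start; polishes the mode to machine
  # precision so the outer objective is smooth in the population parameters
  newton <- function(eta) {
    gv <- g(eta)
    if (!is.finite(gv)) return(NULL)
    for (it in 1:10) {
      gr <- grad(eta)
      if (sqrt(sum(gr^2)) < 1e-10) break
      H <- hess(eta)
      step <- tryCatch(solve(H, gr), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      ok <- FALSE
      for (half in 0:5) {
        cand <- eta - step / 2^half
        gc <- g(cand)
        if (is.finite(gc) && gc <= gv + 1e-12) {
          eta <- cand; gv <- gc; ok <- TRUE; break
        }
      }
      if (!ok) break
    }
    list(par = eta, objective = gv)
  }
  opt <- newton(warm)
  if (is.null(opt) || sqrt(sum(grad(opt$par)^2)) > 1e-6) {
    opt <- tryCatch(
      nlminb(numeric(d), g, gradient = grad,
             control = list(rel.tol = inner_rel_tol, x.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective))
      stop("inner optimisation failed to converge for a subject")
    pol <- newton(opt$par)
    if (!is.null(pol) && pol$objective <= opt$objective) opt <- pol
  }
  H <- hess(opt$par)
  detH <- det(H)
  if (!is.finite(detH) || detH <= 0) {
    # fall back to the prior curvature when the mode Hessian is indefinite
    detH <- prod(1 / omega^2)
  }
  list(ofv = 2 * opt$objective + log(detH) - d * .LOG2PI, eta = opt$par)
}

# ---- parameter packing -----------------------------------------------------

.POSITIVE_THETAS <- c("cl", "v1", "q", "v2")

.pack <- function(theta_free, omega, sigma) {
  th <- ifelse(names(theta_free) %in% .POSITIVE_THETAS,
               log(theta_free), theta_free)
  c(setNames(th, paste0("th_", names(theta_free))),
    setNames(log(omega), paste0("om_", names(omega))),
    sig = log(sigma))
}

.unpack <- function(par, free_names, iiv) {
  nth <- length(free_names)
  th <- par[seq_len(nth)]
  th <- ifelse(free_names %in% .POSITIVE_THETAS, exp(th), th)
  names(th) <- free_names
  om <- exp(par[nth + seq_along(iiv)])
  names(om) <- iiv
  list(theta = th, omega = om, sigma = exp(par[[length(par)]]))
}

#' Control settings for \code{\link{pkfit}}
#'
#' @param outer_iter,outer_eval Iteration/evaluation caps of the outer
#'   quasi-Newton optimiser.
#' @param outer_rel_tol Outer relative convergence tolerance.
#' @param inner_rel_tol Inner (eta-mode) relative tolerance.
#' @param compute_se Compute the numerical Hessian at the optimum for
#'   standard errors (disable for speed in repeated fits).
#' @param n_starts Number of starts; starts after the first perturb the
#'   initial values (multi-start guards against local minima).
#' @param jitter_sd Log-scale SD of the multi-start perturbation.
#' @param max_restarts Maximum outer restarts from the incumbent when the
#'   optimiser reports non-zero convergence.
#' @return A list of settings.
#' @export
pkfit_control <- function(outer_iter = 300, outer_eval = 1000,
                          outer_rel_tol = 1e-7, inner_rel_tol = 1e-12,
                          compute_se = TRUE, n_starts = 1, jitter_sd = 0.2,
                          max_restarts = 8) {
  list(outer_iter = outer_iter, outer_eval = outer_eval,
       outer_rel_tol = outer_rel_tol, inner_rel_tol = inner_rel_tol,
       compute_se = compute_se, n_starts = n_starts, jitter_sd = jitter_sd,
       max_restarts = max_restarts)
}

.default_start <- function(model, fixed) {
  gen <- c(cl = 10, cl_ce = 1, v1 = 5, q = 4, q_lbm = 1, v2 = 3, v2_wt = 0.02)
  th <- model$theta
  for (nm in names(th)) if (!nm %in% fixed && nm %in% names(gen))
    th[nm] <- gen[[nm]]
  list(theta = th,
       omega = setNames(rep(0.1, length(model$omega)), names(model$omega)),
       sigma = 0.15)
}

# ---- the fitting function --------------------------------------------------

#' Fit a population PK model by Laplace-approximation NLME
#'
#' Maximises the Laplace-approximated marginal likelihood of the
#' two-compartment infusion model over the fixed effects and variance
#' components. Structural parameters constrained positive (\code{cl, v1, q,
#' v2}) are estimated on the log scale; covariate exponents are unbounded;
#' variance components are estimated as log-SDs. The per-subject eta modes
#' are warm-started across outer iterations.
#'
#' @param data A \code{study_data} data.frame (see \code{\link{read_study}}).
#' @param model A \code{\link{pk_model}} defining the structural/covariate
#'   model; its theta names decide which covariate terms exist.
#' @param fixed Names of thetas fixed at the model's values (default: the
#'   model's own \code{fixed} set, e.g. the intercompartmental clearance for
#'   piperacillin).
#' @param iiv Names of parameters carrying log-normal interindividual
#'   variability (default: those in the model's \code{omega}).
#' @param start Optional list with elements \code{theta}, \code{omega},
#'   \code{sigma} providing initial values; defaults to generic values.
#' @param control A \code{\link{pkfit_control}} list.
#' @return An object of class \code{pkfit} with \code{print}, \code{summary},
#'   \code{coef}, \code{logLik}, \code{predict}, \code{residuals},
#'   \code{simulate} and \code{plot} methods.
#' @examples
#' \donttest{
#' ds <- generate_study(study_design(n = 12, seed = 1), pk_model("tazobactam"))
#' fit <- pkfit(ds, pk_model("tazobactam"),
#'              control = pkfit_control(compute_se = FALSE))
#' coef(fit)
#' }
#' @export
pkfit <- function(data, model, fixed = model$fixed,
                  iiv = names(model$omega), start = NULL,
                  control = pkfit_control()) {
  stopifnot(inherits(model, "pk_model"))
  subjects <- .split_subjects(data)
  if (!all(iiv %in% c("cl", "v1", "q", "v2")))
    stop("iiv must name structural parameters")
  free_names <- setdiff(names(model$theta), fixed)
  if (length(free_names) == 0 && length(iiv) == 0)
    stop("nothing to estimate")
  st <- .default_start(model, fixed)
  if (!is.null(start)) {
    if (!is.null(start$theta)) st$theta[names(start$theta)] <- start$theta
    if (!is.null(start$omega)) st$omega[names(start$omega)] <- start$omega
    if (!is.null(start$sigma)) st$sigma <- start$sigma
  }
  st$omega <- st$omega[iiv]
  if (length(iiv) && (anyNA(st$omega) || any(st$omega <= 0)))
    stop("positive starting omega required for each iiv parameter")

  nsub <- length(subjects)
  subj_cpp <- .subjects_for_cpp(subjects, model)
  iiv_idx <- match(iiv, c("cl", "v1", "q", "v2")) - 1L
  warm_env <- new.env(parent = emptyenv())
  warm_env$eta <- matrix(0, nsub, length(iiv))
  theta_full <- model$theta   # fixed values live here

  objective <- function(par) {
    up <- .unpack(par, free_names, iiv)
    th <- theta_full
    th[free_names] <- up$theta
    res <- .ofv_all_cpp(subj_cpp, .theta7(th), iiv_idx, up$omega, up$sigma,
                        warm_env$eta)
    if (isTRUE(res$failed) || !is.finite(res$ofv)) return(1e10)
    warm_env$eta[] <- res$eta
    res$ofv
  }

  # explicit central-difference gradient: the FD step is chosen well above
  # the (tiny, Newton-polished) objective noise floor
  outer_grad <- function(par) {
    h <- 1e-5
    gr <- numeric(length(par))
    for (i in seq_along(par)) {
      ei <- replace(numeric(length(par)), i, h)
      gr[i] <- (objective(par + ei) - objective(par - ei)) / (2 * h)
    }
    gr
  }
  par0 <- .pack(st$theta[free_names], st$omega, st$sigma)
  run_start <- function(p0) {
    warm_env$eta[] <- 0
    opt <- nlminb(p0, objective, gradient = outer_grad,
                  control = list(rel.tol = control$outer_rel_tol,
                                 iter.max = control$outer_iter,
                                 eval.max = control$outer_eval))
    # PORT occasionally reports false convergence on this objective;
    # restarting from the incumbent until the OFV stops moving fixes it
    opt$converged <- opt$convergence == 0
    for (r in seq_len(control$max_restarts)) {
      if (opt$convergence == 0) break
      opt2 <- nlminb(opt$par, objective, gradient = outer_grad,
                     control = list(rel.tol = control$outer_rel_tol,
                                    iter.max = control$outer_iter,
                                    eval.max = control$outer_eval))
      improved <- opt$objective - opt2$objective
      opt2$converged <- opt2$convergence == 0 || improved < 1e-3
      opt <- opt2
      if (opt$converged) break
    }
    opt
  }
  best <- NULL
  for (s in seq_len(max(1L, control$n_starts))) {
    p0 <- if (s == 1L) par0 else par0 + rnorm(length(par0), 0, control$jitter_sd)
    opt <- run_start(p0)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  opt <- best

  up <- .unpack(opt$par, free_names, iiv)
  theta_hat <- theta_full
  theta_hat[free_names] <- up$theta

  # refresh eta modes at the optimum
  ofv_final <- objective(opt$par)
  eta_hat <- warm_env$eta
  colnames(eta_hat) <- iiv

  se <- rse <- NULL
  if (isTRUE(control$compute_se) && length(opt$par) > 0) {
    Hofv <- tryCatch(optimHess(opt$par, objective), error = function(e) NULL)
    if (!is.null(Hofv)) {
      cov <- tryCatch(2 * solve(Hofv), error = function(e) NULL)
      if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
        se <- sqrt(diag(cov))
        names(se) <- names(opt$par)
        # on the log scale, SE(log x) is already a relative SE
        est_nat <- c(up$theta, up$omega, sigma = up$sigma)
        logscale <- c(free_names %in% .POSITIVE_THETAS,
                      rep(TRUE, length(iiv)), TRUE)
        rse <- ifelse(logscale, se, se / abs(unlist(est_nat))) * 100
        names(rse) <- names(opt$par)
      }
    }
  }

  shr <- if (length(iiv))
    100 * (1 - apply(eta_hat, 2, sd) / up$omega) else numeric(0)

  structure(list(
    model = update_pk_model(model, theta = theta_hat, omega = up$omega,
                            sigma = up$sigma),
    coefficients = theta_hat[free_names],
    theta = theta_hat, omega = up$omega, sigma = up$sigma,
    ofv = ofv_final, se = se, rse = rse,
    eta = eta_hat, shrinkage = shr,
    fixed = fixed, iiv = iiv, free_names = free_names,
    par = opt$par, convergence = opt$convergence,
    converged = isTRUE(opt$converged),
    message = opt$message, n_subjects = nsub,
    n_obs = sum(vapply(subjects, function(s) length(s$y), 0L)),
    data = data, subjects = subjects, control = control),
    class = "pkfit")
}

# pack the structural thetas into the fixed 7-slot layout the C++ kernel uses
.theta7 <- function(th) {
  out <- rep(NA_real_, 7)
  slots <- c(cl = 1, cl_ce = 2, v1 = 3, q = 4, q_lbm = 5, v2 = 6, v2_wt = 7)
  for (nm in names(th)) out[slots[[nm]]] <- th[[nm]]
  out
}

.subjects_for_cpp <- function(subjects, model) {
  refs <- model$refs
  lapply(subjects, function(s)
    list(t = s$t, y = s$y, rate = s$rate, dur = s$dur,
         ce_r = s$ce / refs[["ce"]], lbm_r = s$lbm / refs[["lbm"]],
         wt_c = s$wt - refs[["wt"]]))
}

#' Laplace objective function value at given parameters
#'
#' Evaluates -2 log of the Laplace-approximated marginal likelihood without
#' optimising the population parameters (the per-subject eta modes are still
#' located). With an empty \code{iiv}, the value reduces to the
#' fixed-effects-only -2 log likelihood.
#'
#' @inheritParams pkfit
#' @return OFV (numeric scalar) with the per-subject eta modes attached as
#'   attribute \code{"eta"}.
#' @export
pk_ofv <- function(data, model, iiv = names(model$omega)) {
  subjects <- .split_subjects(data)
  iiv <- iiv[model$omega[iiv] > 0]
  omega <- model$omega[iiv]
  res <- .ofv_all_cpp(.subjects_for_cpp(subjects, model),
                      .theta7(model$theta),
                      match(iiv, c("cl", "v1", "q", "v2")) - 1L,
                      omega, model$sigma,
                      matrix(0, length(subjects), length(iiv)))
  if (isTRUE(res$failed)) stop("inner optimisation failed to converge")
  tot <- res$ofv
  eta <- res$eta
  dimnames(eta) <- list(NULL, iiv)
  attr(tot, "eta") <- eta
  tot
}
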