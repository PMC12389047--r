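#' Load a published population PK model
#'
#' Returns the final two-compartment covariate model for piperacillin or
#' tazobactam. Structural model (reference covariates CE = 108.25 mL/min,
#' WT = 61.7 kg, LBM = 50.08 kg):
#' \deqn{CL = \theta_{CL} (CE/108.25)^{\theta_{CL,CE}}, \quad V_1 = \theta_{V1},}
#' \deqn{Q = \theta_{Q} (LBM/50.08)^{\theta_{Q,LBM}}, \quad
#'       V_2 = \theta_{V2} \exp(\theta_{V2,WT} (WT - 61.7)),}
#' where the Q-on-LBM power is present for piperacillin only. Interindividual
#' variability is log-normal on CL (and V1 for piperacillin); residual error
#' is proportional. The free (unbound) fraction fu = 0.7 applies to
#' piperacillin; tazobactam concentrations carry no pharmacodynamic target.
#'
#' Parameters are read from a versioned JSON file shipped with the package;
#' an alternative file with the same schema can be supplied.
#'
#' @param drug \code{"piperacillin"} or \code{"tazobactam"}.
#' @param file Optional path to a parameter JSON file.
#' @return An object of class \code{pk_model}: a list with elements
#'   \code{drug}, \code{theta} (named vector), \code{fixed} (names of thetas
#'   fixed during estimation), \code{omega} (named vector of log-normal IIV
#'   standard deviations), \code{sigma} (proportional residual SD),
#'   \code{refs} (reference covariates) and \code{fu}.
#' @examples
#' mod <- pk_model("piperacillin")
#' typical_params(mod, ce = 108.25, wt = 61.7, lbm = 50.08)
#' @export
pk_model <- function(drug = c("piperacillin", "tazobactam"), file = NULL) {
  drug <- match.arg(drug)
  if (is.null(file))
    file <- system.file("extdata", "piptaz_parameters.json", package = "piptazpk")
  pars <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(pars$schema, "piptazpk-parameters"))
    stop("not a piptazpk parameter file: ", file)
  d <- pars$drugs[[drug]]
  if (is.null(d)) stop("no parameters for drug '", drug, "' in ", file)
  new_pk_model(
    drug  = drug,
    theta = unlist(d$theta),
    fixed = as.character(d$fixed),
    omega = unlist(d$omega),
    sigma = d$sigma,
    refs  = unlist(pars$reference_covariates),
    fu    = if (is.null(d$fu)) NA_real_ else d$fu)
}

new_pk_model <- function(drug, theta, fixed, omega, sigma, refs, fu) {
  stopifnot(all(c("cl", "v1", "q", "v2") %in% names(theta)),
            all(c("ce", "wt", "lbm") %in% names(refs)))
  if (any(theta[c("cl", "v1", "q", "v2")] <= 0))
    stop("clearances and volumes must be strictly positive")
  if (any(omega < 0) || sigma < 0)
    stop("variance components must be non-negative")
  structure(list(drug = drug, theta = theta, fixed = fixed,
                 omega = omega, sigma = sigma, refs = refs, fu = fu),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Population PK model:", x$drug, "(two-compartment, zero-order infusion)\n")
  cat("Thetas:\n")
  print(round(x$theta, 4))
  if (length(x$fixed)) cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  cat("IIV (CV):", paste(sprintf("%s=%.1f%%", names(x$omega), 100 * x$omega),
                         collapse = ", "), "\n")
  cat("Proportional residual error:", sprintf("%.1f%%", 100 * x$sigma), "\n")
  if (!is.na(x$fu)) cat("Unbound fraction fu:", x$fu, "\n")
  invisible(x)
}

#' Typical (population) PK parameters at given covariates
#'
#' Evaluates the covariate model at CE (BSA-adjusted absolute CKD-EPI
#' creatinine eGFR, mL/min), total body weight WT (kg) and lean body mass
#' LBM (kg). Vectorised over covariates.
#'
#' @param model A \code{\link{pk_model}}.
#' @param ce,wt,lbm Covariate values.
#' @return data.frame with columns \code{cl}, \code{v1}, \code{q}, \code{v2}
#'   (L/h and L).
#' @export
typical_params <- function(model, ce, wt = model$refs[["wt"]],
                           lbm = model$refs[["lbm"]]) {
  stopifnot(inherits(model, "pk_model"))
  if (any(ce <= 0) || any(wt <= 0) || any(lbm <= 0))
    stop("covariates must be strictly positive")
  th <- model$theta; refs <- model$refs
  n <- max(length(ce), length(wt), length(lbm))
  ce <- rep_len(ce, n); wt <- rep_len(wt, n); lbm <- rep_len(lbm, n)
  cl <- th[["cl"]] *
    (if ("cl_ce" %in% names(th)) (ce / refs[["ce"]])^th[["cl_ce"]] else 1)
  q <- th[["q"]] *
    (if ("q_lbm" %in% names(th)) (lbm / refs[["lbm"]])^th[["q_lbm"]] else 1)
  v2 <- th[["v2"]] *
    (if ("v2_wt" %in% names(th)) exp(th[["v2_wt"]] * (wt - refs[["wt"]])) else 1)
  data.frame(cl = cl, v1 = rep_len(th[["v1"]], n), q = q, v2 = v2)
}

#' Individual PK parameters from typical values and random effects
#'
#' Applies log-normal interindividual variability: each parameter named in
#' \code{eta} is multiplied by \code{exp(eta)}; all others are unchanged.
#'
#' @param typical data.frame from \code{\link{typical_params}} (or a
#'   one-row list with cl, v1, q, v2).
#' @param eta Named numeric vector, or a matrix with one row per subject;
#'   names must be a subset of \code{c("cl", "v1", "q", "v2")}.
#' @return data.frame of individual parameters.
#' @export
individual_params <- function(typical, eta) {
  typical <- as.data.frame(typical)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow(typical), length(eta),
                                       byrow = TRUE, dimnames = list(NULL, names(eta)))
  if (is.null(colnames(eta)) || !all(colnames(eta) %in% c("cl", "v1", "q", "v2")))
    stop("eta must be named with a subset of cl, v1, q, v2")
  if (nrow(eta) != nrow(typical))
    stop("eta has ", nrow(eta), " rows but typical has ", nrow(typical))
  for (p in colnames(eta)) typical[[p]] <- typical[[p]] * exp(eta[, p])
  typical
}

#' Steady-state volume of distribution
#'
#' @param p A parameter set with elements/columns \code{v1} and \code{v2}.
#' @return \code{v1 + v2} in litres.
#' @examples
#' vss(typical_params(pk_model("piperacillin"), ce = 108.25))  # 8.83 L
#' @export
vss <- function(p) {
  if (any(p$v1 <= 0) || any(p$v2 <= 0)) stop("volumes must be positive")
  p$v1 + p$v2
}

# replace estimated components of a model (used by the fitting machinery)
update_pk_model <- function(model, theta = NULL, omega = NULL, sigma = NULL,
                            fixed = NULL) {
  if (!is.null(theta)) model$theta <- theta
  if (!is.null(omega)) model$omega <- omega
  if (!is.null(sigma)) model$sigma <- sigma
  if (!is.null(fixed)) model$fixed <- fixed
  new_pk_model(model$drug, model$theta, model$fixed, model$omega,
               model$sigma, model$refs, model$fu)
}

#' Write a parameter file for one or two models
#'
#' Emits the same JSON schema the package ships, so user-modified models can
#' be reloaded with \code{\link{pk_model}}.
#'
#' @param models A list of \code{pk_model} objects (named by drug or not).
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_pk_parameters <- function(models, file) {
  if (inherits(models, "pk_model")) models <- list(models)
  refs <- models[[1]]$refs
  drugs <- lapply(models, function(m) {
    list(theta = as.list(m$theta), fixed = I(m$fixed),
         omega = as.list(m$omega), sigma = m$sigma,
         fu = if (is.na(m$fu)) NULL else m$fu)
  })
  names(drugs) <- vapply(models, `[[`, "", "drug")
  jsonlite::write_json(
    list(schema = "piptazpk-parameters", version = "1.0",
         reference_covariates = as.list(refs), drugs = drugs),
    file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
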