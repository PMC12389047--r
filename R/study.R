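#' Specify a synthetic single-dose study design
#'
#' Mirrors the clinical design: a single 30-min zero-order infusion of
#' 4 g piperacillin / 0.5 g tazobactam with rich plasma sampling immediately
#' before dosing and at 0.5, 0.75, 1, 2, 3 and 6 h after the start of the
#' infusion. Covariates are drawn uniformly within sex-specific observed
#' ranges (configurable to truncated normal via
#' \code{\link{default_demographics}}-style parameters).
#'
#' @param n Number of subjects (default 12).
#' @param female_fraction Expected fraction of female subjects (default 1/3,
#'   as in the study: 4 of 12).
#' @param dose Named vector of doses in mg per drug.
#' @param duration Infusion duration in hours.
#' @param times Nominal sampling times (h); the first must be the predose 0.
#' @param ranges Sex-specific covariate min-max ranges (uniform sampling):
#'   nested list \code{$male}/\code{$female} each with \code{age, height,
#'   weight, cr, cc} as \code{c(min, max)}.
#' @param seed Optional integer seed.
#' @return Object of class \code{study_design}.
#' @export
study_design <- function(n = 12, female_fraction = 4 / 12,
                         dose = c(piperacillin = 4000, tazobactam = 500),
                         duration = 0.5,
                         times = c(0, 0.5, 0.75, 1, 2, 3, 6),
                         ranges = study_covariate_ranges(),
                         seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (is.unsorted(times, strictly = TRUE)) stop("sampling times must be sorted")
  if (times[1] != 0) stop("first sample must be the predose time 0")
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 dose = dose, duration = duration, times = times,
                 ranges = ranges, seed = seed),
            class = "study_design")
}

#' @rdname study_design
#' @export
study_covariate_ranges <- function() {
  list(
    male = list(age = c(32, 50), height = c(160, 182), weight = c(54.5, 88.5),
                cr = c(0.80, 1.08), cc = c(0.66, 1.01)),
    female = list(age = c(26, 36), height = c(158, 167), weight = c(45.8, 59.5),
                  cr = c(0.59, 0.75), cc = c(0.62, 0.74)))
}

#' Generate a synthetic study dataset
#'
#' Draws covariates, applies log-normal interindividual variability
#' (\eqn{\theta_i = \theta e^{\eta_i}}), computes noiseless profiles with the
#' analytic solver, and adds proportional residual error
#' \eqn{y = f (1 + \epsilon)}, \eqn{\epsilon \sim N(0, \sigma^2)}, resampling
#' \eqn{\epsilon} when a simulated concentration would be non-positive. The
#' predose sample is a true zero flagged as missing (\code{MDV = 1}).
#' Subjects are generated sequentially, so enlarging \code{n} under the same
#' seed preserves the first subjects.
#'
#' @param design A \code{\link{study_design}}.
#' @param model A \code{\link{pk_model}}; its drug selects the dose.
#' @param omega,sigma Override the model's variability components (useful
#'   for noise-free or inflated-variability experiments).
#' @return A \code{study_data} data.frame in NONMEM-convention layout with
#'   columns \code{ID, TIME, AMT, RATE, EVID, DV, MDV, CE, WT, LBM, SEX,
#'   AGE}. The generating truth (theta/omega/sigma), the drawn etas and the
#'   number of resampled residuals are attached as attributes.
#' @examples
#' ds <- generate_study(study_design(n = 4, seed = 7), pk_model("piperacillin"))
#' head(ds)
#' @export
generate_study <- function(design, model, omega = model$omega,
                           sigma = model$sigma) {
  stopifnot(inherits(design, "study_design"), inherits(model, "pk_model"))
  dose <- design$dose[[model$drug]]
  if (is.null(dose)) stop("design carries no dose for ", model$drug)
  if (!is.null(design$seed)) set.seed(design$seed)
  rate <- dose / design$duration
  t_obs <- design$times[-1]
  rows <- vector("list", design$n)
  etas <- matrix(0, design$n, length(omega),
                 dimnames = list(NULL, names(omega)))
  n_resampled <- 0L
  for (i in seq_len(design$n)) {
    female <- rbinom(1, 1, design$female_fraction) == 1
    rg <- design$ranges[[if (female) "female" else "male"]]
    age <- runif(1, rg$age[1], rg$age[2])
    ht <- runif(1, rg$height[1], rg$height[2])
    wt <- runif(1, rg$weight[1], rg$weight[2])
    cr <- runif(1, rg$cr[1], rg$cr[2])
    bc <- body_composition(ht, wt, female)
    ce <- bsa_adjust(egfr_ckdepi(age, cr, female = female), bc$bsa)
    eta <- rnorm(length(omega), 0, omega)
    names(eta) <- names(omega)
    etas[i, ] <- eta
    typ <- typical_params(model, ce, wt, bc$lbm)
    ind <- individual_params(typ, matrix(eta, 1, dimnames = list(NULL, names(eta))))
    f <- .conc1(t_obs, ind$cl, ind$v1, ind$q, ind$v2, rate, design$duration)
    dv <- numeric(length(f))
    for (j in seq_along(f)) {
      repeat {
        y <- f[j] * (1 + rnorm(1, 0, sigma))
        if (y > 0 || sigma == 0) break
        n_resampled <- n_resampled + 1L
      }
      dv[j] <- y
    }
    cov <- data.frame(CE = ce, WT = wt, LBM = bc$lbm,
                      SEX = as.integer(female), AGE = age)
    rows[[i]] <- cbind(
      data.frame(
        ID = i,
        TIME = c(0, 0, t_obs),
        AMT = c(NA, dose, rep(NA, length(t_obs))),
        RATE = c(NA, rate, rep(NA, length(t_obs))),
        EVID = c(0L, 1L, rep(0L, length(t_obs))),
        DV = c(0, NA, dv),
        MDV = c(1L, 1L, rep(0L, length(t_obs)))),
      cov[rep(1, length(t_obs) + 2), , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, design = design,
            truth = list(theta = model$theta, omega = omega, sigma = sigma),
            etas = etas, n_resampled = n_resampled,
            drug = model$drug,
            class = c("study_data", "data.frame"))
}

#' Read/write NONMEM-convention study datasets
#'
#' CSV dialect with columns \code{ID, TIME, AMT, RATE, EVID, DV, MDV} plus
#' covariates \code{CE, WT, LBM, SEX, AGE}. Numeric values are written with
#' 17 significant digits so datasets round-trip losslessly. The reader
#' validates that every modelled observation is preceded by a dose event.
#'
#' @param data A \code{study_data} data.frame.
#' @param file Path to the CSV file.
#' @return \code{write_study}: \code{file}, invisibly. \code{read_study}:
#'   a \code{study_data} data.frame.
#' @export
write_study <- function(data, file) {
  out <- as.data.frame(data)
  for (v in names(out))
    if (is.double(out[[v]])) out[[v]] <- sprintf("%.17g", out[[v]])
  out[out == "NA"] <- ""
  write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname write_study
#' @export
read_study <- function(file) {
  x <- read.csv(file)
  req <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV")
  if (!all(req %in% names(x)))
    stop("study dataset must contain columns ", paste(req, collapse = ", "))
  for (v in c("TIME", "AMT", "RATE", "DV", "CE", "WT", "LBM", "AGE"))
    if (v %in% names(x)) x[[v]] <- as.double(x[[v]])
  for (v in c("ID", "EVID", "MDV", "SEX"))
    if (v %in% names(x)) x[[v]] <- as.integer(x[[v]])
  for (id in unique(x$ID)) {
    sub <- x[x$ID == id, ]
    doses <- sub$TIME[sub$EVID == 1]
    if (length(doses) == 0) stop("subject ", id, " has no dose event")
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    if (any(obs$TIME < min(doses)))
      stop("subject ", id, " has modelled observations before the first dose")
    if (any(obs$DV <= 0))
      stop("subject ", id, " has non-positive modelled concentrations")
  }
  structure(x, class = c("study_data", "data.frame"))
}

#' Build a deterministic PTA regression fixture
#'
#' Samples a small cohort, computes its PTA table for a regimen/target grid,
#' and writes cohort, expected-PTA table and a manifest (seed + MD5
#' checksums) to \code{dir}. Intended for committed regression fixtures, so
#' the cohort size is capped at 200.
#'
#' @param spec A \code{\link{population_spec}} (with its seed set).
#' @param regimens List of \code{\link{regimen}} objects.
#' @param targets List of \code{\link{pd_target}} objects.
#' @param dir Output directory (created if needed).
#' @param mic_grid MIC grid.
#' @return Invisibly, the manifest as a list.
#' @export
generate_pta_fixture <- function(spec, regimens, targets, dir,
                                 mic_grid = mic_grid_default()) {
  if (spec$n > 200) stop("fixture cohorts are capped at 200 subjects")
  if (is.null(spec$seed)) stop("fixture generation requires a seeded spec")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- sample_cohort(spec)
  tab <- regimen_sweep(list(fixture = coh), regimens, targets, mic_grid)
  cohort_file <- file.path(dir, "cohort.csv")
  pta_file <- file.path(dir, "expected_pta.csv")
  co <- as.data.frame(coh)
  for (v in names(co)) if (is.double(co[[v]])) co[[v]] <- sprintf("%.17g", co[[v]])
  write.csv(co, cohort_file, row.names = FALSE, quote = FALSE)
  write.csv(tab, pta_file, row.names = FALSE)
  manifest <- list(seed = spec$seed, n = spec$n, mode = spec$mode,
                   egfr_range = spec$egfr_range,
                   files = list(
                     cohort = unname(tools::md5sum(cohort_file)),
                     expected_pta = unname(tools::md5sum(pta_file))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
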