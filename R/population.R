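#' Default demographic sampling distributions
#'
#' Sex-specific truncated-normal parameters for age, height, weight, serum
#' creatinine and cystatin C, read from a JSON configuration shipped with
#' the package. Means sit at the healthy-adult cohort medians; SDs place the
#' observed min-max range at the central 95\%; truncation bounds exclude
#' non-physiological values.
#'
#' @param file Optional path to an alternative configuration file.
#' @return Nested list: \code{$male} / \code{$female}, each with
#'   \code{age, height, weight, cr, cc}, each a list
#'   \code{mean, sd, lower, upper}.
#' @export
default_demographics <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "population_defaults.json", package = "piptazpk")
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(cfg$schema, "piptazpk-population"))
    stop("not a piptazpk population configuration: ", file)
  cfg[c("male", "female")]
}

#' Renal function categories used for targeted dosing simulations
#'
#' @return Named list of \code{c(lower, upper)} eGFR bounds in mL/min.
#' @export
egfr_categories <- function() {
  list("0-20" = c(0, 20), "20-40" = c(20, 40), "40-90" = c(40, 90),
       "90-130" = c(90, 130), "130-180" = c(130, 180))
}

#' Specify a virtual population
#'
#' Two sampling modes are supported. In \code{"free"} mode, demographics are
#' drawn from sex-specific truncated normal distributions, renal function is
#' computed as the BSA-adjusted absolute CKD-EPI creatinine eGFR, and
#' subjects are retained only if that eGFR falls within \code{egfr_range}
#' (rejection sampling); the default window 90-130 mL/min operationalises
#' "normal renal function". In \code{"category"} mode, eGFR is drawn
#' uniformly within the category bounds and weight and lean body mass are
#' fixed at the study medians (61.7 and 50.08 kg), isolating the effect of
#' renal function.
#'
#' @param n Number of subjects.
#' @param mode \code{"free"} or \code{"category"}.
#' @param egfr_range \code{c(lower, upper)} eGFR window in mL/min, or (in
#'   category mode) the name of a category from \code{\link{egfr_categories}}.
#' @param female_fraction Probability that a subject is female (free mode).
#' @param demographics Configuration as from \code{\link{default_demographics}}.
#' @param fixed_wt,fixed_lbm Fixed covariates used in category mode.
#' @param seed Optional integer seed; sampling is then reproducible.
#' @return Object of class \code{population_spec}.
#' @export
population_spec <- function(n, mode = c("free", "category"),
                            egfr_range = if (mode[1] == "free") c(90, 130) else "90-130",
                            female_fraction = 0.5,
                            demographics = default_demographics(),
                            fixed_wt = 61.7, fixed_lbm = 50.08,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (n <= 0) stop("n must be positive")
  if (is.character(egfr_range)) {
    egfr_range <- egfr_categories()[[egfr_range]]
    if (is.null(egfr_range)) stop("unknown eGFR category")
  }
  if (length(egfr_range) != 2 || diff(egfr_range) <= 0)
    stop("egfr_range must be an ordered pair")
  structure(list(n = as.integer(n), mode = mode, egfr_range = egfr_range,
                 female_fraction = female_fraction,
                 demographics = demographics,
                 fixed_wt = fixed_wt, fixed_lbm = fixed_lbm, seed = seed),
            class = "population_spec")
}

# one truncated-normal draw consuming exactly one normal deviate per attempt
.rtnorm1 <- function(par) {
  for (i in 1:10000) {
    x <- rnorm(1, par$mean, par$sd)
    if (x > par$lower && x < par$upper) return(x)
  }
  stop("truncation bounds rejected >99.99% of draws")
}

#' Sample a virtual cohort
#'
#' Draws subjects one at a time so that enlarging \code{n} under the same
#' seed preserves the first subjects exactly. Each subject's random-effect
#' vector is drawn once (per drug) and reused across regimens, making
#' regimen comparisons paired.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param models List of \code{\link{pk_model}} objects (default: both
#'   shipped drugs).
#' @return Object of class \code{pk_cohort}: a data.frame with one row per
#'   subject carrying demographics, body composition, the renal covariate
#'   \code{ce}, and per-drug individual PK parameters (columns
#'   \code{cl_pip}, \code{v1_pip}, ... / \code{cl_taz}, ...), with the spec
#'   and models attached as attributes.
#' @examples
#' sp <- population_spec(20, mode = "category", egfr_range = "90-130", seed = 1)
#' coh <- sample_cohort(sp)
#' summary(coh)
#' @export
sample_cohort <- function(spec,
                          models = list(pk_model("piperacillin"),
                                        pk_model("tazobactam"))) {
  stopifnot(inherits(spec, "population_spec"))
  if (inherits(models, "pk_model")) models <- list(models)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (spec$mode == "category") {
      sub <- data.frame(id = i, sex = NA_integer_, age = NA_real_,
                        height = NA_real_, weight = spec$fixed_wt,
                        cr = NA_real_, cc = NA_real_, bsa = NA_real_,
                        lbm = spec$fixed_lbm,
                        ce = runif(1, spec$egfr_range[1], spec$egfr_range[2]))
    } else {
      ok <- FALSE
      for (att in 1:10000) {
        female <- rbinom(1, 1, spec$female_fraction) == 1
        cfg <- spec$demographics[[if (female) "female" else "male"]]
        age <- .rtnorm1(cfg$age); ht <- .rtnorm1(cfg$height)
        wt <- .rtnorm1(cfg$weight); cr <- .rtnorm1(cfg$cr)
        cc <- .rtnorm1(cfg$cc)
        bc <- body_composition(ht, wt, female)
        ce <- bsa_adjust(egfr_ckdepi(age, cr, female = female), bc$bsa)
        if (ce >= spec$egfr_range[1] && ce < spec$egfr_range[2]) { ok <- TRUE; break }
      }
      if (!ok) stop("eGFR window rejected >99.99% of sampled subjects")
      sub <- data.frame(id = i, sex = as.integer(female), age = age,
                        height = ht, weight = wt, cr = cr, cc = cc,
                        bsa = bc$bsa, lbm = bc$lbm, ce = ce)
    }
    # per-drug random effects, drawn in a fixed order for stream stability
    for (m in models) {
      pre <- substr(m$drug, 1, 3)
      eta <- rnorm(length(m$omega), 0, m$omega)
      names(eta) <- names(m$omega)
      typ <- typical_params(m, sub$ce, sub$weight, sub$lbm)
      ind <- individual_params(typ, matrix(eta, 1, dimnames = list(NULL, names(eta))))
      for (pp in c("cl", "v1", "q", "v2"))
        sub[[paste0(pp, "_", pre)]] <- ind[[pp]]
      for (en in names(eta))
        sub[[paste0("eta_", en, "_", pre)]] <- eta[[en]]
    }
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  names(models) <- vapply(models, `[[`, "", "drug")
  structure(out, spec = spec, models = models,
            class = c("pk_cohort", "data.frame"))
}

#' Extract one drug's individual PK parameters from a cohort
#'
#' @param cohort A \code{pk_cohort}.
#' @param drug Drug name (matched against the models attached to the cohort).
#' @return data.frame with columns \code{cl}, \code{v1}, \code{q}, \code{v2}.
#' @export
subject_params <- function(cohort, drug = "piperacillin") {
  stopifnot(inherits(cohort, "pk_cohort"))
  pre <- substr(drug, 1, 3)
  cols <- paste0(c("cl", "v1", "q", "v2"), "_", pre)
  if (!all(cols %in% names(cohort))) stop("cohort has no parameters for ", drug)
  setNames(as.data.frame(cohort)[cols], c("cl", "v1", "q", "v2"))
}

#' @export
print.pk_cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("Virtual cohort: %d subjects, %s mode, eGFR [%g, %g) mL/min\n",
              nrow(x), sp$mode, sp$egfr_range[1], sp$egfr_range[2]))
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more subjects\n")
  invisible(x)
}

#' Summarise a cohort as median (min-max) by sex
#'
#' @param cohort A \code{pk_cohort} (or plain data.frame of subjects).
#' @param object,... Method arguments (the cohort and unused extras).
#' @return data.frame of formatted summaries, one row per variable.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  x <- as.data.frame(cohort)
  vars <- setdiff(names(x), c("id", "sex"))
  vars <- vars[vapply(vars, function(v) !all(is.na(x[[v]])), TRUE)]
  fmt <- function(v) {
    if (all(is.na(v))) return(NA_character_)
    sprintf("%.3g (%.3g-%.3g)", median(v, na.rm = TRUE),
            min(v, na.rm = TRUE), max(v, na.rm = TRUE))
  }
  groups <- list(total = rep(TRUE, nrow(x)))
  if (!all(is.na(x$sex))) {
    groups$female <- x$sex == 1
    groups$male <- x$sex == 0
  }
  out <- data.frame(variable = vars)
  for (g in names(groups))
    out[[g]] <- vapply(vars, function(v) fmt(x[[v]][groups[[g]]]), "")
  out
}

#' @rdname summarize_cohort
#' @export
summary.pk_cohort <- function(object, ...) summarize_cohort(object)
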