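#' Pharmacodynamic target
#'
#' A \%fT>MIC-type target: attainment requires the free concentration to
#' exceed \code{mic_multiplier} times the MIC for at least
#' \code{time_fraction} of the steady-state 24-h window (comparison is
#' non-strict, \code{>=}).
#'
#' @param time_fraction Required fraction of the window in (0, 1].
#' @param mic_multiplier 1 (fT>MIC) or 4 (fT>4MIC).
#' @return Object of class \code{pd_target}.
#' @examples
#' pd_target(0.5)        # 50%fT>MIC
#' pd_target(1, 4)       # 100%fT>4MIC
#' @export
pd_target <- function(time_fraction, mic_multiplier = 1) {
  if (time_fraction <= 0 || time_fraction > 1)
    stop("time_fraction must be in (0, 1]")
  if (!mic_multiplier %in% c(1, 4))
    stop("mic_multiplier must be 1 or 4")
  structure(list(time_fraction = time_fraction,
                 mic_multiplier = mic_multiplier,
                 label = sprintf("%g%%fT>%sMIC", 100 * time_fraction,
                                 if (mic_multiplier == 1) "" else mic_multiplier)),
            class = "pd_target")
}

#' @export
print.pd_target <- function(x, ...) { cat(x$label, "\n"); invisible(x) }

#' Doubling MIC grid 0.5-128 mg/L
#' @return Numeric vector \code{c(0.5, 1, 2, ..., 128)}.
#' @export
mic_grid_default <- function() 2^(-1:7)

#' Probability of target attainment across an MIC grid
#'
#' For each MIC, the fraction of cohort subjects whose steady-state free
#' piperacillin concentration stays above \code{mic_multiplier * MIC} for at
#' least the target fraction of the 24-h window. Residual (assay) error is
#' not applied: attainment is a function of model-predicted exposure.
#'
#' @param cohort A \code{\link{sample_cohort}} result, or a data.frame of
#'   individual parameters with columns \code{cl}, \code{v1}, \code{q},
#'   \code{v2}.
#' @param reg A \code{\link{regimen}}.
#' @param target A \code{\link{pd_target}}.
#' @param mic_grid Positive, strictly increasing MIC grid (mg/L).
#' @param drug Drug whose parameters are used (must carry an unbound
#'   fraction; piperacillin).
#' @param fu Unbound fraction; defaults to the drug model's value when the
#'   cohort carries models, else 0.7.
#' @return Object of class \code{pta_result}: data.frame with columns
#'   \code{mic} and \code{pta}, with regimen/target/n attached.
#' @export
pta <- function(cohort, reg, target, mic_grid = mic_grid_default(),
                drug = "piperacillin", fu = NULL) {
  stopifnot(inherits(reg, "regimen"), inherits(target, "pd_target"))
  if (any(mic_grid <= 0) || is.unsorted(mic_grid, strictly = TRUE))
    stop("mic_grid must be positive and strictly increasing")
  if (inherits(cohort, "pk_cohort")) {
    pars <- subject_params(cohort, drug)
    if (is.null(fu)) fu <- attr(cohort, "models")[[drug]]$fu
  } else {
    pars <- as.data.frame(cohort)
    if (is.null(fu)) fu <- 0.7
  }
  if (is.na(fu)) stop("no unbound fraction available for ", drug)
  if (nrow(pars) == 0) stop("empty cohort")
  thr <- target$mic_multiplier * mic_grid
  attain <- matrix(FALSE, nrow(pars), length(mic_grid))
  for (i in seq_len(nrow(pars))) {
    pr <- steady_state_profile(pars[i, ], reg, fu = fu)
    fmax <- fu * max(pr$conc)
    fmin <- fu * min(pr$conc)
    for (k in seq_along(thr)) {
      if (thr[k] >= fmax) break                      # above the whole profile
      if (thr[k] < fmin) { attain[i, k] <- TRUE; next }
      attain[i, k] <- ft_above(pr, thr[k]) >= target$time_fraction
    }
  }
  structure(data.frame(mic = mic_grid, pta = colMeans(attain)),
            regimen = reg, target = target, n = nrow(pars), drug = drug,
            fu = fu, class = c("pta_result", "data.frame"))
}

#' @export
print.pta_result <- function(x, ...) {
  cat("PTA (", attr(x, "target")$label, ", ", format(attr(x, "regimen")),
      ", n = ", attr(x, "n"), "):\n", sep = "")
  print(data.frame(mic = x$mic, pta = round(x$pta, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.pta_result <- function(x, ..., threshold = 0.9) {
  plot.default(log2(x$mic), x$pta, type = "b", pch = 16, xaxt = "n",
               xlab = "MIC (mg/L)", ylab = "PTA", ylim = c(0, 1), ...)
  axis(1, at = log2(x$mic), labels = x$mic)
  abline(h = threshold, lty = 2)
  mtext(paste(attr(x, "target")$label, format(attr(x, "regimen")), sep = ", "))
  invisible(x)
}

#' PK/PD breakpoint
#'
#' The highest MIC on the grid at which PTA meets the threshold. Returns
#' \code{NA} when even the lowest MIC fails; when the whole grid meets the
#' threshold the top MIC is returned with attribute
#' \code{right_censored = TRUE}.
#'
#' @param res A \code{\link{pta}} result.
#' @param threshold PTA threshold (default 0.90).
#' @return Breakpoint MIC in mg/L, or \code{NA}.
#' @export
breakpoint <- function(res, threshold = 0.90) {
  stopifnot(inherits(res, "pta_result") || all(c("mic", "pta") %in% names(res)))
  ok <- res$pta >= threshold
  if (!any(ok)) return(NA_real_)
  bp <- max(res$mic[ok])
  if (all(ok)) attr(bp, "right_censored") <- TRUE
  bp
}

#' Read an MIC frequency distribution
#'
#' CSV with header and columns \code{mic} (mg/L) and \code{frequency}
#' (relative frequencies summing to 1). This is the shape of an aggregated
#' EUCAST distribution export; the distribution shipped with the package is
#' a synthetic example, not EUCAST data.
#'
#' @param file Path to the CSV file.
#' @return Object of class \code{mic_distribution} (data.frame
#'   \code{mic, frequency}).
#' @export
read_mic_distribution <- function(file) {
  x <- read.csv(file)
  if (!all(c("mic", "frequency") %in% names(x)))
    stop("MIC distribution needs columns 'mic' and 'frequency'")
  mic_distribution(x$mic, x$frequency, source = basename(file))
}

#' @rdname read_mic_distribution
#' @param mic,frequency Vectors defining the distribution directly.
#' @param source Label recording where the distribution came from.
#' @export
mic_distribution <- function(mic, frequency, source = "constructed") {
  if (any(frequency < 0)) stop("frequencies must be non-negative")
  if (abs(sum(frequency) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (is.unsorted(mic, strictly = TRUE)) stop("MICs must be strictly increasing")
  structure(data.frame(mic = mic, frequency = frequency),
            source = source, class = c("mic_distribution", "data.frame"))
}

#' Cumulative fraction of response
#'
#' \eqn{CFR = \sum_i PTA_i f_i} over the pathogen's MIC distribution. Every
#' distribution MIC must be present in the PTA grid exactly; there is no
#' interpolation between dilutions.
#'
#' @param res A \code{\link{pta}} result.
#' @param dist A \code{\link{mic_distribution}}.
#' @return CFR as a fraction in [0, 1].
#' @export
cfr <- function(res, dist) {
  idx <- match(dist$mic, res$mic)
  if (anyNA(idx))
    stop("distribution MIC(s) ", paste(dist$mic[is.na(idx)], collapse = ", "),
         " absent from the PTA grid; no interpolation is performed")
  sum(res$pta[idx] * dist$frequency)
}

#' Sweep regimens, targets and renal categories
#'
#' Computes PTA for every combination of cohort, regimen and target over an
#' MIC grid and returns one long table (category x regimen x target x MIC).
#'
#' @param cohorts Named list of cohorts (names become the \code{category}
#'   column).
#' @param regimens List of \code{\link{regimen}} objects.
#' @param targets List of \code{\link{pd_target}} objects.
#' @param mic_grid MIC grid (mg/L).
#' @param drug Drug analysed.
#' @return data.frame with columns \code{category, regimen, dose_mg,
#'   interval_h, duration_h, target, mic, pta}.
#' @export
regimen_sweep <- function(cohorts, regimens, targets,
                          mic_grid = mic_grid_default(),
                          drug = "piperacillin") {
  if (inherits(cohorts, "pk_cohort")) cohorts <- list(cohort = cohorts)
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  if (inherits(targets, "pd_target")) targets <- list(targets)
  if (is.null(names(cohorts))) names(cohorts) <- seq_along(cohorts)
  out <- list()
  for (cat_name in names(cohorts)) for (rg in regimens) for (tg in targets) {
    res <- pta(cohorts[[cat_name]], rg, tg, mic_grid, drug = drug)
    out[[length(out) + 1L]] <- data.frame(
      category = cat_name, regimen = format(rg),
      dose_mg = if (rg$mode == "continuous") rg$daily_dose else rg$dose,
      interval_h = if (rg$mode == "continuous") 24 else rg$interval,
      duration_h = if (rg$mode == "continuous") 24 else rg$duration,
      target = tg$label, mic = res$mic, pta = res$pta)
  }
  do.call(rbind, out)
}
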