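#' Creatinine clearance by Cockcroft-Gault
#'
#' Estimates creatinine clearance (mL/min) from age, total body weight and
#' serum creatinine: \eqn{(140 - age) \times WT / (72 \times CR)}, multiplied
#' by 0.85 for females.
#'
#' @param age Age in years (0 < age < 140).
#' @param weight Total body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param female Logical; \code{TRUE} for female subjects.
#' @return Creatinine clearance in mL/min.
#' @examples
#' crcl_cockcroft_gault(40, 72, 1.0, female = FALSE)  # 100 mL/min
#' @export
crcl_cockcroft_gault <- function(age, weight, scr, female = FALSE) {
  stopifnot(length(female) %in% c(1L, length(age)))
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0))
    stop("age, weight and serum creatinine must be strictly positive")
  if (any(age >= 140))
    stop("Cockcroft-Gault is undefined for age >= 140 years")
  (140 - age) * weight / (72 * scr) * ifelse(female, 0.85, 1)
}

#' Estimated GFR by the 4-variable MDRD equation
#'
#' \eqn{175 \times CR^{-1.154} \times age^{-0.203}}, times 0.742 for females.
#' The value is normalised to 1.73 m^2 body surface area; use
#' \code{\link{bsa_adjust}} to convert to an absolute clearance.
#'
#' @inheritParams crcl_cockcroft_gault
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_mdrd <- function(age, scr, female = FALSE) {
  if (any(age <= 0) || any(scr <= 0))
    stop("age and serum creatinine must be strictly positive")
  175 * scr^-1.154 * age^-0.203 * ifelse(female, 0.742, 1)
}

#' Estimated GFR by the 2021 race-free CKD-EPI equations
#'
#' Piecewise power ("spline") equations with sex-specific knots: creatinine
#' knot 0.7 (female) / 0.9 (male) mg/dL, cystatin C knot 0.8 mg/dL. Three
#' variants are provided: creatinine only (\code{"cr"}), cystatin C only
#' (\code{"cc"}), and the combined creatinine-cystatin form (\code{"crcc"}).
#' Values are normalised to 1.73 m^2; see \code{\link{bsa_adjust}}.
#'
#' @inheritParams crcl_cockcroft_gault
#' @param cys Serum cystatin C in mg/dL (required for \code{"cc"} and
#'   \code{"crcc"}).
#' @param variant One of \code{"cr"}, \code{"cc"}, \code{"crcc"}.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckdepi(40, 0.9, female = FALSE)                   # 110.7
#' egfr_ckdepi(40, cys = 0.8, variant = "cc")             # 114.2
#' @export
egfr_ckdepi <- function(age, scr = NULL, cys = NULL,
                        female = FALSE, variant = c("cr", "cc", "crcc")) {
  variant <- match.arg(variant)
  if (any(age <= 0)) stop("age must be strictly positive")
  need_cr <- variant %in% c("cr", "crcc")
  need_cc <- variant %in% c("cc", "crcc")
  if (need_cr && (is.null(scr) || any(scr <= 0)))
    stop("serum creatinine must be supplied and strictly positive")
  if (need_cc && (is.null(cys) || any(cys <= 0)))
    stop("serum cystatin C must be supplied and strictly positive for the '",
         variant, "' variant")
  kcr <- ifelse(female, 0.7, 0.9)
  switch(variant,
    cr = {
      a1 <- ifelse(female, -0.241, -0.302)
      142 * pmin(scr / kcr, 1)^a1 * pmax(scr / kcr, 1)^-1.200 *
        0.9938^age * ifelse(female, 1.012, 1)
    },
    cc = {
      133 * pmin(cys / 0.8, 1)^-0.499 * pmax(cys / 0.8, 1)^-1.328 *
        0.9962^age * ifelse(female, 0.932, 1)
    },
    crcc = {
      a1 <- ifelse(female, -0.219, -0.144)
      135 * pmin(scr / kcr, 1)^a1 * pmax(scr / kcr, 1)^-0.544 *
        pmin(cys / 0.8, 1)^-0.323 * pmax(cys / 0.8, 1)^-0.778 *
        0.9961^age * ifelse(female, 0.963, 1)
    })
}

#' Convert a BSA-normalised clearance to an absolute clearance
#'
#' @param value_norm Clearance in mL/min/1.73 m^2.
#' @param bsa Body surface area in m^2.
#' @return Absolute clearance in mL/min (\code{value_norm * bsa / 1.73}).
#' @export
bsa_adjust <- function(value_norm, bsa) {
  if (any(bsa <= 0)) stop("bsa must be strictly positive")
  value_norm * bsa / 1.73
}

#' Body surface area and lean body mass
#'
#' BSA by Du Bois-Du Bois (default) or Mosteller; LBM by the James equation.
#' These are the conventional pharmacometric choices; the formulas producing
#' the study's summary table are not stated, and Du Bois/James reproduce its
#' medians from median height and weight within about 2\%.
#'
#' @param height Height in cm.
#' @param weight Total body weight in kg.
#' @param female Logical; \code{TRUE} for female subjects.
#' @param bsa_formula \code{"dubois"} or \code{"mosteller"}.
#' @return A data.frame with columns \code{bsa} (m^2) and \code{lbm} (kg).
#' @examples
#' body_composition(168, 61.7, female = FALSE)
#' @export
body_composition <- function(height, weight, female = FALSE,
                             bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be strictly positive")
  bsa <- switch(bsa_formula,
    dubois    = 0.007184 * height^0.725 * weight^0.425,
    mosteller = sqrt(height * weight / 3600))
  lbm <- ifelse(female,
    1.07 * weight - 148 * (weight / height)^2,
    1.10 * weight - 128 * (weight / height)^2)
  bad <- lbm <= 0 | lbm >= weight | bsa <= 0.5 | bsa >= 3.5
  if (any(bad))
    stop("implausible body composition (LBM outside (0, weight) or BSA outside (0.5, 3.5))")
  data.frame(bsa = bsa, lbm = lbm)
}

#' All renal-function indices for a set of subjects
#'
#' Computes BSA/LBM and the five renal estimators (Cockcroft-Gault CrCl and
#' BSA-adjusted absolute MDRD and CKD-EPI cr/cc/cr-cc eGFRs, all mL/min).
#' The model covariate \code{CE} used throughout the package is the
#' BSA-adjusted absolute CKD-EPI creatinine eGFR
#' (\code{egfr_ckdepi_cr_abs}); the others are exposed for exploration.
#'
#' @param age,height,weight,scr Numeric vectors of demographics.
#' @param cys Serum cystatin C (mg/dL); may be \code{NA}, in which case the
#'   cystatin-based columns are \code{NA}.
#' @param female Logical vector.
#' @return data.frame with columns \code{bsa}, \code{lbm}, \code{crcl_cg},
#'   \code{egfr_mdrd_abs}, \code{egfr_ckdepi_cr_abs},
#'   \code{egfr_ckdepi_cc_abs}, \code{egfr_ckdepi_crcc_abs}.
#' @export
renal_indices <- function(age, height, weight, scr, cys = NA, female = FALSE) {
  n <- length(age)
  female <- rep_len(female, n)
  cys <- rep_len(cys, n)
  bc <- body_composition(height, weight, female)
  out <- data.frame(
    bsa = bc$bsa, lbm = bc$lbm,
    crcl_cg = crcl_cockcroft_gault(age, weight, scr, female),
    egfr_mdrd_abs = bsa_adjust(egfr_mdrd(age, scr, female), bc$bsa),
    egfr_ckdepi_cr_abs = bsa_adjust(egfr_ckdepi(age, scr, female = female), bc$bsa),
    egfr_ckdepi_cc_abs = NA_real_,
    egfr_ckdepi_crcc_abs = NA_real_)
  has_cc <- !is.na(cys)
  if (any(has_cc)) {
    out$egfr_ckdepi_cc_abs[has_cc] <- bsa_adjust(
      egfr_ckdepi(age[has_cc], cys = cys[has_cc], female = female[has_cc],
                  variant = "cc"), bc$bsa[has_cc])
    out$egfr_ckdepi_crcc_abs[has_cc] <- bsa_adjust(
      egfr_ckdepi(age[has_cc], scr[has_cc], cys[has_cc], female[has_cc],
                  variant = "crcc"), bc$bsa[has_cc])
  }
  out
}

#' Append renal/body-composition covariates to a covariate table
#'
#' Reads (or takes) a table with columns \code{ID, SEX (0=male, 1=female),
#' AGE, HT_CM, WT_KG, CR} and optionally \code{CC}, and appends the columns
#' produced by \code{\link{renal_indices}} (upper-cased). If \code{file} is
#' given the augmented table is also written back as CSV.
#'
#' @param x A data.frame or path to a CSV file.
#' @param file Optional output CSV path.
#' @return The augmented data.frame (invisibly when \code{file} is given).
#' @export
augment_covariates <- function(x, file = NULL) {
  if (is.character(x)) x <- read.csv(x)
  req <- c("ID", "SEX", "AGE", "HT_CM", "WT_KG", "CR")
  if (!all(req %in% names(x)))
    stop("covariate table must contain columns ", paste(req, collapse = ", "))
  cys <- if ("CC" %in% names(x)) x$CC else NA
  idx <- renal_indices(x$AGE, x$HT_CM, x$WT_KG, x$CR, cys, x$SEX == 1)
  names(idx) <- toupper(names(idx))
  out <- cbind(x, idx)
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
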