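test_that("Cockcroft-Gault matches hand-evaluated values and rejects bad input", {
  expect_equal(crcl_cockcroft_gault(40, 72, 1.0), 100)
  expect_equal(crcl_cockcroft_gault(40, 72, 1.0, female = TRUE), 85)
  expect_error(crcl_cockcroft_gault(140, 72, 1.0), "age")
  expect_error(crcl_cockcroft_gault(40, -1, 1.0), "positive")
  expect_error(crcl_cockcroft_gault(40, 72, 0), "positive")
})

test_that("MDRD matches hand evaluation and scales as a power law", {
  expect_equal(egfr_mdrd(40, 1.0), 175 * 40^-0.203, tolerance = 1e-12)
  expect_equal(egfr_mdrd(40, 1.0), 82.76, tolerance = 1e-3)
  expect_equal(egfr_mdrd(40, 1.0, female = TRUE), egfr_mdrd(40, 1.0) * 0.742)
  expect_equal(egfr_mdrd(40, 2.0) / egfr_mdrd(40, 1.0), 2^-1.154)
})

test_that("CKD-EPI 2021 variants match hand evaluation at the knots", {
  expect_equal(egfr_ckdepi(40, 0.9), 142 * 0.9938^40, tolerance = 1e-12)
  expect_equal(egfr_ckdepi(40, 0.9), 110.73, tolerance = 1e-3)
  # at the female knot with negligible age factor only the sex multiplier acts
  expect_equal(egfr_ckdepi(1e-9, 0.7, female = TRUE), 142 * 1.012,
               tolerance = 1e-6)
  expect_equal(egfr_ckdepi(40, cys = 0.8, variant = "cc"),
               133 * 0.9962^40, tolerance = 1e-12)
  expect_equal(egfr_ckdepi(40, cys = 0.8, variant = "cc"), 114.21,
               tolerance = 1e-3)
  expect_error(egfr_ckdepi(40, 0.9, variant = "cc"), "cystatin")
  expect_error(egfr_ckdepi(40, 0.9, variant = "crcc"), "cystatin")
})

test_that("CKD-EPI creatinine spline is continuous at the sex-specific knots", {
  for (female in c(FALSE, TRUE)) {
    knot <- if (female) 0.7 else 0.9
    lo <- egfr_ckdepi(50, knot * (1 - 1e-10), female = female)
    hi <- egfr_ckdepi(50, knot * (1 + 1e-10), female = female)
    expect_equal(lo, hi, tolerance = 1e-9)
  }
})

test_that("all estimators decrease in creatinine (and cystatin) and in age", {
  crs <- seq(0.5, 2, by = 0.1)
  for (f in list(function(cr) crcl_cockcroft_gault(40, 70, cr),
                 function(cr) egfr_mdrd(40, cr),
                 function(cr) egfr_ckdepi(40, cr),
                 function(cr) egfr_ckdepi(40, cr, cys = 0.9, variant = "crcc")))
    expect_true(all(diff(f(crs)) < 0))
  ccs <- seq(0.5, 2, by = 0.1)
  expect_true(all(diff(egfr_ckdepi(40, cys = ccs, variant = "cc")) < 0))
  expect_true(all(diff(egfr_ckdepi(40, 1.0, cys = ccs, variant = "crcc")) < 0))
  ages <- seq(20, 80, by = 5)
  expect_true(all(diff(crcl_cockcroft_gault(ages, 70, 1)) < 0))
  expect_true(all(diff(egfr_mdrd(ages, 1)) < 0))
  expect_true(all(diff(egfr_ckdepi(ages, 1)) < 0))
})

test_that("BSA adjustment is the identity at 1.73 m^2 and linear in BSA", {
  expect_equal(bsa_adjust(100, 1.73), 100)
  expect_equal(bsa_adjust(100, 2.076), 120)
  expect_equal(bsa_adjust(110.7, 1.90), 121.6, tolerance = 1e-3)
  expect_error(bsa_adjust(100, 0), "positive")
})

test_that("body composition reproduces cohort medians and enforces plausibility", {
  bc <- body_composition(168, 61.7)
  expect_equal(bc$bsa, 1.71, tolerance = 0.02)   # Du Bois vs reported median
  expect_error(body_composition(168, 0), "positive")
  bc2 <- body_composition(180, 80)
  expect_lt(bc2$lbm, 80)
  expect_gt(bc2$lbm, 0)
  # Mosteller alternative stays within a few percent of Du Bois
  bm <- body_composition(168, 61.7, bsa_formula = "mosteller")
  expect_equal(bm$bsa, bc$bsa, tolerance = 0.03)
})

test_that("a median male subject lands inside the cohort's reported ranges", {
  idx <- renal_indices(age = 39, height = 171, weight = 69.1,
                       scr = 0.965, cys = 0.830, female = FALSE)
  expect_gt(idx$crcl_cg, 76.2);             expect_lt(idx$crcl_cg, 146)
  expect_gt(idx$egfr_mdrd_abs, 73.3);       expect_lt(idx$egfr_mdrd_abs, 120)
  expect_gt(idx$egfr_ckdepi_cr_abs, 86.2);  expect_lt(idx$egfr_ckdepi_cr_abs, 136)
  expect_gt(idx$egfr_ckdepi_cc_abs, 86.2);  expect_lt(idx$egfr_ckdepi_cc_abs, 145)
  expect_gt(idx$egfr_ckdepi_crcc_abs, 89.6); expect_lt(idx$egfr_ckdepi_crcc_abs, 145)
})

test_that("covariate tables round-trip through augment_covariates", {
  tab <- data.frame(ID = 1:3, SEX = c(0, 1, 0), AGE = c(30, 40, 50),
                    HT_CM = c(175, 160, 180), WT_KG = c(70, 55, 85),
                    CR = c(0.9, 0.7, 1.1), CC = c(0.8, 0.7, 0.9))
  out <- augment_covariates(tab)
  expect_true(all(c("BSA", "LBM", "CRCL_CG", "EGFR_CKDEPI_CR_ABS") %in% names(out)))
  f <- tempfile(fileext = ".csv")
  augment_covariates(tab, file = f)
  back <- read.csv(f)
  expect_equal(back$EGFR_CKDEPI_CR_ABS, out$EGFR_CKDEPI_CR_ABS, tolerance = 1e-6)
  expect_error(augment_covariates(tab[, -1]), "must contain")
})
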