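# With a prediction that does not depend on eta, the random effect
# integrates out exactly and the Laplace approximation is exact:
# -2 log L = (y-m)^2/(sigma m)^2 + log(2 pi sigma^2 m^2).
test_that("the Laplace machinery is exact when eta drops out of the likelihood", {
  m <- 30; y <- 27; sigma <- 0.15; omega <- 0.2
  const_pred <- function(th, eta) m
  li <- piptazpk:::.laplace_subject(const_pred, y, theta = c(cl = 1),
                                    omega = omega, sigma = sigma, warm = 0)
  closed <- (y - m)^2 / (sigma * m)^2 + log(2 * pi * sigma^2 * m^2)
  expect_equal(li$ofv, closed, tolerance = 1e-8)
  expect_equal(li$eta, 0, tolerance = 1e-6)
})

test_that("Laplace OFV agrees with numerical quadrature on one subject", {
  ds <- generate_study(study_design(n = 1, seed = 101), taz_model)
  sub <- piptazpk:::.split_subjects(ds)[[1]]
  pred <- piptazpk:::.pred_factory(taz_model, sub, iiv = "cl")
  omega <- taz_model$omega[["cl"]]; sigma <- taz_model$sigma
  # brute-force marginal likelihood over eta
  integrand <- Vectorize(function(eta)
    exp(-piptazpk:::.nll_data(sub$y, pred(taz_model$theta, eta), sigma)) *
      dnorm(eta, 0, omega))
  quad <- -2 * log(integrate(integrand, -8 * omega, 8 * omega,
                             rel.tol = 1e-10)$value)
  lap <- piptazpk:::.laplace_subject(pred, sub$y, taz_model$theta,
                                     omega, sigma, warm = 0)$ofv
  expect_lt(abs(lap - quad), 0.5)
})

test_that("the compiled kernel reproduces the R reference implementation", {
  ds <- generate_study(study_design(n = 6, seed = 101), pip_model)
  subs <- piptazpk:::.split_subjects(ds)
  ofv_r <- sum(vapply(subs, function(sub) {
    pred <- piptazpk:::.pred_factory(pip_model, sub, iiv = c("cl", "v1"))
    piptazpk:::.laplace_subject(pred, sub$y, pip_model$theta,
                                pip_model$omega, pip_model$sigma,
                                warm = c(0, 0))$ofv
  }, 0))
  ofv_cpp <- pk_ofv(ds, pip_model)
  expect_equal(as.numeric(ofv_cpp), ofv_r, tolerance = 1e-6)
})

test_that("without random effects the OFV is the fixed-effects -2 log likelihood", {
  ds <- generate_study(study_design(n = 5, seed = 101), taz_model)
  ofv0 <- as.numeric(pk_ofv(ds, taz_model, iiv = character(0)))
  obs <- ds[ds$MDV == 0, ]
  by_hand <- sum(vapply(split(obs, obs$ID), function(sub) {
    typ <- typical_params(taz_model, sub$CE[1], sub$WT[1], sub$LBM[1])
    f <- .conc1_r(sub$TIME, typ, 1000, 0.5)
    v <- taz_model$sigma^2 * f^2
    sum((sub$DV - f)^2 / v + log(2 * pi * v))
  }, 0))
  expect_equal(ofv0, by_hand, tolerance = 1e-10)
  # and a vanishing omega approaches that limit
  tiny <- piptazpk:::update_pk_model(taz_model, omega = c(cl = 1e-6))
  expect_equal(as.numeric(pk_ofv(ds, tiny)), ofv0, tolerance = 1e-3)
})

test_that("refitting from the optimum is a fixed point", {
  ds <- generate_study(study_design(n = 10, seed = 101), taz_model)
  ctrl <- pkfit_control(compute_se = FALSE)
  fit <- pkfit(ds, taz_model, control = ctrl)
  refit <- pkfit(ds, taz_model,
                 start = list(theta = fit$theta, omega = fit$omega,
                              sigma = fit$sigma), control = ctrl)
  expect_lt(abs(refit$ofv - fit$ofv), 0.01)
  expect_true(fit$converged)
  expect_lt(fit$ofv, as.numeric(pk_ofv(ds, taz_model)) + 1e-6)
})

test_that("fit interface validates inputs", {
  ds <- generate_study(study_design(n = 3, seed = 101), taz_model)
  expect_error(pkfit(ds, taz_model, iiv = "banana"), "structural")
  expect_error(pkfit(ds[, -1], taz_model), "must contain")
  two_dose <- rbind(as.data.frame(ds), transform(as.data.frame(ds)[2, ], TIME = 1))
  expect_error(pkfit(two_dose, taz_model), "single-dose")
})

test_that("diagnostics distinguish population from individual predictions", {
  ds <- generate_study(study_design(n = 40, seed = 101), taz_model)
  fit <- pkfit(ds, taz_model, control = pkfit_control(compute_se = FALSE))
  g <- gof_table(fit)
  expect_equal(nrow(g), 240)
  expect_false(isTRUE(all.equal(g$PRED, g$IPRED)))   # eta modes are not all zero
  # CWRES behave like standardised residuals under the correct model
  expect_lt(abs(mean(g$CWRES)), 0.2)
  expect_gt(sd(g$CWRES), 0.8)
  expect_lt(sd(g$CWRES), 1.2)
  expect_equal(residuals(fit, "iwres"),
               (g$DV - g$IPRED) / (fit$sigma * g$IPRED), tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.pkfit")
  expect_true(all(c("parameter", "estimate") %in% names(s$table)))
})

test_that("standard errors are finite and on a sane scale at n = 30", {
  ds <- generate_study(study_design(n = 30, seed = 101), taz_model)
  fit <- pkfit(ds, taz_model)
  expect_false(is.null(fit$rse))
  expect_true(all(is.finite(fit$rse)))
  # the well-identified clearance intercept is estimated precisely
  expect_lt(fit$rse[["th_cl"]], 15)
  expect_true(all(abs(fit$shrinkage) < 100))
})

test_that("a single-simulation VPC collapses onto that replicate", {
  ds <- generate_study(study_design(n = 15, seed = 101), taz_model)
  v <- vpc(ds, taz_model, n_sim = 1, seed = 101)
  expect_equal(v$lower, v$upper)
  expect_equal(v$lower, v$sim_median)
  expect_equal(nrow(v), 6 * 3)                   # 6 post-dose bins x 3 percentiles
})

test_that("a grossly misspecified model fails its own VPC", {
  ds <- generate_study(study_design(n = 60, seed = 101), taz_model)
  wrong <- piptazpk:::update_pk_model(
    taz_model, theta = replace(taz_model$theta, "cl", taz_model$theta[["cl"]] / 2))
  v <- vpc(ds, wrong, n_sim = 150, seed = 101)
  med <- v[v$prob == 0.5, ]
  expect_gt(sum(!med$inside), 0)
})

test_that("the bootstrap is deterministic under a seed and brackets the estimates", {
  ds <- generate_study(study_design(n = 8, seed = 101), taz_model)
  fit <- pkfit(ds, taz_model, control = pkfit_control(compute_se = FALSE))
  b1 <- pk_bootstrap(fit, n_resamples = 3, seed = 101)
  b2 <- pk_bootstrap(fit, n_resamples = 3, seed = 101)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$upper))
  expect_equal(b1$parameter,
               c(names(fit$coefficients), names(fit$omega), "sigma"))
})

test_that("covariate stepping with no candidates returns the base model", {
  ds <- generate_study(study_design(n = 8, seed = 101), taz_model)
  base <- piptazpk:::update_pk_model(
    taz_model, theta = taz_model$theta[setdiff(names(taz_model$theta), "cl_ce")])
  st <- covariate_step(ds, base, candidates = character(0), iiv = "cl")
  expect_length(st$selected, 0)
  expect_setequal(names(st$model$theta), names(base$theta))
  expect_null(st$trace)
})
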