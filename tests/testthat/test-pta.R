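test_that("fraction of time above threshold handles the analytic edge cases", {
  reg <- regimen(daily_dose = 16000)
  pr <- steady_state_profile(pip_ref, reg, fu = 0.7)
  expect_equal(0.7 * pr$conc[1], 41.67, tolerance = 1e-3)
  expect_equal(ft_above(pr, 0), 1)
  expect_equal(ft_above(pr, 32), 1)
  expect_equal(ft_above(pr, 64), 0)
  expect_error(ft_above(steady_state_profile(pip_ref, reg), 1), "unbound")
  expect_error(ft_above(pr, -1), "non-negative")
})

test_that("crossing-located time fractions agree with brute-force integration", {
  pr <- steady_state_profile(pip_ref, regimen(4000, 6, 0.5), fu = 0.7)
  tg <- seq(0, 6, by = 1e-4)
  free <- 0.7 * pr$fn(tg)
  for (thr in c(2, 8, 20, 60)) {
    brute <- mean(free > thr)
    expect_equal(ft_above(pr, thr), brute, tolerance = 2e-4)
  }
})

test_that("PTA is one for trivially low and zero for unreachable MICs", {
  res <- pta(pip_ref, regimen(daily_dose = 16000), pd_target(1.0),
             mic_grid = c(0.5, 32, 1024))
  expect_equal(res$pta, c(1, 1, 0))
  # the single typical subject attains 100%fT>MIC at MIC 32 on 16 g/day
  expect_equal(res$pta[res$mic == 32], 1)
})

test_that("with no IIV the continuous-infusion PTA is a step at fu*Css/multiplier", {
  pars <- typical_params(pip_model, ce = c(95, 105, 115, 125))
  reg <- regimen(daily_dose = 12000)
  for (target in list(pd_target(1.0), pd_target(1.0, 4))) {
    res <- pta(pars, reg, target, mic_grid = mic_grid_default())
    css_free <- 0.7 * (12000 / 24) / pars$cl
    closed <- vapply(mic_grid_default(), function(m)
      mean(css_free > target$mic_multiplier * m), 0)
    expect_equal(res$pta, closed)
  }
})

test_that("PTA is monotone: non-increasing in MIC, non-decreasing in dose", {
  set.seed(101)
  coh <- sample_cohort(population_spec(40, mode = "category",
                                       egfr_range = "90-130", seed = 101))
  for (reg in list(regimen(2000, 8, 0.5), regimen(4000, 6, 3),
                   regimen(daily_dose = 8000))) {
    for (tf in c(0.5, 1.0)) {
      res <- pta(coh, reg, pd_target(tf))
      expect_true(all(diff(res$pta) <= 0))
      expect_true(all(res$pta >= 0 & res$pta <= 1))
    }
  }
  # paired etas: doubling the dose never lowers PTA at any MIC
  lo <- pta(coh, regimen(2000, 6, 0.5), pd_target(0.5))
  hi <- pta(coh, regimen(4000, 6, 0.5), pd_target(0.5))
  expect_true(all(hi$pta - lo$pta >= 0))
})

test_that("the breakpoint operator implements 'highest MIC with PTA >= threshold'", {
  grid <- mic_grid_default()
  mk <- function(p) structure(data.frame(mic = grid, pta = p),
                              class = c("pta_result", "data.frame"))
  expect_equal(as.numeric(breakpoint(mk(rep(0.95, 9)))), 128)
  expect_true(attr(breakpoint(mk(rep(0.95, 9))), "right_censored"))
  expect_true(is.na(breakpoint(mk(rep(0.5, 9)))))
  expect_equal(breakpoint(mk(c(0.99, 0.95, 0.91, 0.70, 0.4, 0.2, 0.1, 0, 0))), 2)
  # ties at the threshold count (comparison is >=)
  expect_equal(breakpoint(mk(c(0.9, rep(0.1, 8)))), 0.5)
})

test_that("CFR is the frequency-weighted sum of PTA, with no interpolation", {
  grid <- mic_grid_default()
  res <- structure(data.frame(mic = grid, pta = seq(1, 0.2, length.out = 9)),
                   class = c("pta_result", "data.frame"))
  point <- mic_distribution(4, 1)
  expect_equal(cfr(res, point), res$pta[res$mic == 4])
  two <- mic_distribution(c(1, 16), c(0.5, 0.5))
  expect_equal(cfr(res, two),
               mean(res$pta[res$mic %in% c(1, 16)]))
  unif <- mic_distribution(grid, rep(1 / 9, 9))
  expect_equal(cfr(res, unif), sum(res$pta) / 9)
  off_grid <- mic_distribution(c(3, 4), c(0.5, 0.5))
  expect_error(cfr(res, off_grid), "absent")
})

test_that("MIC distributions validate and load from the bundled synthetic CSV", {
  expect_error(mic_distribution(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(mic_distribution(c(2, 1), c(0.5, 0.5)), "increasing")
  expect_error(mic_distribution(c(1, 2), c(-0.5, 1.5)), "non-negative")
  f <- system.file("extdata", "synthetic_mic_example.csv", package = "piptazpk")
  dist <- read_mic_distribution(f)
  expect_s3_class(dist, "mic_distribution")
  expect_equal(sum(dist$frequency), 1)
  expect_true(all(dist$mic %in% mic_grid_default()))
})

test_that("regimen sweeps stack the grid into one long table", {
  coh <- sample_cohort(population_spec(10, mode = "category",
                                       egfr_range = "90-130", seed = 101))
  regs <- list(regimen(4000, 6, 0.5), regimen(daily_dose = 16000))
  tgts <- list(pd_target(0.5), pd_target(1.0))
  tab <- regimen_sweep(list(normal = coh), regs, tgts, mic_grid = c(1, 8, 64))
  expect_equal(nrow(tab), 1 * 2 * 2 * 3)
  expect_named(tab, c("category", "regimen", "dose_mg", "interval_h",
                      "duration_h", "target", "mic", "pta"))
  direct <- pta(coh, regs[[1]], tgts[[1]], mic_grid = c(1, 8, 64))
  sub <- tab[tab$regimen == format(regs[[1]]) & tab$target == "50%fT>MIC", ]
  expect_equal(sub$pta, direct$pta)
})
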