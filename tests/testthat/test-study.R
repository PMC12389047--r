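test_that("the default design reproduces the clinical sampling structure", {
  ds <- generate_study(study_design(seed = 101), pip_model)
  expect_equal(sum(ds$EVID == 0), 84)            # 12 subjects x 7 nominal times
  expect_equal(sum(ds$EVID == 0 & ds$MDV == 0), 72)
  expect_equal(sum(ds$EVID == 1), 12)
  pre <- ds[ds$TIME == 0 & ds$EVID == 0, ]
  expect_true(all(pre$MDV == 1))
  expect_true(all(pre$DV == 0))
  expect_true(all(ds$DV[ds$MDV == 0] > 0))
  dose <- ds[ds$EVID == 1, ]
  expect_true(all(dose$AMT == 4000))
  expect_true(all(dose$RATE == 8000))            # 30-min infusion
  taz <- generate_study(study_design(n = 3, seed = 101), taz_model)
  expect_true(all(taz$AMT[taz$EVID == 1] == 500))
})

test_that("noise-free generation returns the typical predictions exactly", {
  des <- study_design(n = 5, seed = 101)
  ds <- generate_study(des, pip_model, omega = c(cl = 0, v1 = 0), sigma = 0)
  obs <- ds[ds$MDV == 0, ]
  for (id in unique(obs$ID)) {
    sub <- obs[obs$ID == id, ]
    typ <- typical_params(pip_model, sub$CE[1], sub$WT[1], sub$LBM[1])
    f <- .conc1_r(sub$TIME, typ, rate = 8000, dur = 0.5)
    expect_equal(sub$DV, f, tolerance = 1e-12)
  }
  expect_equal(attr(ds, "etas"), matrix(0, 5, 2, dimnames = list(NULL, c("cl", "v1"))))
})

test_that("the proportional-error CV matches the generating sigma", {
  set.seed(101)
  des <- study_design(n = 400, seed = 101)
  ds <- generate_study(des, pip_model, omega = c(cl = 0, v1 = 0))
  obs <- ds[ds$MDV == 0, ]
  f <- unlist(lapply(split(obs, obs$ID), function(sub) {
    typ <- typical_params(pip_model, sub$CE[1], sub$WT[1], sub$LBM[1])
    .conc1_r(sub$TIME, typ, 8000, 0.5)
  }))
  y <- unlist(lapply(split(obs, obs$ID), `[[`, "DV"))
  expect_equal(sd(y / f - 1), 0.134, tolerance = 0.02)
})

test_that("datasets round-trip losslessly through the NONMEM-convention CSV", {
  ds <- generate_study(study_design(n = 6, seed = 101), pip_model)
  f <- tempfile(fileext = ".csv")
  write_study(ds, f)
  back <- read_study(f)
  for (v in names(ds)) expect_identical(back[[v]], as.vector(ds[[v]]))
})

test_that("the reader rejects malformed event sequences", {
  ds <- generate_study(study_design(n = 2, seed = 101), pip_model)
  f <- tempfile(fileext = ".csv")
  bad <- as.data.frame(ds)
  bad <- bad[bad$EVID != 1 | bad$ID != 1, ]      # drop subject 1's dose
  write_study(bad, f)
  expect_error(read_study(f), "no dose event")
  bad2 <- as.data.frame(ds)
  bad2$DV[bad2$MDV == 0][1] <- -1
  write_study(bad2, f)
  expect_error(read_study(f), "non-positive")
})

test_that("enlarging the study under a fixed seed preserves the first subjects", {
  d5 <- generate_study(study_design(n = 5, seed = 101), pip_model)
  d8 <- generate_study(study_design(n = 8, seed = 101), pip_model)
  expect_identical(strip_df(d5),
                   strip_df(as.data.frame(d8)[seq_len(nrow(d5)), ]))
})

test_that("design validation catches unsorted and dose-first violations", {
  expect_error(study_design(times = c(0, 2, 1)), "sorted")
  expect_error(study_design(times = c(0.5, 1)), "predose")
  expect_error(study_design(n = 0), "positive")
})

test_that("PTA fixtures regenerate byte-identically and attain at low MIC", {
  sp <- population_spec(50, mode = "free", seed = 101)
  regs <- list(regimen(4000, 6, 0.5))
  tgts <- list(pd_target(0.5))
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  m1 <- generate_pta_fixture(sp, regs, tgts, d1, mic_grid = c(0.25, 4, 64))
  m2 <- generate_pta_fixture(sp, regs, tgts, d2, mic_grid = c(0.25, 4, 64))
  expect_identical(m1$files, m2$files)
  tab <- read.csv(file.path(d1, "expected_pta.csv"))
  expect_gte(tab$pta[tab$mic == 0.25], 0.99)
  expect_error(generate_pta_fixture(population_spec(500, seed = 1),
                                    regs, tgts, d1), "capped")
})

test_that("inflating IIV widens the spread of individual exposure", {
  base <- sample_cohort(population_spec(150, mode = "category",
                                        egfr_range = "90-130", seed = 101))
  m5 <- pip_model
  m5$omega <- 5 * m5$omega
  infl <- sample_cohort(population_spec(150, mode = "category",
                                        egfr_range = "90-130", seed = 101),
                        models = list(m5))
  ft_sd <- function(coh) {
    pars <- subject_params(coh, "piperacillin")
    sd(vapply(seq_len(nrow(pars)), function(i)
      ft_above(steady_state_profile(pars[i, ], regimen(4000, 6, 0.5), fu = 0.7),
               16), 0))
  }
  expect_gt(ft_sd(infl), ft_sd(base))
})
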