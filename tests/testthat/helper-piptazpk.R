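# shared fixtures for the test suite; all stochastic tests run under seed 101

pip_model <- pk_model("piperacillin")
taz_model <- pk_model("tazobactam")
pip_ref <- typical_params(pip_model, ce = 108.25)  # cl 11.2, v1 6.24, q 4.32, v2 2.59

random_pk_params <- function(n) {
  data.frame(cl = runif(n, 2, 20), v1 = runif(n, 3, 15),
             q = runif(n, 1, 10), v2 = runif(n, 1, 10))
}

.conc1_r <- function(t, p, rate, dur)
  piptazpk:::.conc1(t, p$cl, p$v1, p$q, p$v2, rate, dur)

# two-phase ODE oracle for a single zero-order infusion (piecewise
# integration so the input discontinuity at end of infusion is exact)
ode_conc1 <- function(times, p, dose, dur) {
  k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
  rhs <- function(t, y, parms)
    list(c(parms$inp - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  tol <- list(rtol = 1e-12, atol = 1e-12)
  t1 <- sort(unique(c(0, times[times <= dur], dur)))
  out1 <- deSolve::ode(c(0, 0), t1, rhs, list(inp = dose / dur),
                       rtol = tol$rtol, atol = tol$atol)
  t2 <- sort(unique(c(dur, times[times > dur])))
  y_dur <- out1[nrow(out1), 2:3]
  out2 <- if (length(t2) > 1)
    deSolve::ode(y_dur, t2, rhs, list(inp = 0),
                 rtol = tol$rtol, atol = tol$atol) else NULL
  lookup <- rbind(out1, out2)
  vapply(times, function(t) lookup[which.min(abs(lookup[, 1] - t)), 2], 0) / p$v1
}

# drop non-structural attributes so content comparisons ignore metadata
strip_df <- function(x) {
  x <- as.data.frame(x)
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class")))
    attr(x, a) <- NULL
  rownames(x) <- NULL
  x
}
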