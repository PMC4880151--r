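# Shared oracles and fixture generators. Everything here is independent
# of the closed-form code paths it is used to check: derivatives are
# differenced numerically, fixed points are refined by damped Newton on
# the right-hand side, and roots are bracketed by Brent's method.

# Draw a valid parameter set with the four healthy-lineage rates uniform
# on [0.1, 0.5] and the remaining parameters at the package defaults.
random_params <- function() {
  v <- runif(4, 0.1, 0.5)
  model_params(rho_S = v[1], delta_S = v[2], rho_A = v[3], delta_A = v[4])
}

random_state <- function(lo = 0, hi = 1.2) {
  population_state(runif(1, lo, hi), runif(1, lo, hi), runif(1, lo, hi),
                   runif(1, lo, hi), runif(1, lo, hi))
}

# Central finite-difference Jacobian of model_rhs.
fd_jacobian <- function(model, params, state, h = 1e-6) {
  J <- matrix(0, 5, 5, dimnames = list(names(state), names(state)))
  for (j in 1:5) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (model_rhs(model, params, up) - model_rhs(model, params, dn)) / (2 * h)
  }
  J
}

# Damped Newton refinement of a root of model_rhs, using the
# finite-difference Jacobian (independent of model_jacobian).
newton_refine <- function(model, params, start, iters = 50, tol = 1e-12) {
  x <- start
  for (k in seq_len(iters)) {
    f <- model_rhs(model, params, x)
    if (max(abs(f)) < tol) break
    J <- fd_jacobian(model, params, x, h = 1e-7)
    step <- solve(J, f)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (max(abs(model_rhs(model, params, xn))) < max(abs(f)) || lambda < 1e-4)
        break
      lambda <- lambda / 2
    }
    x <- xn
  }
  x
}

# Model I analytic L* as a function of one varied parameter, for Brent
# root oracles on the critical values.
lstar_model1 <- function(params, vary, value) {
  params[[vary]] <- value
  fixed_point_model1(params)$state[["L"]]
}

# Construct a sweep_result by hand (for unit tests of the reporting
# layer that need a controlled flag stream).
make_sweep_result <- function(df, lo = 0.1, hi = 0.5) {
  need <- c("rho_S", "delta_S", "rho_A", "delta_A", "S", "A", "D", "L", "T",
            "a_positive", "l_positive", "coexistence",
            "a_dominates", "l_dominates", "indeterminate", "reason")
  for (nm in setdiff(need, names(df))) {
    df[[nm]] <- switch(nm,
      reason = NA_character_,
      indeterminate = FALSE,
      a_positive = df$A > 1e-6, l_positive = df$L > 1e-6,
      coexistence = df$A > 1e-6 & df$L > 1e-6,
      a_dominates = df$A > 1e-6 & df$L > 1e-6 & df$A > df$L,
      l_dominates = df$A > 1e-6 & df$L > 1e-6 & df$L > df$A,
      0)
  }
  structure(df[need],
            metadata = list(model = "I", engine = "SYNTHETIC", eps = 1e-6,
                            design = list(mode = "manual", lo = lo, hi = hi)),
            class = c("sweep_result", "data.frame"))
}

flags_logical <- function(f) as.logical(unclass(f))
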