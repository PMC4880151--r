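# Numerical integration to (near-)equilibrium.
#
# Both models are stiff in parts of parameter space, so integration uses
# the LSODA core (deSolve::lsodar) with the right-hand sides compiled in
# src/models.c. A root function — the max-norm of the right-hand side
# minus the convergence tolerance — lets the solver stop at the first
# instant the steady-state criterion is met instead of integrating to the
# horizon. Convergence is declared on the residual norm, not on the state
# difference between checks, to avoid false convergence on slow
# transients.

.pack_parms <- function(params, conv_tol) {
  c(params$rho_S, params$delta_S, params$rho_A, params$delta_A,
    params$rho_L, params$delta_L, params$mu_D, params$mu_T,
    params$K1, params$K2, conv_tol)
}

#' Integration settings
#'
#' Bundle of the numerical protocol for [integrate_to_steady_state()].
#' Defaults: a small equal seeding of all five species
#' (`(0.01, 0.01, 0.01, 0.01, 0.01)`) so that either lineage can invade;
#' horizon `t_max = 10000` time units (rates are O(0.1-0.5)/time, so
#' relaxation times are O(10-100)); solver tolerances
#' `rtol = 1e-8`, `atol = 1e-10`; steady state declared when the
#' right-hand-side max-norm falls below `convergence_norm_tol = 1e-9`;
#' `check_interval = 50` sets the reporting grid of the trajectory (the
#' compiled root function monitors convergence continuously in between).
#'
#' @param initial_state nonnegative population state vector.
#' @param t_max time horizon (> 0).
#' @param rtol,atol relative/absolute solver tolerances (> 0).
#' @param convergence_norm_tol threshold on the right-hand-side max-norm
#'   for declaring steady state (> 0).
#' @param check_interval time between reported convergence checks (> 0).
#' @return An `integration_settings` object (named list).
#' @export
integration_settings <- function(initial_state = population_state(0.01, 0.01, 0.01, 0.01, 0.01),
                                 t_max = 10000, rtol = 1e-8, atol = 1e-10,
                                 convergence_norm_tol = 1e-9,
                                 check_interval = 50) {
  initial_state <- validate_state(initial_state)
  if (any(initial_state < 0))
    stop("initial_state components must be nonnegative")
  for (nm in c("t_max", "rtol", "atol", "convergence_norm_tol", "check_interval"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || get(nm) <= 0)
      stop("'", nm, "' must be a positive scalar")
  structure(list(initial_state = initial_state, t_max = t_max,
                 rtol = rtol, atol = atol,
                 convergence_norm_tol = convergence_norm_tol,
                 check_interval = check_interval),
            class = "integration_settings")
}

#' Integrate a model to (near-)steady state
#'
#' Runs the stiff LSODA solver from `settings$initial_state`, stopping at
#' the first time the max-norm of the right-hand side drops below
#' `settings$convergence_norm_tol`, or at `t_max` otherwise. Tiny negative
#' components of the final state (solver overshoot larger than `-atol`)
#' are clamped to zero.
#'
#' @param model `"I"` or `"II"`.
#' @param params a [model_params()] object.
#' @param settings an [integration_settings()] object.
#' @return A `trajectory_result` object: list with `final_state`,
#'   `converged` (TRUE iff the residual criterion holds at the final
#'   state), `t_final`, and `n_steps` (solver step count).
#' @examples
#' r <- integrate_to_steady_state("I", model_params(), integration_settings())
#' r$final_state
#' @export
integrate_to_steady_state <- function(model, params, settings = integration_settings()) {
  model <- match_model(model)
  validate_params(params)
  stopifnot(inherits(settings, "integration_settings"))
  n <- max(2L, ceiling(settings$t_max / settings$check_interval) + 1L)
  times <- seq(0, settings$t_max, length.out = n)
  which <- if (model == "I") c("hscniche_derivs1", "hscniche_root1")
           else c("hscniche_derivs2", "hscniche_root2")
  out <- tryCatch(
    deSolve::lsodar(y = settings$initial_state, times = times,
                    func = which[1], rootfunc = which[2], nroot = 1,
                    dllname = "hscniche", initfunc = "hscniche_initmod",
                    parms = .pack_parms(params, settings$convergence_norm_tol),
                    rtol = settings$rtol, atol = settings$atol),
    error = function(e)
      stop(structure(class = c("hscniche_integration_error", "error", "condition"),
                     list(message = paste0("integration failed: ",
                                           conditionMessage(e)),
                          call = sys.call(-1)))))
  last <- out[nrow(out), ]
  final <- setNames(as.numeric(last[2:6]), STATE_NAMES)
  # clamp solver overshoot
  tiny <- final < 0 & final > -settings$atol
  final[tiny] <- 0
  resid <- max(abs(model_rhs(model, params, final)))
  structure(list(final_state = final,
                 converged = resid < settings$convergence_norm_tol,
                 t_final = unname(last[1]),
                 n_steps = attr(out, "istate")[2],
                 residual_norm = resid),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("Trajectory: %s at t = %.6g (%d steps, ||rhs||_inf = %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$t_final, x$n_steps, x$residual_norm))
  print(x$final_state)
  invisible(x)
}

#' Simulate and tabulate a trajectory
#'
#' Dense trajectory of either model at user-chosen output times, as a
#' CSV-ready data.frame (time, S, A, D, L, T).
#'
#' @inheritParams integrate_to_steady_state
#' @param times numeric vector of output times (first element the initial
#'   time).
#' @return A data.frame with columns `time`, `S`, `A`, `D`, `L`, `T`.
#' @export
simulate_trajectory <- function(model, params, times,
                                settings = integration_settings()) {
  model <- match_model(model)
  validate_params(params)
  which <- if (model == "I") "hscniche_derivs1" else "hscniche_derivs2"
  out <- deSolve::lsoda(y = settings$initial_state, times = times,
                        func = which, dllname = "hscniche",
                        initfunc = "hscniche_initmod",
                        parms = .pack_parms(params, settings$convergence_norm_tol),
                        rtol = settings$rtol, atol = settings$atol)
  out <- as.data.frame(out)
  names(out) <- c("time", STATE_NAMES)
  out
}
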