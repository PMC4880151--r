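# Right-hand sides and Jacobians of the two competition models.
#
# Model I:
#   dS/dt = rho_S S (K1 - Z1) - delta_S S          Z1 = S
#   dA/dt = delta_S S + rho_A A (K2 - Z2) - delta_A A
#   dD/dt = delta_A A - mu_D D                     Z2 = A + L
#   dL/dt = rho_L L (K2 - Z2) - delta_L L
#   dT/dt = delta_L L - mu_T T
#
# Model II replaces the A -> D differentiation flux delta_A * A by
# delta_A * A / (1 + D) in both dA/dt and dD/dt: accumulating
# differentiated cells feed back to delay progenitor differentiation.
# The S, L and T equations are identical between models.

match_model <- function(model) {
  if (is.numeric(model)) model <- c("I", "II")[model]
  model <- toupper(as.character(model))
  if (!model %in% c("I", "II"))
    stop("model must be \"I\" or \"II\"")
  model
}

#' Right-hand side of a competition model
#'
#' Evaluates the five time-derivatives of the chosen model at a state.
#' The two models agree exactly in the S, L and T equations and differ
#' only in the A-to-D differentiation flux (`delta_A * A` for Model I,
#' `delta_A * A / (1 + D)` for Model II), which appears with opposite
#' signs in dA/dt and dD/dt; at `D = 0` the models coincide.
#'
#' @param model `"I"` or `"II"` (also accepts 1 or 2).
#' @param params a [model_params()] object.
#' @param state a population state vector `(S, A, D, L, T)`; see
#'   [population_state()]. Components must be finite but may be negative
#'   (mid-integration solver overshoot is not clipped here).
#' @return Named numeric vector of the five derivatives, in state order.
#' @examples
#' p <- model_params()
#' model_rhs("I", p, population_state(0.72, 0, 0, 0, 0))
#' @export
model_rhs <- function(model, params, state) {
  model <- match_model(model)
  validate_params(params)
  state <- validate_state(state)
  S <- state[["S"]]; A <- state[["A"]]; D <- state[["D"]]
  L <- state[["L"]]; T <- state[["T"]]
  Z2 <- A + L
  flux <- if (model == "II") params$delta_A * A / (1 + D) else params$delta_A * A
  c(S = params$rho_S * S * (params$K1 - S) - params$delta_S * S,
    A = params$delta_S * S + params$rho_A * A * (params$K2 - Z2) - flux,
    D = flux - params$mu_D * D,
    L = params$rho_L * L * (params$K2 - Z2) - params$delta_L * L,
    T = params$delta_L * L - params$mu_T * T)
}

#' Analytic Jacobian of a competition model
#'
#' The 5x5 matrix of partial derivatives of [model_rhs()] with respect to
#' the state, evaluated at `state`. Hand-derived (not differenced):
#' eigenvalue classification near marginal stability is sensitive to
#' differencing noise, so the analytic form is used for all stability
#' work and finite-difference agreement is enforced in the test suite.
#'
#' @inheritParams model_rhs
#' @return A 5x5 numeric matrix with dimnames `(S, A, D, L, T)`; entry
#'   `(i, j)` is the derivative of equation `i` with respect to species `j`.
#' @export
model_jacobian <- function(model, params, state) {
  model <- match_model(model)
  validate_params(params)
  state <- validate_state(state)
  S <- state[["S"]]; A <- state[["A"]]; D <- state[["D"]]; L <- state[["L"]]
  fb  <- if (model == "II") 1 / (1 + D) else 1          # feedback factor
  dfb <- if (model == "II") params$delta_A * A / (1 + D)^2 else 0

  J <- matrix(0, 5, 5, dimnames = list(STATE_NAMES, STATE_NAMES))
  J["S", "S"] <- params$rho_S * (params$K1 - 2 * S) - params$delta_S

  J["A", "S"] <- params$delta_S
  J["A", "A"] <- params$rho_A * (params$K2 - 2 * A - L) - params$delta_A * fb
  J["A", "D"] <- dfb
  J["A", "L"] <- -params$rho_A * A

  J["D", "A"] <- params$delta_A * fb
  J["D", "D"] <- -dfb - params$mu_D

  J["L", "A"] <- -params$rho_L * L
  J["L", "L"] <- params$rho_L * (params$K2 - A - 2 * L) - params$delta_L

  J["T", "L"] <- params$delta_L
  J["T", "T"] <- -params$mu_T
  J
}
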