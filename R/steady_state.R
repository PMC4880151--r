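# Closed-form steady states, critical values and coexistence
# classification.
#
# With K1 = K2 = 1 the Model I interior fixed point is
#   S* = 1 - delta_S/rho_S
#   A* = -delta_S S* / (rho_A delta_L/rho_L - delta_A)
#   D* = delta_A A* / mu_D
#   L* = 1 - A* - delta_L/rho_L
#   T* = delta_L L* / mu_T
# The L equation pins the occupancy Z2* = A* + L* = 1 - delta_L/rho_L
# whenever L is present, which is where the L* expression comes from.
#
# Model II keeps S*, L*, T* and replaces the (A*, D*) pair by the two
# roots of a quadratic in D* (see fixed_points_model2), giving a minus
# and a plus branch that may be complex.

# guard band around the pole of A* (the delta_A asymptote)
SINGULAR_TOL <- 1e-9

new_fixed_point <- function(state, branch, is_real, model, params) {
  is_nonneg <- is_real && all(state >= 0)
  structure(list(state = if (is_real) validate_state(state) else NULL,
                 branch = branch, is_real = is_real,
                 is_nonnegative = is_nonneg, model = model),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Model %s fixed point (branch %s): ", x$model, x$branch))
  if (!x$is_real) {
    cat("complex (no real state)\n")
  } else {
    cat(if (x$is_nonnegative) "nonnegative\n" else "has negative component(s)\n")
    print(x$state)
  }
  invisible(x)
}

#' Analytic fixed point of Model I
#'
#' The unique interior fixed point in closed form. The identities
#' `D* = delta_A A*/mu_D`, `T* = delta_L L*/mu_T` and (when leukaemia is
#' present) `A* + L* = K2 - delta_L/rho_L` hold exactly by construction.
#' Any of the components may be negative; use [classify_region()] to
#' interpret the point.
#'
#' @param params a [model_params()] object.
#' @return A `fixed_point` object with `branch = "unique"`.
#' @section Singularities: `A*` has a pole where
#'   `rho_A delta_L / rho_L - delta_A` vanishes (the `delta_A` asymptote);
#'   parameter sets within `1e-9` of it raise an error of class
#'   `hscniche_singular`.
#' @examples
#' fixed_point_model1(model_params())
#' @export
fixed_point_model1 <- function(params) {
  validate_params(params)
  den <- params$rho_A * params$delta_L / params$rho_L - params$delta_A
  if (abs(den) < SINGULAR_TOL)
    stop(structure(class = c("hscniche_singular", "error", "condition"),
                   list(message = paste0(
                          "singular steady state: |rho_A*delta_L/rho_L - delta_A| = ",
                          format(abs(den)), " < ", SINGULAR_TOL,
                          " (A* diverges at the delta_A asymptote)"),
                        call = sys.call(-1))))
  S <- params$K1 - params$delta_S / params$rho_S
  A <- -params$delta_S * S / den
  D <- params$delta_A * A / params$mu_D
  L <- params$K2 - A - params$delta_L / params$rho_L
  T <- params$delta_L * L / params$mu_T
  new_fixed_point(c(S = S, A = A, D = D, L = L, T = T),
                  "unique", TRUE, "I", params)
}

#' Analytic fixed points of Model II (both branches)
#'
#' `S*`, and the expressions for `L*` and `T*` given `A*`, carry over from
#' Model I; the `(A*, D*)` pair solves
#' `A* = mu_D D* (1 + D*) / delta_A` together with a quadratic in `D*`,
#'
#' `D* = (beta - 1)/2 +- sqrt((beta - 1)^2/4 - delta_S delta_A rho_L S* / (rho_A delta_L mu_D))`
#'
#' with `beta = delta_A rho_L / (rho_A delta_L)`. When the discriminant is
#' negative both branches are complex and no state is reported.
#'
#' @param params a [model_params()] object.
#' @return A list of two `fixed_point` objects, in branch order
#'   `(minus, plus)` — the first and second solution respectively; the
#'   plus branch is the one that admits coexistence.
#' @examples
#' fixed_points_model2(model_params(rho_S = 0.3, delta_S = 0.25))
#' @export
fixed_points_model2 <- function(params) {
  validate_params(params)
  S <- params$K1 - params$delta_S / params$rho_S
  beta <- params$delta_A * params$rho_L / (params$rho_A * params$delta_L)
  disc <- (beta - 1)^2 / 4 -
    params$delta_S * params$delta_A * params$rho_L * S /
      (params$rho_A * params$delta_L * params$mu_D)
  mk <- function(sgn, branch) {
    if (disc < 0)
      return(new_fixed_point(NULL, branch, FALSE, "II", params))
    D <- (beta - 1) / 2 + sgn * sqrt(disc)
    A <- params$mu_D * D * (1 + D) / params$delta_A
    L <- params$K2 - A - params$delta_L / params$rho_L
    T <- params$delta_L * L / params$mu_T
    new_fixed_point(c(S = S, A = A, D = D, L = L, T = T),
                    branch, TRUE, "II", params)
  }
  list(minus = mk(-1, "minus"), plus = mk(1, "plus"))
}

#' Critical and asymptotic parameter values (Model I)
#'
#' The parameter values at which a species' Model I steady state crosses
#' zero or diverges, partitioning parameter space into qualitatively
#' distinct regions. With `phi = K2 - delta_L/rho_L` (the occupancy the
#' leukaemia equation enforces) and `d = rho_A delta_L/rho_L - delta_A`:
#'
#' * `rho_S_crit = delta_S` — `S*` (and hence `A*`) vanishes;
#' * `rho_S_Lzero = delta_S / (1 + phi d / delta_S)` — `L*` crosses zero
#'   as `rho_S` varies;
#' * `xi` with `xi^2 = rho_S^2/4 + rho_S phi d`, and
#'   `delta_S_crit = rho_S/2 + xi` — the upper root in `delta_S` of
#'   `L* = 0` (the lower root is `rho_S/2 - xi`); both are complex when
#'   `xi^2 < 0`, in which case `L*` does not change sign in `delta_S`;
#' * `rho_A_crit = (rho_L/delta_L) (delta_A - delta_S S*/phi)` — `L*`
#'   crosses zero as `rho_A` increases;
#' * `delta_A_crit = rho_A delta_L/rho_L + delta_S S*/phi` — `L*` crosses
#'   zero as `delta_A` decreases;
#' * `delta_A_asymp = rho_A delta_L/rho_L` — the pole where `A*` diverges.
#'
#' These formulas are re-derived from the steady-state expressions (set
#' `S* = 0` or `L* = 0` and solve); each is verified in the test suite by
#' an independent root-finding oracle on the corresponding steady-state
#' curve. `A*` and `D*` are largest, and `L*`, `T*` smallest, at
#' `delta_S = rho_S / 2`, independent of all other parameters.
#'
#' @param params a [model_params()] object.
#' @return An object of class `critical_values`: a list with fields
#'   `rho_S_crit`, `rho_S_Lzero`, `delta_S_crit`, `xi`, `rho_A_crit`,
#'   `delta_A_crit`, `delta_A_asymp`, plus logical flags
#'   `xi_real` and `delta_S_crit_real`. Values that are undefined for the
#'   given parameters are reported as `NA` with the flag set to `FALSE`,
#'   never as an error.
#' @examples
#' critical_values(model_params())
#' @export
critical_values <- function(params) {
  validate_params(params)
  phi <- params$K2 - params$delta_L / params$rho_L
  d <- params$rho_A * params$delta_L / params$rho_L - params$delta_A
  S_star <- params$K1 - params$delta_S / params$rho_S

  xi2 <- params$rho_S^2 / 4 + params$rho_S * phi * d
  xi_real <- xi2 >= 0
  xi <- if (xi_real) sqrt(xi2) else NA_real_

  structure(list(
    rho_S_crit = params$delta_S,
    rho_S_Lzero = params$delta_S / (1 + phi * d / params$delta_S),
    delta_S_crit = if (xi_real) params$rho_S / 2 + xi else NA_real_,
    xi = xi,
    rho_A_crit = (params$rho_L / params$delta_L) *
      (params$delta_A - params$delta_S * S_star / phi),
    delta_A_crit = params$rho_A * params$delta_L / params$rho_L +
      params$delta_S * S_star / phi,
    delta_A_asymp = params$rho_A * params$delta_L / params$rho_L,
    xi_real = xi_real,
    delta_S_crit_real = xi_real),
    class = "critical_values")
}

#' @export
print.critical_values <- function(x, ...) {
  cat("Critical/asymptotic parameter values (Model I):\n")
  v <- unlist(x[c("rho_S_crit", "rho_S_Lzero", "delta_S_crit", "xi",
                  "rho_A_crit", "delta_A_crit", "delta_A_asymp")])
  print(v)
  if (!x$xi_real)
    cat("(xi and delta_S_crit are complex for these parameters)\n")
  invisible(x)
}

#' Classify a fixed point into survival/coexistence/dominance features
#'
#' Applies the positivity threshold `eps` to the progenitor and leukaemia
#' components of a fixed point: `a_positive` iff `A* > eps`, `l_positive`
#' iff `L* > eps`, `coexistence` iff both, and the dominance flags compare
#' `A*` with `L*` only within coexistence (a tie within `eps` sets
#' neither). A non-real fixed point yields all-`FALSE` flags.
#'
#' @param params the parameter set the fixed point was computed for
#'   (carried into the record; not re-validated against `fp`).
#' @param fp a `fixed_point` object, or any object with `$state` and
#'   `$is_real`.
#' @param eps positivity threshold on scaled population sizes; the default
#'   `1e-6` is far above solver tolerance and far below any biologically
#'   meaningful population fraction.
#' @return A `feature_flags` object: named logical vector with elements
#'   `a_positive`, `l_positive`, `coexistence`, `a_dominates`,
#'   `l_dominates`.
#' @examples
#' p <- model_params(rho_S = 0.3, delta_S = 0.25)
#' classify_region(p, fixed_point_model1(p))
#' @export
classify_region <- function(params, fp, eps = 1e-6) {
  stopifnot(eps > 0)
  if (!isTRUE(fp$is_real))
    return(feature_flags(FALSE, FALSE))
  st <- fp$state
  feature_flags(st[["A"]], st[["L"]], eps)
}

# Build the flag vector from A and L steady-state values (or logicals).
feature_flags <- function(A, L, eps = 1e-6) {
  if (is.logical(A)) {
    a <- A; l <- L; ad <- FALSE; ld <- FALSE
  } else {
    a <- is.finite(A) && A > eps
    l <- is.finite(L) && L > eps
    ad <- a && l && (A - L) > eps
    ld <- a && l && (L - A) > eps
  }
  structure(c(a_positive = a, l_positive = l, coexistence = a && l,
              a_dominates = ad, l_dominates = ld),
            class = "feature_flags")
}

#' Exportable JSON record of a fixed point
#'
#' A flat record (keyed by the canonical parameter key) suitable for
#' `jsonlite::write_json()`: parameter key, model, branch, realness and
#' nonnegativity flags, and the state when real.
#'
#' @param fp a `fixed_point` object.
#' @param params the parameter set it was computed for.
#' @return A named list.
#' @export
fixed_point_record <- function(fp, params) {
  list(key = param_key(params), model = fp$model, branch = fp$branch,
       is_real = fp$is_real, is_nonnegative = fp$is_nonnegative,
       state = if (fp$is_real) as.list(fp$state) else NULL)
}

#' Tabulate a steady-state curve over one varied parameter
#'
#' Varies a single parameter over a grid, holding the rest fixed, and
#' returns the analytic steady states of the requested model — the data
#' behind one panel of a steady-state-versus-parameter figure. For
#' Model II both branches are returned (complex branches as `NA` rows).
#'
#' @param model `"I"` or `"II"`.
#' @param params baseline [model_params()].
#' @param vary name of the parameter to vary.
#' @param values numeric grid of values for the varied parameter.
#' @return A data.frame with columns `vary` name, `branch`, `S`, `A`,
#'   `D`, `L`, `T` (a CSV-ready table; one row per grid point per branch).
#' @export
steady_state_curve <- function(model, params, vary, values) {
  model <- match_model(model)
  stopifnot(vary %in% PARAM_NAMES)
  rows <- lapply(values, function(v) {
    p <- params; p[[vary]] <- v
    fps <- if (model == "I") {
      list(unique = tryCatch(fixed_point_model1(p),
                             hscniche_singular = function(e) NULL))
    } else fixed_points_model2(p)
    do.call(rbind, lapply(names(fps), function(br) {
      fp <- fps[[br]]
      st <- if (!is.null(fp) && fp$is_real) fp$state else
        setNames(rep(NA_real_, 5), STATE_NAMES)
      cbind(data.frame(v, branch = br), as.data.frame(t(st)))
    }))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- vary
  rownames(out) <- NULL
  out
}
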