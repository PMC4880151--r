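# Linear stability of fixed points, and the stable-fraction study over
# uniformly sampled parameter sets.

#' Linear stability of a fixed point
#'
#' Computes the eigenvalues of the analytic Jacobian at a (real) fixed
#' point. The point is classified stable iff every eigenvalue real part
#' is below `-stability_tol`; "negative eigenvalues" is read as negative
#' real parts (complex eigenvalues are possible for a 5x5 system), and
#' marginal cases within the tolerance band are conservatively classified
#' unstable.
#'
#' @param model `"I"` or `"II"`.
#' @param params a [model_params()] object.
#' @param fp a `fixed_point` object (must be real), or a bare state
#'   vector.
#' @param stability_tol band around zero within which a real part counts
#'   as marginal (default `1e-9`).
#' @return A `stability_result` object: list with
#'   `eigenvalue_real_parts` (sorted decreasing), `is_stable`, and
#'   `margin` (the largest real part; stable iff `margin < -stability_tol`).
#' @examples
#' p <- model_params(rho_S = 0.3, delta_S = 0.25, rho_A = 0.2, delta_A = 0.3)
#' assess_stability("I", p, fixed_point_model1(p))
#' @export
assess_stability <- function(model, params, fp, stability_tol = 1e-9) {
  model <- match_model(model)
  state <- if (inherits(fp, "fixed_point")) {
    if (!fp$is_real)
      stop("cannot assess stability of a non-real fixed point")
    fp$state
  } else validate_state(fp)
  J <- model_jacobian(model, params, state)
  re <- sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
  structure(list(eigenvalue_real_parts = re,
                 is_stable = re[1] < -stability_tol,
                 margin = re[1]),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("%s (largest eigenvalue real part %.6g)\n",
              if (x$is_stable) "Linearly stable" else "Not stable", x$margin))
  invisible(x)
}

#' Stable fraction within the coexistence region
#'
#' Draws `n_samples` iid parameter sets with `(rho_S, rho_A, delta_S,
#' delta_A)` uniform on `[range[1], range[2]]^4` and the remaining
#' parameters fixed at `fixed`, computes the requested analytic fixed
#' point of the chosen model, keeps the draws whose point is real with
#' `A* > eps` and `L* > eps` (the coexistence region), and reports the
#' fraction of those that are linearly stable.
#'
#' @param model `"I"` or `"II"`.
#' @param branch fixed-point branch: `"unique"` (Model I), or `"minus"` /
#'   `"plus"` (first / second Model II solution).
#' @param n_samples number of parameter draws.
#' @param range length-2 sampling interval for each varied rate.
#' @param seed RNG seed recorded in the result (default 20160401).
#' @param eps positivity threshold defining coexistence.
#' @param fixed a [model_params()] object supplying `rho_L`, `delta_L`,
#'   `mu_D`, `mu_T`, `K1`, `K2`.
#' @param stability_tol passed to [assess_stability()].
#' @return A `stable_fraction_study` object: list with `model`, `branch`,
#'   `n_samples`, `range`, `seed`, `n_coexistent`, `n_stable`,
#'   `fraction_stable` (`NA` with `defined = FALSE` when no draw is
#'   coexistent).
#' @examples
#' stable_fraction_in_coexistence("I", n_samples = 200, seed = 1)
#' @export
stable_fraction_in_coexistence <- function(model,
                                           branch = c("unique", "minus", "plus"),
                                           n_samples = 10000,
                                           range = c(0.1, 0.5),
                                           seed = 20160401,
                                           eps = 1e-6,
                                           fixed = model_params(),
                                           stability_tol = 1e-9) {
  model <- match_model(model)
  branch <- match.arg(branch)
  if (model == "I" && branch != "unique")
    stop("Model I has a unique fixed point; use branch = \"unique\"")
  if (model == "II" && branch == "unique")
    stop("Model II has minus/plus branches; choose one")
  stopifnot(n_samples > 0, length(range) == 2L, range[1] < range[2])
  validate_params(fixed)

  set.seed(seed)
  draws <- matrix(runif(4L * n_samples, range[1], range[2]), ncol = 4L,
                  dimnames = list(NULL, c("rho_S", "rho_A", "delta_S", "delta_A")))
  n_coex <- 0L; n_stable <- 0L
  for (i in seq_len(n_samples)) {
    p <- fixed
    p[c("rho_S", "rho_A", "delta_S", "delta_A")] <- as.list(draws[i, ])
    fp <- if (model == "I") {
      tryCatch(fixed_point_model1(p), hscniche_singular = function(e) NULL)
    } else fixed_points_model2(p)[[branch]]
    if (is.null(fp) || !fp$is_real) next
    st <- fp$state
    if (st[["A"]] > eps && st[["L"]] > eps) {
      n_coex <- n_coex + 1L
      if (assess_stability(model, p, fp, stability_tol)$is_stable)
        n_stable <- n_stable + 1L
    }
  }
  structure(list(model = model, branch = branch, n_samples = n_samples,
                 range = range, seed = seed, eps = eps,
                 n_coexistent = n_coex, n_stable = n_stable,
                 fraction_stable = if (n_coex > 0) n_stable / n_coex else NA_real_,
                 defined = n_coex > 0),
            class = "stable_fraction_study")
}

#' @export
print.stable_fraction_study <- function(x, ...) {
  cat(sprintf(
    "Stable-fraction study: Model %s, branch %s, n = %d (seed %d)\n",
    x$model, x$branch, x$n_samples, x$seed))
  cat(sprintf("  coexistent: %d   stable: %d   fraction: %s\n",
              x$n_coexistent, x$n_stable,
              if (x$defined) format(x$fraction_stable, digits = 4)
              else "undefined (no coexistent draws)"))
  invisible(x)
}
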