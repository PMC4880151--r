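# Feature classification over parameter ensembles, probability summaries
# and 2D density tables.
#
# Two engines classify a parameter set:
#
#   * "analytic"    — closed-form prediction of the long-run (t -> infinity)
#                     state. For Model I this is exact: S relaxes
#                     autonomously to max(0, K1 - delta_S/rho_S); given
#                     that, the interior fixed point is the attractor
#                     exactly when it is coexistent, otherwise the
#                     healthy-only boundary root (leukaemia cannot invade
#                     it precisely when the interior L* <= 0), and when S
#                     dies the (A, L) pair reduces to competitive
#                     exclusion decided by the smaller delta/rho ratio.
#                     For Model II the analytic branches are a documented
#                     over-approximation used for cross-checks only.
#   * "integration" — stiff LSODA integration from the default initial
#                     condition and classification of the final state;
#                     this mirrors the simulation protocol under which
#                     the reference survival/coexistence probabilities
#                     were measured. Near exclusion boundaries the decay
#                     of the losing species can be slower than any
#                     practical horizon, so the finite-time state may
#                     legitimately count as coexistent where the t ->
#                     infinity limit is not; `on_nonconverged` chooses
#                     whether such unconverged points are classified
#                     as-is ("classify") or reported indeterminate and
#                     excluded ("exclude").

# rhs without validation overhead, parms packed as in .pack_parms()
.rhs_raw <- function(model, pv, y) {
  Z2 <- y[2] + y[4]
  flux <- if (model == "II") pv[4] * y[2] / (1 + y[3]) else pv[4] * y[2]
  c(pv[1] * y[1] * (pv[9] - y[1]) - pv[2] * y[1],
    pv[2] * y[1] + pv[3] * y[2] * (pv[10] - Z2) - flux,
    flux - pv[7] * y[3],
    pv[5] * y[4] * (pv[10] - Z2) - pv[6] * y[4],
    pv[6] * y[4] - pv[8] * y[5])
}

# Vectorised Model I long-run attractor over a varied-parameter matrix.
# Returns a list of five state vectors plus an indeterminate flag
# (singular parameter sets on the delta_A asymptote).
.attractor_model1_vec <- function(V, fixed, eps) {
  rS <- V[, "rho_S"]; dS <- V[, "delta_S"]
  rA <- V[, "rho_A"]; dA <- V[, "delta_A"]
  K1 <- fixed$K1; K2 <- fixed$K2
  rL <- fixed$rho_L; dL <- fixed$delta_L
  muD <- fixed$mu_D; muT <- fixed$mu_T
  n <- nrow(V)

  den <- rA * dL / rL - dA
  singular <- abs(den) < SINGULAR_TOL
  up <- rS * K1 > dS                       # S persists
  Sinf <- ifelse(up, K1 - dS / rS, 0)

  A <- numeric(n); L <- numeric(n)
  # interior fixed point, where coexistent
  Ai <- -dS * Sinf / den
  Li <- K2 - Ai - dL / rL
  coex <- up & !singular & is.finite(Ai) & Ai > eps & Li > eps
  # healthy-only boundary root (positive root of the A quadratic)
  q <- rA * K2 - dA
  Ah <- (q + sqrt(q^2 + 4 * rA * dS * Sinf)) / (2 * rA)
  A[up] <- ifelse(coex[up], Ai[up], Ah[up])
  L[up] <- ifelse(coex[up], Li[up], 0)
  # S extinct: competitive exclusion in the shared niche, won by the
  # smaller delta/rho ratio (ties, a measure-zero set, go to leukaemia)
  a_wins <- !up & (dA / rA < dL / rL)
  l_wins <- !up & !a_wins
  A[a_wins] <- pmax(0, K2 - dA[a_wins] / rA[a_wins])
  L[l_wins] <- max(0, K2 - dL / rL)

  S <- Sinf
  D <- dA * A / muD
  T <- dL * L / muT
  list(S = S, A = A, D = D, L = L, T = T, indeterminate = singular)
}

# Representative analytic flags for Model II: a point counts as
# coexistent if any real nonnegative branch is coexistent (documented
# over-approximation; cross-check use only).
.analytic_flags_model2 <- function(params, eps) {
  fps <- fixed_points_model2(params)
  qual <- Filter(function(fp) fp$is_real && all(fp$state > -eps), fps)
  if (!length(qual))
    return(list(flags = feature_flags(FALSE, FALSE), state = NULL))
  cf <- vapply(qual, function(fp)
    fp$state[["A"]] > eps && fp$state[["L"]] > eps, TRUE)
  # prefer the plus branch, but honour a coexistent branch wherever it is
  pick <- if (any(cf)) rev(which(cf))[1L] else length(qual)
  fp <- qual[[pick]]
  list(flags = feature_flags(fp$state[["A"]], fp$state[["L"]], eps),
       state = fp$state)
}

.fast_integrate_final <- function(model, pv, settings) {
  which <- if (model == "I") c("hscniche_derivs1", "hscniche_root1")
           else c("hscniche_derivs2", "hscniche_root2")
  out <- deSolve::lsodar(y = settings$initial_state,
                         times = c(0, settings$t_max),
                         func = which[1], rootfunc = which[2], nroot = 1,
                         dllname = "hscniche", initfunc = "hscniche_initmod",
                         parms = pv, rtol = settings$rtol, atol = settings$atol)
  y <- as.numeric(out[nrow(out), 2:6])
  y[y < 0 & y > -settings$atol] <- 0
  y
}

#' Classify one parameter set
#'
#' Evaluates the survival/coexistence/dominance features of a single
#' parameter set with either engine (see the module comments in this
#' file for the engine semantics).
#'
#' @param model `"I"` or `"II"`.
#' @param params a [model_params()] object.
#' @param engine `"analytic"` or `"integration"`. The analytic engine is
#'   exact and fast for Model I; the integration engine is the default
#'   and primary choice for Model II (branch/basin ambiguity makes the
#'   analytic branches an over-approximation there).
#' @param eps positivity threshold (see [classify_region()]).
#' @param settings [integration_settings()] for the integration engine.
#' @param on_nonconverged `"classify"` (classify the state at `t_max`;
#'   finite-time protocol) or `"exclude"` (flag indeterminate).
#' @return A `feature_flags` vector with attributes `state` (the steady /
#'   final state used), `indeterminate` (logical) and `reason`
#'   (`NA` or a short string).
#' @examples
#' evaluate_point("I", model_params(rho_S = 0.3, delta_S = 0.25), "analytic")
#' @export
evaluate_point <- function(model, params,
                           engine = c("integration", "analytic"),
                           eps = 1e-6,
                           settings = integration_settings(),
                           on_nonconverged = c("classify", "exclude")) {
  model <- match_model(model)
  engine <- match.arg(engine)
  on_nonconverged <- match.arg(on_nonconverged)
  validate_params(params)

  indet <- FALSE; reason <- NA_character_; state <- NULL
  if (engine == "analytic") {
    if (model == "I") {
      V <- matrix(unlist(params[VARIED_NAMES]), nrow = 1,
                  dimnames = list(NULL, VARIED_NAMES))
      at <- .attractor_model1_vec(V, params, eps)
      if (at$indeterminate[1]) {
        indet <- TRUE; reason <- "singular"
        flags <- feature_flags(FALSE, FALSE)
      } else {
        state <- population_state(at$S[1], at$A[1], at$D[1], at$L[1], at$T[1])
        flags <- feature_flags(state[["A"]], state[["L"]], eps)
      }
    } else {
      r <- .analytic_flags_model2(params, eps)
      flags <- r$flags; state <- r$state
      if (is.null(state)) { indet <- TRUE; reason <- "complex" }
    }
  } else {
    res <- integrate_to_steady_state(model, params, settings)
    state <- res$final_state
    if (!res$converged && on_nonconverged == "exclude") {
      indet <- TRUE; reason <- "nonconverged"
      flags <- feature_flags(FALSE, FALSE)
    } else {
      flags <- feature_flags(state[["A"]], state[["L"]], eps)
    }
  }
  attr(flags, "state") <- state
  attr(flags, "indeterminate") <- indet
  attr(flags, "reason") <- reason
  flags
}

#' Run a feature-classification sweep
#'
#' Classifies every parameter set of a design and returns a per-point
#' table: the four varied rates, the steady/final state, the five
#' feature flags, and an indeterminate marker with reason (singular
#' parameter sets, complex branches, or — under
#' `on_nonconverged = "exclude"` — unconverged integrations).
#'
#' For Model I with the analytic engine the whole sweep is vectorised and
#' a full-scale grid runs in seconds; integration sweeps run one compiled
#' LSODA solve per point.
#'
#' @param model `"I"` or `"II"`.
#' @param design a [sweep_design()].
#' @param engine,eps,settings,on_nonconverged see [evaluate_point()].
#' @param override passed to [generate_params()].
#' @return A `sweep_result`: data.frame with columns `rho_S`, `delta_S`,
#'   `rho_A`, `delta_A`, `S`, `A`, `D`, `L`, `T`, `a_positive`,
#'   `l_positive`, `coexistence`, `a_dominates`, `l_dominates`,
#'   `indeterminate`, `reason`; run provenance (engine, eps, settings,
#'   design, package version) in `attr(, "metadata")`.
#' @examples
#' d <- sweep_design("grid", points_per_axis = 5)
#' r <- run_sweep("I", d, engine = "analytic")
#' summarize_sweep(r)
#' @export
run_sweep <- function(model, design,
                      engine = c("integration", "analytic"),
                      eps = 1e-6,
                      settings = integration_settings(),
                      on_nonconverged = c("classify", "exclude"),
                      override = FALSE) {
  model <- match_model(model)
  engine <- match.arg(engine)
  on_nonconverged <- match.arg(on_nonconverged)
  stopifnot(inherits(design, "sweep_design"))
  V <- generate_params(design, override)
  n <- nrow(V)
  fixed <- design$fixed

  states <- matrix(NA_real_, n, 5, dimnames = list(NULL, STATE_NAMES))
  indet <- logical(n)
  reason <- rep(NA_character_, n)

  if (engine == "analytic" && model == "I") {
    at <- .attractor_model1_vec(V, fixed, eps)
    states[, "S"] <- at$S; states[, "A"] <- at$A; states[, "D"] <- at$D
    states[, "L"] <- at$L; states[, "T"] <- at$T
    indet <- at$indeterminate
    reason[indet] <- "singular"
    states[indet, ] <- NA_real_
  } else if (engine == "analytic") {
    for (i in seq_len(n)) {
      p <- complete_params(V[i, ], fixed)
      r <- .analytic_flags_model2(p, eps)
      if (is.null(r$state)) { indet[i] <- TRUE; reason[i] <- "complex" }
      else states[i, ] <- r$state
    }
  } else {
    fixedvec <- c(fixed$rho_L, fixed$delta_L, fixed$mu_D, fixed$mu_T,
                  fixed$K1, fixed$K2, settings$convergence_norm_tol)
    for (i in seq_len(n)) {
      pv <- c(V[i, 1], V[i, 2], V[i, 3], V[i, 4], fixedvec)
      y <- .fast_integrate_final(model, pv, settings)
      states[i, ] <- y
      if (on_nonconverged == "exclude" &&
          max(abs(.rhs_raw(model, pv, y))) >= settings$convergence_norm_tol) {
        indet[i] <- TRUE; reason[i] <- "nonconverged"
        states[i, ] <- NA_real_
      }
    }
  }

  A <- states[, "A"]; L <- states[, "L"]
  ap <- !indet & is.finite(A) & A > eps
  lp <- !indet & is.finite(L) & L > eps
  cx <- ap & lp
  ad <- cx & (A - L) > eps
  ld <- cx & (L - A) > eps

  out <- data.frame(V, states, a_positive = ap, l_positive = lp,
                    coexistence = cx, a_dominates = ad, l_dominates = ld,
                    indeterminate = indet, reason = reason)
  attr(out, "metadata") <- list(
    model = model, engine = toupper(engine), eps = eps,
    design = design[c("mode", "points_per_axis", "n_samples", "lo", "hi", "seed")],
    fixed = unclass(fixed),
    settings = if (engine == "integration") unclass(settings) else NULL,
    on_nonconverged = if (engine == "integration") on_nonconverged else NULL,
    package_version = as.character(utils::packageVersion("hscniche")))
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Aggregate a sweep into feature probabilities
#'
#' Feature counts over the determinate points of a sweep; indeterminate
#' points are excluded from the denominator and reported separately. The
#' dominance columns are joint probabilities
#' `P(A* > L* and coexistence)` / `P(L* > A* and coexistence)`, so they
#' sum to the coexistence probability up to ties.
#'
#' @param result a `sweep_result` from [run_sweep()].
#' @return A `sweep_summary`: list with `n_total` (determinate points),
#'   `n_indeterminate`, the five probabilities `p_a_positive`,
#'   `p_l_positive`, `p_coexistence`, `p_a_dominates`, `p_l_dominates`,
#'   and the run metadata (`engine`, `model`, `design`).
#' @export
summarize_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  md <- attr(result, "metadata")
  ok <- !result$indeterminate
  n <- sum(ok)
  if (n == 0L) stop("all points in the sweep are indeterminate")
  structure(list(
    model = md$model, engine = md$engine, design = md$design,
    n_total = n, n_indeterminate = sum(!ok),
    p_a_positive = mean(result$a_positive[ok]),
    p_l_positive = mean(result$l_positive[ok]),
    p_coexistence = mean(result$coexistence[ok]),
    p_a_dominates = mean(result$a_dominates[ok]),
    p_l_dominates = mean(result$l_dominates[ok])),
    class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf("Sweep summary: Model %s, %s engine, n = %d (%d indeterminate)\n",
              x$model, x$engine, x$n_total, x$n_indeterminate))
  v <- unlist(x[c("p_a_positive", "p_l_positive", "p_coexistence",
                  "p_a_dominates", "p_l_dominates")])
  print(round(v, 4))
  invisible(x)
}

.bin_index <- function(v, breaks) {
  i <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  i
}

#' Two-dimensional feature density table
#'
#' Bins a sweep over a pair of the varied parameters and tabulates, per
#' bin, the number of parameter sets exhibiting a feature and the total
#' number of sets — the numeric content of one panel of a feature-density
#' figure.
#'
#' @param result a `sweep_result`.
#' @param pair character vector of two varied-parameter names.
#' @param feature one of `"a_positive"`, `"l_positive"`, `"coexistence"`,
#'   `"a_dominates"`, `"l_dominates"`.
#' @param n_bins number of bins per axis (default 40).
#' @param subset optional logical vector selecting rows (recycled across
#'   determinate points); used by [dominance_report()] to condition on
#'   coexistence.
#' @return A `density_grid`: list with `pair`, `feature`, `breaks_x`,
#'   `breaks_y` (strictly increasing, spanning the design range),
#'   `count` and `total` matrices, `fraction` (`NA` for empty bins), and
#'   an `empty` flag (no rows selected).
#' @export
density2d <- function(result, pair, feature = "coexistence", n_bins = 40,
                      subset = NULL) {
  stopifnot(inherits(result, "sweep_result"),
            length(pair) == 2L, all(pair %in% VARIED_NAMES),
            feature %in% c("a_positive", "l_positive", "coexistence",
                           "a_dominates", "l_dominates"))
  md <- attr(result, "metadata")
  keep <- !result$indeterminate
  if (!is.null(subset)) keep <- keep & subset
  breaks <- seq(md$design$lo, md$design$hi, length.out = n_bins + 1L)
  count <- total <- matrix(0L, n_bins, n_bins)
  if (any(keep)) {
    ix <- .bin_index(result[[pair[1]]][keep], breaks)
    iy <- .bin_index(result[[pair[2]]][keep], breaks)
    f <- result[[feature]][keep]
    for (k in seq_along(ix)) {
      total[ix[k], iy[k]] <- total[ix[k], iy[k]] + 1L
      if (f[k]) count[ix[k], iy[k]] <- count[ix[k], iy[k]] + 1L
    }
  }
  frac <- ifelse(total > 0, count / total, NA_real_)
  structure(list(pair = pair, feature = feature,
                 breaks_x = breaks, breaks_y = breaks,
                 count = count, total = total, fraction = frac,
                 empty = !any(keep)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %s over (%s, %s), %dx%d bins%s\n",
              x$feature, x$pair[1], x$pair[2],
              nrow(x$count), ncol(x$count),
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Minimal image plot of a density grid
#'
#' @param x a `density_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_grid <- function(x, ...) {
  mx <- seq_len(length(x$breaks_x) - 1L)
  graphics::image(x = x$breaks_x, y = x$breaks_y, z = x$fraction,
                  xlab = x$pair[1], ylab = x$pair[2],
                  main = x$feature, ...)
}

#' Dominance density grids within the coexistence region
#'
#' As [density2d()] but restricted to coexistent points, tabulating which
#' lineage dominates: the per-bin fraction of coexistent sets where the
#' healthy progenitors exceed the leukaemia stem cells, and vice versa.
#'
#' @inheritParams density2d
#' @return A list with elements `a_dominates` and `l_dominates` (both
#'   `density_grid`s over the coexistent subset) and `empty` (TRUE when
#'   the sweep has no coexistent points).
#' @export
dominance_report <- function(result, pair, n_bins = 40) {
  cx <- result$coexistence
  list(a_dominates = density2d(result, pair, "a_dominates", n_bins, subset = cx),
       l_dominates = density2d(result, pair, "l_dominates", n_bins, subset = cx),
       empty = !any(cx & !result$indeterminate))
}

#' Write a sweep's per-point table as CSV
#'
#' Columns: the four varied rates, steady-state components, flags and
#' indeterminate reason.
#'
#' @param result a `sweep_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sweep_csv <- function(result, file) {
  utils::write.csv(as.data.frame(result), file, row.names = FALSE)
  invisible(file)
}
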