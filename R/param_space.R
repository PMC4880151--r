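# Parameter-ensemble generation: endpoint-inclusive grids and seeded
# uniform samples over the four varied healthy-lineage rates
# (rho_S, delta_S, rho_A, delta_A), with the leukaemia and clearance
# parameters held fixed.

VARIED_NAMES <- c("rho_S", "delta_S", "rho_A", "delta_A")

#' Sweep design
#'
#' Describes a parameter ensemble over the four varied rates
#' `(rho_S, delta_S, rho_A, delta_A)`. `"grid"` mode enumerates an
#' endpoint-inclusive, evenly spaced grid of `points_per_axis^4`
#' combinations; `"random"` mode draws `n_samples` iid points uniform on
#' `[lo, hi]^4`, reproducible from `seed`. The remaining parameters
#' (`rho_L`, `delta_L`, `mu_D`, `mu_T`, `K1`, `K2`) are taken from
#' `fixed`.
#'
#' @param mode `"grid"` or `"random"`.
#' @param points_per_axis grid resolution per axis (grid mode).
#' @param n_samples number of draws (random mode).
#' @param lo,hi range bounds for every varied rate (default `[0.1, 0.5]`).
#' @param seed RNG seed (random mode).
#' @param fixed a [model_params()] object supplying the fixed parameters.
#' @param max_points memory guard: [generate_params()] refuses designs
#'   larger than this unless `override = TRUE` there. Default `2^22`
#'   (about 4.2 million, enough for a 42-points-per-axis full-scale grid).
#' @return A `sweep_design` object.
#' @examples
#' sweep_design("grid", points_per_axis = 3)
#' sweep_design("random", n_samples = 100, seed = 1)
#' @export
sweep_design <- function(mode = c("grid", "random"),
                         points_per_axis = 21, n_samples = NULL,
                         lo = 0.1, hi = 0.5, seed = NULL,
                         fixed = model_params(), max_points = 2^22) {
  mode <- match.arg(mode)
  stopifnot(lo < hi, lo > 0)
  validate_params(fixed)
  if (mode == "grid") {
    stopifnot(points_per_axis >= 1)
    n_total <- as.numeric(points_per_axis)^4
  } else {
    if (is.null(n_samples) || n_samples < 1)
      stop("random mode requires n_samples >= 1")
    if (is.null(seed))
      stop("random mode requires an explicit seed for reproducibility")
    n_total <- n_samples
  }
  structure(list(mode = mode, varied_names = VARIED_NAMES,
                 points_per_axis = if (mode == "grid") points_per_axis else NULL,
                 n_samples = if (mode == "random") n_samples else NULL,
                 lo = lo, hi = hi, seed = seed, fixed = fixed,
                 n_total = n_total, max_points = max_points),
            class = "sweep_design")
}

#' @export
print.sweep_design <- function(x, ...) {
  if (x$mode == "grid")
    cat(sprintf("Grid sweep design: %d points/axis on [%g, %g]^4 = %s sets\n",
                x$points_per_axis, x$lo, x$hi,
                format(x$n_total, big.mark = ",")))
  else
    cat(sprintf("Random sweep design: %d iid uniform draws on [%g, %g]^4 (seed %d)\n",
                x$n_samples, x$lo, x$hi, x$seed))
  invisible(x)
}

#' Generate the parameter ensemble of a design
#'
#' Materialises the varied-parameter combinations of a [sweep_design()]
#' as a numeric matrix with columns `rho_S`, `delta_S`, `rho_A`,
#' `delta_A`. Grid mode enumerates combinations in deterministic
#' lexicographic order with `rho_S` varying fastest and `delta_A`
#' slowest; random mode is reproducible from the design seed. Every row,
#' completed with the design's fixed parameters, is a valid parameter
#' set.
#'
#' @param design a [sweep_design()].
#' @param override set `TRUE` to generate designs larger than
#'   `design$max_points` anyway.
#' @return Numeric matrix, one row per parameter set.
#' @examples
#' nrow(generate_params(sweep_design("grid", points_per_axis = 3)))  # 81
#' @export
generate_params <- function(design, override = FALSE) {
  stopifnot(inherits(design, "sweep_design"))
  if (design$n_total > design$max_points && !override)
    stop("design enumerates ", format(design$n_total, big.mark = ","),
         " sets, above the cap of ", format(design$max_points, big.mark = ","),
         "; pass override = TRUE if this is intended")
  if (design$mode == "grid") {
    axis <- seq(design$lo, design$hi, length.out = design$points_per_axis)
    g <- expand.grid(rho_S = axis, delta_S = axis,
                     rho_A = axis, delta_A = axis,
                     KEEP.OUT.ATTRS = FALSE)
    as.matrix(g)
  } else {
    set.seed(design$seed)
    matrix(runif(4L * design$n_samples, design$lo, design$hi),
           ncol = 4L, dimnames = list(NULL, VARIED_NAMES))
  }
}

# Complete row i of a varied-parameter matrix into a full model_params.
complete_params <- function(row, fixed) {
  p <- fixed
  p[VARIED_NAMES] <- as.list(row[VARIED_NAMES])
  p
}

#' Dump a design to a data.frame / CSV
#'
#' One row per parameter set, including the fixed parameters, suitable
#' for `write.csv()` and external use.
#'
#' @inheritParams generate_params
#' @param file optional path; when given, the table is also written as CSV.
#' @return The data.frame, invisibly when `file` is given.
#' @export
design_table <- function(design, file = NULL, override = FALSE) {
  varied <- as.data.frame(generate_params(design, override))
  fixedcols <- design$fixed[setdiff(PARAM_NAMES, VARIED_NAMES)]
  out <- cbind(varied, as.data.frame(fixedcols))
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
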