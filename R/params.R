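#' @useDynLib hscniche
#' @importFrom stats runif uniroot setNames
#' @importFrom utils head
"_PACKAGE"

# Canonical state ordering used everywhere: vectors, matrices, CSV columns.
STATE_NAMES <- c("S", "A", "D", "L", "T")

PARAM_NAMES <- c("rho_S", "rho_A", "rho_L",
                 "delta_S", "delta_A", "delta_L",
                 "mu_D", "mu_T", "K1", "K2")

#' Model parameters
#'
#' Construct and validate the ten parameters defining one instance of the
#' niche-competition system: proliferation rates `rho_S`, `rho_A`, `rho_L`
#' (1/time), differentiation rates `delta_S` (S to A), `delta_A` (A to D),
#' `delta_L` (L to T), migration/clearance rates `mu_D`, `mu_T` of the
#' terminally differentiated populations, and the niche carrying capacities
#' `K1` (stem-cell niche) and `K2` (progenitor/leukaemia niche).
#'
#' Populations are scaled to the carrying capacities, so the defaults set
#' `K1 = K2 = 1`. The default rate values are the reference parameter set
#' used throughout the package examples: leukaemia and clearance rates
#' `rho_L = 0.27`, `delta_L = 0.2`, `mu_D = 0.275`, `mu_T = 0.3` (leukaemia
#' cells slightly shorter-lived, compensated by a proliferation rate above
#' their differentiation rate), and healthy-lineage rates
#' `(rho_S, rho_A, delta_S, delta_A) = (0.5, 0.43, 0.14, 0.44)`.
#'
#' @param rho_S,rho_A,rho_L proliferation rates (1/time), strictly positive.
#' @param delta_S,delta_A,delta_L differentiation rates (1/time), strictly
#'   positive.
#' @param mu_D,mu_T migration rates of differentiated cells into the blood
#'   (1/time), strictly positive.
#' @param K1,K2 carrying capacities of the two niches (scaled population
#'   units), strictly positive.
#'
#' @return An object of class `model_params`: a named list with the ten
#'   fields above.
#' @examples
#' p <- model_params()
#' p$rho_S
#' model_params(rho_S = 0.3, delta_S = 0.25)
#' @export
model_params <- function(rho_S = 0.5, rho_A = 0.43, rho_L = 0.27,
                         delta_S = 0.14, delta_A = 0.44, delta_L = 0.2,
                         mu_D = 0.275, mu_T = 0.3, K1 = 1, K2 = 1) {
  p <- list(rho_S = rho_S, rho_A = rho_A, rho_L = rho_L,
            delta_S = delta_S, delta_A = delta_A, delta_L = delta_L,
            mu_D = mu_D, mu_T = mu_T, K1 = K1, K2 = K2)
  validate_params(p)
  structure(p, class = "model_params")
}

#' Validate a parameter set
#'
#' Checks that all ten fields are present, finite, numeric scalars and
#' strictly positive. The error message names the offending field.
#'
#' @param p a `model_params` object or named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Niche-competition model parameters (1/time; K in scaled units):\n")
  v <- unlist(x[PARAM_NAMES])
  print(v)
  invisible(x)
}

#' @export
as.data.frame.model_params <- function(x, ...) {
  as.data.frame(x[PARAM_NAMES], ...)
}

#' Population state vector
#'
#' Build a named state vector in the canonical ordering
#' `(S, A, D, L, T)`: haematopoietic stem cells, healthy progenitors,
#' terminally differentiated blood cells, leukaemia stem cells, and
#' terminally differentiated leukaemia cells (all in scaled units).
#'
#' @param S,A,D,L,T population sizes (scaled units), finite.
#' @return A named numeric vector of length 5.
#' @examples
#' population_state(0.5, 0.2, 0.3, 0.1, 0.05)
#' @export
population_state <- function(S = 0, A = 0, D = 0, L = 0, T = 0) {
  x <- c(S = S, A = A, D = D, L = L, T = T)
  validate_state(x)
  x
}

validate_state <- function(state) {
  if (length(state) != 5L)
    stop("state must have 5 components (S, A, D, L, T)")
  if (is.null(names(state)) || !all(names(state) == STATE_NAMES)) {
    if (!is.null(names(state)) && setequal(names(state), STATE_NAMES))
      state <- state[STATE_NAMES]
    else
      names(state) <- STATE_NAMES
  }
  bad <- !is.finite(state)
  if (any(bad))
    stop("state component '", STATE_NAMES[which(bad)[1L]],
         "' is not finite")
  state
}

#' Niche occupancies of a state
#'
#' The crowding terms that down-regulate proliferation: `Z1 = S` occupies
#' the stem-cell niche, and `Z2 = A + L` the shared progenitor/leukaemia
#' niche.
#'
#' @param state a population state vector (see [population_state()]).
#' @return Named numeric vector `c(Z1, Z2)`.
#' @export
niche_occupancy <- function(state) {
  state <- validate_state(state)
  c(Z1 = unname(state["S"]), Z2 = unname(state["A"] + state["L"]))
}

#' Read/write parameter sets as flat key-value configuration files
#'
#' Parameters are stored as a flat mapping with exactly the field names of
#' [model_params()] (`rho_S` ... `mu_T`, `K1`, `K2`), either as YAML or as
#' JSON. The format is chosen from the file extension (`.yml`/`.yaml` vs
#' `.json`) unless given explicitly.
#'
#' @param p a `model_params` object.
#' @param file path to read from / write to.
#' @param format `"yaml"` or `"json"`; default guesses from the extension.
#' @return `read_params()` returns a `model_params` object;
#'   `write_params()` returns `file` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(model_params(), f)
#' read_params(f)
#' @export
write_params <- function(p, file, format = c("auto", "yaml", "json")) {
  format <- guess_format(match.arg(format), file)
  validate_params(p)
  flat <- lapply(p[PARAM_NAMES], as.numeric)
  if (format == "yaml")
    yaml::write_yaml(flat, file)
  else
    jsonlite::write_json(flat, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file, format = c("auto", "yaml", "json")) {
  format <- guess_format(match.arg(format), file)
  flat <- if (format == "yaml") yaml::read_yaml(file)
          else jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(model_params, as.list(flat[PARAM_NAMES]))
}

guess_format <- function(format, file) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", file, ignore.case = TRUE)) "json" else "yaml"
}

#' Canonical key for a parameter set
#'
#' A deterministic string key identifying a parameter set (used to key
#' exported JSON records of fixed points and critical values).
#'
#' @param p a `model_params` object.
#' @return A single character string.
#' @export
param_key <- function(p) {
  validate_params(p)
  paste(PARAM_NAMES, vapply(p[PARAM_NAMES], function(v)
    format(as.numeric(v), digits = 15, scientific = TRUE), ""),
    sep = "=", collapse = ";")
}
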