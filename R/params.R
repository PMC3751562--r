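#' Model parameters for the lateral-signaling fate-control circuit
#'
#' Constructs the parameter set of the four-factor gene-regulatory model with
#' contact-mediated coupling. Defaults are the published reference
#' parameterization under which acinar (`Y` high), islet (`Z` high) and mixed
#' tissue states coexist.
#'
#' @param a Strength of lateral inhibition (neighbour `X` represses own `X`
#'   production). Dimensionless, `>= 0`.
#' @param b Strength of lateral stabilization (multiplicative positive
#'   feedback between `Y`-expressing neighbours). `>= 0`.
#' @param c Strength of the inhibition of `Y` by `X` and by `Z`. `>= 0`.
#' @param q Strength of the induction of `X` and `Y` by the upstream factor
#'   `A`. `>= 0`.
#' @param r Strength of the inhibition of `A` by `Y` and by `Z`. `>= 0`.
#' @param s Strength of the `Z` auto-activation. `>= 0`.
#' @param n Hill coefficient shared by all regulatory terms; positive
#'   integer.
#' @param eta_x,eta_y Amplitudes of the additive Gaussian white noise on the
#'   `X` and `Y` equations. `>= 0`.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [grn_rhs()], [simulate_tissue()]
#' @examples
#' p <- model_params()          # reference values
#' p2 <- model_params(b = 0)    # stabilization lost
#' @export
model_params <- function(a = 1000, b = 2000, c = 500, q = 1e-4, r = 100,
                         s = 50, n = 3, eta_x = 1e-3, eta_y = 1e-3) {
  p <- list(a = a, b = b, c = c, q = q, r = r, s = s, n = n,
            eta_x = eta_x, eta_y = eta_y)
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  num <- c("a", "b", "c", "q", "r", "s", "eta_x", "eta_y")
  for (k in num) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("parameter '", k, "' must be a single non-negative finite number",
           call. = FALSE)
    }
  }
  n <- p$n
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop("parameter 'n' must be a positive integer", call. = FALSE)
  }
  invisible(p)
}

#' @exportS3Method base::print
print.model_params <- function(x, ...) {
  cat("Model parameters (lateral-signaling fate-control circuit)\n")
  cat(sprintf("  lateral inhibition   a = %g\n", x$a))
  cat(sprintf("  lateral stabilization b = %g\n", x$b))
  cat(sprintf("  X,Z -| Y inhibition  c = %g\n", x$c))
  cat(sprintf("  A -> X,Y induction   q = %g\n", x$q))
  cat(sprintf("  Y,Z -| A inhibition  r = %g\n", x$r))
  cat(sprintf("  Z auto-activation    s = %g\n", x$s))
  cat(sprintf("  Hill coefficient     n = %d\n", as.integer(x$n)))
  cat(sprintf("  noise amplitudes     eta_x = %g, eta_y = %g\n",
              x$eta_x, x$eta_y))
  invisible(x)
}

# Apply a named list of overrides (e.g. from a schedule) to a parameter set.
override_params <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  bad <- setdiff(names(overrides), names(unclass(p)))
  if (length(bad)) {
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(overrides)) p[[k]] <- overrides[[k]]
  validate_params(p)
  p
}

#' Initial per-cell expression states
#'
#' Returns the matrix of per-cell expression levels for one of the two
#' reference initial conditions: `"embryo"` (early progenitor tissue, the
#' upstream inducer `A` homogeneously expressed, `A = 1`, `X = Y = Z = 0`)
#' or `"adult"` (mature acinar tissue, `Y = 1`, `A = X = Z = 0`).
#'
#' @param tissue A [tissue][hex_lattice()] object, or an integer cell count.
#' @param preset `"embryo"` or `"adult"`.
#' @return A numeric matrix with one row per cell and columns
#'   `A`, `X`, `Y`, `Z`.
#' @examples
#' initial_states(triangle3(), "adult")
#' @export
initial_states <- function(tissue, preset = c("embryo", "adult")) {
  preset <- match.arg(preset)
  n <- if (is.numeric(tissue)) as.integer(tissue) else tissue$n_cells
  s <- matrix(0, nrow = n, ncol = 4,
              dimnames = list(NULL, c("A", "X", "Y", "Z")))
  if (n == 0L) return(s)
  if (preset == "embryo") s[, "A"] <- 1 else s[, "Y"] <- 1
  s
}

as_state_matrix <- function(states) {
  if (is.null(dim(states))) {
    if (length(states) != 4L)
      stop("a cell state has exactly four components (A, X, Y, Z)",
           call. = FALSE)
    states <- matrix(states, nrow = 1,
                     dimnames = list(NULL, c("A", "X", "Y", "Z")))
  }
  if (ncol(states) != 4L)
    stop("state matrix must have four columns (A, X, Y, Z)", call. = FALSE)
  if (!all(is.finite(states)))
    stop("non-finite expression state", call. = FALSE)
  colnames(states) <- c("A", "X", "Y", "Z")
  states
}
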