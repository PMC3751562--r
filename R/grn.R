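#' Deterministic drift of the per-cell gene-regulatory circuit
#'
#' Evaluates the deterministic right-hand side of the four-factor model for
#' one cell or for a matrix of cells, given the neighbour signals. Per cell,
#' with Hill coefficient `n` and neighbour averages `Xbar`, `Ybar`:
#'
#' \deqn{dA/dt = 1 / (1 + r Y^n + r Z^n) - A}
#' \deqn{dX/dt = q A^n / (q + a \bar{X}^n) - X}
#' \deqn{dY/dt = (q A^n + b (Y \bar{Y})^n) /
#'              (q + b (Y \bar{Y})^n + c X^n + c Z^n) - Y}
#' \deqn{dZ/dt = (X^n + s Z^n) / (1 + s Z^n) - Z}
#'
#' The `a` term implements lateral inhibition (neighbour `X` represses own
#' `X` production irrespective of the cell's own `X`), while the
#' multiplicative `b (Y Ybar)^n` term implements lateral stabilization:
#' it is non-zero only when `Y` is expressed in the cell *and* its
#' neighbours. Stochastic forcing is not applied here; it is the
#' integrator's job (see [heun_maruyama_step()]).
#'
#' @param state Numeric vector `c(A, X, Y, Z)` or an `n_cells x 4` matrix.
#' @param nb Neighbour signal: vector `c(Xbar, Ybar)` or an `n_cells x 2`
#'   matrix (see [neighbor_signals()]). Use `c(0, 0)` for an isolated cell.
#' @param params A [model_params()] object.
#' @return Drift with the same shape as `state`.
#' @examples
#' grn_rhs(c(0, 0, 0, 0), c(0, 0), model_params())   # c(1, 0, 0, 0)
#' @export
grn_rhs <- function(state, nb, params) {
  vec <- is.null(dim(state))
  state <- as_state_matrix(state)
  if (is.null(dim(nb))) nb <- matrix(nb, nrow = nrow(state), ncol = 2,
                                     byrow = TRUE)
  if (!all(is.finite(nb)) || any(nb < 0))
    stop("neighbour signals must be finite and non-negative", call. = FALSE)
  if (nrow(nb) != nrow(state))
    stop("states and neighbour signals disagree in cell count", call. = FALSE)
  d <- drift_matrix(state, nb[, 1], nb[, 2], params)
  if (vec) setNames(as.vector(d), c("A", "X", "Y", "Z")) else d
}

# Vectorized drift over cells; xb, yb are per-cell neighbour averages.
drift_matrix <- function(states, xb, yb, p) {
  A <- states[, 1]; X <- states[, 2]; Y <- states[, 3]; Z <- states[, 4]
  n <- p$n
  An <- A^n; Xn <- X^n; Yn_pair <- (Y * yb)^n; Zn <- Z^n
  stab <- p$b * Yn_pair
  cbind(A = 1 / (1 + p$r * Y^n + p$r * Zn) - A,
        X = p$q * An / (p$q + p$a * xb^n) - X,
        Y = (p$q * An + stab) / (p$q + stab + p$c * Xn + p$c * Zn) - Y,
        Z = (Xn + p$s * Zn) / (1 + p$s * Zn) - Z)
}

#' Classify cell states into fates
#'
#' Maps expression states to the three fate labels used throughout:
#' `islet` if the terminal endocrine marker `Z` exceeds its threshold
#' (islet takes precedence over acinar in the transient case where both
#' markers are high), `acinar` if the exocrine marker `Y` exceeds its
#' threshold and `Z` does not, and `progenitor` otherwise (the multipotent
#' low-`Y`, low-`Z` state). Steady states cluster near 0 and 1, so any
#' mid-range threshold separates them; 0.5 is the symmetric default.
#'
#' @param states State vector or matrix as in [grn_rhs()].
#' @param y_threshold,z_threshold Classification thresholds in `(0, 1)`.
#' @return A character vector with values `"acinar"`, `"islet"`,
#'   `"progenitor"`, one per cell.
#' @examples
#' classify_fates(c(0, 0, 0.99, 0))   # "acinar"
#' @export
classify_fates <- function(states, y_threshold = 0.5, z_threshold = 0.5) {
  states <- as_state_matrix(states)
  out <- rep("progenitor", nrow(states))
  out[states[, "Y"] > y_threshold] <- "acinar"
  out[states[, "Z"] > z_threshold] <- "islet"
  out
}

#' Reference parameter set
#'
#' The published reference values of all rate, coupling and noise constants:
#' `a = 1000`, `b = 2000`, `c = 500`, `q = 1e-4`, `r = 100`, `s = 50`,
#' `n = 3`, `eta_x = eta_y = 1e-3`. Identical to calling [model_params()]
#' with no arguments; provided as an explicitly named entry point.
#'
#' @return A [model_params()] object.
#' @export
table1_defaults <- function() model_params()
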