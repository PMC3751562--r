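#' Drift and analytic Jacobian of the coupled deterministic system
#'
#' The coupled system stacks the four variables of every cell into one
#' vector (cell-major order: `A1, X1, Y1, Z1, A2, ...`). The Jacobian is
#' assembled from the closed-form partial derivatives of the per-cell
#' kinetics, including the coupling blocks that enter through the
#' neighbour averages `Xbar` and `Ybar`.
#'
#' @param x Stacked state vector of length `4 * n_cells`.
#' @param tissue A `tissue` object.
#' @param params A [model_params()] object.
#' @return `coupled_drift()` the stacked drift vector; `coupled_jacobian()`
#'   the dense `4n x 4n` Jacobian matrix.
#' @keywords internal
#' @export
coupled_drift <- function(x, tissue, params) {
  s <- matrix(x, ncol = 4, byrow = TRUE)
  sig <- as.matrix(tissue$adjacency %*% s[, 2:3, drop = FALSE]) /
    tissue$coordination
  as.vector(t(drift_matrix(s, sig[, 1], sig[, 2], params)))
}

#' @rdname coupled_drift
#' @export
coupled_jacobian <- function(x, tissue, params) {
  p <- params
  n <- p$n
  nc <- tissue$n_cells
  s <- matrix(x, ncol = 4, byrow = TRUE)
  A <- s[, 1]; X <- s[, 2]; Y <- s[, 3]; Z <- s[, 4]
  m <- tissue$coordination
  sig <- as.matrix(tissue$adjacency %*% s[, 2:3, drop = FALSE]) / m
  xb <- sig[, 1]; yb <- sig[, 2]

  J <- matrix(0, 4 * nc, 4 * nc)
  ia <- function(i) 4 * (i - 1) + 1
  hA <- 1 / (1 + p$r * Y^n + p$r * Z^n)
  DX <- p$q + p$a * xb^n
  P <- p$b * (Y * yb)^n
  NY <- p$q * A^n + P
  DY <- p$q + P + p$c * X^n + p$c * Z^n
  DZ <- 1 + p$s * Z^n

  for (i in seq_len(nc)) {
    r0 <- ia(i)
    # A equation
    J[r0, r0] <- -1
    J[r0, r0 + 2] <- -p$r * n * Y[i]^(n - 1) * hA[i]^2
    J[r0, r0 + 3] <- -p$r * n * Z[i]^(n - 1) * hA[i]^2
    # X equation
    J[r0 + 1, r0] <- p$q * n * A[i]^(n - 1) / DX[i]
    J[r0 + 1, r0 + 1] <- -1
    # Y equation
    pyi <- p$b * n * Y[i]^(n - 1) * yb[i]^n
    J[r0 + 2, r0] <- p$q * n * A[i]^(n - 1) / DY[i]
    J[r0 + 2, r0 + 1] <- -NY[i] * p$c * n * X[i]^(n - 1) / DY[i]^2
    J[r0 + 2, r0 + 2] <- pyi * (DY[i] - NY[i]) / DY[i]^2 - 1
    J[r0 + 2, r0 + 3] <- -NY[i] * p$c * n * Z[i]^(n - 1) / DY[i]^2
    # Z equation
    J[r0 + 3, r0 + 1] <- n * X[i]^(n - 1) / DZ[i]
    J[r0 + 3, r0 + 3] <- p$s * n * Z[i]^(n - 1) * (1 - X[i]^n) /
      DZ[i]^2 - 1
    # coupling through the neighbour averages
    for (j in tissue$neighbors[[i]]) {
      c0 <- ia(j)
      J[r0 + 1, c0 + 1] <- J[r0 + 1, c0 + 1] -
        p$q * A[i]^n * p$a * n * xb[i]^(n - 1) / (m * DX[i]^2)
      pyj <- p$b * n * Y[i]^n * yb[i]^(n - 1) / m
      J[r0 + 2, c0 + 2] <- J[r0 + 2, c0 + 2] +
        pyj * (DY[i] - NY[i]) / DY[i]^2
    }
  }
  J
}

#' Locate a steady state of the coupled deterministic system
#'
#' Newton iteration on the stacked drift with the analytic Jacobian
#' (coupling included). Stability is classified from the eigenvalues of the
#' Jacobian at the converged point; because the symmetric tissues force
#' eigenvalue multiplicities, the call compares real parts against a small
#' tolerance rather than relying on eigenvalue ordering. Non-convergence is
#' reported in the `converged` flag, not as an error: the fold bisection
#' relies on probing parameter values where no nearby solution exists.
#'
#' @param guess Initial `n_cells x 4` state matrix (see
#'   [steady_state_guess()]) or stacked vector.
#' @param tissue A `tissue` object (intended for small systems: the minimal
#'   three-cell tissue or a small explicit graph).
#' @param params A [model_params()] object.
#' @param tol Residual max-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @param eig_tol Real-part tolerance for stability calls.
#' @return A `fixed_point` object: `states`, `residual_norm`, `converged`,
#'   `jacobian`, `eigenvalues`, `stable`, and `directional` (per-variable
#'   stability, see [directional_stability()]).
#' @examples
#' fp <- find_fixed_point(steady_state_guess(triangle3(), "acinar"),
#'                        triangle3(), model_params())
#' sum(fp$states[, "Y"])  # ~3
#' @export
find_fixed_point <- function(guess, tissue, params, tol = 1e-10,
                             max_iter = 100, eig_tol = 1e-8) {
  x <- if (is.matrix(guess)) as.vector(t(guess)) else as.numeric(guess)
  if (length(x) != 4 * tissue$n_cells)
    stop("guess has the wrong dimension", call. = FALSE)
  if (!all(is.finite(x)) || any(x < 0))
    stop("guess must be finite and non-negative", call. = FALSE)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- coupled_drift(x, tissue, params)
    if (max(abs(f)) < tol) { converged <- TRUE; break }
    J <- coupled_jacobian(x, tissue, params)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx) || !all(is.finite(dx))) break
    x <- x + dx
  }
  res <- max(abs(coupled_drift(x, tissue, params)))
  converged <- converged && res < tol && all(is.finite(x))
  J <- coupled_jacobian(x, tissue, params)
  eig <- eigen(J)
  states <- matrix(x, ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, c("A", "X", "Y", "Z")))
  fp <- structure(list(states = states, residual_norm = res,
                       converged = converged, jacobian = J,
                       eigenvalues = eig$values,
                       eigenvectors = eig$vectors,
                       stable = converged &&
                         max(Re(eig$values)) < -eig_tol,
                       params = params, tissue = tissue,
                       eig_tol = eig_tol),
                  class = "fixed_point")
  fp$directional <- directional_stability(fp)
  fp
}

#' @exportS3Method base::print
print.fixed_point <- function(x, ...) {
  cat(sprintf(
    "Fixed point (%sconverged): residual %.2e, sum(Y) = %.4f, %s\n",
    if (x$converged) "" else "NOT ", x$residual_norm,
    sum(x$states[, "Y"]), if (x$stable) "stable" else "unstable"))
  print(round(x$states, 4))
  cat("directional:",
      paste(names(x$directional), x$directional, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-variable (directional) stability of a fixed point
#'
#' Operationalizes statements like "stable against perturbations in `Y` but
#' unstable against perturbations in `X`": each growing eigenvalue of the
#' coupled Jacobian is assigned to the variable whose perturbation excites
#' it most strongly, i.e. the variable carrying the largest absolute
#' loading of the corresponding *left* eigenvector (summed over cells). A
#' variable is unstable iff some growing mode is assigned to it. The
#' left-eigenvector reading matters: in this circuit the exocrine factor
#' `Y` responds strongly to the endocrine factor `X` (it dominates the
#' right eigenvector of the lateral-inhibition mode) even though only `X`
#' perturbations excite that mode. For ill-conditioned eigenbases the
#' assignment is flagged and [probe_stability()] offers an independent
#' perturbation check.
#'
#' @param fp A `fixed_point`.
#' @return Named character vector over `A`, `X`, `Y`, `Z` with values
#'   `"stable"`/`"unstable"`; attribute `ill_conditioned` is `TRUE` when
#'   the eigenbasis is close to defective.
#' @export
directional_stability <- function(fp) {
  vars <- c("A", "X", "Y", "Z")
  out <- setNames(rep("stable", 4), vars)
  grow <- which(Re(fp$eigenvalues) > fp$eig_tol)
  ill <- FALSE
  if (length(grow)) {
    W <- tryCatch(solve(fp$eigenvectors), error = function(e) NULL)
    one_norm <- function(M) max(colSums(Mod(M)))
    ill <- is.null(W) ||
      one_norm(fp$eigenvectors) * one_norm(W) > 1e10
    for (k in grow) {
      per_var <- if (!is.null(W)) rowSums(matrix(abs(W[k, ]), nrow = 4))
        else rowSums(matrix(abs(fp$eigenvectors[, k]), nrow = 4))
      out[vars[which.max(per_var)]] <- "unstable"
    }
  }
  attr(out, "ill_conditioned") <- ill
  out
}

#' Perturbation probe of directional stability
#'
#' Independent of the eigen-decomposition: integrates the deterministic
#' system from the fixed point with a single cell displaced by `+delta` in
#' one variable and tests growth over a short horizon. The horizon is
#' deliberately short: near an unstable point, *any* asymmetric
#' perturbation eventually leaks into the growing mode through the
#' regulatory couplings, so the directional statement ("perturbations in
#' this variable destabilize the state") is about direct excitation, which
#' the first few time units separate cleanly.
#'
#' @param fp A converged `fixed_point`.
#' @param variable One of `"A"`, `"X"`, `"Y"`, `"Z"`.
#' @param delta Perturbation size.
#' @param t_end Probe horizon.
#' @return `TRUE` (stable: the displacement has not grown beyond
#'   `10 * delta` by the end of the horizon) or `FALSE`.
#' @export
probe_stability <- function(fp, variable = c("A", "X", "Y", "Z"),
                            delta = 1e-3, t_end = 10) {
  variable <- match.arg(variable)
  init <- fp$states
  init[1, variable] <- init[1, variable] + delta
  cfg <- sim_config(t_end = t_end, noise_on = FALSE, seed = NULL,
                    record_every = 1e9)
  tr <- simulate_tissue(fp$tissue, init, fp$params, cfg)
  max(abs(final_states(tr) - fp$states)) < 10 * delta
}

#' Guess states for the named steady-state branches
#'
#' @param tissue A `tissue` object.
#' @param which Branch name: `"acinar"` (all cells `Y = 1`), `"islet"`
#'   (all cells `Z ~ 1`), `"mixed"` (all but one cell acinar, one islet),
#'   `"progenitor"` (upstream factor high, fate markers low).
#' @return An `n_cells x 4` guess matrix for [find_fixed_point()].
#' @export
steady_state_guess <- function(tissue,
                               which = c("acinar", "islet", "mixed",
                                         "progenitor")) {
  which <- match.arg(which)
  n <- tissue$n_cells
  per <- switch(which,
    acinar = c(0.01, 0, 1, 0),
    islet = c(0, 0, 0, 0.98),
    progenitor = c(1, 0.02, 0.03, 0),
    mixed = c(0.01, 0, 1, 0))
  g <- matrix(per, nrow = n, ncol = 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "X", "Y", "Z")))
  if (which == "mixed") {
    if (n < 3) stop("the mixed state needs at least 3 cells", call. = FALSE)
    g[n, ] <- c(0, 0, 0, 0.98)
  }
  g
}

#' Continue a steady-state branch in one parameter
#'
#' Natural-parameter continuation with multiplicative steps and adaptive
#' step halving on Newton failure: from a converged start, the parameter is
#' moved by a factor, the solution re-converged from the previous point,
#' and a point accepted only when Newton converges to a branch-continuous
#' solution (within `cont_tol` in max-norm of the previous point). The
#' branch terminates at a fold (step factor exhausted), at the parameter
#' boundary, or at the step cap. Every accepted point is re-classified for
#' stability and its summed `Y` recorded for diagram plotting.
#'
#' @param start A converged `fixed_point` at `params`.
#' @param tissue,params As in [find_fixed_point()].
#' @param parameter Parameter to vary (`"a"` or `"b"`).
#' @param p_end Parameter value at which continuation stops
#'   (the boundary).
#' @param step_factor Multiplicative step (applied towards `p_end`),
#'   in `(0, 1)`.
#' @param cont_tol Branch-continuity bound (max-norm between consecutive
#'   accepted states).
#' @param max_steps Cap on accepted points.
#' @param tol Newton residual tolerance.
#' @return A `branch` object: `points` (data frame with `param`, `sumY`,
#'   `max_re`, `stable`), the full `states` per point, `parameter` and
#'   `terminus` (one of `"fold"`, `"boundary"`, `"max_steps"`).
#' @export
continue_branch <- function(start, tissue, params, parameter, p_end,
                            step_factor = 0.8, cont_tol = 0.25,
                            max_steps = 500, tol = 1e-10) {
  if (!start$converged) stop("start fixed point is not converged",
                             call. = FALSE)
  stopifnot(parameter %in% c("a", "b"))
  p_cur <- params[[parameter]]
  down <- p_end < p_cur
  if (p_end <= 0 && down) p_end <- 1e-8  # multiplicative steps need > 0
  pts <- data.frame(param = p_cur, sumY = sum(start$states[, "Y"]),
                    max_re = max(Re(start$eigenvalues)),
                    stable = start$stable)
  states <- list(start$states)
  seed <- start$states
  fac <- step_factor
  terminus <- "max_steps"
  for (k in seq_len(max_steps)) {
    p_next <- if (down) max(p_cur * fac, p_end) else min(p_cur / fac, p_end)
    pp <- override_params(params, setNames(list(p_next), parameter))
    fp <- find_fixed_point(seed, tissue, pp, tol = tol)
    ok <- fp$converged && max(abs(fp$states - seed)) < cont_tol
    if (ok) {
      p_cur <- p_next
      seed <- fp$states
      pts <- rbind(pts, data.frame(param = p_cur,
                                   sumY = sum(fp$states[, "Y"]),
                                   max_re = max(Re(fp$eigenvalues)),
                                   stable = fp$stable))
      states[[length(states) + 1L]] <- fp$states
      fac <- step_factor  # reset after success
      if (p_cur == p_end) { terminus <- "boundary"; break }
    } else {
      fac <- sqrt(fac)   # halve the log-step
      if (1 - fac < 1e-7) { terminus <- "fold"; break }
    }
  }
  structure(list(parameter = parameter, points = pts, states = states,
                 terminus = terminus),
            class = "branch")
}

#' @exportS3Method base::print
print.branch <- function(x, ...) {
  rng <- range(x$points$param)
  cat(sprintf(
    "Branch in %s over [%g, %g], %d points, terminus: %s\n",
    x$parameter, rng[1], rng[2], nrow(x$points), x$terminus))
  invisible(x)
}

#' Write branch points as CSV
#'
#' Columns: parameter value, summed `Y`, largest eigenvalue real part,
#' stability flag, and the per-variable directional flags of the last
#' solved point are not stored per row (recompute via
#' [find_fixed_point()] where needed).
#' @param branch A `branch`.
#' @param path Output file.
#' @export
write_branch <- function(branch, path) {
  df <- branch$points
  names(df)[1] <- branch$parameter
  write_csv_full(df, path)
}

#' Locate a fold (existence boundary) of a branch by bisection
#'
#' Walks the branch from the high end of the bracket downwards by
#' continuation, then bisects on the question "does Newton, seeded from the
#' nearest accepted branch point, converge to a branch-continuous fixed
#' point at this parameter value?". The bracket is refined to width `tol`
#' and the midpoint of the final bracket returned. Errors if the branch
#' exists on both ends of the bracket (no existence boundary) or already
#' fails at the high end.
#'
#' @inheritParams continue_branch
#' @param start A converged `fixed_point` on the branch, at a parameter
#'   value at or above the high end of the bracket.
#' @param bracket Length-2 numeric: the fold is sought inside
#'   `[bracket[1], bracket[2]]`.
#' @param tol Final bracket width.
#' @return List with `value` (midpoint of the final bracket), `bracket`,
#'   and `last_point` (the branch solution nearest the fold).
#' @examples
#' \donttest{
#' tri <- triangle3()
#' p0 <- model_params(b = 0)
#' fp <- find_fixed_point(steady_state_guess(tri, "progenitor"), tri, p0)
#' find_fold(fp, tri, p0, "a", c(1e-4, 1), tol = 1e-5)$value  # ~0.0017
#' }
#' @export
find_fold <- function(start, tissue, params, parameter, bracket,
                      tol = 1e-4, cont_tol = 0.25, step_factor = 0.8) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (!start$converged) stop("start fixed point is not converged",
                             call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  p_cur <- params[[parameter]]
  seed <- start$states

  solve_at <- function(p_val, seed) {
    pp <- override_params(params, setNames(list(p_val), parameter))
    fp <- find_fixed_point(seed, tissue, pp)
    list(ok = fp$converged && max(abs(fp$states - seed)) < cont_tol,
         fp = fp)
  }

  # walk down to the high end of the bracket
  walk_targets <- c()
  if (p_cur > hi) {
    walk_targets <- 10^seq(log10(p_cur), log10(hi),
                           by = log10(step_factor))
    walk_targets <- unique(c(walk_targets[-1], hi))
  } else if (p_cur < hi) {
    stop("start fixed point lies below the bracket's high end",
         call. = FALSE)
  }
  for (p_val in walk_targets) {
    r <- solve_at(p_val, seed)
    if (!r$ok) stop("branch lost before reaching the bracket's high end",
                    call. = FALSE)
    seed <- r$fp$states
  }
  r <- solve_at(hi, seed)
  if (!r$ok) stop("branch does not exist at the high end of the bracket",
                  call. = FALSE)
  seed <- r$fp$states
  last_fp <- r$fp

  # walk down towards lo with geometric steps until the branch is lost
  exists_at_lo <- TRUE
  p_val <- hi
  while (p_val > lo) {
    p_try <- max(p_val * step_factor, lo)
    rr <- solve_at(p_try, seed)
    if (!rr$ok) { exists_at_lo <- FALSE; hi <- p_val; lo <- p_try; break }
    seed <- rr$fp$states; last_fp <- rr$fp; p_val <- p_try
  }
  if (exists_at_lo)
    stop("no existence boundary in bracket: branch persists at the low end",
         call. = FALSE)

  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    rr <- solve_at(mid, seed)
    if (rr$ok) { hi <- mid; seed <- rr$fp$states; last_fp <- rr$fp }
    else lo <- mid
  }
  list(value = (lo + hi) / 2, bracket = c(lo, hi), last_point = last_fp)
}
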