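#' Integration settings
#'
#' @param dt Time step of the Heun-Maruyama scheme (model time is
#'   dimensionless; the reference step is 0.02).
#' @param t_end Final time of the run.
#' @param record_every Sampling stride in steps (states are kept every
#'   `record_every`-th step, plus the initial and final states).
#' @param seed Integer RNG seed; every random draw of the run derives from
#'   it, so equal seeds give bitwise-identical trajectories.
#' @param noise_on Apply the additive noise terms on `X` and `Y`?
#' @param t_pre Burn-in time: integration starts at `t = -t_pre` with the
#'   initial parameters so that scheduled parameter changes can mark
#'   `t = 0`.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation; identical scheme and draw order).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.02, t_end = 100, record_every = 50L,
                       seed = 1L, noise_on = TRUE, t_pre = 0,
                       engine = c("cpp", "r")) {
  stopifnot(dt > 0, t_end >= 0, record_every >= 1, t_pre >= 0)
  structure(list(dt = dt, t_end = t_end,
                 record_every = as.integer(record_every), seed = seed,
                 noise_on = isTRUE(noise_on), t_pre = t_pre,
                 engine = match.arg(engine)),
            class = "sim_config")
}

# One generic Heun-Maruyama update: predictor with full drift + additive
# increment g_dw, corrector averaging the drifts, the SAME increment in both
# stages, states clamped at `lower` after each stage.
hm_step_generic <- function(f, y, dt, g_dw, lower = 0) {
  f1 <- f(y)
  yp <- pmax(y + f1 * dt + g_dw, lower)
  y2 <- pmax(y + 0.5 * (f1 + f(yp)) * dt + g_dw, lower)
  y2
}

#' One Heun-Maruyama step of the coupled tissue system
#'
#' Advances all cells by one time step `dt`. The scheme is the standard
#' predictor-corrector (Heun) treatment of the additive-noise SDE: the
#' predictor takes a full Euler-Maruyama step, neighbour signals are
#' recomputed from the predictor state for the corrector drift, and the
#' same Wiener increment enters both stages (for additive noise the Ito and
#' Stratonovich readings coincide, so the corrector is unambiguous). Noise
#' enters only the `X` and `Y` components, scaled as
#' `eta * sqrt(dt) * N(0, 1)`. All components are clamped at 0 after the
#' update: expression levels are non-negative, and with the reference noise
#' amplitudes clamping is a rare guard rather than a driver of the
#' dynamics.
#'
#' @param states `n_cells x 4` state matrix.
#' @param tissue A `tissue` object.
#' @param params A [model_params()] object.
#' @param dt Time step.
#' @param noise Optional `n_cells x 2` matrix of standard normal draws (for
#'   `X` and `Y`); `NULL` means a deterministic (noise-free) step.
#' @return The updated state matrix.
#' @export
heun_maruyama_step <- function(states, tissue, params, dt = 0.02,
                               noise = NULL) {
  states <- as_state_matrix(states)
  n <- nrow(states)
  g_dw <- matrix(0, n, 4)
  if (!is.null(noise)) {
    noise <- as.matrix(noise)
    stopifnot(nrow(noise) == n, ncol(noise) == 2)
    g_dw[, 2] <- params$eta_x * sqrt(dt) * noise[, 1]
    g_dw[, 3] <- params$eta_y * sqrt(dt) * noise[, 2]
  }
  f <- function(s) {
    sig <- neighbor_signals(tissue, s)
    drift_matrix(s, sig[, 1], sig[, 2], params)
  }
  out <- hm_step_generic(f, states, dt, g_dw, lower = 0)
  if (!all(is.finite(out)))
    stop("non-finite state after step in cell(s) ",
         paste(which(!apply(is.finite(out), 1, all)), collapse = ", "),
         call. = FALSE)
  dimnames(out) <- list(NULL, c("A", "X", "Y", "Z"))
  out
}

# CSR-style adjacency arrays for the compiled kernel (0-based).
tissue_csr <- function(tissue) {
  deg <- lengths(tissue$neighbors)
  list(idx = as.integer(unlist(tissue$neighbors, use.names = FALSE) - 1L),
       ptr = as.integer(c(0L, cumsum(deg))))
}

#' Simulate the coupled stochastic tissue system
#'
#' Integrates the lateral-signaling model on a tissue with the
#' Heun-Maruyama scheme (see [heun_maruyama_step()] for the stepping
#' contract). Integration starts at `t = -t_pre` (burn-in with the initial
#' parameters) and runs to `t_end`; a `schedule` of parameter overrides is
#' applied at the given times (snapped to the step grid), which is how
#' protocols such as "lateral stabilization lost at t = 0" are expressed.
#' Random draws are taken in a fixed order (per step: one standard-normal
#' vector for all cells' `X`, then one for `Y`), so runs are reproducible
#' for a given seed.
#'
#' @param tissue A `tissue` object.
#' @param init `n_cells x 4` initial state matrix (see [initial_states()]).
#' @param params A [model_params()] object.
#' @param config A [sim_config()] object.
#' @param schedule Optional data frame with columns `time`, `parameter`,
#'   `value`; rows beyond `t_end` are dropped with a warning.
#' @return A `trajectory` object: `times`, a `n_cells x 4 x length(times)`
#'   state array, the final state matrix, the applied `events`, and the
#'   fraction of clamped component updates.
#' @examples
#' tis <- triangle3()
#' cfg <- sim_config(t_end = 50, noise_on = FALSE)
#' tr <- simulate_tissue(tis, initial_states(tis, "adult"),
#'                       model_params(), cfg)
#' sum(final_states(tr)[, "Y"])  # ~3: the all-acinar state is stable
#' @export
simulate_tissue <- function(tissue, init, params, config = sim_config(),
                            schedule = NULL) {
  n <- tissue$n_cells
  init <- as_state_matrix(init)
  if (nrow(init) != n)
    stop("init must have one row per occupied cell", call. = FALSE)
  if (any(init < 0)) stop("initial states must be non-negative",
                          call. = FALSE)
  dt <- config$dt
  t0 <- if (config$t_pre > 0) -config$t_pre else 0
  n_steps <- as.integer(round((config$t_end - t0) / dt))

  # resolve schedule into step-aligned parameter switches
  switches <- data.frame(step = integer(0), parameter = character(0),
                         value = numeric(0))
  if (!is.null(schedule) && nrow(schedule) > 0) {
    stopifnot(all(c("time", "parameter", "value") %in% names(schedule)))
    if (is.unsorted(schedule$time))
      stop("schedule times must be sorted", call. = FALSE)
    bad <- setdiff(schedule$parameter, names(unclass(params)))
    if (length(bad))
      stop("unknown parameter(s) in schedule: ",
           paste(bad, collapse = ", "), call. = FALSE)
    late <- schedule$time > config$t_end
    if (any(late)) {
      warning("dropping ", sum(late), " schedule entr",
              if (sum(late) == 1) "y" else "ies", " beyond t_end")
      schedule <- schedule[!late, , drop = FALSE]
    }
    if (nrow(schedule) > 0)
      switches <- data.frame(
        step = as.integer(round((schedule$time - t0) / dt)),
        parameter = as.character(schedule$parameter),
        value = schedule$value)
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  csr <- tissue_csr(tissue)
  bounds <- sort(unique(c(0L, switches$step, n_steps)))
  bounds <- bounds[bounds >= 0L & bounds <= n_steps]

  S <- init
  times <- t0
  samples <- list(init)
  events <- data.frame(time = numeric(0), parameter = character(0),
                       old = numeric(0), new = numeric(0))
  p <- params
  clamped <- 0; updates <- 0; clamp_max <- 0
  for (seg in seq_len(length(bounds) - 1L)) {
    from <- bounds[seg]; to <- bounds[seg + 1L]
    sw <- switches[switches$step == from, , drop = FALSE]
    for (k in seq_len(nrow(sw))) {
      events <- rbind(events, data.frame(
        time = t0 + from * dt, parameter = sw$parameter[k],
        old = p[[sw$parameter[k]]], new = sw$value[k]))
      p <- override_params(p, setNames(list(sw$value[k]), sw$parameter[k]))
    }
    if (to == from) next
    seg_len <- to - from
    if (config$engine == "cpp") {
      res <- .hm_segment_cpp(S, csr$idx, csr$ptr, tissue$coordination,
                             param_vector(p), dt, seg_len,
                             config$record_every, from, config$noise_on, 0)
      S <- res$final
      if (length(res$rec_steps)) {
        arr <- array(res$samples, dim = c(n, 4, length(res$rec_steps)))
        for (m in seq_along(res$rec_steps)) {
          times <- c(times, t0 + res$rec_steps[m] * dt)
          samples[[length(samples) + 1L]] <- arr[, , m, drop = TRUE]
        }
      }
      clamped <- clamped + res$n_clamped
      clamp_max <- max(clamp_max, res$max_clamp)
      updates <- updates + res$n_updates
    } else {
      for (k in seq_len(seg_len)) {
        noise <- if (config$noise_on && n > 0)
          cbind(rnorm(n), rnorm(n)) else NULL
        S <- heun_maruyama_step(S, tissue, p, dt, noise)
        gk <- from + k
        if (gk %% config$record_every == 0L) {
          times <- c(times, t0 + gk * dt)
          samples[[length(samples) + 1L]] <- S
        }
        updates <- updates + 4 * n
      }
    }
  }
  dimnames(S) <- list(NULL, c("A", "X", "Y", "Z"))
  arr <- array(unlist(samples, use.names = FALSE),
               dim = c(n, 4, length(samples)),
               dimnames = list(NULL, c("A", "X", "Y", "Z"), NULL))
  structure(list(times = times, states = arr, final = S, events = events,
                 tissue = tissue, params = params, config = config,
                 clamped_fraction = if (updates > 0) clamped / updates
                                    else 0,
                 clamp_max = clamp_max),
            class = "trajectory")
}

param_vector <- function(p)
  c(p$a, p$b, p$c, p$q, p$r, p$s, p$n, p$eta_x, p$eta_y)

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d cells, t in [%g, %g], %d samples, %d event(s)\n",
    dim(x$states)[1], x$times[1], x$times[length(x$times)],
    length(x$times), nrow(x$events)))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj A `trajectory`.
#' @return The `n_cells x 4` state matrix at the end of the run.
#' @export
final_states <- function(traj) traj$final

#' Population-average expression over time
#'
#' @param traj A `trajectory`.
#' @return A data frame with columns `t`, `A`, `X`, `Y`, `Z`: the
#'   arithmetic mean over occupied cells at each recorded time.
#' @export
population_average <- function(traj) {
  n <- dim(traj$states)[1]
  if (n == 0L) stop("trajectory has no cells", call. = FALSE)
  avg <- t(apply(traj$states, c(2, 3), mean))
  data.frame(t = traj$times, avg)
}

#' Fate composition over time
#'
#' @param traj A `trajectory`.
#' @inheritParams classify_fates
#' @return Data frame with columns `t`, `acinar`, `islet`, `progenitor`
#'   (fractions of occupied cells).
#' @export
fate_fractions <- function(traj, y_threshold = 0.5, z_threshold = 0.5) {
  n <- dim(traj$states)[1]
  if (n == 0L) stop("trajectory has no cells", call. = FALSE)
  f <- vapply(seq_along(traj$times), function(m) {
    lab <- classify_fates(traj$states[, , m, drop = TRUE],
                          y_threshold, z_threshold)
    c(acinar = mean(lab == "acinar"), islet = mean(lab == "islet"),
      progenitor = mean(lab == "progenitor"))
  }, numeric(3))
  data.frame(t = traj$times, t(f))
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  n <- dim(x$states)[1]
  m <- length(x$times)
  tis <- x$tissue
  df <- data.frame(
    t = rep(x$times, each = n),
    cell_id = rep(seq_len(n), times = m),
    row = rep(tis$cell_row, times = m),
    col = rep(tis$cell_col, times = m),
    A = as.vector(x$states[, 1, ]), X = as.vector(x$states[, 2, ]),
    Y = as.vector(x$states[, 3, ]), Z = as.vector(x$states[, 4, ]))
  df$fate <- classify_fates(as.matrix(df[, c("A", "X", "Y", "Z")]))
  df
}

#' Write a trajectory as tidy CSV / its events as JSON
#'
#' Numeric columns are written with 17 significant digits so a read-back
#' reproduces the doubles exactly.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_csv_full(as.data.frame(traj), path)
}

#' @rdname write_trajectory
#' @export
write_events <- function(traj, path) {
  jsonlite::write_json(traj$events, path, dataframe = "rows", digits = NA)
  invisible(path)
}

# CSV writer preserving full double precision (repr-style %.17g).
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
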