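# Shared fixtures and pattern statistics used across test files.

tri <- triangle3()
p_ref <- model_params()

# Random valid (state, signal) draws inside the unit box.
random_states <- function(n, seed) {
  set.seed(seed)
  list(states = matrix(runif(4 * n), n, 4,
                       dimnames = list(NULL, c("A", "X", "Y", "Z"))),
       nb = matrix(runif(2 * n), n, 2))
}

# First sample index at which each cell carries the given fate (NA if never).
commit_times <- function(traj, fate = "acinar") {
  m <- length(traj$times)
  n <- dim(traj$states)[1]
  out <- rep(NA_integer_, n)
  for (k in seq_len(m)) {
    lab <- classify_fates(traj$states[, , k, drop = TRUE])
    newly <- is.na(out) & lab == fate
    out[newly] <- k
  }
  out
}

# Mean absolute commitment-time gap over adjacent committed pairs: fate
# waves make neighbours commit at similar times, so spatial clustering of
# commitment shows up as a small gap relative to a shuffled null.
pair_time_gap <- function(commits, tissue) {
  s <- 0; n <- 0L
  for (i in seq_along(commits)) for (j in tissue$neighbors[[i]]) {
    if (j <= i) next
    if (!is.na(commits[i]) && !is.na(commits[j])) {
      s <- s + abs(commits[i] - commits[j]); n <- n + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  s / n
}

# Fraction of adjacent pairs where both cells carry the given fate.
adjacent_pair_fraction <- function(fates, tissue, fate = "islet") {
  hits <- 0L; tot <- 0L
  for (i in seq_along(fates)) for (j in tissue$neighbors[[i]]) {
    if (j <= i) next
    tot <- tot + 1L
    if (fates[i] == fate && fates[j] == fate) hits <- hits + 1L
  }
  if (tot == 0L) return(NA_real_)
  hits / tot
}

shuffled_null <- function(stat_fn, values, n_shuffles = 200, seed = 99) {
  set.seed(seed)
  vapply(seq_len(n_shuffles),
         function(k) stat_fn(sample(values)), numeric(1))
}
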