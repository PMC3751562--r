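# One development run shared by several expectations below.
dev_run <- run_development(seed = 3)

test_that("development produces scattered islet cells in acinar tissue", {
  fates <- dev_run$final_fates
  expect_true(all(c("acinar", "islet") %in% fates))
  islet_frac <- mean(fates == "islet")
  expect_gt(islet_frac, 0.02)
  expect_lt(islet_frac, 0.4)
  expect_gt(mean(fates == "acinar"), 0.5)
  # nascent islet cells avoid each other (lateral inhibition): adjacent
  # islet-islet pairs are rarer than in a spatially shuffled pattern
  obs <- adjacent_pair_fraction(fates, dev_run$tissue)
  null <- shuffled_null(function(v)
    adjacent_pair_fraction(v, dev_run$tissue), fates)
  expect_lt(obs, mean(null))
})

test_that("development transits a promiscuous co-expression phase", {
  tr <- dev_run$trajectory
  k2 <- which.min(abs(tr$times - 2))
  st <- tr$states[, , k2]
  expect_true(all(st[, "X"] > 0.005 & st[, "X"] < 0.3))
  expect_true(all(st[, "Y"] > 0.005 & st[, "Y"] < 0.3))
  # the pro-endocrine factor is only transiently expressed
  pa <- population_average(tr)
  expect_gt(max(pa$X), 10 * pa$X[nrow(pa)])
  expect_lt(pa$X[nrow(pa)], 0.01)
})

test_that("acinar commitment propagates as spatial waves", {
  commits <- commit_times(dev_run$trajectory, "acinar")
  obs <- pair_time_gap(commits, dev_run$tissue)
  null <- shuffled_null(function(v) pair_time_gap(v, dev_run$tissue),
                        commits)
  expect_lt(obs, quantile(null, 0.05))
})

test_that("without noise the developmental symmetry never breaks", {
  d0 <- run_development(width = 8, height = 8, t_end = 60,
                        noise_on = FALSE, seed = 1)
  expect_equal(length(unique(d0$final_fates)), 1L)
  st <- final_states(d0$trajectory)
  expect_equal(max(apply(st, 2, function(v) diff(range(v)))), 0)
})

test_that("loss of stabilization converts the whole tissue sequentially", {
  r <- run_conversion("stab", seed = 5, keep_trajectory = TRUE)
  expect_equal(r$conversion_fraction, 1.0)
  expect_false(is.na(r$time_to_half))
  # nascent islet cells appear in an alternating (non-adjacent) pattern:
  # when the first quarter has committed, islet-islet adjacency is below
  # the spatially shuffled null
  tr <- r$trajectory
  ff <- fate_fractions(tr)
  k25 <- which(ff$islet >= 0.25)[1]
  fates25 <- classify_fates(tr$states[, , k25])
  obs <- adjacent_pair_fraction(fates25, r$tissue)
  null <- shuffled_null(function(v)
    adjacent_pair_fraction(v, r$tissue), fates25)
  expect_lt(obs, quantile(null, 0.05))
})

test_that("conversion protocols are deterministic given a seed", {
  r1 <- run_conversion("stab", width = 12, height = 12, t_end = 60,
                       seed = 17)
  r2 <- run_conversion("stab", width = 12, height = 12, t_end = 60,
                       seed = 17)
  expect_identical(r1$final_states, r2$final_states)
  expect_identical(r1$time_to_half, r2$time_to_half)
})

test_that("losing inhibition alone leaves acinar identity intact", {
  r <- run_conversion("inhibition_only", width = 12, height = 12,
                      t_end = 80, seed = 2)
  expect_equal(r$conversion_fraction, 0)
  expect_true(all(r$final_fates == "acinar"))
})

test_that("recovery outcome depends on when stabilization returns", {
  no_rec <- run_conversion("stab", width = 16, height = 16, t_end = 150,
                           seed = 2)
  early <- run_recovery(5, width = 16, height = 16, t_end = 150, seed = 2)
  mid <- run_recovery(12, width = 16, height = 16, t_end = 150, seed = 2)
  late <- run_recovery(60, width = 16, height = 16, t_end = 150, seed = 2)
  # early recovery re-runs the developmental decision: a mixed pattern
  expect_equal(early$outcome, "mixed_pattern")
  expect_true(all(c("acinar", "islet") %in% early$final_fates))
  # mid-conversion recovery arrests it: strictly fewer conversions
  expect_lt(mid$conversion_fraction, no_rec$conversion_fraction)
  expect_equal(mid$outcome, "arrested_conversion")
  # late recovery does not revert committed islet cells
  expect_equal(late$conversion_fraction, 1.0)
  expect_equal(late$outcome, "completed_conversion")
  expect_error(run_recovery(0), "positive")
  expect_error(run_recovery(-3), "positive")
})

test_that("isolated cells always transdifferentiate", {
  skip_if_not_installed("deSolve")
  # 3x3 grid of mutually non-adjacent cells, stabilization intact
  iso <- data.frame(row = rep(c(2, 4, 6), each = 3),
                    col = rep(c(2, 4, 6), times = 3))
  sw <- run_shape_sweep(list(iso), params = model_params(),
                        replicates = 2, width = 8, height = 8,
                        t_end = 100, seed = 4)
  expect_equal(sw$mean_neighbors, 0)
  expect_equal(sw$mean_conversion, 1.0)
  # single-cell ODE oracle: with no neighbour signals the adult state
  # relaxes to the islet attractor
  f <- function(t, y, parms) list(unname(grn_rhs(y, c(0, 0), parms)))
  ref <- deSolve::lsoda(c(0, 0, 1, 0), c(0, 100), f, model_params(),
                        rtol = 1e-8, atol = 1e-10)
  expect_equal(classify_fates(ref[2, -1]), "islet")
})

test_that("aggregate compactness protects against conversion", {
  chain <- data.frame(row = 5, col = 3:6)
  rhomb <- data.frame(row = c(5, 5, 6, 6), col = c(3, 4, 3, 4))
  sw <- run_shape_sweep(list(chain, rhomb), params = model_params(b = 0.1),
                        replicates = 4, width = 10, height = 10,
                        t_end = 300, seed = 2)
  expect_lt(sw$mean_neighbors[1], sw$mean_neighbors[2])
  expect_gte(sw$mean_conversion[1], sw$mean_conversion[2])
  expect_gt(sw$mean_conversion[1], 0.9)  # loose chains convert
  expect_lt(sw$mean_conversion[2], 0.1)  # compact rhombi persist
  # unequal cell counts are flagged as confounded
  expect_warning(
    run_shape_sweep(list(chain, rbind(chain, data.frame(row = 7, col = 3))),
                    replicates = 1, width = 10, height = 10, t_end = 1),
    "confounded")
})

test_that("a confluent lattice with intact stabilization never converts", {
  full <- matrix(TRUE, 8, 8)
  sw <- run_shape_sweep(list(full), params = model_params(),
                        replicates = 1, width = 8, height = 8,
                        t_end = 50, seed = 1)
  expect_equal(sw$mean_conversion, 0)
})

test_that("density sweeps report replicate means with standard errors", {
  sw <- run_density_sweep(densities = c(0.3, 0.7), b_values = 0.1,
                          replicates = 3, width = 10, height = 10,
                          t_end = 60, seed = 6)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$n_replicates, c(3, 3))
  expect_true(all(sw$mean_conversion >= 0 & sw$mean_conversion <= 1))
  expect_true(all(is.finite(sw$se)))
  # sparse tissue converts more than dense tissue
  expect_gt(sw$mean_conversion[sw$density == 0.3],
            sw$mean_conversion[sw$density == 0.7])
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, f)
  expect_identical(read.csv(f)$mean_conversion, sw$mean_conversion)
})
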