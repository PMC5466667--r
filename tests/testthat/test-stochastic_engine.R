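test_that("an inert system is constant for any seed", {
  sys <- compile_system(inert_model(), default_physics(),
                        mode = "fixed", closed = TRUE)
  y0 <- make_y0(sys, c(A = 1000, Z = 500))
  for (s in c(1, 77)) {
    tr <- run_ssa(sys, y0, t_end = 10, seed = s, n_out = 5)
    expect_equal(tr$n_events, 0)
    expect_true(all(apply(tr$counts, 2, function(x) all(x == x[1]))))
  }
})

test_that("pure death matches the closed form in ensemble mean", {
  sys <- compile_system(tiny_decay_model(1), default_physics(),
                        mode = "fixed", closed = TRUE)
  y0 <- make_y0(sys, c(Z = 1000))
  finals <- vapply(1:50, function(s)
    run_ssa(sys, y0, t_end = 1, seed = s, n_out = 2)$counts[2, "Z"],
    numeric(1))
  se <- sd(finals) / sqrt(50)
  expect_lt(abs(mean(finals) - 1000 * exp(-1)), 3 * se)
  # counts are conserved exactly event by event (sampled states)
  tr <- run_ssa(sys, y0, t_end = 3, seed = 5, n_out = 31)
  expect_true(all(tr$counts[, "Z"] + tr$counts[, "w"] == 1000))
})

test_that("identical seeds give bit-identical runs", {
  st <- stationary_pm2_state()
  a <- run_ssa(st$sys, st$y, t_end = 2, seed = 11, n_out = 11)
  b <- run_ssa(st$sys, st$y, t_end = 2, seed = 11, n_out = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$n_events, b$n_events)
  c <- run_ssa(st$sys, st$y, t_end = 2, seed = 12, n_out = 11)
  expect_false(identical(a$counts, c$counts))
})

test_that("stochastic divisions conserve molecules and keep isotonicity", {
  st <- stationary_pm2_state()
  tr <- run_ssa(st$sys, st$y, t_end = 12, seed = 4, n_out = 13)
  expect_gte(nrow(tr$divisions), 1)
  p <- tr$division_partitions
  expect_equal(max(abs(p$mother - (p$daughter1 + p$daughter2))), 0)
  expect_lt(tr$max_iso_dev, 1e-12)
  # the followed daughter is one of the two partitions
  expect_true(all(p$followed %in% 1:2))
})

test_that("division_stats summarises the stationary window", {
  rec <- data.frame(T_div = c(2.0, 2.2, 1.8), chi_L = c(0.5, 0.5, 0.5))
  st <- division_stats(rec, window = 3)
  expect_equal(st$mean_T_div, 2.0)
  expect_equal(st$sd_T_div, 0.2, tolerance = 1e-12)
  expect_equal(st$mean_chi_L, 0.5)
  same <- data.frame(T_div = rep(1.5, 10), chi_L = rep(0.9, 10))
  expect_equal(division_stats(same)$sd_T_div, 0)
  expect_error(division_stats(rec, window = 10), "insufficient")
})

test_that("population projection doubles per division time", {
  pc <- project_population(2.5, c(0, 25))
  expect_equal(pc$population, c(1, 1024))
  faster <- project_population(2, c(1, 5, 20))
  expect_true(all(faster$population >=
                  project_population(2.5, c(1, 5, 20))$population))
  expect_error(project_population(0, 1:3), "T_div")
})

test_that("deterministic-engine intervals fed to division_stats are tight", {
  res <- exp_reproduction("pm2", k_d = 0.2, t_end = 400)
  st <- division_stats(res$trajectory$divisions)
  expect_lt(st$sd_T_div / st$mean_T_div, 0.01)
})
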