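test_that("an inert system yields a constant trajectory", {
  sys <- compile_system(inert_model(), default_physics(),
                        mode = "fixed", closed = TRUE)
  y0 <- make_y0(sys, c(A = 1000, Z = 500))
  tr <- integrate_system(sys, y0, c(0, 50), n_out = 11)
  expect_true(all(apply(tr$counts, 2, function(x) all(x == x[1]))))
})

test_that("unimolecular decay matches the closed form to 1e-6 relative", {
  k <- 0.7
  sys <- compile_system(tiny_decay_model(k), default_physics(),
                        mode = "fixed", closed = TRUE)
  y0 <- make_y0(sys, c(Z = 1e6))
  tr <- integrate_system(sys, y0, c(0, 5), n_out = 21)
  expect_equal(tr$counts[, "Z"], 1e6 * exp(-k * tr$times),
               tolerance = 1e-6)
  # and the moiety total Z + w is conserved along the trajectory
  expect_equal(tr$counts[, "Z"] + tr$counts[, "w"],
               rep(1e6, 21), tolerance = 1e-9)
})

test_that("steady_state polishes to a true root of the dynamics", {
  sys <- compile_system(build_pm2(), default_physics(), mode = "fixed")
  ss <- steady_state(sys, initial_state(sys,
                                        metab_seed = c(AB = 3, AC = 3,
                                                       ACD = 3)))
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-8)
  # dead start of a catalysed-only network stays dead, nutrients at
  # transport equilibrium
  ss0 <- steady_state(sys, initial_state(sys, metab_seed = c(AB = 0)))
  expect_lt(max(ss0$concentrations[c("AB", "AC", "ACD")]), 1e-10)
  expect_equal(unname(ss0$concentrations[c("A", "B", "C", "D")]),
               rep(20, 4), tolerance = 1e-6)
})

test_that("PM1 is monostable: distinct viable starts converge", {
  sys <- compile_system(build_pm1(), default_physics(), mode = "fixed")
  ss1 <- steady_state(sys, initial_state(sys, metab_seed =
                                           c(AB = 1e-4, ACD = 1e-4)))
  ss2 <- steady_state(sys, initial_state(sys, metab_seed =
                                           c(AB = 20, ACD = 20)))
  rel <- abs(ss1$concentrations - ss2$concentrations) /
    pmax(abs(ss1$concentrations), 1e-8)
  expect_lt(max(rel[c("AB", "ACD")]), 1e-6)
  expect_gt(ss1$concentrations[["AB"]], 1)   # and the state is viable
})

test_that("PM2 is bistable at the default operating point", {
  sys <- compile_system(build_pm2(), default_physics(), mode = "fixed")
  low <- steady_state(sys, initial_state(sys, metab_seed =
                                           c(AB = 1e-4, AC = 1e-4,
                                             ACD = 1e-4)))
  high <- steady_state(sys, initial_state(sys, metab_seed =
                                            c(AB = 20, AC = 20,
                                              ACD = 20)))
  expect_lt(low$concentrations[["AB"]], 1e-6)
  expect_gt(high$concentrations[["AB"]], 1)
  expect_gt(abs(high$concentrations[["AB"]] -
                low$concentrations[["AB"]]) /
            high$concentrations[["AB"]], 0.01)
})

test_that("extreme catalyst decay kills every branch", {
  sys <- compile_system(build_pm2(), default_physics(), mode = "fixed",
                        decay_mult = 1e6)
  for (seed in list(c(AB = 1e-4, AC = 1e-4, ACD = 1e-4),
                    c(AB = 20, AC = 20, ACD = 20))) {
    ss <- steady_state(sys, initial_state(sys, metab_seed = seed),
                       t_relax = 200)
    expect_lt(max(ss$concentrations[c("AB", "AC", "ACD")]), 1e-6)
  }
})

test_that("bistability_scan classifies attractors on a small grid", {
  map <- bistability_scan(build_pm2(), default_physics(),
                          decay_grid = c(0.02, 0.1, 0.5),
                          perm_grid = c(0.5, 1, 2),
                          t_relax = 2000)
  expect_s3_class(map, "steady_state_map")
  expect_equal(nrow(map$summary), 9)
  expect_true(all(map$summary$n_attractors %in% 0:2))
  expect_gt(sum(map$summary$bistable), 0)
  # tidy cells: one row per cell x branch x metabolite
  expect_equal(nrow(map$cells), 9 * 2 * 3)
  # ss_AB non-increasing in decay along each branch (per permeability)
  for (p in unique(map$summary$permeability)) {
    sub <- map$summary[map$summary$permeability == p, ]
    sub <- sub[order(sub$decay_rate), ]
    expect_true(all(diff(sub$ss_AB_high) <= 1e-6))
  }
})

test_that("deterministic reproduction settles to a constant division time", {
  res <- exp_reproduction("pm2", k_d = 0, t_end = 500)
  expect_identical(res$outcome, "completed")
  div <- res$trajectory$divisions
  expect_gte(nrow(div), 10)
  late <- utils::tail(div$T_div, 5)
  expect_lt(max(abs(diff(late))) / mean(late), 0.01)
  # successive daughters at threshold have Phi cycling over 2^(1/3)
  expect_equal(utils::tail(div$T_div, 1),
               utils::tail(div$T_div, 2)[1], tolerance = 1e-4)
})

test_that("division time falls as a uniform permeability multiplier rises", {
  ps <- default_parameter_set("pm2", "reproducing")
  phys <- default_physics(curve = flat_curve())
  td <- vapply(c(0.75, 1.5), function(pm) {
    tr <- run_reproduction(ps$model, phys, t_end = 700, perm_mult = pm,
                           k_d = 0.2)
    division_stats(tr$divisions, 5)$mean_T_div
  }, numeric(1))
  expect_lt(td[2], td[1])
})
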