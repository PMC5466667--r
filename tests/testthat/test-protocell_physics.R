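test_that("surface area matches a 200 nm sphere built from pure l", {
  m <- sphere_membrane(200)            # N_l = 5,026,548
  expect_equal(m$N_l, 5026548)
  expect_equal(surface_area(m, "nm2"), 4 * pi * 200^2, tolerance = 1e-6)
  expect_equal(surface_area(m), 4 * pi * (200e-9)^2, tolerance = 1e-6)
  m2 <- membrane_state(2 * m$N_l, 0)
  expect_equal(surface_area(m2), 2 * surface_area(m), tolerance = 1e-12)
  expect_error(membrane_state(0, 0), "minimum closure")
})

test_that("surface fraction weights counts by head areas", {
  expect_equal(surface_fraction_L(membrane_state(1e4, 0)), 0)
  expect_equal(surface_fraction_L(membrane_state(1e4, 1e4,
                                                 alpha_l = 0.2,
                                                 alpha_L = 0.6)), 0.75)
  expect_equal(surface_fraction_L(membrane_state(3e4, 1e4,
                                                 alpha_l = 0.2,
                                                 alpha_L = 0.4)), 0.4)
})

test_that("isotonic volume is the algebraic osmotic projection", {
  expect_equal(isotonic_volume(c(a = 2e6), 100),
               2e6 / (N_AVOGADRO * 100))
  expect_equal(isotonic_volume(c(a = 2e6), 100), 3.321e-20,
               tolerance = 1e-4)
  expect_equal(isotonic_volume(c(a = 4e6), 100),
               2 * isotonic_volume(c(a = 2e6), 100))
  # membrane-excluded species do not contribute
  expect_equal(isotonic_volume(c(a = 2e6, b = 5e5), 100,
                               osmotically_active = c(TRUE, FALSE)),
               isotonic_volume(c(a = 2e6), 100))
  expect_error(isotonic_volume(c(a = 0), 100), "degenerate")
  # the projection restores the isotonic condition exactly
  V <- isotonic_volume(c(a = 1.23e6), 250)
  expect_equal(1.23e6 / (N_AVOGADRO * V), 250)
})

test_that("reduced surface is 1 for spheres and 2^(1/3) at the two-sphere area", {
  r <- 123e-9
  expect_equal(reduced_surface(4 * pi * r^2, 4 / 3 * pi * r^3), 1,
               tolerance = 1e-12)
  V <- 4 / 3 * pi * r^3
  S2 <- 2 * 4 * pi * (r / 2^(1 / 3))^2    # two spheres of volume V/2
  expect_equal(reduced_surface(S2, V), 2^(1 / 3), tolerance = 1e-12)
  # monotone decreasing in V at fixed S
  S <- 4 * pi * r^2
  expect_true(reduced_surface(S, V / 2) > reduced_surface(S, V))
})

test_that("permeability curve is an exact-matching polynomial", {
  cv <- permeability_curve(c(0, 0.5, 1), c(1, 10, 2))
  expect_equal(eval_curve(cv, c(0, 0.5, 1)), c(1, 10, 2))
  expect_equal(eval_curve(cv, 0.25), 7.625, tolerance = 1e-12)
  expect_error(eval_curve(cv, 1.2), "extrapolation")
  expect_error(permeability_curve(c(0, 0.5), c(1, 2)), "chi = 1")
  expect_error(permeability_curve(c(0, 0.4, 0.4, 1), c(1, 2, 3, 4)),
               "duplicate|increasing")
  expect_error(permeability_curve(c(0, 0.5, 1), c(1, -2, 2)), "> 0")
})

test_that("effective permeability dispatches on the permeability class", {
  cv <- permeability_curve(c(0, 0.375, 1), c(1, 10, 2))
  acd <- species_spec("acd", "waste", "impermeable")
  expect_equal(effective_permeability(acd, 0.5, cv), 0)
  w <- species_spec("w", "waste", "constant", base_permeability = 1e-10)
  expect_equal(effective_permeability(w, 0.9, cv), 1e-10)
  a <- species_spec("A", "nutrient", "composition_dependent",
                    base_permeability = 2e-12, env_concentration = 20)
  expect_equal(effective_permeability(a, 0.375, cv), 2e-12 * 10)
})

test_that("transport fluxes follow P * S * c with influx/efflux split", {
  a <- species_spec("A", "nutrient", "composition_dependent",
                    base_permeability = 1e-12, env_concentration = 100)
  st <- protocell_state(c(A = 0, X = 2e6), sphere_membrane(200),
                        C_out = 100)
  st$S_mu <- 5e-13  # the worked geometry of the flux example
  fl <- transport_fluxes(st, c(A = 100), list(a), flat_curve())
  expect_equal(fl$influx, 1e-12 * 5e-13 * 100 * N_AVOGADRO,
               tolerance = 1e-12)
  expect_equal(fl$influx, 30.1, tolerance = 1e-2)
  expect_equal(fl$efflux, 0)
  # equal inside and outside concentrations: zero net flux
  n_eq <- 100 * st$V_in * N_AVOGADRO
  st2 <- st; st2$counts[["A"]] <- n_eq
  fl2 <- transport_fluxes(st2, c(A = 100), list(a), flat_curve())
  expect_equal(fl2$influx, fl2$efflux, tolerance = 1e-9)
  # impermeable species move nothing
  acd <- species_spec("acd", "waste", "impermeable")
  st3 <- protocell_state(c(acd = 50, X = 2e6), sphere_membrane(200),
                         C_out = 100)
  fl3 <- transport_fluxes(st3, c(acd = 50), list(acd), flat_curve())
  expect_equal(fl3$influx + fl3$efflux, 0)
})

test_that("event rule classifies divide / burst / none with precedence", {
  rule <- event_rule()
  expect_identical(check_event(1.30, rule), "divide")
  expect_identical(check_event(2^(1 / 3), rule), "divide")
  expect_identical(check_event(0.85, rule), "burst")
  expect_identical(check_event(1.00, rule), "none")
  expect_error(event_rule(epsilon_burst = 1.2), "epsilon_burst")
  expect_error(event_rule(phi_divide = 0.9), "phi_divide")
})

test_that("division conserves every species and splits on average evenly", {
  st <- protocell_state(c(AB = 10, X = 2e6), sphere_membrane(200),
                        C_out = 100)
  for (seed in 1:10) {
    set.seed(seed)
    d <- divide(st)
    expect_equal(d[[1]]$counts + d[[2]]$counts, st$counts)
    expect_equal(d[[1]]$membrane$N_l + d[[2]]$membrane$N_l,
                 st$membrane$N_l)
  }
  set.seed(99)
  ab1 <- replicate(400, divide(st)[[1]]$counts[["AB"]])
  se <- sd(ab1) / sqrt(length(ab1))
  expect_lt(abs(mean(ab1) - 5), 3 * se + 1e-9)
})

test_that("an equal-split daughter of a mother at threshold is spherical", {
  # the pure geometry: S and V halve, Phi scales by 2^(-1/3)
  r <- 200e-9
  V <- 4 / 3 * pi * r^3
  S <- 2^(1 / 3) * 4 * pi * r^2        # mother exactly at threshold
  expect_equal(reduced_surface(S, V), 2^(1 / 3), tolerance = 1e-12)
  expect_equal(reduced_surface(S / 2, V / 2), 1, tolerance = 1e-9)
  # and through the state machinery with an exactly even composition
  st <- protocell_state(c(X = 2e6), membrane_state(round(2 ^ (1 / 3) *
    2 * 4 * pi * 200^2 / 0.2)), C_out = 100)
  half <- protocell_state(st$counts / 2,
                          membrane_state(st$membrane$N_l / 2, 0),
                          C_out = 100)
  expect_equal(half$Phi, st$Phi * 2^(-1 / 3), tolerance = 1e-9)
})

test_that("lipid exchange propensities implement the four channels", {
  st <- protocell_state(c(L = 500, X = 2e6),
                        membrane_state(4e6, 1e6), C_out = 100)
  pr <- lipid_exchange_propensities(st, c_l_env = 1e-4, k_in = 1e-9,
                                    k_out = 2e-5, k_d = 0.1)
  kin_h <- 1e-9 * 3600
  expect_equal(pr[["l_uptake"]], kin_h * st$S_mu * 1e-4 * N_AVOGADRO)
  expect_equal(pr[["l_release"]], 2e-5 * 4e6)
  expect_equal(pr[["L_insertion"]], kin_h * st$S_mu * 500 / st$V_in)
  expect_equal(pr[["displacement"]], 0.1 * 1e6)
  # default k_out balances uptake against release for a pure-l sphere
  ph <- default_physics()
  st0 <- protocell_state(c(L = 0, X = 2e6), sphere_membrane(200),
                         C_out = 100)
  pr0 <- lipid_exchange_propensities(st0, ph$c_l_env, ph$k_in,
                                     ph$k_out, 0)
  expect_equal(pr0[["l_uptake"]], pr0[["l_release"]], tolerance = 1e-6)
})

test_that("stationary membrane composition decreases monotonically in k_d", {
  ps <- default_parameter_set("pm2", "reproducing")
  chis <- vapply(c(0, 0.05, 0.2, 0.5, 1), function(kd) {
    tr <- run_reproduction(ps$model, ps$physics, t_end = 350, k_d = kd)
    utils::tail(tr$divisions$chi_L, 1)
  }, numeric(1))
  expect_true(all(diff(chis) < 0))
})

test_that("a dead protocell with balanced exchange holds a steady Phi", {
  m <- build_pm2()
  sys <- compile_system(m, default_physics(), mode = "protocell")
  y0 <- initial_state(sys, metab_seed = c(AB = 0, AC = 0, ACD = 0))
  tr <- integrate_system(sys, y0, c(0, 100), n_out = 11)
  expect_identical(tr$outcome, "completed")
  expect_lt(max(abs(tr$geom$Phi - 1)), 1e-5)
})
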