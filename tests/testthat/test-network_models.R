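test_that("PM1 has the expected structure and fails loudly on missing rates", {
  m <- build_pm1()
  expect_s3_class(m, "network_model")
  expect_length(m$reactions, 4)
  expect_setequal(vapply(m$species, function(s) s$name, character(1)),
                  c("A", "B", "C", "D", "AB", "ACD", "w", "acd"))
  # permeability classes: nutrients composition-dependent, w constant,
  # acd impermeable
  cls <- vapply(m$species, function(s) s$permeability_class, character(1))
  names(cls) <- vapply(m$species, function(s) s$name, character(1))
  expect_true(all(cls[c("A", "B", "C", "D")] == "composition_dependent"))
  expect_identical(cls[["w"]], "constant")
  expect_identical(cls[["acd"]], "impermeable")

  expect_error(build_pm1(params = c(k1 = 1, k2 = 1, d1 = 0.1)), "d2")
  expect_error(build_pm1(params = c(k1 = -1, k2 = 1, d1 = 1, d2 = 1)),
               "must be > 0")
})

test_that("PM2 adds the AC cycle and reduces to PM1 topology", {
  m2 <- build_pm2()
  expect_length(m2$reactions, 6)
  expect_true(has_species(m2, "AC"))
  expect_false(has_species(build_pm1(), "AC"))

  # replacing the AC route (R2, R3, D3) with PM1's ternary condensation
  # reproduces PM1's stoichiometry matrix
  keep <- vapply(m2$reactions, function(r)
    !(r$name %in% c("R2", "R3", "D3")), logical(1))
  pm1_r2 <- build_pm1()$reactions[[2]]
  m2to1 <- network_model("pm2to1",
                         Filter(function(s) s$name != "AC", m2$species),
                         append(m2$reactions[keep], list(pm1_r2), 1))
  S1 <- stoichiometry_matrix(build_pm1())
  S2 <- stoichiometry_matrix(m2to1)
  expect_identical(S1[rownames(S1), order(colnames(S1))],
                   S2[rownames(S1), order(colnames(S2))])
})

test_that("condensations conserve moieties; decays are the only sinks", {
  for (m in list(build_pm1(), build_pm2())) {
    bal <- moiety_balanced(m)
    decays <- grepl("^D", names(bal))
    expect_true(all(bal[!decays]),
                info = paste("condensations of", m$name))
    # the closed variant balances every reaction
    expect_true(all(moiety_balanced(closed_variant(m))),
                info = paste("closed variant of", m$name))
  }
})

test_that("reaction_rate implements mass action with optional catalyst", {
  r_ab <- reaction_spec("r", c(A = 1, B = 1), c(AB = 1),
                        rate_constant = 1)
  expect_equal(reaction_rate(r_ab, c(A = 2, B = 3)), 6)
  r_cat <- reaction_spec("r", c(A = 1), c(B = 1), catalyst = "E",
                         rate_constant = 0.5)
  expect_equal(reaction_rate(r_cat, c(A = 4, E = 2)), 4)
  expect_equal(reaction_rate(r_cat, c(A = 4, E = 0)), 0)
  r_k2 <- reaction_spec("r", c(A = 2), c(B = 1), rate_constant = 2)
  expect_equal(reaction_rate(r_k2, c(A = 3)), 18)
  expect_error(reaction_rate(r_ab, c(A = -1, B = 1)), "negative")
  expect_error(reaction_rate(r_ab, c(A = 1)), "missing")
})

test_that("catalysed networks keep the dead state fixed", {
  m <- build_pm2()
  sys <- compile_system(m, default_physics(), mode = "fixed",
                        closed = TRUE)
  y <- make_y0(sys, c(A = 1e5, B = 1e5, C = 1e5, D = 1e5))
  dy <- protocell:::cpp_rhs(unclass(sys), y)
  expect_equal(max(abs(dy)), 0)
})

test_that("reaction and species validation enforce the declared invariants", {
  expect_error(species_spec("x", "nutrient", "impermeable",
                            base_permeability = 1e-12), "base_permeability")
  expect_error(species_spec("x", "metabolite", head_area = 0.3),
               "head_area")
  expect_error(species_spec("x", "membrane_lipid"), "head_area")
  expect_error(reaction_spec("r", c(A = 1.5), c(B = 1),
                             rate_constant = 1), "positive integers")
  expect_error(reaction_spec("r", c(A = 1), c(B = 1), catalyst = "A",
                             rate_constant = 1), "catalyst")
  expect_error(network_model("m", list(species_spec("A", "nutrient")),
                             list()), "metabolite")
  expect_error(
    network_model("m",
                  list(species_spec("A", "nutrient"),
                       species_spec("Z", "metabolite")),
                  list(reaction_spec("r", c(Q = 1), c(Z = 1),
                                     rate_constant = 1))),
    "undeclared")
})

test_that("add_lipid_synthesis wires the extension without touching RS kinetics", {
  base <- build_pm2()
  n0 <- length(base$reactions)
  m <- add_lipid_synthesis(base, k_syn = 0.1, k_d = 0.3)
  expect_length(m$reactions, n0 + 1)
  expect_true(all(c("P", "L", "l_mem", "L_mem") %in%
                  vapply(m$species, function(s) s$name, character(1))))
  expect_equal(m$metadata$k_d, 0.3)
  # k_d is registered with the membrane machinery, not the rate law
  rs1 <- Filter(function(r) r$name == "RS",
                add_lipid_synthesis(base, k_syn = 0.1, k_d = 0)$reactions)
  rs2 <- Filter(function(r) r$name == "RS",
                add_lipid_synthesis(base, k_syn = 0.1, k_d = 5)$reactions)
  expect_identical(rs1, rs2)
  expect_error(add_lipid_synthesis(base, k_syn = 0), "k_syn")
  expect_error(add_lipid_synthesis(tiny_decay_model(), k_syn = 1),
               "lacks the catalyst AB")
})

test_that("model + physics configs round-trip losslessly through JSON", {
  m <- add_lipid_synthesis(build_pm2(), k_syn = 0.07, k_d = 0.12)
  ph <- default_physics(r0 = 150, k_in = 2e-9,
                        curve = permeability_curve(c(0, 0.3, 0.7, 1),
                                                   c(1, 4, 9, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  save_config(m, path, physics = ph)
  back <- load_config(path)
  expect_equal(back$model, m)
  expect_equal(back$physics, ph)
  # and a second dump is byte-identical (serialisation is stable)
  path2 <- withr::local_tempfile(fileext = ".json")
  save_config(back$model, path2, physics = back$physics)
  expect_identical(readLines(path), readLines(path2))
})
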