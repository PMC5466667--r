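# Shared fixtures. Everything is generated in code; the only on-disk
# fixture is the packaged synthetic assay CSV under inst/extdata.

N_AVOGADRO <- 6.02214076e23

# minimal closed network with a single unimolecular decay Z -> w
tiny_decay_model <- function(k = 1) {
  network_model(
    "tiny_decay",
    list(species_spec("A", "nutrient"),
         species_spec("Z", "metabolite"),
         species_spec("w", "waste")),
    list(reaction_spec("D", c(Z = 1), c(w = 1), rate_constant = k)))
}

# minimal network with no reactions at all is not allowed to skip
# validation, so the "empty" fixture carries one reaction with rate 0
inert_model <- function() {
  network_model(
    "inert",
    list(species_spec("A", "nutrient"),
         species_spec("Z", "metabolite"),
         species_spec("w", "waste")),
    list(reaction_spec("D", c(Z = 1), c(w = 1), rate_constant = 0)))
}

# named initial count vector aligned with a compiled system
make_y0 <- function(sys, counts) {
  y <- stats::setNames(numeric(length(sys$species)), sys$species)
  y[names(counts)] <- counts
  if (sys$mode == 1L) y <- c(y, N_l = 0, N_L = 0)
  y
}

# spherical membrane of pure primitive lipid at radius r0_nm
sphere_membrane <- function(r0_nm = 200, alpha_l = 0.2) {
  membrane_state(round(2 * 4 * pi * r0_nm^2 / alpha_l), 0,
                 alpha_l = alpha_l)
}

# deterministic stationary protocell state for the default reproducing
# PM2 scenario (computed once per test run, then cached)
.fixture_cache <- new.env(parent = emptyenv())
stationary_pm2_state <- function() {
  if (!is.null(.fixture_cache$pm2_stationary))
    return(.fixture_cache$pm2_stationary)
  ps <- default_parameter_set("pm2", "reproducing")
  sys <- compile_system(ps$model, ps$physics, mode = "protocell",
                        k_d = 0)
  conc0 <- equilibrium_concentrations(ps$model, ps$physics)
  y0 <- initial_state(sys, metab_seed = conc0)
  traj <- integrate_system(sys, y0, c(0, 400), n_out = 5)
  out <- list(sys = sys, model = ps$model, physics = ps$physics,
              y = round(traj$counts[5, ]))
  .fixture_cache$pm2_stationary <- out
  out
}

flat_curve <- function() permeability_curve(c(0, 1), c(1, 1))
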