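#' Default mass-action rate constants
#'
#' Named default parameter tables for the two proto-metabolic networks.
#' Units: a reaction of total order n (catalyst included) has its
#' constant in (mol/m^3)^(1-n) per hour. The defaults are chosen so
#' that, at the default environmental concentrations and a 200 nm
#' compartment, the encapsulated network settles into a non-trivial
#' steady state on a timescale of hours to days.
#'
#' @param model `"pm1"` or `"pm2"`.
#' @return Named numeric vector of rate constants.
#' @export
pm_default_rates <- function(model = c("pm1", "pm2")) {
  model <- match.arg(model)
  if (model == "pm1")
    c(k1 = 2e-3, k2 = 2e-4, d1 = 0.05, d2 = 0.05)
  else
    c(k1 = 2e-3, k2 = 2e-3, k3 = 2e-3, d1 = 0.05, d2 = 0.05, d3 = 0.05)
}

#' Default environmental concentrations (mol/m^3)
#'
#' The outer medium buffers the four energy-rich nutrients and, when
#' lipid synthesis is enabled, the lipid precursor P and a trace of
#' free primitive lipid monomer l. The total external osmolarity
#' `C_out` (default 100 mol/m^3, the assay buffer) is dominated by the
#' buffer and is configured in the physics parameters, not here.
#'
#' @return Named numeric vector of concentrations.
#' @export
pm_default_environment <- function() {
  c(A = 20, B = 20, C = 20, D = 20, P = 10, w = 0)
}

.need_rates <- function(params, needed, reactions) {
  for (i in seq_along(needed)) {
    nm <- needed[i]
    if (!nm %in% names(params) || !is.finite(params[[nm]]))
      stop("missing rate constant '", nm, "' for reaction ", reactions[i])
    if (params[[nm]] <= 0)
      stop("rate constant '", nm, "' for reaction ", reactions[i],
           " must be > 0")
  }
}

.core_species <- function(env, base_P_nutrient = 2e-12,
                          base_P_w = 1e-10, with_AC = FALSE) {
  nut <- function(nm) species_spec(
    nm, "nutrient", "composition_dependent",
    base_permeability = base_P_nutrient,
    env_concentration = env[[nm]])
  sp <- list(
    nut("A"), nut("B"), nut("C"), nut("D"),
    species_spec("AB", "metabolite"),
    species_spec("ACD", "metabolite"),
    species_spec("w", "waste", "constant", base_permeability = base_P_w,
                 env_concentration = env[["w"]]),
    species_spec("acd", "waste", "impermeable")
  )
  if (with_AC) sp <- append(sp, list(species_spec("AC", "metabolite")), 6)
  sp
}

#' Build the two-cycle 'heterotrophic' network PM1
#'
#' Two mutually promoting catalytic condensation cycles: AB is formed
#' from A + B under ACD catalysis, and ACD is formed from A + C + D
#' under AB catalysis. Each condensation releases one permeable leaving
#' group w per bond formed; both catalysts have limited lifespans (AB
#' decays to 2 w, ACD to the completely impermeable end-product acd).
#'
#' @param params Named rate-constant table with entries `k1` (R1),
#'   `k2` (R2), `d1` (decay of AB), `d2` (decay of ACD). See
#'   [pm_default_rates()].
#' @param env Named environmental concentrations, see
#'   [pm_default_environment()].
#' @param base_P_nutrient,base_P_w Base permeabilities (m/s) of the
#'   nutrients (composition-dependent class) and of w (constant class).
#' @return A [network_model()].
#' @export
build_pm1 <- function(params = pm_default_rates("pm1"),
                      env = pm_default_environment(),
                      base_P_nutrient = 2e-12, base_P_w = 1e-10) {
  .need_rates(params, c("k1", "k2", "d1", "d2"),
              c("R1", "R2", "D1", "D2"))
  network_model(
    "pm1",
    .core_species(env, base_P_nutrient, base_P_w),
    list(
      reaction_spec("R1", c(A = 1, B = 1), c(AB = 1, w = 1),
                    catalyst = "ACD", rate_constant = params[["k1"]]),
      reaction_spec("R2", c(A = 1, C = 1, D = 1), c(ACD = 1, w = 2),
                    catalyst = "AB", rate_constant = params[["k2"]]),
      reaction_spec("D1", c(AB = 1), c(w = 2),
                    rate_constant = params[["d1"]]),
      reaction_spec("D2", c(ACD = 1), c(acd = 1),
                    rate_constant = params[["d2"]])
    )
  )
}

#' Build the three-cycle 'autotrophic' network PM2
#'
#' As PM1, but with one extra reinforcing cycle: ACD is no longer made
#' in a single ternary condensation; instead ACD catalysis first forms
#' the intermediate AC (from A + C), which then condenses with D under
#' AB catalysis. All three catalysts decay (AB and AC to w, ACD to the
#' impermeable acd).
#'
#' @param params Named rate-constant table: `k1` (R1), `k2` (R2),
#'   `k3` (R3), `d1`..`d3` (decays of AB, ACD, AC).
#' @inheritParams build_pm1
#' @return A [network_model()].
#' @export
build_pm2 <- function(params = pm_default_rates("pm2"),
                      env = pm_default_environment(),
                      base_P_nutrient = 2e-12, base_P_w = 1e-10) {
  .need_rates(params, c("k1", "k2", "k3", "d1", "d2", "d3"),
              c("R1", "R2", "R3", "D1", "D2", "D3"))
  network_model(
    "pm2",
    .core_species(env, base_P_nutrient, base_P_w, with_AC = TRUE),
    list(
      reaction_spec("R1", c(A = 1, B = 1), c(AB = 1, w = 1),
                    catalyst = "ACD", rate_constant = params[["k1"]]),
      reaction_spec("R2", c(A = 1, C = 1), c(AC = 1, w = 1),
                    catalyst = "ACD", rate_constant = params[["k2"]]),
      reaction_spec("R3", c(AC = 1, D = 1), c(ACD = 1, w = 1),
                    catalyst = "AB", rate_constant = params[["k3"]]),
      reaction_spec("D1", c(AB = 1), c(w = 2),
                    rate_constant = params[["d1"]]),
      reaction_spec("D2", c(ACD = 1), c(acd = 1),
                    rate_constant = params[["d2"]]),
      reaction_spec("D3", c(AC = 1), c(w = 2),
                    rate_constant = params[["d3"]])
    )
  )
}

#' Add endogenous lipid synthesis to a network
#'
#' Registers the membrane-coupling extension: a diffusible precursor P
#' is converted to the amphiphilic lipid L inside the compartment, in a
#' reaction catalysed by AB. L inserts spontaneously into the bilayer
#' (handled by the membrane-exchange machinery, as are the membrane
#' pools `l_mem` / `L_mem` declared here), while the displacement
#' constant `k_d` -- how efficiently membrane L is swapped for
#' environmental l -- is registered as model metadata, not as a bulk
#' reaction: it has no influence on the synthesis rate law.
#'
#' @param model A [network_model()] containing the catalyst AB.
#' @param k_syn Rate constant of P -> L (catalysed by AB), in
#'   (mol/m^3)^-1 per hour; must be > 0.
#' @param k_d Membrane displacement rate constant (per hour); >= 0.
#' @param env_P Environmental precursor concentration (mol/m^3).
#' @param base_P_precursor Base permeability of P (m/s),
#'   composition-dependent class.
#' @param alpha_l,alpha_L Head areas (nm^2) of the primitive and the
#'   synthesised membrane lipid.
#' @return A new [network_model()] with the extra species, the single
#'   extra bulk reaction RS, and `k_d` in `$metadata`.
#' @export
add_lipid_synthesis <- function(model, k_syn = 0.1, k_d = 0,
                                env_P = pm_default_environment()[["P"]],
                                base_P_precursor = 1e-11,
                                alpha_l = 0.2, alpha_L = 0.6) {
  if (!has_species(model, "AB"))
    stop("model '", model$name, "' lacks the catalyst AB")
  if (!is.finite(k_syn) || k_syn <= 0) stop("k_syn must be > 0")
  if (!is.finite(k_d) || k_d < 0) stop("k_d must be >= 0")
  species <- c(model$species, list(
    species_spec("P", "lipid_precursor", "composition_dependent",
                 base_permeability = base_P_precursor,
                 env_concentration = env_P),
    species_spec("L", "aqueous_lipid"),
    species_spec("l_mem", "membrane_lipid", head_area = alpha_l),
    species_spec("L_mem", "membrane_lipid", head_area = alpha_L)
  ))
  reactions <- c(model$reactions, list(
    reaction_spec("RS", c(P = 1), c(L = 1), catalyst = "AB",
                  rate_constant = k_syn)
  ))
  md <- model$metadata
  md$k_d <- k_d
  md$lipid_synthesis <- TRUE
  network_model(model$name, species, reactions, md)
}
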