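# JSON (de)serialisation of networks and physics parameter sets.
# Round-trips are lossless: load(dump(x)) reproduces x exactly.

.species_to_list <- function(s) {
  list(name = s$name, role = s$role,
       permeability_class = s$permeability_class,
       base_permeability = s$base_permeability,
       osmotically_active = s$osmotically_active,
       head_area = if (is.finite(s$head_area)) s$head_area else NULL,
       env_concentration = if (is.finite(s$env_concentration))
         s$env_concentration else NULL)
}

.species_from_list <- function(x) {
  species_spec(x$name, x$role, x$permeability_class,
               x$base_permeability, x$osmotically_active,
               head_area = x$head_area %||% NA_real_,
               env_concentration = x$env_concentration %||% NA_real_)
}

.reaction_to_list <- function(r) {
  list(name = r$name, reactants = as.list(r$reactants),
       products = as.list(r$products), catalyst = r$catalyst,
       rate_constant = r$rate_constant)
}

.reaction_from_list <- function(x) {
  reaction_spec(x$name, unlist(x$reactants), unlist(x$products),
                catalyst = x$catalyst, rate_constant = x$rate_constant)
}

#' Serialise a model (and optionally physics) to JSON
#'
#' @param model A [network_model()].
#' @param path Output path (`.json`).
#' @param physics Optional [default_physics()] list stored alongside.
#' @return The path, invisibly.
#' @export
save_config <- function(model, path, physics = NULL) {
  cfg <- list(
    name = model$name,
    species = lapply(model$species, .species_to_list),
    reactions = lapply(model$reactions, .reaction_to_list),
    metadata = model$metadata)
  if (!is.null(physics)) {
    ph <- unclass(physics)
    ph$curve <- list(chi = physics$curve$chi,
                     multiplier = physics$curve$multiplier)
    cfg$physics <- ph
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a model (and physics, if present) from JSON
#'
#' @param path Path written by [save_config()].
#' @return List with `model` and (possibly `NULL`) `physics`.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  model <- network_model(
    cfg$name,
    lapply(cfg$species, .species_from_list),
    lapply(cfg$reactions, .reaction_from_list),
    metadata = lapply(cfg$metadata, function(x) x))
  physics <- NULL
  if (!is.null(cfg$physics)) {
    ph <- cfg$physics
    physics <- default_physics(
      r0 = ph$r0, C_out = ph$C_out,
      curve = permeability_curve(unlist(ph$curve$chi),
                                 unlist(ph$curve$multiplier)),
      alpha_l = ph$alpha_l, alpha_L = ph$alpha_L, lambda = ph$lambda,
      k_in = ph$k_in, c_l_env = ph$c_l_env, k_out = ph$k_out,
      phi_divide = ph$phi_divide, epsilon_burst = ph$epsilon_burst,
      min_lipids = ph$min_lipids, fixed_chi = ph$fixed_chi)
  }
  list(model = model, physics = physics)
}
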