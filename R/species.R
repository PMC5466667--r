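#' Species specification
#'
#' Declares one chemical species of a protocell reaction network: its
#' functional role, how it crosses the membrane, and whether it counts
#' towards the internal osmotic balance.
#'
#' @param name Species identifier (single string).
#' @param role One of `"nutrient"`, `"metabolite"`, `"waste"`,
#'   `"lipid_precursor"`, `"aqueous_lipid"`, `"membrane_lipid"`,
#'   `"inert_osmolyte"`.
#' @param permeability_class One of `"composition_dependent"`,
#'   `"constant"`, `"impermeable"`.
#' @param base_permeability Membrane permeability coefficient in m/s at
#'   the reference composition (chi = 0). Must be 0 for impermeable
#'   species.
#' @param osmotically_active Logical; does the species contribute to the
#'   internal osmolarity while in the aqueous lumen? Membrane lipids are
#'   never osmotically active.
#' @param head_area Polar head area in nm^2; required for (and only
#'   allowed on) `membrane_lipid` species.
#' @param env_concentration Environmental (buffered) concentration in
#'   mol/m^3, for species present in the outer medium; `NA` otherwise.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, role,
                         permeability_class = "impermeable",
                         base_permeability = 0,
                         osmotically_active = TRUE,
                         head_area = NA_real_,
                         env_concentration = NA_real_) {
  roles <- c("nutrient", "metabolite", "waste", "lipid_precursor",
             "aqueous_lipid", "membrane_lipid", "inert_osmolyte")
  classes <- c("composition_dependent", "constant", "impermeable")
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, roles)
  permeability_class <- match.arg(permeability_class, classes)
  if (permeability_class == "impermeable" && base_permeability != 0)
    stop("impermeable species '", name, "' must have base_permeability = 0")
  if (permeability_class != "impermeable" && base_permeability <= 0)
    stop("permeable species '", name, "' needs base_permeability > 0")
  if (role == "membrane_lipid") {
    if (!is.finite(head_area) || head_area <= 0)
      stop("membrane_lipid '", name, "' requires a positive head_area (nm^2)")
    osmotically_active <- FALSE
  } else if (is.finite(head_area)) {
    stop("head_area is only meaningful for membrane_lipid species ('",
         name, "')")
  }
  if (is.finite(env_concentration) && env_concentration < 0)
    stop("env_concentration must be >= 0 for '", name, "'")
  structure(
    list(name = name, role = role,
         permeability_class = permeability_class,
         base_permeability = base_permeability,
         osmotically_active = isTRUE(osmotically_active),
         head_area = head_area,
         env_concentration = env_concentration),
    class = "species_spec"
  )
}

#' Mass-action reaction specification
#'
#' An irreversible reaction with integer stoichiometry and an optional
#' catalyst. The catalyst enters the rate law linearly but appears on
#' neither side of the reaction.
#'
#' @param name Reaction identifier.
#' @param reactants Named integer vector, species -> stoichiometry.
#' @param products Named integer vector, species -> stoichiometry.
#' @param catalyst Optional catalyst species name.
#' @param rate_constant Mass-action constant; units
#'   (mol/m^3)^(1 - order) per hour, where order counts the catalyst.
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(name, reactants, products, catalyst = NULL,
                          rate_constant) {
  check_stoich <- function(x, what) {
    if (length(x) == 0L && what == "reactants")
      stop("reaction '", name, "' needs at least one reactant")
    if (length(x) > 0L) {
      if (is.null(names(x)) || any(!nzchar(names(x))))
        stop(what, " of '", name, "' must be a named vector")
      if (any(x != round(x)) || any(x < 1))
        stop(what, " stoichiometries of '", name,
             "' must be positive integers")
    }
    stats::setNames(as.integer(x), names(x))
  }
  reactants <- check_stoich(reactants, "reactants")
  products <- check_stoich(products, "products")
  if (!is.null(catalyst)) {
    stopifnot(is.character(catalyst), length(catalyst) == 1L)
    if (catalyst %in% c(names(reactants), names(products)))
      stop("catalyst of '", name,
           "' must not appear among reactants or products")
  }
  if (!is.numeric(rate_constant) || length(rate_constant) != 1L ||
      !is.finite(rate_constant) || rate_constant < 0)
    stop("rate_constant of '", name, "' must be a finite number >= 0")
  structure(
    list(name = name, reactants = reactants, products = products,
         catalyst = catalyst, rate_constant = rate_constant),
    class = "reaction_spec"
  )
}

#' Reaction network model
#'
#' A declarative container of species and mass-action reactions. All
#' species referenced by reactions must be declared, and a viable
#' network holds at least one nutrient and one metabolite.
#'
#' @param name Model identifier.
#' @param species List of [species_spec()] objects.
#' @param reactions List of [reaction_spec()] objects.
#' @param metadata Optional named list of model-level parameters (for
#'   example the membrane displacement constant `k_d` registered by
#'   [add_lipid_synthesis()]).
#' @return An object of class `network_model`.
#' @export
network_model <- function(name, species, reactions, metadata = list()) {
  stopifnot(is.list(species), is.list(reactions))
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names))
    stop("duplicate species declarations: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  roles <- vapply(species, function(s) s$role, character(1))
  if (!any(roles == "nutrient") || !any(roles == "metabolite"))
    stop("a network needs at least one nutrient and one metabolite")
  for (rx in reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$catalyst)
    missing <- setdiff(refs, sp_names)
    if (length(missing))
      stop("reaction '", rx$name, "' references undeclared species: ",
           paste(missing, collapse = ", "))
  }
  structure(
    list(name = name, species = species, reactions = reactions,
         metadata = metadata),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$name, ": ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

species_names <- function(model) {
  vapply(model$species, function(s) s$name, character(1))
}

get_species <- function(model, name) {
  for (s in model$species) if (s$name == name) return(s)
  stop("species '", name, "' not in model '", model$name, "'")
}

has_species <- function(model, name) name %in% species_names(model)

#' Mass-action rate of a single reaction
#'
#' rate = k * c_catalyst * prod(c_reactant^stoichiometry), in
#' mol/m^3 per hour.
#'
#' @param rxn A [reaction_spec()].
#' @param concentrations Named numeric vector of concentrations
#'   (mol/m^3); must cover reactants and catalyst.
#' @return Non-negative reaction rate.
#' @export
reaction_rate <- function(rxn, concentrations) {
  need <- c(names(rxn$reactants), rxn$catalyst)
  if (!all(need %in% names(concentrations)))
    stop("missing concentrations for: ",
         paste(setdiff(need, names(concentrations)), collapse = ", "))
  if (any(concentrations[need] < 0))
    stop("negative concentration supplied to reaction_rate()")
  rate <- rxn$rate_constant
  if (!is.null(rxn$catalyst)) rate <- rate * concentrations[[rxn$catalyst]]
  for (i in seq_along(rxn$reactants))
    rate <- rate * concentrations[[names(rxn$reactants)[i]]]^rxn$reactants[[i]]
  unname(rate)
}

#' Primitive-moiety composition matrix
#'
#' Each nutrient letter (A, B, C, D) defines a primitive moiety;
#' condensation products carry the moieties of their constituent
#' letters (case-insensitively, so the trapped end-product `acd`
#' carries a, c, d). The condensation leaving group `w` carries none,
#' and the lipid precursor P and lipid L share a `p` moiety.
#'
#' @param model A [network_model()].
#' @return Matrix (species x moieties) of moiety counts.
#' @export
moiety_matrix <- function(model) {
  moieties <- c("a", "b", "c", "d", "p")
  sp <- species_names(model)
  M <- matrix(0, length(sp), length(moieties),
              dimnames = list(sp, moieties))
  for (s in sp) {
    if (s %in% c("P", "L", "L_mem"))
      M[s, "p"] <- 1
    else if (s != "w") {
      letters_of <- strsplit(tolower(s), "")[[1]]
      for (m in c("a", "b", "c", "d"))
        M[s, m] <- sum(letters_of == m)
    }
  }
  M
}

#' Net stoichiometry matrix (products minus reactants)
#'
#' @param model A [network_model()].
#' @return Matrix (species x reactions) of net stoichiometric change.
#' @export
stoichiometry_matrix <- function(model) {
  sp <- species_names(model)
  S <- matrix(0L, length(sp),
              length(model$reactions),
              dimnames = list(sp, vapply(model$reactions,
                                         function(r) r$name, character(1))))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }
  S
}

#' Moiety-closed variant of a network
#'
#' Decay reactions dissipate moieties by construction (their products
#' are the inert sinks `w` / `acd`). For conservation checks, this
#' helper reroutes every reaction that does not balance the primitive
#' moieties so that its products are the constituent nutrient letters
#' of its reactant (e.g. the decay of AB becomes AB -> A + B), leaving
#' balanced reactions untouched.
#'
#' @param model A [network_model()].
#' @return A `network_model` in which every reaction conserves moieties.
#' @export
closed_variant <- function(model) {
  M <- moiety_matrix(model)
  reactions <- lapply(model$reactions, function(rx) {
    S_net <- rep(0, nrow(M)); names(S_net) <- rownames(M)
    S_net[names(rx$reactants)] <- S_net[names(rx$reactants)] - rx$reactants
    S_net[names(rx$products)] <- S_net[names(rx$products)] + rx$products
    if (all(abs(drop(S_net %*% M)) < 1e-12)) return(rx)
    # products = the letter multiset of the reactants
    need <- drop(rx$reactants %*% M[names(rx$reactants), , drop = FALSE])
    prods <- need[need > 0]
    names(prods) <- toupper(names(prods))
    reaction_spec(paste0(rx$name, "_closed"), rx$reactants, prods,
                  catalyst = rx$catalyst, rate_constant = rx$rate_constant)
  })
  network_model(paste0(model$name, "_closed"), model$species, reactions,
                model$metadata)
}

#' Check per-reaction moiety balance
#'
#' @param model A [network_model()].
#' @return Named logical vector, one entry per reaction: does the
#'   reaction conserve every primitive moiety?
#' @export
moiety_balanced <- function(model) {
  M <- moiety_matrix(model)
  S <- stoichiometry_matrix(model)
  res <- apply(abs(t(S) %*% M), 1, max) < 1e-12
  stats::setNames(res, colnames(S))
}
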