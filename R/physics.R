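#' Membrane state
#'
#' Counts of the two lipid species forming the bilayer, with their head
#' areas and the bilayer thickness. Surface area assumes the two
#' leaflets share the lipids evenly: S_mu = (N_l a_l + N_L a_L) / 2.
#'
#' @param N_l,N_L Molecule counts of the primitive (l) and synthesised
#'   (L) membrane lipids.
#' @param alpha_l,alpha_L Head areas in nm^2 (defaults: 0.2 for the
#'   C12 fatty acid, 0.6 for the bulky-head derivative).
#' @param lambda Bilayer thickness in nm (default 3).
#' @param min_lipids Minimum total lipid count for a closed bilayer.
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(N_l, N_L = 0, alpha_l = 0.2, alpha_L = 0.6,
                           lambda = 3, min_lipids = 1000) {
  if (N_l < 0 || N_L < 0) stop("lipid counts must be >= 0")
  if (N_l + N_L < min_lipids)
    stop("total lipid count ", N_l + N_L,
         " below minimum closure count ", min_lipids)
  stopifnot(alpha_l > 0, alpha_L > 0, lambda > 0)
  structure(list(N_l = N_l, N_L = N_L, alpha_l = alpha_l,
                 alpha_L = alpha_L, lambda = lambda,
                 min_lipids = min_lipids),
            class = "membrane_state")
}

#' Bilayer surface area
#'
#' @param m A [membrane_state()].
#' @param unit `"m2"` (default) or `"nm2"`.
#' @return S_mu = (N_l alpha_l + N_L alpha_L) / 2.
#' @export
surface_area <- function(m, unit = c("m2", "nm2")) {
  unit <- match.arg(unit)
  s_nm2 <- (m$N_l * m$alpha_l + m$N_L * m$alpha_L) / 2
  if (s_nm2 <= 0) stop("degenerate membrane: surface area must be > 0")
  if (unit == "nm2") s_nm2 else s_nm2 * .NM2_TO_M2
}

#' Surface fraction covered by the synthesised lipid
#'
#' @param m A [membrane_state()].
#' @return chi_L = N_L alpha_L / (N_l alpha_l + N_L alpha_L), in [0, 1].
#' @export
surface_fraction_L <- function(m) {
  tot <- m$N_l * m$alpha_l + m$N_L * m$alpha_L
  if (tot <= 0) stop("degenerate membrane: no lipids")
  m$N_L * m$alpha_L / tot
}

#' Isotonic internal volume
#'
#' The aqueous lumen adjusts instantaneously to osmotic differences, so
#' the internal volume is the algebraic projection that equalises the
#' total internal osmolyte concentration with the external osmolarity:
#' V_in = sum(N_i, osmotically active) / (N_Avogadro * C_out).
#'
#' @param counts Named vector of internal molecule counts.
#' @param C_out External osmolarity (mol/m^3).
#' @param osmotically_active Logical vector aligned with `counts`
#'   (default: all active). Membrane lipids must not be included.
#' @return Volume in m^3.
#' @export
isotonic_volume <- function(counts, C_out,
                            osmotically_active = rep(TRUE, length(counts))) {
  stopifnot(C_out > 0, length(osmotically_active) == length(counts))
  n <- sum(counts[osmotically_active])
  if (n <= 0)
    stop("degenerate volume: no osmotically active internal solutes")
  n / (.AVOGADRO * C_out)
}

#' Reduced surface
#'
#' Ratio of the actual membrane area to the surface of the sphere that
#' would hold the current internal volume: Phi = S / (36 pi V^2)^(1/3).
#' Phi = 1 for a sphere; Phi >= 2^(1/3) provides enough surface for two
#' equal spheres of half the volume; Phi < 1 means osmotic tension.
#'
#' @param S Surface area (m^2).
#' @param V Volume (m^3).
#' @return Dimensionless reduced surface.
#' @export
reduced_surface <- function(S, V) {
  stopifnot(S > 0, V > 0)
  S / (36 * pi * V^2)^(1 / 3)
}

#' Composition-to-permeability calibration curve
#'
#' Control points (chi, multiplier) interpolated by the unique
#' exact-matching polynomial (evaluated in barycentric Lagrange form).
#' The curve must bracket the composition axis (chi = 0 and chi = 1
#' present) and passes exactly through every control point.
#'
#' @param chi Strictly increasing surface fractions in [0, 1],
#'   including 0 and 1.
#' @param multiplier Positive permeability multipliers (f(0) is the
#'   reference composition; use [fit_permeability_curve()] to build a
#'   normalised curve from assay data).
#' @return An object of class `permeability_curve`.
#' @export
permeability_curve <- function(chi = c(0, 0.375, 1),
                               multiplier = c(1, 10, 2)) {
  stopifnot(length(chi) == length(multiplier), length(chi) >= 2)
  if (anyDuplicated(chi)) stop("duplicate chi control points")
  if (is.unsorted(chi, strictly = TRUE))
    stop("chi control points must be strictly increasing")
  if (chi[1] != 0 || chi[length(chi)] != 1)
    stop("control points must include chi = 0 and chi = 1")
  if (any(multiplier <= 0)) stop("multipliers must be > 0")
  # barycentric weights w_j = 1 / prod_{k != j} (x_j - x_k)
  w <- vapply(seq_along(chi), function(j)
    1 / prod(chi[j] - chi[-j]), numeric(1))
  structure(list(chi = chi, multiplier = multiplier, weights = w),
            class = "permeability_curve")
}

#' Evaluate a permeability curve
#'
#' @param curve A [permeability_curve()].
#' @param x Surface fractions in [0, 1] (no extrapolation).
#' @return Interpolated multiplier values.
#' @export
eval_curve <- function(curve, x) {
  if (any(x < 0 | x > 1))
    stop("composition outside [0, 1]: extrapolation not allowed")
  vapply(x, function(xi) {
    hit <- which(abs(xi - curve$chi) < .Machine$double.eps * 4)
    if (length(hit)) return(curve$multiplier[hit[1]])
    terms <- curve$weights / (xi - curve$chi)
    sum(terms * curve$multiplier) / sum(terms)
  }, numeric(1))
}

#' @export
print.permeability_curve <- function(x, ...) {
  cat("<permeability_curve> degree", length(x$chi) - 1, "through",
      paste0("(", format(x$chi), ", ", format(x$multiplier), ")",
             collapse = " "), "\n")
  invisible(x)
}

#' Effective permeability of a species
#'
#' composition_dependent species scale their base permeability by the
#' calibration curve evaluated at the current surface fraction;
#' constant species ignore composition; impermeable species return 0.
#'
#' @param species A [species_spec()].
#' @param chi Current surface fraction of the synthesised lipid.
#' @param curve A [permeability_curve()].
#' @return Permeability in m/s.
#' @export
effective_permeability <- function(species, chi, curve) {
  switch(species$permeability_class,
         impermeable = 0,
         constant = species$base_permeability,
         composition_dependent =
           species$base_permeability * eval_curve(curve, chi))
}

#' Event rule for division and burst
#'
#' @param phi_divide Division threshold on the reduced surface
#'   (default 2^(1/3): the surface of two equal spheres of half the
#'   mother volume).
#' @param epsilon_burst Osmotic-tension tolerance: burst when
#'   Phi <= 1 - epsilon (default 0.1).
#' @return An object of class `event_rule`.
#' @export
event_rule <- function(phi_divide = 2^(1 / 3), epsilon_burst = 0.1) {
  stopifnot(epsilon_burst > 0, epsilon_burst < 1, phi_divide > 1)
  structure(list(phi_divide = phi_divide, epsilon_burst = epsilon_burst),
            class = "event_rule")
}

#' Classify the current morphological event
#'
#' @param phi Reduced surface (> 0).
#' @param rule An [event_rule()].
#' @return `"divide"`, `"burst"`, or `"none"`. Division takes
#'   precedence (unreachable with default thresholds).
#' @export
check_event <- function(phi, rule = event_rule()) {
  stopifnot(phi > 0)
  if (phi >= rule$phi_divide) "divide"
  else if (phi <= 1 - rule$epsilon_burst) "burst"
  else "none"
}

#' Protocell state
#'
#' Bundles the internal aqueous counts, the membrane state and the
#' simulation clock; derived quantities (V_in, S_mu, Phi, chi) are
#' recomputed by [update_derived()].
#'
#' @param counts Named vector of internal molecule counts.
#' @param membrane A [membrane_state()].
#' @param C_out External osmolarity (mol/m^3).
#' @param osmotically_active Named logical vector or NULL (all active).
#' @param t Simulation time (h).
#' @param lineage_id,generation Lineage bookkeeping.
#' @return An object of class `protocell_state` with derived fields
#'   `V_in`, `S_mu`, `Phi`, `chi_L`.
#' @export
protocell_state <- function(counts, membrane, C_out = 100,
                            osmotically_active = NULL, t = 0,
                            lineage_id = 1L, generation = 0L) {
  if (any(counts < 0)) stop("negative internal counts")
  if (is.null(osmotically_active))
    osmotically_active <- stats::setNames(rep(TRUE, length(counts)),
                                          names(counts))
  st <- structure(
    list(t = t, counts = counts, membrane = membrane, C_out = C_out,
         osmotically_active = osmotically_active[names(counts)],
         lineage_id = lineage_id, generation = generation),
    class = "protocell_state")
  update_derived(st)
}

#' Recompute derived geometry of a protocell state
#'
#' Projects the volume back onto the isotonic constraint and refreshes
#' S_mu, Phi and chi_L.
#'
#' @param state A [protocell_state()].
#' @return The state with current `V_in`, `S_mu`, `Phi`, `chi_L`.
#' @export
update_derived <- function(state) {
  state$V_in <- isotonic_volume(state$counts, state$C_out,
                                state$osmotically_active)
  state$S_mu <- surface_area(state$membrane)
  state$Phi <- reduced_surface(state$S_mu, state$V_in)
  state$chi_L <- surface_fraction_L(state$membrane)
  state
}

#' @export
print.protocell_state <- function(x, ...) {
  cat(sprintf(
    "<protocell_state> t = %.3g h, gen %d: Phi = %.4f, chi_L = %.4f,\n  V_in = %.4g m^3, S_mu = %.4g m^2, %d aqueous species\n",
    x$t, x$generation, x$Phi, x$chi_L, x$V_in, x$S_mu, length(x$counts)))
  invisible(x)
}

#' Passive transport fluxes across the membrane
#'
#' For each permeant species X: influx = P_X S_mu c_out,X N_A and
#' efflux = P_X S_mu N_X / V_in, in molecules per second; both reported
#' separately (the stochastic engine needs separate propensities).
#'
#' @param state A [protocell_state()] with current derived geometry.
#' @param env Named environmental concentrations (mol/m^3); species
#'   absent from `env` are treated as absent outside (influx 0).
#' @param species_table List of [species_spec()] for the species in
#'   `state$counts`.
#' @param curve A [permeability_curve()].
#' @return Data frame: species, permeability (m/s), influx, efflux
#'   (molecules/s).
#' @export
transport_fluxes <- function(state, env, species_table, curve) {
  rows <- lapply(species_table, function(sp) {
    P <- effective_permeability(sp, state$chi_L, curve)
    c_out <- if (sp$name %in% names(env)) env[[sp$name]] else
      if (is.finite(sp$env_concentration)) sp$env_concentration else 0
    data.frame(species = sp$name, permeability = P,
               influx = P * state$S_mu * c_out * .AVOGADRO,
               efflux = P * state$S_mu *
                 (state$counts[[sp$name]] / state$V_in))
  })
  do.call(rbind, rows)
}

#' Lipid exchange event propensities
#'
#' Four membrane channels (propensities per hour): uptake of l from the
#' environment (k_in S_mu c_l,env N_A), release of membrane l
#' (k_out N_l), insertion of internally synthesised aqueous L
#' (k_in S_mu [L]_aq N_A) and the atomic displacement of one membrane L
#' by one environmental l (k_d N_L), which conserves total lipid count.
#'
#' @param state A [protocell_state()] (derived geometry current).
#' @param c_l_env Environmental free-monomer concentration of l
#'   (mol/m^3).
#' @param k_in Association rate constant (m/s, applied to both lipids).
#' @param k_out Dissociation rate constant of membrane l (per hour).
#' @param k_d Displacement rate constant (per hour).
#' @param N_L_aq Aqueous count of the synthesised lipid L.
#' @return Named numeric vector of propensities (events per hour).
#' @export
lipid_exchange_propensities <- function(state, c_l_env, k_in, k_out, k_d,
                                        N_L_aq = state$counts[["L"]]) {
  stopifnot(k_in >= 0, k_out >= 0, k_d >= 0)
  kin_h <- k_in * .PER_S_TO_PER_H
  c(l_uptake = kin_h * state$S_mu * c_l_env * .AVOGADRO,
    l_release = k_out * state$membrane$N_l,
    L_insertion = kin_h * state$S_mu * (N_L_aq / state$V_in),
    displacement = k_d * state$membrane$N_L)
}

#' Divide a protocell into two daughters
#'
#' Membrane lipids are split evenly per species (an odd remainder goes
#' to a random daughter); every internal aqueous count is partitioned
#' binomially with p = 1/2; each daughter's volume is re-projected onto
#' the isotonic constraint. Daughter sums equal the mother exactly.
#'
#' @param state A [protocell_state()] at (or above) the division
#'   threshold.
#' @return List of two `protocell_state` daughters.
#' @export
divide <- function(state) {
  counts1 <- vapply(state$counts, function(n)
    stats::rbinom(1L, as.integer(round(n)), 0.5), numeric(1))
  counts2 <- round(state$counts) - counts1
  # even split; an odd remainder goes to a random daughter
  split_even <- function(n) {
    n <- round(n)
    half <- n %/% 2
    if (n %% 2 == 1) {
      if (stats::runif(1) < 0.5) c(half + 1, half) else c(half, half + 1)
    } else c(half, half)
  }
  l_split <- split_even(state$membrane$N_l)
  L_split <- split_even(state$membrane$N_L)
  mk <- function(i, counts) {
    mem <- membrane_state(l_split[i], L_split[i],
                          state$membrane$alpha_l, state$membrane$alpha_L,
                          state$membrane$lambda, min_lipids = 1)
    protocell_state(counts, mem, state$C_out, state$osmotically_active,
                    t = state$t,
                    lineage_id = state$lineage_id * 2L + (i - 1L),
                    generation = state$generation + 1L)
  }
  list(mk(1L, counts1), mk(2L, counts2))
}
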