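#' Physics parameter set for the protocell compartment
#'
#' Geometry, osmotic, membrane-exchange and event parameters shared by
#' both engines.
#'
#' @param r0 Initial vesicle radius (nm). The full-scale default is
#'   200, matching the extruded vesicle populations of leakage assays;
#'   the stochastic engine is usually run at a reduced scale.
#' @param C_out External osmolarity (mol/m^3); 100 matches the 100 mM
#'   assay buffer.
#' @param curve A [permeability_curve()] mapping the surface fraction
#'   of the synthesised lipid to a permeability multiplier.
#' @param alpha_l,alpha_L Head areas (nm^2).
#' @param lambda Bilayer thickness (nm).
#' @param k_in Lipid association rate constant (m/s).
#' @param c_l_env Environmental free monomer concentration of the
#'   primitive lipid (mol/m^3).
#' @param k_out Dissociation rate constant of membrane l (per hour);
#'   `NULL` selects the value that balances uptake and release for a
#'   pure-l membrane of any size (so l exchange alone causes no net
#'   drift).
#' @param phi_divide,epsilon_burst Event thresholds, see [event_rule()].
#' @param min_lipids Minimum lipid count for a closed bilayer.
#' @param fixed_chi Membrane composition used in fixed-compartment mode.
#' @return A list of physics parameters (class `protocell_physics`).
#' @export
default_physics <- function(r0 = 200, C_out = 100,
                            curve = permeability_curve(),
                            alpha_l = 0.2, alpha_L = 0.6, lambda = 3,
                            k_in = 1e-9, c_l_env = 1e-4, k_out = NULL,
                            phi_divide = 2^(1 / 3), epsilon_burst = 0.1,
                            min_lipids = 1000, fixed_chi = 0) {
  if (is.null(k_out))
    k_out <- k_in * .PER_S_TO_PER_H * (alpha_l * .NM2_TO_M2 / 2) *
      c_l_env * .AVOGADRO
  structure(list(r0 = r0, C_out = C_out, curve = curve,
                 alpha_l = alpha_l, alpha_L = alpha_L, lambda = lambda,
                 k_in = k_in, c_l_env = c_l_env, k_out = k_out,
                 phi_divide = phi_divide, epsilon_burst = epsilon_burst,
                 min_lipids = min_lipids, fixed_chi = fixed_chi),
            class = "protocell_physics")
}

.is_decay <- function(rx) {
  is.null(rx$catalyst) && length(rx$reactants) == 1L &&
    sum(rx$reactants) == 1L
}

#' Compile a network + physics into an engine-ready system
#'
#' Flattens the declarative model into the matrix/vector form consumed
#' by the C++ engines. An inert internal osmolyte `X` is appended
#' automatically (it holds the buffer that makes the initial state
#' isotonic). Membrane lipids are carried as two extra state entries
#' after the aqueous species.
#'
#' @param model A [network_model()].
#' @param physics A [default_physics()] list.
#' @param mode `"protocell"` (dynamic volume/surface, events) or
#'   `"fixed"` (fixed compartment of radius `r0`, composition
#'   `fixed_chi`).
#' @param decay_mult Multiplier applied to the rate constants of
#'   uncatalysed unimolecular (decay) reactions.
#' @param perm_mult Multiplier applied to the base permeability of
#'   composition-dependent species (the nutrient-permeability axis of
#'   the steady-state maps).
#' @param k_d Override for the displacement constant (default: model
#'   metadata, else 0).
#' @param closed Zero out every permeability and the lipid-exchange
#'   environment coupling: a fully closed system, used by the
#'   conservation checks.
#' @return A list understood by the C++ engines (class
#'   `protocell_system`).
#' @export
compile_system <- function(model, physics = default_physics(),
                           mode = c("protocell", "fixed"),
                           decay_mult = 1, perm_mult = 1, k_d = NULL,
                           closed = FALSE) {
  mode <- match.arg(mode)
  aq <- Filter(function(s) s$role != "membrane_lipid", model$species)
  if (!any(vapply(aq, function(s) s$role, character(1)) ==
           "inert_osmolyte"))
    aq <- c(aq, list(species_spec("X", "inert_osmolyte")))
  nm <- vapply(aq, function(s) s$name, character(1))
  n_sp <- length(aq)
  n_rxn <- length(model$reactions)
  nu_r <- matrix(0L, n_sp, n_rxn, dimnames = list(nm, NULL))
  nu_p <- matrix(0L, n_sp, n_rxn, dimnames = list(nm, NULL))
  cat_idx <- integer(n_rxn)
  k <- numeric(n_rxn)
  for (j in seq_len(n_rxn)) {
    rx <- model$reactions[[j]]
    nu_r[names(rx$reactants), j] <- rx$reactants
    nu_p[names(rx$products), j] <- rx$products
    cat_idx[j] <- if (is.null(rx$catalyst)) -1L else
      match(rx$catalyst, nm) - 1L
    k[j] <- rx$rate_constant * if (.is_decay(rx)) decay_mult else 1
  }
  pc_map <- c(impermeable = 0L, constant = 1L, composition_dependent = 2L)
  perm_class <- pc_map[vapply(aq, function(s) s$permeability_class,
                              character(1))]
  base_P <- vapply(aq, function(s) s$base_permeability, numeric(1))
  base_P[perm_class == 2L] <- base_P[perm_class == 2L] * perm_mult
  if (closed) base_P[] <- 0
  env <- vapply(aq, function(s)
    if (is.finite(s$env_concentration)) s$env_concentration else 0,
    numeric(1))
  osmo <- as.integer(vapply(aq, function(s) s$osmotically_active,
                            logical(1)))
  aqL <- match("L", nm, nomatch = 0L) - 1L
  lipids <- isTRUE(model$metadata$lipid_synthesis)
  if (is.null(k_d))
    k_d <- if (!is.null(model$metadata$k_d)) model$metadata$k_d else 0
  curve <- physics$curve
  r0_m <- physics$r0 * .NM_TO_M
  structure(list(
    nu_r = nu_r, nu_p = nu_p, cat = as.integer(cat_idx), k = k,
    perm_class = unname(perm_class), base_P = unname(base_P),
    env = unname(env), osmo = osmo,
    chi_x = curve$chi, chi_f = curve$multiplier, chi_w = curve$weights,
    aqL = as.integer(aqL),
    alpha_l = physics$alpha_l * .NM2_TO_M2,
    alpha_L = physics$alpha_L * .NM2_TO_M2,
    k_in = if (closed) 0 else physics$k_in,
    k_out = if (closed) 0 else physics$k_out,
    k_d = if (closed) 0 else k_d,
    c_l_env = if (closed) 0 else physics$c_l_env,
    C_out = physics$C_out,
    phi_divide = physics$phi_divide, eps_burst = physics$epsilon_burst,
    mode = if (mode == "protocell") 1L else 0L,
    fixedV = .sphere_volume(r0_m), fixedS = .sphere_area(r0_m),
    fixed_chi = physics$fixed_chi, lipids = lipids,
    species = nm, model_name = model$name, physics = physics),
    class = "protocell_system")
}

#' Initial state vector for a compiled system
#'
#' Nutrients (and the precursor) start at their environmental
#' concentrations, metabolites at a small seed concentration, and the
#' inert osmolyte X absorbs the slack so the initial spherical vesicle
#' of radius `r0` is exactly isotonic with `C_out`. In protocell mode
#' the membrane starts as pure primitive lipid l sized to the same
#' sphere.
#'
#' @param sys A [compile_system()] result.
#' @param metab_seed Named seed concentrations (mol/m^3) for
#'   metabolites (defaults: 1 for each of AB, AC, ACD when present).
#'   Use 0 to start from the dead state.
#' @param r0 Initial radius (nm), defaulting to the physics value.
#' @return Numeric state vector (aqueous counts, then N_l, N_L in
#'   protocell mode) with names.
#' @export
initial_state <- function(sys, metab_seed = NULL, r0 = NULL) {
  ph <- sys$physics
  if (is.null(r0)) r0 <- ph$r0
  r0_m <- r0 * .NM_TO_M
  V0 <- if (sys$mode == 1L) .sphere_volume(r0_m) else sys$fixedV
  target <- V0 * .AVOGADRO * ph$C_out
  if (is.null(metab_seed)) {
    metab_seed <- c(AB = 1, AC = 1, ACD = 1)
    metab_seed <- metab_seed[names(metab_seed) %in% sys$species]
  }
  conc <- stats::setNames(numeric(length(sys$species)), sys$species)
  conc[sys$env > 0] <- sys$env[sys$env > 0]
  conc[names(metab_seed)] <- metab_seed
  counts <- round(conc * V0 * .AVOGADRO)
  slack <- target - sum(counts[as.logical(sys$osmo)])
  if (slack < 0) {
    if (sys$mode == 1L)
      stop("initial solutes exceed C_out; lower seeds or env levels")
    slack <- 0  # fixed compartment: osmotic budget not binding
  }
  counts[["X"]] <- counts[["X"]] + round(slack)
  if (sys$mode == 1L) {
    S0 <- .sphere_area(r0_m)
    N_l <- round(2 * S0 / sys$alpha_l)
    counts <- c(counts, N_l = N_l, N_L = 0)
  }
  counts
}

.traj_from_raw <- function(sys, raw) {
  y <- raw$y
  nmy <- sys$species
  if (sys$mode == 1L) nmy <- c(nmy, "N_l", "N_L")
  colnames(y) <- nmy
  g <- raw$geom
  colnames(g) <- c("V_in", "S_mu", "chi_L", "Phi")
  div <- data.frame(
    generation = seq_along(raw$div_t),
    t_division = raw$div_t, T_div = raw$div_interval,
    chi_L = raw$div_chi, V_in = raw$div_V, S_mu = raw$div_S)
  if (length(raw$div_t) && !is.null(raw$div_states)) {
    st <- raw$div_states
    colnames(st) <- nmy
    div <- cbind(div, st)
  }
  structure(list(
    times = raw$times, counts = y, geom = as.data.frame(g),
    divisions = div, outcome = raw$outcome, t_end = raw$t_end,
    species = sys$species, model = sys$model_name),
    class = "protocell_trajectory")
}

#' Deterministic integration of a compiled system
#'
#' Adaptive Dormand-Prince RK45 over molecule counts. In protocell
#' mode, crossings of the reduced surface through the division or burst
#' threshold are located by bisection; a division deterministically
#' halves every extensive quantity (the stochastic engine owns
#' partition noise) and is recorded; a burst terminates the lineage.
#'
#' @param sys A [compile_system()] result.
#' @param y0 Initial state ([initial_state()] by default).
#' @param t_span Length-2 vector (hours).
#' @param n_out Number of uniformly spaced output times.
#' @param rtol,atol Relative and absolute (molecule-count) tolerances.
#' @param max_steps Step budget before giving up.
#' @param events Apply division/burst event logic (protocell mode).
#' @return A `protocell_trajectory`: output grid, count matrix, derived
#'   geometry, division records and outcome.
#' @export
integrate_system <- function(sys, y0 = initial_state(sys),
                             t_span = c(0, 100), n_out = 201,
                             rtol = 1e-8, atol = 1e-3,
                             max_steps = 5e7, events = TRUE) {
  raw <- cpp_integrate(unclass(sys), as.numeric(y0), t_span[1],
                       t_span[2], as.integer(n_out), rtol, atol,
                       max_steps, events, TRUE)
  if (raw$outcome == "max_steps")
    warning("integrator stopped at the step budget (t = ",
            signif(raw$t_end, 6), " h)")
  .traj_from_raw(sys, raw)
}

#' @export
print.protocell_trajectory <- function(x, ...) {
  cat("<protocell_trajectory> ", x$model, ": t in [",
      signif(x$times[1], 4), ", ", signif(x$t_end, 6), "] h, ",
      nrow(x$divisions), " divisions, outcome: ", x$outcome, "\n",
      sep = "")
  invisible(x)
}

#' Steady state of a fixed compartment
#'
#' Long relaxation with the deterministic engine followed by Newton
#' root-polishing on the mass-action + transport right-hand side.
#' Non-convergence is reported through the `converged` flag (scan cells
#' flag it rather than raising).
#'
#' @param sys A fixed-mode [compile_system()] result.
#' @param y0 Initial counts.
#' @param t_relax Relaxation horizon (hours).
#' @param tol Residual target, infinity norm of the concentration
#'   derivative (mol/m^3 per hour).
#' @return List: `concentrations` (mol/m^3), `counts`, `residual`,
#'   `converged`.
#' @export
steady_state <- function(sys, y0 = initial_state(sys), t_relax = 4000,
                         tol = 1e-10) {
  stopifnot(sys$mode == 0L)
  VN <- sys$fixedV * .AVOGADRO
  # pure accumulators (impermeable product-only sinks such as acd, and
  # the inert osmolyte) never stop growing in a fixed compartment and
  # are excluded from the steady-state residual and the Newton solve
  consumed <- rowSums(sys$nu_r) > 0
  catalysing <- seq_along(sys$species) %in% (sys$cat + 1L)
  dyn <- which(consumed | catalysing | sys$perm_class != 0L)
  nd <- length(dyn)
  f <- function(y) cpp_rhs(unclass(sys), y)[dyn] / VN  # conc/hour
  jac <- function(y) {
    J <- matrix(0, nd, nd)
    for (i in seq_len(nd)) {
      h <- max(abs(y[dyn[i]]) * 1e-6, 1e-2)
      yp <- y; yp[dyn[i]] <- yp[dyn[i]] + h
      ym <- y; ym[dyn[i]] <- ym[dyn[i]] - h
      J[, i] <- (f(yp) - f(ym)) / (2 * h)
    }
    J * VN  # d(conc rate)/d(conc): counts cancel
  }
  polish <- function(y) {
    res <- max(abs(f(y)))
    for (it in seq_len(60)) {
      if (res < tol) break
      fy <- f(y)
      J <- jac(y) / VN
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        y_new <- y
        y_new[dyn] <- pmax(y[dyn] + lambda * step, 0)
        if (max(abs(f(y_new))) < res || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      y[dyn] <- pmax(y[dyn] + lambda * step, 0)
      res_new <- max(abs(f(y)))
      if (res_new >= res * (1 - 1e-12) && it > 5) {
        res <- res_new; break
      }
      res <- res_new
    }
    list(y = y, res = res)
  }
  y <- y0
  res <- Inf
  # Newton converges to any root, including unstable ones (a branch
  # lingering near an unstable dead state gets polished onto it); if
  # the polished root is linearly unstable, kick and re-relax.
  for (attempt in seq_len(4)) {
    traj <- integrate_system(sys, y, c(0, t_relax), n_out = 2,
                             events = FALSE)
    p <- polish(traj$counts[nrow(traj$counts), ])
    y <- p$y; res <- p$res
    ev <- tryCatch(max(Re(eigen(jac(y), only.values = TRUE)$values)),
                   error = function(e) -Inf)
    if (!is.finite(ev) || ev < 1e-6) break
    y[dyn] <- y[dyn] + 1e-3 * VN  # +1e-3 mol/m^3 on dynamic species
  }
  list(concentrations = stats::setNames(y / VN, sys$species),
       counts = stats::setNames(y, sys$species),
       residual = res, converged = res < tol * 10)
}

.metabolite_names <- function(model) {
  vapply(Filter(function(s) s$role == "metabolite", model$species),
         function(s) s$name, character(1))
}

#' Two-parameter steady-state / bistability scan
#'
#' For every (catalyst decay rate, nutrient permeability multiplier)
#' grid cell the fixed compartment is relaxed from each branch start
#' (by default a near-dead and an elevated metabolite seed), the steady
#' states are classified as dead or viable, and the number of distinct
#' attractors is counted (two states are the same attractor when their
#' metabolite concentrations differ by < `attractor_tol` relative).
#'
#' @param model A [network_model()] (PM1 or PM2).
#' @param physics A [default_physics()] list.
#' @param decay_grid Strictly increasing decay-rate values (per hour),
#'   applied to all decay reactions.
#' @param perm_grid Strictly increasing multipliers on the nutrient
#'   base permeability.
#' @param branch_seeds List of named metabolite seed concentrations,
#'   one per branch (>= 2 branches).
#' @param t_relax Relaxation horizon per cell (hours).
#' @param attractor_tol Relative tolerance identifying attractors.
#' @param dead_tol Metabolite concentration (mol/m^3) below which a
#'   state counts as dead.
#' @return Object of class `steady_state_map`: tidy data frame
#'   `$cells` (one row per cell x branch x metabolite) and summary
#'   `$summary` (one row per cell with `n_attractors`, `ss_AB` per
#'   branch).
#' @export
bistability_scan <- function(model, physics = default_physics(),
                             decay_grid = 10^seq(-2, 0, length.out = 10),
                             perm_grid = 10^seq(-1, 1, length.out = 10),
                             branch_seeds = list(
                               low = c(AB = 1e-4, AC = 1e-4, ACD = 1e-4),
                               high = c(AB = 20, AC = 20, ACD = 20)),
                             t_relax = 4000, attractor_tol = 1e-2,
                             dead_tol = 1e-6) {
  stopifnot(!is.unsorted(decay_grid, strictly = TRUE),
            !is.unsorted(perm_grid, strictly = TRUE),
            length(branch_seeds) >= 2)
  metab <- .metabolite_names(model)
  cells <- list(); summ <- list(); ci <- 1L
  for (d in decay_grid) for (p in perm_grid) {
    sys <- compile_system(model, physics, mode = "fixed",
                          decay_mult = d /
                            model$reactions[[
                              which(vapply(model$reactions, .is_decay,
                                           logical(1)))[1]]]$rate_constant,
                          perm_mult = p)
    states <- list()
    cell_rows <- list()
    for (b in seq_along(branch_seeds)) {
      seed <- branch_seeds[[b]]
      seed <- seed[names(seed) %in% sys$species]
      y0 <- initial_state(sys, metab_seed = seed)
      ss <- steady_state(sys, y0, t_relax = t_relax)
      states[[b]] <- ss
      cell_rows[[b]] <- data.frame(
        decay_rate = d, permeability = p,
        branch = names(branch_seeds)[b] %||% as.character(b),
        species = metab,
        steady_value = unname(ss$concentrations[metab]),
        converged = ss$converged)
    }
    mm <- lapply(states, function(s) s$concentrations[metab])
    is_dead <- vapply(mm, function(x) all(x < dead_tol), logical(1))
    n_attr <- if (all(is_dead)) 0L else {
      uniq <- list(mm[[1]])
      for (x in mm[-1]) {
        new <- TRUE
        for (u in uniq) {
          rel <- max(abs(x - u) / pmax(abs(x), abs(u), dead_tol))
          if (rel < attractor_tol) { new <- FALSE; break }
        }
        if (new) uniq[[length(uniq) + 1L]] <- x
      }
      length(uniq)
    }
    cells[[ci]] <- do.call(rbind, cell_rows)
    cells[[ci]]$n_attractors <- n_attr
    ab <- vapply(states, function(s) s$concentrations[["AB"]],
                 numeric(1))
    summ[[ci]] <- data.frame(
      decay_rate = d, permeability = p, n_attractors = n_attr,
      ss_AB_low = ab[1], ss_AB_high = ab[length(ab)],
      bistable = n_attr >= 2L)
    ci <- ci + 1L
  }
  structure(list(cells = do.call(rbind, cells),
                 summary = do.call(rbind, summ),
                 model = model$name),
            class = "steady_state_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.steady_state_map <- function(x, ...) {
  cat("<steady_state_map> ", x$model, ": ", nrow(x$summary),
      " cells, ", sum(x$summary$bistable), " bistable\n", sep = "")
  invisible(x)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Channels are the mass-action reactions, per-species transport influx
#' and efflux, and the four lipid-exchange channels. After every firing
#' the volume is re-projected onto the isotonic constraint, the surface
#' and reduced surface recomputed and the event rule applied. At a
#' division, every aqueous count is partitioned binomially (p = 1/2),
#' membrane lipids split evenly (odd remainder randomised), and one
#' daughter is followed (seeded uniform choice). A burst stops the
#' simulation with outcome `"burst"`.
#'
#' @param sys A [compile_system()] result.
#' @param y0 Initial counts, see [initial_state()].
#' @param t_end Final time (hours).
#' @param seed Integer RNG seed (all stochasticity flows from it).
#' @param n_out Uniform output grid size.
#' @param max_events Event budget.
#' @param events Apply division/burst logic.
#' @return A `protocell_trajectory` with additional fields:
#'   `division_partitions` (mother/daughter snapshots), `n_events`,
#'   `max_iso_dev` (worst relative deviation of the internal total
#'   concentration from C_out seen after any event).
#' @export
run_ssa <- function(sys, y0 = initial_state(sys), t_end = 100,
                    seed = 1L, n_out = 201, max_events = 5e7,
                    events = TRUE) {
  set.seed(seed)
  raw <- cpp_ssa(unclass(sys), as.numeric(y0), 0, t_end,
                 as.integer(n_out), max_events, events)
  out <- .traj_from_raw(sys, raw)
  nmy <- colnames(out$counts)
  part <- list(mother = raw$div_mother, daughter1 = raw$div_daughter1,
               daughter2 = raw$div_daughter2,
               followed = raw$div_follow)
  for (nm in c("mother", "daughter1", "daughter2"))
    colnames(part[[nm]]) <- nmy
  out$division_partitions <- part
  out$n_events <- raw$n_events
  out$max_iso_dev <- raw$max_iso_dev
  out$final_state <- stats::setNames(raw$final_state, nmy)
  out$seed <- seed
  out
}

#' Division-time statistics over a stationary window
#'
#' @param records Division-record data frame (a `$divisions` element)
#'   with columns `T_div` and `chi_L`.
#' @param window Number of trailing generations to average (default
#'   10, the stationary-regime window used throughout).
#' @return List: `mean_T_div`, `sd_T_div`, `mean_chi_L`, `n`.
#' @export
division_stats <- function(records, window = 10) {
  if (nrow(records) < window)
    stop("insufficient data: ", nrow(records),
         " division records, need ", window)
  tail_rec <- utils::tail(records, window)
  list(mean_T_div = mean(tail_rec$T_div),
       sd_T_div = stats::sd(tail_rec$T_div),
       mean_chi_L = mean(tail_rec$chi_L),
       n = window)
}

#' Project population growth from a division time
#'
#' Under non-limiting resources a lineage dividing every `T_div` time
#' units projects to N(t) = 2^(t / T_div) descendants of one ancestor.
#'
#' @param T_div Division time (> 0), any time unit.
#' @param t_grid Times at which to evaluate (same unit).
#' @return Data frame `time`, `population`.
#' @export
project_population <- function(T_div, t_grid) {
  stopifnot(T_div > 0)
  data.frame(time = t_grid, population = 2^(t_grid / T_div))
}
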