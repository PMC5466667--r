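# The four computational experiments, chained from the module layer.
# CSVs are the output contract; returned objects carry the same data.

.write_if <- function(df, out, name) {
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  }
}

#' Steady-state / bistability map experiment
#'
#' Runs [bistability_scan()] for the chosen network over the
#' decay-rate x nutrient-permeability grid and reports the fraction of
#' bistable cells.
#'
#' @param model `"pm1"`, `"pm2"` or a [network_model()].
#' @param decay_grid,perm_grid Scan axes (see [bistability_scan()]).
#' @param physics Physics parameters.
#' @param out Optional output directory for the tidy CSVs.
#' @param t_relax Relaxation horizon per cell (hours).
#' @return The [bistability_scan()] map, with `$bistable_fraction`.
#' @export
exp_steady_map <- function(model = "pm2",
                           decay_grid = 10^seq(-2, 0, length.out = 10),
                           perm_grid = 10^seq(-1, 1, length.out = 10),
                           physics = default_physics(), out = NULL,
                           t_relax = 3000) {
  if (is.character(model))
    model <- if (model == "pm1") build_pm1() else build_pm2()
  map <- bistability_scan(model, physics, decay_grid, perm_grid,
                          t_relax = t_relax)
  map$bistable_fraction <- mean(map$summary$bistable)
  .write_if(map$cells, out, paste0(model$name, "_steady_cells.csv"))
  .write_if(map$summary, out, paste0(model$name, "_steady_summary.csv"))
  map
}

#' Steady-state concentrations of the encapsulated network
#'
#' Relaxes the fixed-compartment variant of a model (at the membrane
#' composition chi = 0, i.e. before any lipid conversion) and returns
#' the steady concentrations of every species that is not a pure
#' accumulator. Growth-and-division runs start from this chemical
#' steady state so that the morphology dynamics are not confounded by
#' the metabolic start-up transient.
#'
#' @param model A [network_model()].
#' @param physics Physics parameters.
#' @param perm_mult Nutrient-permeability multiplier, matching the run.
#' @param t_relax Relaxation horizon (hours).
#' @return Named concentrations (mol/m^3), accumulators (L, acd, X)
#'   excluded.
#' @export
equilibrium_concentrations <- function(model,
                                       physics = default_physics(),
                                       perm_mult = 1, t_relax = 3000) {
  msys <- compile_system(model, physics, mode = "fixed",
                         perm_mult = perm_mult)
  seed <- c(AB = 3, AC = 3, ACD = 3)
  y0 <- initial_state(msys,
                      metab_seed = seed[names(seed) %in% msys$species])
  ss <- steady_state(msys, y0, t_relax = t_relax)
  conc <- pmax(ss$concentrations, 0)
  conc[setdiff(names(conc), c("L", "acd", "X"))]
}

#' Run one growth-and-division simulation
#'
#' Shared runner behind the reproduction and selection experiments.
#'
#' @param model A lipid-synthesising [network_model()] (see
#'   [add_lipid_synthesis()]).
#' @param physics Physics parameters.
#' @param engine `"ode"` (deterministic, halving divisions) or
#'   `"ssa"` (exact stochastic, binomial partitioning).
#' @param t_end Horizon (hours).
#' @param init `"equilibrate"` (default: start from the encapsulated
#'   network's steady state, see [equilibrium_concentrations()]) or
#'   `"seed"` (start from `metab_seed`).
#' @param metab_seed Initial metabolite concentrations (mol/m^3) for
#'   `init = "seed"`.
#' @param seed RNG seed (ssa engine).
#' @param perm_mult Uniform multiplier on nutrient permeability.
#' @param k_d Override of the displacement constant.
#' @param r0 Initial radius (nm); defaults to the physics value
#'   ("ode") or a reduced desk-scale radius of 60 nm ("ssa").
#' @param n_out Output grid size.
#' @param y0 Explicit initial state (overrides `init`).
#' @return A `protocell_trajectory`.
#' @export
run_reproduction <- function(model, physics = default_physics(),
                             engine = c("ode", "ssa"), t_end = 600,
                             init = c("equilibrate", "seed"),
                             metab_seed = c(AB = 3, AC = 3, ACD = 3),
                             seed = 1L, perm_mult = 1, k_d = NULL,
                             r0 = NULL, n_out = 401, y0 = NULL) {
  engine <- match.arg(engine)
  init <- match.arg(init)
  sys <- compile_system(model, physics, mode = "protocell",
                        perm_mult = perm_mult, k_d = k_d)
  if (is.null(r0)) r0 <- if (engine == "ode") physics$r0 else 60
  if (is.null(y0)) {
    conc0 <- if (init == "equilibrate")
      equilibrium_concentrations(model, physics, perm_mult)
    else metab_seed[names(metab_seed) %in% sys$species]
    # a composition richer than the osmotic budget cannot be held
    # isotonically; scale it into the budget and let the dynamics
    # find their own partition of C_out
    if (sum(conc0) > 0.95 * physics$C_out)
      conc0 <- conc0 * 0.95 * physics$C_out / sum(conc0)
    y0 <- initial_state(sys, metab_seed = conc0, r0 = r0)
  }
  if (engine == "ode")
    integrate_system(sys, y0, c(0, t_end), n_out = n_out)
  else
    run_ssa(sys, y0, t_end = t_end, seed = seed, n_out = n_out)
}

#' Stationary reproduction experiment
#'
#' Runs the lipid-synthesising protocell and reports the stationary
#' division time, the membrane-composition asymptote and metabolite
#' stationarity diagnostics. A burst outcome is reported, not raised.
#'
#' @param model `"pm1"`, `"pm2"` or a lipid-synthesising
#'   [network_model()].
#' @param k_d Displacement constant (per hour).
#' @param engine,t_end,seed,physics,out See [run_reproduction()].
#' @param window Stationary window (generations) for the statistics.
#' @return List: `trajectory`, `stats` (NULL if too few divisions),
#'   `chi_asymptote`, `outcome`.
#' @export
exp_reproduction <- function(model = "pm2", k_d = 0,
                             engine = c("ode", "ssa"), t_end = 600,
                             seed = 1L, physics = default_physics(),
                             out = NULL, window = 10) {
  engine <- match.arg(engine)
  if (is.character(model)) {
    ps <- default_parameter_set(model, "reproducing")
    model <- ps$model
  }
  traj <- run_reproduction(model, physics, engine, t_end = t_end,
                           seed = seed, k_d = k_d)
  stats <- if (nrow(traj$divisions) >= window)
    division_stats(traj$divisions, window) else NULL
  chi_asym <- if (nrow(traj$divisions) >= 1)
    utils::tail(traj$divisions$chi_L, 1) else
      utils::tail(traj$geom$chi_L, 1)
  .write_if(traj$divisions, out,
            sprintf("%s_kd%g_divisions.csv", traj$model, k_d))
  .write_if(cbind(t = traj$times, as.data.frame(traj$counts),
                  traj$geom), out,
            sprintf("%s_kd%g_trajectory.csv", traj$model, k_d))
  if (!is.null(out)) {
    # run-metadata sidecar: everything needed to reproduce the run
    meta <- list(model = traj$model, engine = engine, seed = seed,
                 k_d = k_d, t_end = t_end, outcome = traj$outcome,
                 physics = list(
                   r0 = physics$r0, C_out = physics$C_out,
                   curve = list(chi = physics$curve$chi,
                                multiplier = physics$curve$multiplier),
                   k_in = physics$k_in, k_out = physics$k_out,
                   c_l_env = physics$c_l_env))
    jsonlite::write_json(
      meta, file.path(out, sprintf("%s_kd%g_meta.json", traj$model,
                                   k_d)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(trajectory = traj, stats = stats, chi_asymptote = chi_asym,
       outcome = traj$outcome)
}

#' Selection experiment: division time across membrane compositions
#'
#' Sweeps the displacement constant k_d (the only varied parameter),
#' collects the stationary composition, division-time statistics and
#' mean nutrient permeability per sweep point, fits the exponential
#' trend of division time versus membrane diffusion rate, and projects
#' population curves.
#'
#' @param model `"pm1"`, `"pm2"` or a lipid-synthesising model.
#' @param k_d_values Sweep values (per hour).
#' @param engine,t_end,seed,physics,out,window As in
#'   [exp_reproduction()].
#' @param t_pop_days Time grid (days) for the population projection.
#' @return List: `table` (per-k_d summary), `fit` (slope of
#'   log T_div vs diffusion rate, R^2; NULL when < 2 usable points),
#'   `population` (long data frame of projected curves).
#' @export
exp_selection <- function(model = "pm2",
                          k_d_values = c(0, 0.02, 0.1, 0.2, 0.8),
                          engine = "ode", t_end = 600, seed = 1L,
                          physics = default_physics(), out = NULL,
                          window = 10, t_pop_days = seq(0, 60, by = 1)) {
  if (is.character(model)) {
    ps <- default_parameter_set(model, "reproducing")
    model <- ps$model
  }
  base_P <- get_species(model, "A")$base_permeability
  rows <- list(); pops <- list()
  for (kd in k_d_values) {
    res <- exp_reproduction(model, k_d = kd, engine = engine,
                            t_end = t_end, seed = seed,
                            physics = physics, window = window)
    ok <- !is.null(res$stats) && res$outcome != "burst"
    chi <- res$chi_asymptote
    P_eff <- base_P * eval_curve(physics$curve, chi)
    D_eff <- P_eff * physics$lambda * .NM_TO_M
    rows[[length(rows) + 1L]] <- data.frame(
      k_d = kd,
      chi_L_stat = chi,
      mean_T_div_h = if (ok) res$stats$mean_T_div else NA_real_,
      sd_T_div_h = if (ok) res$stats$sd_T_div else NA_real_,
      mean_T_div_days = if (ok) res$stats$mean_T_div / 24 else NA_real_,
      P_nutrient = P_eff, D_nutrient = D_eff,
      n_divisions = nrow(res$trajectory$divisions),
      outcome = res$outcome, usable = ok)
    if (ok) {
      pc <- project_population(res$stats$mean_T_div / 24, t_pop_days)
      pc$k_d <- kd
      pops[[length(pops) + 1L]] <- pc
    }
  }
  tab <- do.call(rbind, rows)
  fit <- NULL
  use <- tab$usable
  if (sum(use) >= 2) {
    lmfit <- stats::lm(log(mean_T_div_h) ~ D_nutrient,
                       data = tab[use, ])
    fit <- list(slope = unname(stats::coef(lmfit)[2]),
                R2 = summary(lmfit)$r.squared)
  }
  pop <- if (length(pops)) do.call(rbind, pops) else
    data.frame(time = numeric(), population = numeric(),
               k_d = numeric())
  .write_if(tab, out, paste0(model$name, "_selection.csv"))
  .write_if(pop, out, paste0(model$name, "_population.csv"))
  list(table = tab, fit = fit, population = pop, model = model$name)
}

#' Assay pipeline experiment
#'
#' The full semi-empirical bridge: fit each release trace, convert to
#' permeability and diffusion coefficients through the assay geometry,
#' and build the exact-matching composition-to-permeability curve the
#' simulator consumes.
#'
#' @param series A [gen_composition_series()] result, or `NULL` to
#'   generate the default synthetic series.
#' @param geom An [assay_geometry()].
#' @param method Fit method, see [fit_release_rate()].
#' @param out Optional output directory (tidy CSV + curve JSON).
#' @param seed Seed for the default synthetic series.
#' @return List: `table` (composition, chi_S, k, R2, P, D),
#'   `curve` (a [permeability_curve()]), `failures` (per-composition
#'   fit errors).
#' @export
exp_assay <- function(series = NULL, geom = assay_geometry(),
                      method = "exponential", out = NULL, seed = 1) {
  if (is.null(series)) {
    a <- default_parameter_set("pm2", "assay")$assay
    series <- gen_composition_series(
      chis = a$chis, peak_chi = a$peak_chi,
      peak_factor = a$peak_factor, end_factor = a$end_factor,
      k0 = a$k0, times = a$times, noise_sd = a$noise_sd, seed = seed)
  }
  rows <- list(); failures <- list()
  for (i in seq_along(series$traces)) {
    tr <- series$traces[[i]]
    fit <- tryCatch(fit_release_rate(tr, method),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[tr$composition]] <- conditionMessage(fit)
      next
    }
    pd <- permeability_from_rate(fit$k, geom, "per_min")
    rows[[length(rows) + 1L]] <- data.frame(
      composition = tr$composition, chi_S = series$chis[i],
      k = fit$k, R2 = fit$R2, P_m_per_s = pd$P, D_m2_per_s = pd$D)
  }
  tab <- do.call(rbind, rows)
  curve <- fit_permeability_curve(tab$chi_S, tab$P_m_per_s)
  .write_if(tab, out, "assay_fits.csv")
  if (!is.null(out))
    jsonlite::write_json(
      list(chi = curve$chi, multiplier = curve$multiplier),
      file.path(out, "permeability_curve.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(table = tab, curve = curve, failures = failures)
}
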