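#' Generate a synthetic release trace
#'
#' Emulates a leakage assay read-out: F(t) = 1 - exp(-k t) plus
#' additive Gaussian measurement noise, clipped to [0, 1]. Either the
#' release rate `k_true` (per minute) or a permeability `P_true` (m/s,
#' converted through the assay geometry) fixes the kinetics. Pure
#' function of its arguments and the seed.
#'
#' @param k_true Release rate (per minute); or
#' @param P_true Permeability (m/s), used when `k_true` is `NULL`.
#' @param times Sample times (minutes).
#' @param noise_sd Gaussian noise SD in fraction units (>= 0).
#' @param seed Integer seed.
#' @param geom An [assay_geometry()].
#' @param composition Label to attach.
#' @return A [release_trace()].
#' @export
gen_release_trace <- function(k_true = NULL, P_true = NULL,
                              times = seq(0, 120, by = 4),
                              noise_sd = 0.01, seed = 1,
                              geom = assay_geometry(),
                              composition = "synthetic") {
  stopifnot(noise_sd >= 0, all(times >= 0))
  if (is.null(k_true)) {
    if (is.null(P_true)) stop("supply k_true or P_true")
    k_true <- rate_from_permeability(P_true, geom, "per_min")
  }
  f <- 1 - exp(-k_true * times)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(times), 0, noise_sd)
  }
  release_trace(times, pmin(pmax(f, 0), 1), composition)
}

#' Generate a per-composition assay series
#'
#' Builds the ground-truth multiplier curve as the exact polynomial
#' through (0, 1), (`peak_chi`, `peak_factor`), (1, `end_factor`)
#' (an interior maximum: the heterogeneous compositions leak fastest),
#' derives a true release rate per requested composition and generates
#' one noisy trace for each. The ground truth is returned for recovery
#' tests.
#'
#' @param chis Surface fractions to sample (should include 0 and 1 if
#'   the recovered curve is to be engine-ready).
#' @param peak_chi Location of the permeability maximum (0 < chi < 1).
#' @param peak_factor,end_factor Multipliers at the peak and at
#'   chi = 1 (> 0).
#' @param k0 Release rate at chi = 0 (per minute).
#' @param times Sample times (minutes).
#' @param noise_sd Noise SD (fraction units).
#' @param seed Integer seed (each trace uses `seed + index`).
#' @param geom An [assay_geometry()].
#' @return List: `chis`, `true_curve` ([permeability_curve()]),
#'   `true_k` (per composition), `traces` (list of
#'   [release_trace()]).
#' @export
gen_composition_series <- function(chis = c(0, 0.2, 0.375, 0.6, 0.8, 1),
                                   peak_chi = 0.375, peak_factor = 10,
                                   end_factor = 2, k0 = 0.01,
                                   times = seq(0, 120, by = 4),
                                   noise_sd = 0.01, seed = 1,
                                   geom = assay_geometry()) {
  stopifnot(peak_chi > 0, peak_chi < 1, peak_factor > 0, end_factor > 0)
  true_curve <- permeability_curve(c(0, peak_chi, 1),
                                   c(1, peak_factor, end_factor))
  true_k <- k0 * eval_curve(true_curve, chis)
  traces <- lapply(seq_along(chis), function(i)
    gen_release_trace(k_true = true_k[i], times = times,
                      noise_sd = noise_sd, seed = seed + i, geom = geom,
                      composition = sprintf("chi=%.3f", chis[i])))
  list(chis = chis, true_curve = true_curve, true_k = true_k,
       traces = traces)
}

#' Packaged default parameter sets
#'
#' Complete, self-consistent configurations for the three scenarios:
#' `fixed_compartment` (steady-state analysis in a fixed 200 nm
#' vesicle), `reproducing` (lipid-synthesising protocell in the
#' growth-and-division regime) and `assay` (synthetic leakage series).
#'
#' @param model_name `"pm1"` or `"pm2"`.
#' @param scenario `"fixed_compartment"`, `"reproducing"` or
#'   `"assay"`.
#' @return A named list: `model` (a [network_model()]), `physics`
#'   (a [default_physics()]), plus scenario extras (`t_end` hours,
#'   `metab_seed`; for `assay` the generator arguments).
#' @export
default_parameter_set <- function(model_name = c("pm1", "pm2"),
                                  scenario = c("fixed_compartment",
                                               "reproducing",
                                               "assay")) {
  if (!model_name[1] %in% c("pm1", "pm2"))
    stop("unknown model '", model_name[1], "'; valid: pm1, pm2")
  model_name <- match.arg(model_name)
  if (!scenario[1] %in% c("fixed_compartment", "reproducing", "assay"))
    stop("unknown scenario '", scenario[1],
         "'; valid: fixed_compartment, reproducing, assay")
  scenario <- match.arg(scenario)
  base <- if (model_name == "pm1") build_pm1() else build_pm2()
  if (scenario == "fixed_compartment") {
    list(model = base, physics = default_physics(), t_end = 4000,
         metab_seed = c(AB = 1, AC = 1, ACD = 1), scenario = scenario)
  } else if (scenario == "reproducing") {
    model <- add_lipid_synthesis(base, k_syn = 0.1, k_d = 0)
    list(model = model, physics = default_physics(), t_end = 600,
         metab_seed = c(AB = 5, AC = 5, ACD = 5), scenario = scenario)
  } else {
    list(model = base, physics = default_physics(),
         assay = list(chis = c(0, 0.2, 0.375, 0.6, 0.8, 1),
                      peak_chi = 0.375, peak_factor = 10,
                      end_factor = 2, k0 = 0.01, noise_sd = 0.01,
                      seed = 20170609, times = seq(0, 120, by = 4)),
         scenario = scenario)
  }
}

#' Regenerate the packaged assay fixtures
#'
#' Writes the synthetic release-trace CSV (and its generating config)
#' for the default assay parameter set. Byte-stable at fixed seed.
#'
#' @param dir Output directory.
#' @param model_name Passed to [default_parameter_set()].
#' @return Invisibly, the paths written.
#' @export
gen_fixtures <- function(dir, model_name = "pm2") {
  ps <- default_parameter_set(model_name, "assay")
  a <- ps$assay
  series <- gen_composition_series(
    chis = a$chis, peak_chi = a$peak_chi, peak_factor = a$peak_factor,
    end_factor = a$end_factor, k0 = a$k0, times = a$times,
    noise_sd = a$noise_sd, seed = a$seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "release_traces.csv")
  cfg <- file.path(dir, "assay_config.json")
  write_traces_csv(series$traces, csv)
  jsonlite::write_json(a, cfg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, cfg))
}
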