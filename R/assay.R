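#' Release trace from a dye-leakage assay
#'
#' Timestamped fraction-released measurements of an encapsulated
#' solute (e.g. carboxyfluorescein) leaking from a vesicle population.
#'
#' @param times Measurement times (minutes), strictly increasing.
#' @param fraction_released Values in [0, 1].
#' @param composition Label (lipid pair + molar ratio).
#' @param temperature Assay temperature (degrees C).
#' @return An object of class `release_trace`.
#' @export
release_trace <- function(times, fraction_released,
                          composition = "unknown", temperature = 45) {
  stopifnot(length(times) == length(fraction_released))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(fraction_released < 0 | fraction_released > 1))
    stop("fraction_released must lie in [0, 1]")
  structure(list(times = times, fraction_released = fraction_released,
                 composition = composition, temperature = temperature),
            class = "release_trace")
}

#' Assay geometry
#'
#' @param radius Vesicle radius (nm, default 200: the monodisperse
#'   extruded population).
#' @param lambda Bilayer thickness (nm, default 3).
#' @return An object of class `assay_geometry`.
#' @export
assay_geometry <- function(radius = 200, lambda = 3) {
  stopifnot(radius > lambda, lambda > 0)
  structure(list(radius = radius, lambda = lambda),
            class = "assay_geometry")
}

#' Fit the release rate of a leakage trace
#'
#' Exponential method: least-squares fit of
#' F(t) = F_inf (1 - exp(-k t)), with F_inf fixed at 1 (perfect-sink
#' assay, complete release) unless the trace ends below 0.9, in which
#' case F_inf is freed. Early-linear method: ordinary least squares on
#' the initial points with F < 0.3 (the linear leakage regime), whose
#' slope estimates k directly.
#'
#' @param trace A [release_trace()] with >= 4 points.
#' @param method `"exponential"` (default) or `"early_linear"`.
#' @return List: `k` (per minute), `method`, `R2`, `residuals`,
#'   `F_inf`.
#' @export
fit_release_rate <- function(trace,
                             method = c("exponential", "early_linear")) {
  method <- match.arg(method)
  t <- trace$times
  f <- trace$fraction_released
  if (length(t) < 4) stop("need at least 4 points")
  if (diff(range(f)) == 0)
    stop("degenerate trace: all fractions equal; no release to fit")
  r2 <- function(obs, fit) 1 - sum((obs - fit)^2) /
    sum((obs - mean(obs))^2)
  if (method == "exponential") {
    # F_inf is freed only for traces that have actually flattened out
    # below complete release (a plateau), not for slow kinetics that
    # simply have not finished within the observation window
    n_pts <- length(f)
    late_gain <- f[n_pts] - f[max(1, floor(3 * n_pts / 4))]
    plateaued <- late_gain < 0.02 * max(diff(range(f)), 1e-12)
    free_Finf <- utils::tail(f, 1) < 0.9 && plateaued
    # rate guess from the log-linearised early data
    sel0 <- f < 0.95 & t > 0
    k0 <- if (sum(sel0) >= 2)
      max(stats::coef(stats::lm(-log(1 - f[sel0]) ~ 0 + t[sel0]))[1],
          1e-6) else 1e-3
    if (free_Finf) {
      fit <- stats::nls(f ~ Finf * (1 - exp(-k * t)),
                        start = list(k = k0, Finf = max(f)),
                        control = stats::nls.control(maxiter = 500,
                                                     warnOnly = TRUE))
      co <- stats::coef(fit)
      k <- unname(co[["k"]])
      Finf <- unname(co[["Finf"]])
    } else {
      # one free parameter: direct least squares (bracketed search,
      # then Newton polish to machine precision)
      rss <- function(k) sum((f - (1 - exp(-k * t)))^2)
      k <- stats::optimize(rss, c(k0 / 50, k0 * 50),
                           tol = 1e-10)$minimum
      for (it in 1:8) {
        e <- exp(-k * t)
        r <- f - (1 - e)
        dm <- t * e
        grad <- -2 * sum(r * dm)
        hess <- 2 * sum(dm * dm + r * t * t * e)
        if (!is.finite(hess) || hess <= 0) break
        step <- grad / hess
        k_new <- k - step
        if (!is.finite(k_new) || k_new <= 0) break
        k <- k_new
        if (abs(step) < 1e-15 * k) break
      }
      Finf <- 1
    }
    pred <- Finf * (1 - exp(-k * t))
  } else {
    sel <- f < 0.3
    if (sum(sel) < 2)
      stop("early-linear window (F < 0.3) holds fewer than 2 points")
    fit <- stats::lm(f[sel] ~ t[sel])
    k <- unname(stats::coef(fit)[2])
    Finf <- 1
    pred <- stats::fitted(fit)
    f <- f[sel]
  }
  if (!is.finite(k) || k <= 0)
    stop("fit failure: non-positive release rate (k = ",
         signif(k, 4), ") for composition ", trace$composition)
  list(k = k, method = method, R2 = r2(f, pred),
       residuals = f - pred, F_inf = Finf)
}

#' Permeability and diffusion coefficient from a release rate
#'
#' For a spherical vesicle the first-order release rate maps to the
#' permeability coefficient as P = k V / S = k r / 3, and to the
#' trans-membrane diffusion rate as D = P lambda.
#'
#' @param k Release rate constant (> 0).
#' @param geom An [assay_geometry()].
#' @param k_unit Unit of `k`: `"per_min"` (assay traces) or `"per_h"`.
#' @return List: `P` (m/s), `D` (m^2/s).
#' @export
permeability_from_rate <- function(k, geom = assay_geometry(),
                                   k_unit = c("per_min", "per_h")) {
  stopifnot(k > 0)
  k_unit <- match.arg(k_unit)
  k_s <- k / switch(k_unit, per_min = 60, per_h = 3600)
  P <- k_s * geom$radius * .NM_TO_M / 3
  list(P = P, D = P * geom$lambda * .NM_TO_M)
}

#' Release rate implied by a permeability coefficient
#'
#' Inverse of [permeability_from_rate()]: k = 3 P / r.
#'
#' @param P Permeability (m/s).
#' @param geom An [assay_geometry()].
#' @param k_unit Output unit.
#' @return Release rate constant.
#' @export
rate_from_permeability <- function(P, geom = assay_geometry(),
                                   k_unit = c("per_min", "per_h")) {
  k_unit <- match.arg(k_unit)
  3 * P / (geom$radius * .NM_TO_M) *
    switch(k_unit, per_min = 60, per_h = 3600)
}

#' Molar fraction to surface fraction
#'
#' Converts the molar fraction of the bulky-head derivative into the
#' fraction of membrane surface it covers, weighting by head areas:
#' chi = x a_d / (x a_d + (1 - x) a_l).
#'
#' @param x_derivative Molar fraction of the derivative in [0, 1].
#' @param alpha_l Head area of the reference fatty acid (nm^2).
#' @param alpha_d Head area of the derivative (nm^2).
#' @return Surface fraction in [0, 1], strictly increasing in x.
#' @export
molar_to_surface_fraction <- function(x_derivative, alpha_l = 0.2,
                                      alpha_d = 0.6) {
  stopifnot(all(x_derivative >= 0 & x_derivative <= 1),
            alpha_l > 0, alpha_d > 0)
  x_derivative * alpha_d /
    (x_derivative * alpha_d + (1 - x_derivative) * alpha_l)
}

#' Build the composition-to-permeability curve from assay points
#'
#' Fits the unique exact-matching polynomial (degree n - 1, evaluated
#' in barycentric Lagrange form) through per-composition permeability
#' or diffusion values and normalises it to multiplier form
#' f(chi) = value / value(chi = 0), the form consumed by the
#' simulation engines.
#'
#' @param chi Surface fractions (distinct; must include 0 and 1).
#' @param value Measured P or D at each composition (> 0).
#' @return A [permeability_curve()] with f(0) = 1.
#' @export
fit_permeability_curve <- function(chi, value) {
  if (length(chi) < 3) stop("need at least 3 points")
  if (anyDuplicated(chi)) stop("duplicate chi values")
  ord <- order(chi)
  chi <- chi[ord]; value <- value[ord]
  permeability_curve(chi, value / value[1])
}

#' Polynomial coefficients of a permeability curve
#'
#' Expands the interpolating polynomial into monomial coefficients
#' (solving the Vandermonde system); mainly for diagnostics such as
#' verifying that collinear points yield a degree-1 polynomial.
#'
#' @param curve A [permeability_curve()].
#' @return Coefficients, constant term first.
#' @export
curve_coefficients <- function(curve) {
  V <- outer(curve$chi, seq_along(curve$chi) - 1, `^`)
  drop(solve(V, curve$multiplier))
}

#' Read / write release traces as CSV
#'
#' Column contract: `time_min`, `fraction_released`, `composition`,
#' `replicate`.
#'
#' @param traces List of [release_trace()] objects (replicate index is
#'   the list position).
#' @param path CSV path.
#' @return `write_traces_csv`: the path, invisibly; `read_traces_csv`:
#'   a list of `release_trace` objects.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(time_min = tr$times,
               fraction_released = tr$fraction_released,
               composition = tr$composition, replicate = i)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "fraction_released", "composition", "replicate")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, interaction(d$composition, d$replicate, drop = TRUE)),
         function(g) release_trace(g$time_min, g$fraction_released,
                                   g$composition[1]))
}
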