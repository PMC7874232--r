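#' Configuration of the C3-to-CAM continuum sweep
#'
#' The sweep varies the light-period CO2 exchange bound from the C3 optimum
#' down to zero — a proxy for progressive stomatal closure — while the
#' RuBisCO carboxylase fraction rises linearly from its C3 value (75
#' percent, ratio 3:1) to its CAM value (83.74 percent, ratio 5.15:1),
#' reflecting the falling photorespiration as internal CO2 from malate
#' decarboxylation rises.
#'
#' @param n_steps number of sweep steps (>= 2; default 50).
#' @param co2_light_start starting light-period CO2 uptake bound
#'   (umol m-2 s-1); `NULL` (default) auto-detects it from the C3 pFBA
#'   solution's light CO2 uptake. The genome-scale core leaf model predicts
#'   13.12 for C3.
#' @param co2_light_end final bound, default 0.
#' @param carb_fraction_start,carb_fraction_end carboxylase fraction
#'   endpoints, defaults 0.75 and 0.8374. Set them equal to disable the ratio
#'   interpolation (the sweep is then a pure constraint tightening).
#' @param o2_policy `"scaled_with_co2"` scales the light O2 exchange
#'   magnitude bound by the same factor `(1 - t)` applied to its C3-solution
#'   value (stomatal closure throttles both gases); `"unbounded"` leaves O2
#'   free for sensitivity analysis.
#' @param dark_ratio `"interpolated"` applies the same ratio interpolation to
#'   the dark phase (consistent with the CAM-cycling dark value of 5.15:1);
#'   `"fixed_3"` pins the dark ratio at 3:1. Dark-phase RuBisCO carries no
#'   flux at the photon optimum, so the choice does not affect the endpoint
#'   solutions.
#' @return object of class `continuum_config`.
#' @export
continuum_config <- function(n_steps = 50, co2_light_start = NULL,
                             co2_light_end = 0,
                             carb_fraction_start = 0.75,
                             carb_fraction_end = 0.8374,
                             o2_policy = c("scaled_with_co2", "unbounded"),
                             dark_ratio = c("interpolated", "fixed_3")) {
  stopifnot(n_steps >= 2)
  for (f in c(carb_fraction_start, carb_fraction_end))
    if (f <= 0 || f >= 1) stop("carboxylase fractions must lie in (0, 1)")
  if (!is.null(co2_light_start) && co2_light_end > co2_light_start)
    stop("co2_light_end must not exceed co2_light_start")
  structure(list(n_steps = as.integer(n_steps),
                 co2_light_start = co2_light_start,
                 co2_light_end = co2_light_end,
                 carb_fraction_start = carb_fraction_start,
                 carb_fraction_end = carb_fraction_end,
                 o2_policy = match.arg(o2_policy),
                 dark_ratio = match.arg(dark_ratio)),
            class = "continuum_config")
}

#' Carboxylase fraction and ratio along the continuum
#'
#' Linear interpolation of the RuBisCO carboxylase fraction between the C3
#' and CAM endpoints: `f(t) = start + t * (end - start)`. The companion
#' carboxylase:oxygenase ratio is `f / (1 - f)` (fraction 0.75 gives ratio 3,
#' fraction 0.8374 gives ratio 5.15).
#'
#' @param t interpolation parameter in `[0, 1]` (0 = C3 endpoint).
#' @param cfg a [continuum_config()] supplying the endpoints.
#' @return the carboxylase fraction (`carb_fraction_at`) or the
#'   carboxylase:oxygenase ratio (`ratio_at`).
#' @export
carb_fraction_at <- function(t, cfg = continuum_config()) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  cfg$carb_fraction_start + t * (cfg$carb_fraction_end - cfg$carb_fraction_start)
}

#' @rdname carb_fraction_at
#' @export
ratio_at <- function(t, cfg = continuum_config()) {
  f <- carb_fraction_at(t, cfg)
  f / (1 - f)
}

#' Run the C3-to-CAM continuum sweep
#'
#' Solves the C3 scenario, reads (or takes from `cfg`) the starting light
#' CO2 uptake, then for each step `t` on a uniform grid from 0 to 1: caps the
#' light-period CO2 import at `(1 - t) * start` (CO2 export stays free, so
#' respiratory release in the light is never forced), throttles light O2
#' exchange per `cfg$o2_policy`, sets the per-phase carboxylase:oxygenase
#' ratio to `ratio_at(t)`, and solves pFBA. Infeasible steps are flagged and
#' the sweep continues.
#'
#' @param model an unconstrained [diel_model()].
#' @param base the base scenario (the C3 column; phloem export 0.259).
#' @param cfg a [continuum_config()].
#' @param backend LP backend, see [solve_lp()].
#' @return a `continuum_result`: a data.frame (one row per step: `t`,
#'   `co2_bound`, `o2_bound`, `carb_fraction`, `ratio`, `status`,
#'   `photon_demand` and all [energetics_summary()] columns) with the
#'   per-step `flux_solution` objects attached as attribute `"solutions"`.
#' @export
run_continuum <- function(model, base = scenario_spec("C3"),
                          cfg = continuum_config(), backend = "simplex") {
  stopifnot(inherits(model, "diel_model"), inherits(base, "scenario_spec"),
            inherits(cfg, "continuum_config"))
  m0 <- apply_scenario(model, base)
  sol0 <- pfba(m0, backend = backend)
  if (sol0$status != "optimal")
    stop("base scenario is ", sol0$status, "; cannot anchor the sweep")
  co2_ids <- role_reactions(model, "co2_exchange_light")
  o2_ids <- role_reactions(model, "o2_exchange_light")
  co2_start <- if (is.null(cfg$co2_light_start))
    sum(sol0$fluxes[co2_ids]) else cfg$co2_light_start
  if (co2_start <= 0)
    stop("light-period CO2 uptake of the base solution is not positive")
  o2_start <- abs(sum(sol0$fluxes[o2_ids]))

  ts <- seq(0, 1, length.out = cfg$n_steps)
  rows <- vector("list", cfg$n_steps)
  sols <- vector("list", cfg$n_steps)
  for (i in seq_along(ts)) {
    t <- ts[i]
    f <- carb_fraction_at(t, cfg)
    r <- f / (1 - f)
    r_dark <- if (cfg$dark_ratio == "interpolated") r else 3
    spec_t <- base
    spec_t$ratio_light <- r
    spec_t$ratio_dark <- r_dark
    mt <- apply_scenario(model, spec_t)
    co2_bound <- (1 - t) * co2_start + t * cfg$co2_light_end
    mt <- set_bounds(mt, co2_ids, lb = -1000, ub = co2_bound)
    o2_bound <- if (cfg$o2_policy == "scaled_with_co2") (1 - t) * o2_start else 1000
    mt <- set_bounds(mt, o2_ids, lb = -o2_bound, ub = o2_bound)
    sol <- pfba(mt, backend = backend)
    sols[[i]] <- sol
    if (sol$status == "optimal") {
      es <- energetics_summary(sol, mt)
      rows[[i]] <- cbind(data.frame(step = i, t = t, co2_bound = co2_bound,
                                    o2_bound = o2_bound, carb_fraction = f,
                                    ratio = r, status = "optimal",
                                    stringsAsFactors = FALSE), es)
    } else {
      rows[[i]] <- data.frame(step = i, t = t, co2_bound = co2_bound,
                              o2_bound = o2_bound, carb_fraction = f,
                              ratio = r, status = sol$status,
                              stringsAsFactors = FALSE)
    }
  }
  feasible <- rows[vapply(rows, function(x) x$status[1] == "optimal", TRUE)]
  template <- if (length(feasible)) names(feasible[[1]]) else names(rows[[1]])
  rows <- lapply(rows, function(x) {
    miss <- setdiff(template, names(x))
    for (m in miss) x[[m]] <- NA_real_
    x[template]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("continuum_result", "data.frame")
  attr(out, "solutions") <- sols
  attr(out, "config") <- cfg
  attr(out, "co2_start") <- co2_start
  out
}

#' @export
print.continuum_result <- function(x, ...) {
  n <- nrow(x)
  ok <- sum(x$status == "optimal")
  cat(sprintf("C3-CAM continuum sweep: %d steps (%d optimal)\n", n, ok))
  cat(sprintf("  light CO2 bound: %.4g -> %.4g umol m-2 s-1\n",
              x$co2_bound[1], x$co2_bound[n]))
  cat(sprintf("  carboxylase:oxygenase ratio: %.3g -> %.3g\n",
              x$ratio[1], x$ratio[n]))
  if (ok)
    cat(sprintf("  photon demand: %.4g -> %.4g (+%.1f%%)\n",
                x$photon_demand[1], x$photon_demand[n],
                percent_change(x$photon_demand[1], x$photon_demand[n])))
  invisible(x)
}

#' Plot the main continuum trends
#'
#' Four base-graphics panels against the light-period CO2 bound (decreasing
#' left to right, i.e. C3 on the left): photon demand, starch and malate
#' accumulation, dark-period PEPC and light-period malate decarboxylation,
#' and dark-period TCA/mito-ETC fluxes.
#'
#' @param x a `continuum_result`.
#' @param ... ignored.
#' @export
plot.continuum_result <- function(x, ...) {
  ok <- x$status == "optimal"
  d <- x[ok, , drop = FALSE]
  xv <- -d$co2_bound
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lab <- "- light CO2 bound (umol m-2 s-1)"
  graphics::plot(xv, d$photon_demand, type = "b", pch = 16, xlab = lab,
                 ylab = "photon demand", main = "Photon demand")
  graphics::plot(xv, d$starch_accumulation, type = "b", pch = 16, xlab = lab,
                 ylab = "accumulation", main = "Starch (solid) / malate (open)",
                 ylim = range(c(d$starch_accumulation, d$malate_accumulation)))
  graphics::lines(xv, d$malate_accumulation, type = "b", pch = 1)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(xv, d$pepc_dark, type = "b", pch = 16, xlab = lab,
                 ylab = "flux", main = "Dark PEPC (solid) / light decarb (open)",
                 ylim = range(c(d$pepc_dark, d$malate_decarboxylation_light)))
  graphics::lines(xv, d$malate_decarboxylation_light, type = "b", pch = 1)
  graphics::plot(xv, d$tca_dark, type = "b", pch = 16, xlab = lab,
                 ylab = "flux", main = "Dark TCA (solid) / mito ETC (open)",
                 ylim = range(c(d$tca_dark, d$mito_etc_dark)))
  graphics::lines(xv, d$mito_etc_dark, type = "b", pch = 1)
  invisible(x)
}
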