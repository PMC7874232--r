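#' Build the FBA linear program of a diel model
#'
#' Constructs `min c'v  s.t.  S v = 0,  lb <= v <= ub` for an arbitrary
#' objective vector over reactions. Extra rows (e.g. a fixed-objective cap for
#' FVA) can be appended by the caller.
#' @noRd
fba_lp <- function(model, objective, extra_A = NULL, extra_sense = NULL,
                   extra_rhs = NULL) {
  S <- stoich_matrix(model)
  A <- S
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    sense <- c(sense, extra_sense)
    rhs <- c(rhs, extra_rhs)
  }
  lp_problem(objective, A, sense, rhs, model$reactions$lb, model$reactions$ub,
             vars = model$reactions$id)
}

photon_objective <- function(model) {
  ids <- role_reactions(model, "photon_uptake_light")
  obj <- stats::setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  obj[ids] <- 1
  obj
}

new_flux_solution <- function(fluxes, objective_value, status, method,
                              model_id, extra = list()) {
  structure(c(list(fluxes = fluxes, objective_value = objective_value,
                   status = status, method = method, model_id = model_id),
              extra),
            class = "flux_solution")
}

#' Photon-minimizing flux balance analysis
#'
#' Solves the primary objective used throughout the pipeline: minimize the
#' total photon uptake (summed over all reactions carrying the
#' `photon_uptake_light` role) subject to steady state (`S v = 0`) and the
#' flux bounds. Minimizing photon demand assumes maximal efficiency of energy
#' conversion — the leaf meets its fixed phloem-export and maintenance
#' demands with as little light capture as possible.
#'
#' @param model a [diel_model()] with the `photon_uptake_light` role mapped
#'   (normally after [apply_scenario()]).
#' @param backend LP backend, see [solve_lp()].
#' @return a `flux_solution`: named flux vector, `objective_value` (photon
#'   demand, umol photons m-2 s-1) and solver `status`. When the constraints
#'   are infeasible the status says so and no fluxes are returned.
#' @seealso [pfba()] for the parsimonious refinement, [fva()] for flux ranges.
#' @export
minimize_photons <- function(model, backend = "simplex") {
  obj <- photon_objective(model)
  res <- solve_lp(fba_lp(model, obj), backend = backend)
  new_flux_solution(res$x, res$objective, res$status, "fba", model$id)
}

#' @rdname minimize_photons
#' @export
fba <- minimize_photons

#' Parsimonious flux balance analysis (pFBA)
#'
#' Fixes the photon demand at its optimum (within a small relative slack to
#' avoid round-off infeasibility) and then minimizes the total absolute flux
#' `sum(|v|)`. This removes substrate cycles and picks the least-flux
#' representative among the alternative optima of [minimize_photons()].
#'
#' Implementation: each reaction `v` in `[lb, ub]` is written as
#' `v = p - q` with `p in [max(lb,0), max(ub,0)]` and
#' `q in [max(-ub,0), max(-lb,0)]`; this box split represents the original
#' bounds exactly (including fixed positive bounds such as phloem export) and
#' `sum(p + q)` equals `sum(|v|)` at the optimum.
#'
#' @param model a [diel_model()].
#' @param slack relative slack on the fixed primary optimum (default 1e-6).
#' @param backend LP backend, see [solve_lp()].
#' @return a `flux_solution` whose `objective_value` is the photon demand
#'   recomputed from the parsimonious fluxes; the minimized total absolute
#'   flux is reported as `sum_abs_flux`.
#' @export
pfba <- function(model, slack = 1e-6, backend = "simplex") {
  primary <- minimize_photons(model, backend = backend)
  if (primary$status != "optimal") return(primary)
  opt <- primary$objective_value

  S <- stoich_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # v = p - q, exact box split of [lb, ub]
  lbp <- pmax(lb, 0); ubp <- pmax(ub, 0)
  lbq <- pmax(-ub, 0); ubq <- pmax(-lb, 0)
  A <- cbind(S, -S)
  sense <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  # cap the primary objective at its optimum (inequality, not equality,
  # so floating-point round-off cannot make the LP infeasible)
  ph <- photon_objective(model)
  A <- rbind(A, c(ph, -ph))
  sense <- c(sense, "<=")
  rhs <- c(rhs, opt * (1 + slack) + if (opt < 1e-9) 1e-9 else 0)
  lp <- lp_problem(rep(1, 2 * n), A, sense, rhs, c(lbp, lbq), c(ubp, ubq),
                   vars = c(paste0(model$reactions$id, "..fwd"),
                            paste0(model$reactions$id, "..rev")))
  res <- solve_lp(lp, backend = backend)
  if (res$status != "optimal")
    return(new_flux_solution(NULL, NA_real_, res$status, "pfba", model$id))
  v <- stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)],
                       model$reactions$id)
  new_flux_solution(v, sum(ph * v), "optimal", "pfba", model$id,
                    extra = list(sum_abs_flux = res$objective,
                                 fba_objective = opt))
}

#' Flux variability analysis at the fixed photon optimum
#'
#' For each reaction, computes the minimum and maximum flux it can carry while
#' total photon demand stays within `optimum * (1 + fraction)`. Used to check
#' that conclusions drawn from a single (degenerate) pFBA solution hold across
#' the whole optimal solution space.
#'
#' @param model a [diel_model()].
#' @param fraction relative slack on the photon optimum (default 1e-6).
#' @param reactions reaction ids to scan; defaults to all.
#' @param backend LP backend, see [solve_lp()].
#' @return a `flux_ranges` data.frame with columns `reaction_id`, `min`,
#'   `max`.
#' @export
fva <- function(model, fraction = 1e-6, reactions = NULL, backend = "simplex") {
  primary <- minimize_photons(model, backend = backend)
  if (primary$status != "optimal")
    stop("primary photon objective is ", primary$status,
         "; FVA needs a feasible model")
  opt <- primary$objective_value
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  ph <- photon_objective(model)
  cap <- opt * (1 + fraction) + if (opt < 1e-9) 1e-9 else 0
  n <- nrow(model$reactions)
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    obj <- stats::setNames(rep(0, n), model$reactions$id)
    obj[reactions[k]] <- 1
    lo <- solve_lp(fba_lp(model, obj, extra_A = matrix(ph, 1), "<=", cap),
                   backend = backend)
    obj[reactions[k]] <- -1
    hi <- solve_lp(fba_lp(model, obj, extra_A = matrix(ph, 1), "<=", cap),
                   backend = backend)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction ", reactions[k])
    out$min[k] <- lo$objective
    out$max[k] <- -hi$objective
  }
  class(out) <- c("flux_ranges", "data.frame")
  attr(out, "photon_optimum") <- opt
  out
}

#' Maximum mass-balance residual of a flux solution
#' @param solution an optimal `flux_solution`.
#' @param model the [diel_model()] it was solved on.
#' @return `max(|S v|)` over metabolites.
#' @export
mass_balance_residual <- function(solution, model) {
  stopifnot(inherits(solution, "flux_solution"),
            solution$status == "optimal")
  S <- stoich_matrix(model)
  max(abs(S %*% solution$fluxes[colnames(S)]))
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("%s solution for '%s': %s\n", toupper(x$method), x$model_id,
              x$status))
  if (x$status == "optimal") {
    cat(sprintf("  photon demand: %.6g umol m-2 s-1\n", x$objective_value))
    if (!is.null(x$sum_abs_flux))
      cat(sprintf("  total absolute flux: %.6g\n", x$sum_abs_flux))
    cat(sprintf("  %d reactions, %d carrying flux (|v| > 1e-7)\n",
                length(x$fluxes), sum(abs(x$fluxes) > 1e-7)))
  }
  invisible(x)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' @export
summary.flux_solution <- function(object, n = 10, ...) {
  print(object)
  if (object$status == "optimal") {
    v <- sort(abs(object$fluxes), decreasing = TRUE)
    cat("  largest fluxes:\n")
    top <- utils::head(v[v > 1e-7], n)
    for (id in names(top))
      cat(sprintf("    %-34s %10.4f\n", id, object$fluxes[[id]]))
  }
  invisible(object)
}
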