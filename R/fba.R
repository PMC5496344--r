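# Flux balance analysis, flux variability, blocked reactions, coupling.

#' Flux balance analysis
#'
#' Solves `max c'v` subject to `S v = 0` and `lb <= v <= ub`, where `c`
#' selects the model's objective reaction (typically a biomass equation, in
#' which case the optimum is the specific growth rate mu in h^-1). The
#' objective value of an optimal solution is unique; the flux vector may be
#' one of several alternate optima.
#'
#' @param model a [metabolic_model()].
#' @return A `flux_solution`: list with `objective_value`, named `fluxes`,
#'   and `status` (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @export
fba <- function(model) {
  if (is.na(model$objective)) stop("model has no objective reaction")
  p <- lp_parts(model)
  sol <- solve_lp(unit_obj(model, model$objective), p$S, p$b, p$lb, p$ub)
  structure(list(objective_value = sol$objective,
                 fluxes = stats::setNames(sol$x, p$ids),
                 status = sol$status),
            class = "flux_solution")
}

#' @exportS3Method base::print
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value), "\n")
  invisible(x)
}

# Inequality row enforcing objective >= fraction * optimum (with a small
# absolute slack so the row is never infeasible by round-off).
objective_floor <- function(model, fraction, optimum, slack = 1e-6) {
  list(A = matrix(-unit_obj(model, model$objective), nrow = 1),
       b = -(fraction * optimum - slack))
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the
#' steady-state and bound constraints and, when `fraction_of_optimum > 0`,
#' to the objective flux staying at or above that fraction of the FBA
#' optimum. `fraction_of_optimum = 0` explores the unconstrained network.
#'
#' @param model a [metabolic_model()].
#' @param fraction_of_optimum number in \[0, 1\].
#' @param reactions reaction ids to scan (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`; the fraction
#'   used is attached as attribute `fraction_of_optimum`.
#' @export
fva <- function(model, fraction_of_optimum = 0, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  A_ub <- NULL; b_ub <- NULL
  if (fraction_of_optimum > 0) {
    base <- fba(model)
    if (base$status != "optimal")
      stop("base FBA problem is ", base$status, "; cannot run FVA")
    fl <- objective_floor(model, fraction_of_optimum, base$objective_value)
    A_ub <- fl$A; b_ub <- fl$b
  }
  p <- lp_parts(model)
  res <- vapply(reactions, function(r) {
    obj <- unit_obj(model, r)
    lo <- solve_lp(obj, p$S, p$b, p$lb, p$ub, A_ub, b_ub, maximize = FALSE)
    hi <- solve_lp(obj, p$S, p$b, p$lb, p$ub, A_ub, b_ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for ", r)
    c(lo$objective, hi$objective)
  }, numeric(2))
  out <- data.frame(reaction = reactions, min = res[1, ], max = res[2, ],
                    row.names = NULL)
  attr(out, "fraction_of_optimum") <- fraction_of_optimum
  out
}

# Open every exchange to default capacities (lb -1000, ub 1000) and every
# demand to (0, 1000): the condition-free context used for topology
# analyses (blocked reactions, coupling).
open_exchanges <- function(model, bound = 1000) {
  ex <- model$reactions$kind == "exchange"
  dm <- model$reactions$kind == "demand"
  model$reactions$lower_bound[ex] <- -bound
  model$reactions$upper_bound[ex] <- bound
  model$reactions$lower_bound[dm] <- 0
  model$reactions$upper_bound[dm] <- bound
  model
}

#' Blocked reactions
#'
#' A reaction is blocked when it can carry no flux in any feasible steady
#' state even with every exchange open: its fraction-0 FVA range is (0, 0).
#'
#' @param model a [metabolic_model()].
#' @param zero_tol fluxes below this magnitude count as zero.
#' @param open if `TRUE` (default), exchange bounds are first opened to
#'   default capacities so blockedness reflects topology, not the medium.
#' @return Character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, zero_tol = 1e-6, open = TRUE) {
  m <- if (open) open_exchanges(model) else model
  rng <- fva(m, fraction_of_optimum = 0)
  rng$reaction[abs(rng$min) < zero_tol & abs(rng$max) < zero_tol]
}

# Can reaction i carry flux while reaction j is fixed to zero?
can_run_without <- function(model, i, j, zero_tol) {
  m <- set_bounds(model, j, lb = 0, ub = 0)
  hi <- optimize_flux(m, i, maximize = TRUE)
  if (!is.na(hi) && hi > zero_tol) return(TRUE)
  lo <- optimize_flux(m, i, maximize = FALSE)
  !is.na(lo) && lo < -zero_tol
}

# Range of v_i with v_j pinned to a feasible nonzero value t; returns the
# ratio range v_i / t.
ratio_range <- function(model, i, j, t) {
  m <- set_bounds(model, j, lb = t, ub = t)
  lo <- optimize_flux(m, i, maximize = FALSE)
  hi <- optimize_flux(m, i, maximize = TRUE)
  c(lo, hi) / t
}

#' Flux coupling analysis
#'
#' Classifies every unordered pair of unblocked reactions:
#' * `fully`: each forces the other and their flux ratio is fixed;
#' * `partially`: each forces the other but the ratio can vary;
#' * `directional_i_to_j` / `directional_j_to_i`: nonzero flux through one
#'   implies nonzero flux through the other, in one direction only;
#' * `uncoupled`: otherwise.
#'
#' "i forces j" is decided by the feasibility test "can `v_i` be nonzero
#' while `v_j = 0`?" (two LPs); ratio fixedness by minimizing and maximizing
#' `v_i` with `v_j` pinned at a feasible nonzero value. Exchange bounds are
#' opened first (see [blocked_reactions()]) so the classification describes
#' the network, not one medium.
#'
#' @param model a [metabolic_model()].
#' @param zero_tol fluxes below this magnitude count as zero.
#' @return A `coupling_report`: list with `pairs` (data.frame `i`, `j`,
#'   `class`) and `blocked` (ids excluded from pairing).
#' @export
flux_coupling <- function(model, zero_tol = 1e-6) {
  m <- open_exchanges(model)
  rng <- fva(m, fraction_of_optimum = 0)
  blocked <- rng$reaction[abs(rng$min) < zero_tol & abs(rng$max) < zero_tol]
  live <- setdiff(rng$reaction, blocked)
  rng <- rng[match(live, rng$reaction), ]

  n <- length(live)
  out <- vector("list", n * (n - 1L) / 2L)
  idx <- 0L
  for (a in seq_len(max(0L, n - 1L))) {
    for (b in seq((a + 1L), n)) {
      i <- live[a]; j <- live[b]
      i_free <- can_run_without(m, i, j, zero_tol)  # i without j possible?
      j_free <- can_run_without(m, j, i, zero_tol)
      cls <- if (!i_free && !j_free) {
        # mutually coupled; pin j at a feasible value and inspect the ratio
        t <- if (rng$max[b] > zero_tol) min(1, rng$max[b] / 2) else
          -min(1, abs(rng$min[b]) / 2)
        rr <- ratio_range(m, i, j, t)
        if (all(is.finite(rr)) &&
            diff(rr) <= 1e-6 * max(1, abs(rr[2]))) "fully" else "partially"
      } else if (!i_free) {
        "directional_i_to_j"   # v_i != 0 implies v_j != 0
      } else if (!j_free) {
        "directional_j_to_i"
      } else "uncoupled"
      idx <- idx + 1L
      out[[idx]] <- data.frame(i = i, j = j, class = cls)
    }
  }
  pairs <- if (idx) do.call(rbind, out[seq_len(idx)]) else
    data.frame(i = character(), j = character(), class = character())
  structure(list(pairs = pairs, blocked = blocked), class = "coupling_report")
}

#' @exportS3Method base::print
print.coupling_report <- function(x, ...) {
  cat("<coupling_report>", nrow(x$pairs), "pairs,",
      length(x$blocked), "blocked reactions\n")
  if (nrow(x$pairs)) print(table(x$pairs$class))
  invisible(x)
}
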