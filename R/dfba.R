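# Staged dynamic FBA for batch cultures with biomass-equation switching.
#
# Static-optimization approach: at each time step the FBA problem is solved
# with the stage's biomass variant as objective (flux capped at mu_max) and
# uptake bounds limited by the extracellular pools; biomass is updated
# exponentially (exact for constant mu within the step) and pools by Euler.

#' Define one culture stage
#'
#' @param name stage label.
#' @param biomass_variant biomass variant to use (name from the model's
#'   `biomass_variants`, e.g. `"replete"`/`"depleted"`).
#' @param mu_max cap on the biomass flux (h^-1), from measured maximum
#'   growth rates.
#' @param duration stage length (h), must be positive.
#' @param medium_events named numeric vector of nutrient additions at stage
#'   start (exchange id -> mmol/L added to the pool).
#' @return A `stage_spec` object.
#' @export
stage_spec <- function(name, biomass_variant, mu_max, duration,
                       medium_events = numeric()) {
  stopifnot(mu_max >= 0, duration > 0)
  structure(list(name = name, biomass_variant = biomass_variant,
                 mu_max = mu_max, duration = duration,
                 medium_events = medium_events),
            class = "stage_spec")
}

#' Switch the active biomass equation
#'
#' Points the objective at the requested biomass variant and closes the
#' other variants (bounds 0, 0), so the inactive biomass composition cannot
#' drain precursors.
#'
#' @param model a [metabolic_model()] with named `biomass_variants`.
#' @param variant variant name.
#' @return The switched model.
#' @export
switch_biomass <- function(model, variant) {
  if (!variant %in% names(model$biomass_variants))
    stop("unknown biomass variant: ", variant)
  target <- model$biomass_variants[[variant]]
  others <- setdiff(model$biomass_variants, target)
  for (r in others) model <- set_bounds(model, r, lb = 0, ub = 0)
  i <- match(target, model$reactions$id)
  if (model$reactions$upper_bound[i] <= 0)
    model$reactions$upper_bound[i] <- 1000
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
  model$objective <- target
  model
}

# One dFBA step as a lexicographic LP: (1) maximize growth; (2) at fixed
# growth, minimize the summed uptake of the tracked (depletable) nutrients;
# (3) additionally minimize the demand (storage) fluxes. Steps 2 and 3
# resolve alternate optima that would otherwise waste pool nutrients in
# futile uptake/secretion cycles or dump surplus carbon into storage: the
# stored amount is exactly what the active biomass equation forces.
dfba_step <- function(model, tracked_ex, demand_rxns, slack = 1e-9) {
  p <- lp_parts(model)
  obj_mu <- unit_obj(model, model$objective)
  s1 <- solve_lp(obj_mu, p$S, p$b, p$lb, p$ub)
  if (s1$status != "optimal") return(NULL)
  mu <- s1$objective
  eps <- slack * max(1, abs(mu))
  obj_up <- rowSums(vapply(tracked_ex, function(r) unit_obj(model, r),
                           numeric(length(obj_mu))))
  A <- matrix(-obj_mu, nrow = 1); b <- -(mu - eps)
  s2 <- solve_lp(obj_up, p$S, p$b, p$lb, p$ub, A, b)   # maximize: uptakes -> 0
  if (s2$status != "optimal") return(list(mu = mu, v = stats::setNames(s1$x, p$ids)))
  obj_dm <- if (length(demand_rxns))
    rowSums(vapply(demand_rxns, function(r) unit_obj(model, r),
                   numeric(length(obj_mu)))) else NULL
  v <- s2$x
  if (!is.null(obj_dm)) {
    A3 <- rbind(A, -obj_up); b3 <- c(b, -(s2$objective - eps))
    s3 <- solve_lp(obj_dm, p$S, p$b, p$lb, p$ub, A3, b3, maximize = FALSE)
    if (s3$status == "optimal") v <- s3$x
  }
  list(mu = mu, v = stats::setNames(v, p$ids))
}

# net biomass-bound coefficient of a species in a biomass reaction:
# consumption minus what the reaction re-deposits elsewhere (e.g. storage)
biomass_lipid_coeff <- function(model, biomass_rxn, species_consumed,
                                species_stored) {
  cons <- if (species_consumed %in% rownames(model$S))
    -model$S[species_consumed, biomass_rxn] else 0
  stor <- if (species_stored %in% rownames(model$S))
    model$S[species_stored, biomass_rxn] else 0
  cons - stor
}

#' Simulate a staged batch culture by dynamic FBA
#'
#' At each step of size `dt`: the stage's biomass variant is activated and
#' capped at the stage's `mu_max`; each tracked nutrient's uptake is bounded
#' by pool availability (`lb >= -pool / (X dt)`); the FBA solution gives mu
#' and exchange fluxes; biomass is updated as `X <- X exp(mu dt)` and pools
#' as `pool <- pool + v_ex X dt`. An exhausted pool keeps its uptake closed
#' until a stage's `medium_events` replenishes it. Demand-reaction fluxes
#' are integrated into storage pools (e.g. storage lipid in lipid bodies).
#' An infeasible step is logged and contributes mu = 0.
#'
#' @param model a [metabolic_model()] with both biomass variants.
#' @param stages list of [stage_spec()].
#' @param X0 initial biomass concentration (gDW/L).
#' @param pools named numeric vector of initial extracellular amounts
#'   (exchange id -> mmol/L); only listed nutrients are depletable, all
#'   other exchanges keep their model bounds.
#' @param dt step size (h).
#' @param lipid_species optional named character vector
#'   `c(consumed = <species>, stored = <species>)` identifying the storage
#'   lipid consumed by the biomass equations and its stored counterpart;
#'   used to report cumulative biomass-bound lipid alongside storage.
#' @return A `dfba_trajectory`: data.frame with one row per step (`time`,
#'   `stage`, `mu`, `X`, one `pool_*` column per tracked nutrient, one
#'   `storage_*` column per demand species, `lipid_biomass` = cumulative
#'   biomass-bound storage-lipid, in mmol/L, and `uptake_*` fluxes).
#' @export
simulate_stages <- function(model, stages, X0, pools, dt = 0.1,
                            lipid_species = NULL) {
  stopifnot(dt > 0, X0 > 0)
  demand_rxns <- model$reactions$id[model$reactions$kind == "demand"]
  demand_species <- vapply(demand_rxns, function(r)
    boundary_species(model, r), character(1))
  storage <- stats::setNames(numeric(length(demand_rxns)), demand_species)
  lipid_bound <- 0
  X <- X0
  rows <- list()
  t <- 0

  for (st in stages) {
    if (length(st$medium_events))
      pools[names(st$medium_events)] <-
        ifelse(is.na(pools[names(st$medium_events)]), 0,
               pools[names(st$medium_events)]) + st$medium_events
    m_st <- switch_biomass(model, st$biomass_variant)
    bio <- m_st$objective
    m_st <- set_bounds(m_st, bio, ub = st$mu_max)
    bcoef <- if (is.null(lipid_species)) 0 else
      biomass_lipid_coeff(m_st, bio, lipid_species[["consumed"]],
                          lipid_species[["stored"]])

    n_steps <- max(1L, round(st$duration / dt))
    for (k in seq_len(n_steps)) {
      m <- m_st
      for (ex in names(pools)) {
        cap <- max(0, pools[[ex]]) / (X * dt)
        i <- match(ex, m$reactions$id)
        m$reactions$lower_bound[i] <- max(m$reactions$lower_bound[i], -cap)
      }
      sol <- dfba_step(m, names(pools), demand_rxns)
      if (is.null(sol)) {
        message("dFBA step at t=", signif(t, 6), " h: infeasible; mu set to 0")
        mu <- 0
        v <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
      } else {
        mu <- sol$mu
        v <- sol$v
      }
      pools <- pmax(pools + v[names(pools)] * X * dt, 0)  # pmax keeps
      # the attributes of its first argument, so pools stay named
      storage <- storage + pmax(0, v[demand_rxns]) * X * dt
      lipid_bound <- lipid_bound + bcoef * v[bio] * X * dt
      X <- X * exp(mu * dt)
      t <- t + dt
      rows[[length(rows) + 1L]] <- c(
        time = t, mu = mu, X = X,
        stats::setNames(pools, paste0("pool_", names(pools))),
        stats::setNames(storage, paste0("storage_", names(storage))),
        lipid_biomass = lipid_bound,
        stats::setNames(v[names(pools)], paste0("uptake_", names(pools))))
    }
    if (!length(rows)) next
    attr(rows[[length(rows)]], "stage_end") <- st$name
  }

  out <- as.data.frame(do.call(rbind, rows))
  out$stage <- rep(vapply(stages, `[[`, "", "name"),
                   vapply(stages, function(s)
                     max(1L, as.integer(round(s$duration / dt))), integer(1)))
  out$total_lipid <- out$lipid_biomass +
    rowSums(out[, grep("^storage_", names(out)), drop = FALSE])
  class(out) <- c("dfba_trajectory", "data.frame")
  out
}

#' Mean per-stage rates from a trajectory
#'
#' Average accumulation rate (mmol L^-1 h^-1) of a trajectory column within
#' each stage, i.e. (last - first) / elapsed time.
#'
#' @param traj a `dfba_trajectory`.
#' @param column column name, e.g. `"storage_mag_lb"` or `"total_lipid"`.
#' @return Named numeric vector, one rate per stage.
#' @export
stage_rates <- function(traj, column) {
  vapply(split(traj, factor(traj$stage, levels = unique(traj$stage))),
         function(d) {
           (d[[column]][nrow(d)] - d[[column]][1]) /
             (d$time[nrow(d)] - d$time[1])
         }, numeric(1))
}
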