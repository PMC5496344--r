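# Randomized pruning search for reaction-knockout sets that growth-couple
# the production of a target biomass constituent (e.g. storage lipid).
#
# Because the target is a biomass constituent rather than a secreted
# product, an artificial route is added first: a synthesis reaction turns
# the target species into an "additional" pseudo-species drained by an
# irreversible demand; that demand is the design objective. A design is
# accepted only if the FVA minimum of the demand at (numerically) optimal
# growth clears the production threshold — a plain FBA flux would not be a
# guarantee, since alternate optima could route the surplus elsewhere.

#' Define a production target
#'
#' @param id short target label, used to derive the synthesis/demand
#'   reaction ids (`SYN_<id>`, `DM_<id>`).
#' @param species named numeric vector: target species id(s) ->
#'   proportion. Proportions must sum to 1 (single species: `c(x = 1)`).
#' @param epsilon minimum guaranteed production rate epsilon_t
#'   (mmol gDW^-1 h^-1), must be positive.
#' @return A `target_spec` object.
#' @export
target_spec <- function(id, species, epsilon = 1e-3) {
  stopifnot(epsilon > 0, all(species > 0))
  if (abs(sum(species) - 1) > 1e-9)
    stop("target proportions must sum to 1")
  structure(list(id = id, species = species, epsilon = epsilon,
                 demand_id = paste0("DM_", id),
                 synthesis_id = paste0("SYN_", id),
                 pseudo_species = paste0("additional_", id)),
            class = "target_spec")
}

#' Add the target demand construction to a model
#'
#' Creates the pseudo-species `additional_<id>`, a synthesis reaction
#' consuming the target species in the given proportions, and an
#' irreversible demand on the pseudo-species. Any pre-existing demand that
#' drains a target species is closed, so the production guarantee cannot
#' leak through a free sink. The biomass equations are untouched.
#'
#' @param model a [metabolic_model()].
#' @param target a [target_spec()].
#' @return The extended model.
#' @export
add_target_demand <- function(model, target) {
  missing_sp <- setdiff(names(target$species), model$metabolites$id)
  if (length(missing_sp))
    stop("target species missing from model: ",
         paste(missing_sp, collapse = ", "))
  comp <- model$metabolites$compartment[
    match(names(target$species)[1], model$metabolites$id)]

  leak <- model$reactions$id[
    model$reactions$kind == "demand" &
      vapply(model$reactions$id, function(r)
        any(boundary_species(model, r) %in% names(target$species)),
        logical(1))]
  if (length(leak)) model <- knockout_reactions(model, leak)

  metabolites <- rbind(model$metabolites,
                       data.frame(id = target$pseudo_species,
                                  name = target$pseudo_species,
                                  compartment = comp, formula = "",
                                  charge = NA_integer_))
  reactions <- model$reactions[, c("id", "name", "lower_bound",
                                   "upper_bound", "subsystem", "gpr")]
  reactions <- rbind(reactions,
                     data.frame(id = c(target$synthesis_id, target$demand_id),
                                name = c(target$synthesis_id, target$demand_id),
                                lower_bound = c(0, 0),
                                upper_bound = c(1000, 1000),
                                subsystem = "", gpr = ""))
  S <- Matrix::Matrix(0, nrow(metabolites), nrow(reactions), sparse = TRUE,
                      dimnames = list(metabolites$id, reactions$id))
  S[rownames(model$S), colnames(model$S)] <- model$S
  S[names(target$species), target$synthesis_id] <- -target$species
  S[target$pseudo_species, target$synthesis_id] <- 1
  S[target$pseudo_species, target$demand_id] <- -1

  metabolic_model(id = model$id, compartments = model$compartments,
                  metabolites = metabolites, reactions = reactions, S = S,
                  genes = model$genes, objective = model$objective,
                  biomass_variants = model$biomass_variants)
}

# Minimum demand flux at (1 - delta)-optimal growth; NA when growth LP is
# not optimal. Returns c(mu, r_t).
min_target_at_optimum <- function(model, target, delta = 1e-6) {
  sol <- fba(model)
  if (sol$status != "optimal") return(c(mu = 0, r_t = 0))
  mu <- sol$objective_value
  fl <- objective_floor(model, 1 - delta, mu, slack = 0)
  r_t <- optimize_flux(model, target$demand_id, maximize = FALSE,
                       A_ub = fl$A, b_ub = fl$b)
  c(mu = mu, r_t = if (is.na(r_t)) 0 else r_t)
}

#' Verify growth-coupled production for a knockout set
#'
#' Knocks out the set, maximizes growth, and computes the FVA minimum of
#' the target demand subject to growth staying within a fractional slack
#' `delta` of its optimum: the guaranteed production rate r_t. The design
#' is sound (`ok`) when the mutant still grows (mu > eps_g) and
#' r_t >= epsilon_t.
#'
#' @param model model containing the target construction
#'   (see [add_target_demand()]).
#' @param k character vector of knocked-out reaction ids.
#' @param target a [target_spec()].
#' @param eps_g growth feasibility threshold (h^-1).
#' @param delta fractional slack on optimal growth.
#' @return list with `mu`, `r_t`, `ok`.
#' @export
verify_coupled <- function(model, k, target, eps_g = 1e-6, delta = 1e-6) {
  m <- knockout_reactions(model, k)
  res <- min_target_at_optimum(m, target, delta)
  list(mu = res[["mu"]], r_t = res[["r_t"]],
       ok = res[["mu"]] > eps_g && res[["r_t"]] >= target$epsilon)
}

# Reactions the search may remove: everything except exchanges, demands,
# biomass equations and the target construction itself.
search_candidates <- function(model, target) {
  k <- model$reactions$kind
  open <- model$reactions$upper_bound > 0 | model$reactions$lower_bound < 0
  model$reactions$id[open & !(k %in% c("exchange", "demand", "biomass")) &
                       !(model$reactions$id %in%
                           c(target$synthesis_id, target$demand_id))]
}

#' One iteration of the randomized pruning search
#'
#' Four steps:
#' 1. traverse the removable reactions in random order, deleting each whose
#'    removal keeps the maximum target-demand flux above epsilon_t; the
#'    reactions that had to stay are "conserved";
#' 2. starting again from the full model, traverse in random order deleting
#'    every reaction not needed to keep growth above eps_g, never touching
#'    the step-1 conserved set;
#' 3. maximize growth on the pruned model and require the guaranteed demand
#'    flux at that optimum to clear epsilon_t, else report failure (the
#'    caller restarts);
#' 4. re-add the deleted reactions one at a time in random order; a
#'    reaction whose return breaks the simultaneous growth + guaranteed
#'    production joins the knockout set k, the others stay re-added.
#'
#' Uses R's RNG; seed it (or let [run_search()] do so) for reproducibility.
#'
#' @param model model containing the target construction.
#' @param target a [target_spec()].
#' @param eps_g growth threshold (h^-1).
#' @param delta fractional slack on optimal growth (see [verify_coupled()]).
#' @return A `ko_candidate` list (`k`, `mu`, `r_t`, `m` = mu * r_t / |k|)
#'   or `NULL` on failure (step-3 rejection or empty k).
#' @export
prune_search_iteration <- function(model, target, eps_g = 1e-6,
                                   delta = 1e-6) {
  if (!target$demand_id %in% model$reactions$id)
    stop("model lacks the target demand; call add_target_demand() first")
  candidates <- search_candidates(model, target)

  # step 1: prune against target production
  cur <- model
  removed1 <- character()
  for (r in sample(candidates)) {
    tent <- knockout_reactions(cur, r)
    keep <- optimize_flux(tent, target$demand_id, maximize = TRUE)
    if (!is.na(keep) && keep > target$epsilon) {
      cur <- tent
      removed1 <- c(removed1, r)
    }
  }
  conserved <- setdiff(candidates, removed1)

  # step 2: prune against biomass, protecting the conserved set
  cur <- model
  removed2 <- character()
  for (r in sample(setdiff(candidates, conserved))) {
    tent <- knockout_reactions(cur, r)
    mu <- optimize_flux(tent, model$objective, maximize = TRUE)
    if (!is.na(mu) && mu > eps_g) {
      cur <- tent
      removed2 <- c(removed2, r)
    }
  }

  # step 3: is production guaranteed at optimal growth of the pruned model?
  chk <- min_target_at_optimum(cur, target, delta)
  if (chk[["mu"]] <= eps_g || chk[["r_t"]] <= target$epsilon) return(NULL)

  # step 4: recover removals that do not break the coupling
  k <- removed2
  for (r in sample(removed2)) {
    trial <- knockout_reactions(model, setdiff(k, r))
    chk <- min_target_at_optimum(trial, target, delta)
    if (chk[["mu"]] > eps_g && chk[["r_t"]] >= target$epsilon)
      k <- setdiff(k, r)
  }
  if (!length(k)) return(NULL)

  vc <- verify_coupled(model, k, target, eps_g, delta)
  if (!vc$ok) return(NULL)
  structure(list(k = sort(k), mu = vc$mu, r_t = vc$r_t,
                 m = vc$mu * vc$r_t / length(k)),
            class = "ko_candidate")
}

#' Randomized search for growth-coupling knockout sets
#'
#' Runs `iterations` independent pruning iterations (each retried up to
#' `retry_cap` times on step-3 failure), deduplicates the returned knockout
#' sets, and ranks them by the metric `m = mu * r_t / |k|` (descending),
#' breaking ties by smaller set size then lexicographically. One seeded RNG
#' stream per search; the iteration index is folded into the stream so runs
#' are reproducible.
#'
#' @param model model containing the target construction.
#' @param target a [target_spec()].
#' @param iterations number of search iterations.
#' @param seed integer seed.
#' @param eps_g,delta see [verify_coupled()].
#' @param retry_cap restarts allowed per iteration.
#' @return A `ko_search` object: list with `candidates` (ranked data.frame:
#'   `rank`, `knockouts`, `size`, `mu`, `r_t`, `m`), `sets` (list of id
#'   vectors in the same order), `iterations`, `seed`, `failures`.
#' @export
run_search <- function(model, target, iterations = 200, seed = 1,
                       eps_g = 1e-6, delta = 1e-6, retry_cap = 50) {
  stopifnot(iterations >= 1)
  found <- list()
  failures <- 0L
  for (it in seq_len(iterations)) {
    set.seed((seed + 104729 * it) %% 2147483647L)
    cand <- NULL
    for (try in seq_len(retry_cap)) {
      cand <- prune_search_iteration(model, target, eps_g, delta)
      if (!is.null(cand)) break
    }
    if (is.null(cand)) {
      failures <- failures + 1L
      next
    }
    key <- paste(cand$k, collapse = ";")
    if (is.null(found[[key]])) found[[key]] <- cand
  }
  if (!length(found)) {
    warning("no successful iterations; empty search result")
    return(structure(list(candidates = data.frame(
      rank = integer(), knockouts = character(), size = integer(),
      mu = numeric(), r_t = numeric(), m = numeric()),
      sets = list(), iterations = iterations, seed = seed,
      failures = failures), class = "ko_search"))
  }

  keys <- names(found)
  m <- vapply(found, `[[`, 0, "m")
  size <- vapply(found, function(x) length(x$k), integer(1))
  ord <- order(-m, size, keys)
  found <- found[ord]
  candidates <- data.frame(
    rank = seq_along(found),
    knockouts = names(found),
    size = size[ord],
    mu = vapply(found, `[[`, 0, "mu"),
    r_t = vapply(found, `[[`, 0, "r_t"),
    m = m[ord], row.names = NULL)
  structure(list(candidates = candidates,
                 sets = unname(lapply(found, `[[`, "k")),
                 iterations = iterations, seed = seed, failures = failures),
            class = "ko_search")
}

#' @exportS3Method base::print
print.ko_search <- function(x, ...) {
  cat("<ko_search>", nrow(x$candidates), "distinct knockout sets from",
      x$iterations, "iterations (seed", x$seed, ")\n")
  print(utils::head(x$candidates, 10))
  invisible(x)
}
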