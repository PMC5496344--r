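# Hand-sized networks with known LP optima, built in code, plus an
# LP-ratio coupling oracle used to cross-check flux_coupling().

# Build a small single-user model: `rxns` is a named list of
# list(sto = c(met = coef, ...), lb, ub); metabolite compartments are "e"
# for ids ending in "_e", else "c".
micro_model <- function(id, rxns, objective) {
  mets <- sort(unique(unlist(lapply(rxns, function(r) names(r$sto)))))
  metabolites <- data.frame(
    id = mets, name = mets,
    compartment = ifelse(grepl("_e$", mets), "e", "c"),
    formula = "", charge = NA_integer_)
  reactions <- data.frame(
    id = names(rxns), name = names(rxns),
    lower_bound = vapply(rxns, function(r) r$lb, 0),
    upper_bound = vapply(rxns, function(r) r$ub, 0),
    subsystem = "", gpr = "")
  S <- Matrix::Matrix(0, length(mets), length(rxns), sparse = TRUE,
                      dimnames = list(mets, names(rxns)))
  for (r in names(rxns)) S[names(rxns[[r]]$sto), r] <- rxns[[r]]$sto
  metabolic_model(id, data.frame(id = c("e", "c"),
                                 name = c("extracellular", "cytosol")),
                  metabolites, reactions, S, objective = objective)
}

rx <- function(sto, lb = 0, ub = 1000) list(sto = sto, lb = lb, ub = ub)

# Five nets with hand-computed optima (frozen expected values).
micro_nets <- function() {
  list(
    # linear chain: uptake 5 flows through to biomass
    chain = list(
      model = micro_model("chain", list(
        EX_A = rx(c(A_e = -1), lb = -5),
        T_A = rx(c(A_e = -1, A_c = 1)),
        R1 = rx(c(A_c = -1, B_c = 1)),
        BIO = rx(c(B_c = -1))), "BIO"),
      mu = 5),
    # diamond: two parallel unit paths, total inflow 5
    diamond = list(
      model = micro_model("diamond", list(
        EX_A = rx(c(A_e = -1), lb = -5),
        T_A = rx(c(A_e = -1, A_c = 1)),
        R1 = rx(c(A_c = -1, B_c = 1)),
        R2 = rx(c(A_c = -1, C_c = 1)),
        R3 = rx(c(B_c = -1, D_c = 1)),
        R4 = rx(c(C_c = -1, D_c = 1)),
        BIO = rx(c(D_c = -1))), "BIO"),
      mu = 5),
    # two-substrate stoichiometric yield: biomass needs 2 A + 1 B
    yield = list(
      model = micro_model("yield", list(
        EX_A = rx(c(A_e = -1), lb = -4),
        EX_B = rx(c(B_e = -1), lb = -1),
        T_A = rx(c(A_e = -1, A_c = 1)),
        T_B = rx(c(B_e = -1, B_c = 1)),
        BIO = rx(c(A_c = -2, B_c = -1))), "BIO"),
      mu = 1),
    # amplifying stoichiometry: 1 A -> 3 B, biomass takes 2 B
    scale = list(
      model = micro_model("scale", list(
        EX_A = rx(c(A_e = -1), lb = -2),
        T_A = rx(c(A_e = -1, A_c = 1)),
        R1 = rx(c(A_c = -1, B_c = 3)),
        BIO = rx(c(B_c = -2))), "BIO"),
      mu = 3),
    # capacity-split: direct route capped at 4, detour carries the rest
    split = list(
      model = micro_model("split", list(
        EX_A = rx(c(A_e = -1), lb = -6),
        T_A = rx(c(A_e = -1, A_c = 1)),
        R1 = rx(c(A_c = -1, B_c = 1), ub = 4),
        R2 = rx(c(A_c = -1, C_c = 1)),
        R3 = rx(c(C_c = -1, B_c = 1)),
        BIO = rx(c(B_c = -1))), "BIO"),
      mu = 6))
}

# LP-ratio coupling oracle: classifies a pair from the attainable range of
# v_i with v_j pinned to zero and to feasible nonzero values of either
# sign (the textbook definitions, computed directly).
oracle_pair <- function(model, i, j, rng, tol = 1e-6) {
  vmax <- function(r, pin, val) {
    m <- set_bounds(model, pin, lb = val, ub = val)
    c(phycoflux:::optimize_flux(m, r, maximize = FALSE),
      phycoflux:::optimize_flux(m, r, maximize = TRUE))
  }
  ri <- rng[rng$reaction == i, ]
  rj <- rng[rng$reaction == j, ]
  i_zero_when_j0 <- all(abs(vmax(i, j, 0)) < tol, na.rm = TRUE)
  j_zero_when_i0 <- all(abs(vmax(j, i, 0)) < tol, na.rm = TRUE)
  if (i_zero_when_j0 && j_zero_when_i0) {
    ratios <- c()
    if (rj$max > tol) {
      t <- min(1, rj$max / 2)
      ratios <- c(ratios, vmax(i, j, t) / t)
    }
    if (rj$min < -tol) {
      t <- -min(1, abs(rj$min) / 2)
      ratios <- c(ratios, vmax(i, j, t) / t)
    }
    ratios <- ratios[is.finite(ratios)]
    if (length(ratios) &&
        diff(range(ratios)) <= 1e-6 * max(1, max(abs(ratios))))
      "fully" else "partially"
  } else if (i_zero_when_j0) {
    "directional_i_to_j"
  } else if (j_zero_when_i0) {
    "directional_j_to_i"
  } else "uncoupled"
}

oracle_coupling <- function(model, tol = 1e-6) {
  m <- phycoflux:::open_exchanges(model)
  rng <- fva(m, fraction_of_optimum = 0)
  blocked <- rng$reaction[abs(rng$min) < tol & abs(rng$max) < tol]
  live <- setdiff(rng$reaction, blocked)
  out <- list()
  for (a in seq_len(max(0L, length(live) - 1L))) {
    for (b in seq(a + 1L, length(live))) {
      out[[length(out) + 1L]] <- data.frame(
        i = live[a], j = live[b],
        class = oracle_pair(m, live[a], live[b], rng, tol))
    }
  }
  list(pairs = do.call(rbind, out), blocked = blocked)
}

# Planted toy shared across test files (generation is cheap and pure).
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_model()
    cache
  }
})
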