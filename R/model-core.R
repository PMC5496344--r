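#' Construct a compartmentalized metabolic model
#'
#' A `metabolic_model` is the central container of the package: a
#' stoichiometric matrix with flux bounds, gene-protein-reaction (GPR) rules,
#' compartment assignments and one or more biomass objectives. Fluxes are in
#' mmol gDW^-1 h^-1 throughout; the flux of a biomass reaction is the
#' specific growth rate mu in h^-1.
#'
#' @param id model identifier.
#' @param compartments data.frame with columns `id`, `name`.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (Hill-notation string, `""` if unknown; pseudo-elements such
#'   as `R` are allowed) and `charge` (integer, `NA` if unknown).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr` (boolean rule over gene ids written
#'   with `and`/`or`/parentheses, `""` for none).
#' @param S stoichiometric matrix (metabolites x reactions), dense or
#'   [Matrix::sparseMatrix()]; dimnames must match metabolite/reaction ids.
#' @param genes character vector of gene ids; defaults to the genes
#'   referenced by the GPR rules.
#' @param objective reaction id whose flux is maximized by [fba()].
#' @param biomass_variants named character vector mapping variant names
#'   (e.g. `replete`, `depleted`) to biomass reaction ids.
#'
#' @return An object of class `metabolic_model`. Reaction kinds
#'   (`exchange`, `demand`, `biomass`, `light`, `transport`, `enzymatic`)
#'   are classified on construction; see [model_stats()].
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions, S,
                            genes = NULL, objective,
                            biomass_variants = character()) {
  compartments <- as.data.frame(compartments, stringsAsFactors = FALSE)
  metabolites  <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions    <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- ""
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  metabolites$formula[is.na(metabolites$formula)] <- ""

  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (nrow(S) != length(rownames(S)) || ncol(S) != length(colnames(S)))
    stop("S must carry metabolite row names and reaction column names")
  S <- S[metabolites$id, reactions$id, drop = FALSE]

  if (anyDuplicated(compartments$id)) stop("duplicate compartment ids")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  bad <- setdiff(metabolites$compartment, compartments$id)
  if (length(bad)) stop("unknown compartment id(s): ", paste(bad, collapse = ", "))
  if (any(reactions$lower_bound > reactions$upper_bound))
    stop("lower_bound > upper_bound for some reaction")
  if (!is.na(objective) && !objective %in% reactions$id)
    stop("objective reaction not in model: ", objective)
  if (length(biomass_variants) &&
      !all(biomass_variants %in% reactions$id))
    stop("biomass variant reaction missing from model")

  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }

  m <- structure(
    list(id = id, compartments = compartments, metabolites = metabolites,
         reactions = reactions, S = S, genes = genes, objective = objective,
         biomass_variants = biomass_variants),
    class = "metabolic_model")
  m$reactions$kind <- classify_reactions(m)
  m
}

#' @exportS3Method base::print
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", nrow(x$reactions), " reactions, ", nrow(x$metabolites),
      " metabolites, ", length(x$genes), " genes, ",
      nrow(x$compartments), " compartments\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  if (length(x$biomass_variants))
    cat("  biomass variants: ",
        paste(names(x$biomass_variants), x$biomass_variants,
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Kind classification. Precedence: exchange > demand > biomass > light >
# transport > enzymatic. An exchange is a single-species boundary reaction
# (EX_ prefix or reversible single-species); a demand is a single-species
# irreversible sink (DM_ prefix or lb >= 0); transport spans >= 2
# compartments; light reactions are those in which a photon species
# participates. This matches common COBRA practice.
classify_reactions <- function(model) {
  S <- model$S
  met_comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  photon <- grepl("photon|hnu", model$metabolites$id, ignore.case = TRUE) |
    grepl("photon", model$metabolites$name, ignore.case = TRUE)
  names(photon) <- model$metabolites$id
  bio_ids <- unique(c(model$biomass_variants,
                      model$reactions$id[grepl("^BIO|biomass", model$reactions$id,
                                               ignore.case = TRUE)]))
  vapply(seq_len(ncol(S)), function(j) {
    part <- rownames(S)[S[, j] != 0]
    rid <- colnames(S)[j]
    lb <- model$reactions$lower_bound[j]
    if (length(part) == 1L) {
      if (grepl("^EX_", rid)) return("exchange")
      if (grepl("^(DM_|SK_|sink_)", rid)) return("demand")
      if (rid %in% bio_ids) return("biomass")
      return(if (lb < 0) "exchange" else "demand")
    }
    if (rid %in% bio_ids) return("biomass")
    if (any(photon[part])) return("light")
    if (length(unique(met_comp[part])) >= 2L) return("transport")
    "enzymatic"
  }, character(1))
}

#' Summary statistics of a model
#'
#' Counts reactions, metabolites, genes and compartments, and partitions the
#' reactions by kind: exchanges with the medium, demand sinks, biomass
#' equations, light-driven reactions, inter-compartment transports, and
#' enzymatic reactions split into gene-associated and orphan (no GPR).
#' The kind partition is exhaustive and disjoint, so the per-kind counts sum
#' to `n_reactions` and `n_gene_associated + n_orphan_enzymatic ==
#' n_enzymatic`.
#'
#' @param model a [metabolic_model()].
#' @return A one-row data.frame of counts.
#' @export
model_stats <- function(model) {
  k <- model$reactions$kind
  enz <- k == "enzymatic"
  has_gpr <- nzchar(model$reactions$gpr)
  data.frame(
    n_reactions = nrow(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_genes = length(model$genes),
    n_compartments = nrow(model$compartments),
    n_exchange = sum(k == "exchange"),
    n_demand = sum(k == "demand"),
    n_biomass = sum(k == "biomass"),
    n_light = sum(k == "light"),
    n_transport = sum(k == "transport"),
    n_enzymatic = sum(enz),
    n_gene_associated = sum(enz & has_gpr),
    n_orphan_enzymatic = sum(enz & !has_gpr))
}

#' Knock out genes
#'
#' Re-evaluates every GPR rule with the given genes absent and closes
#' (bounds 0,0) each reaction whose rule evaluates to inactive. Reactions
#' without a GPR are untouched. The input model is not modified.
#'
#' @param model a [metabolic_model()].
#' @param gene_ids character vector of gene ids to delete.
#' @return A new model with the affected reactions disabled.
#' @export
knockout_genes <- function(model, gene_ids) {
  if (!length(gene_ids)) return(model)
  unknown <- setdiff(gene_ids, model$genes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  off <- vapply(model$reactions$gpr, function(g) {
    nzchar(g) && !gpr_eval(g, absent = gene_ids)
  }, logical(1), USE.NAMES = FALSE)
  model$reactions$lower_bound[off] <- 0
  model$reactions$upper_bound[off] <- 0
  model
}

#' Disable reactions by id
#'
#' Sets bounds (0, 0) on the listed reactions; used for reaction-knockout
#' simulations and by the strain-design search.
#'
#' @param model a [metabolic_model()].
#' @param reaction_ids character vector of reaction ids.
#' @return A new model with those reactions closed.
#' @export
knockout_reactions <- function(model, reaction_ids) {
  if (!length(reaction_ids)) return(model)
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}

#' Set bounds of a reaction
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction id.
#' @param lb,ub new bounds; `NA` keeps the current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NA, ub = NA) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  if (!is.na(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.na(ub)) model$reactions$upper_bound[i] <- ub
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
    stop("lower bound above upper bound for ", reaction_id)
  model
}

# internal: ids of exchange reactions (optionally restricted to uptakes open)
exchange_ids <- function(model) model$reactions$id[model$reactions$kind == "exchange"]

# internal: the single species of a single-species reaction
boundary_species <- function(model, rid) {
  j <- match(rid, colnames(model$S))
  rownames(model$S)[model$S[, j] != 0]
}

#' Metabolite connectivity ranking
#'
#' Number of reactions each metabolite participates in, ranked in decreasing
#' order. Highly connected metabolites are typically currency species (H+,
#' ATP, water, phosphate, coenzyme A in genome-scale models).
#'
#' @param model a [metabolic_model()].
#' @param top_k optionally return only the first `top_k` rows.
#' @return data.frame with columns `metabolite`, `name`, `n_reactions`.
#' @export
connectivity <- function(model, top_k = NULL) {
  counts <- Matrix::rowSums(model$S != 0)
  ord <- order(counts, decreasing = TRUE)
  out <- data.frame(metabolite = model$metabolites$id[ord],
                    name = model$metabolites$name[ord],
                    n_reactions = as.integer(counts[ord]),
                    row.names = NULL)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
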