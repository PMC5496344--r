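# Declarative media conditions: trophic templates, exchange-bound overrides,
# reaction disabling and gene knockouts, applied as a pure overlay.

#' Describe one growth condition
#'
#' A `media_condition` is a declarative constraint overlay for a single
#' experiment: a trophic template plus exchange-bound overrides, disabled
#' reactions and gene knockouts, optionally with the in vivo growth
#' observation it is validated against.
#'
#' Templates encode the standard in silico media:
#' * `autotrophic`: organic-carbon uptakes closed, oxygen uptake capped at
#'   10 mmol gDW^-1 h^-1, photon uptake open, light-inhibited enzymes
#'   (subsystem tagged `light-inhibited`) turned off, chloroplast-to-cytosol
#'   water transport made irreversible where such a transport exists;
#' * `mixotrophic`: as autotrophic but organic carbon allowed;
#' * `heterotrophic`: photon uptakes and light-driven reactions closed,
#'   organic carbon, CO2 and O2 allowed;
#' * `dark`: photon uptakes and light-driven reactions closed;
#' * `none`: no template constraints.
#'
#' @param name condition label.
#' @param template one of `"none"`, `"autotrophic"`, `"mixotrophic"`,
#'   `"heterotrophic"`, `"dark"`.
#' @param exchange_lb,exchange_ub named numeric vectors of bound overrides,
#'   names are exchange reaction ids (uptake is negative flux).
#' @param disable_reactions reaction ids forced to (0, 0).
#' @param knockout_genes gene ids to delete.
#' @param expected_growth in vivo observation (`TRUE`/`FALSE`/`NA`).
#' @param closed_by_default if `TRUE`, all uptakes not named in
#'   `exchange_lb` are closed before applying the overrides.
#' @return A `media_condition` object.
#' @export
media_condition <- function(name, template = "none",
                            exchange_lb = numeric(), exchange_ub = numeric(),
                            disable_reactions = character(),
                            knockout_genes = character(),
                            expected_growth = NA,
                            closed_by_default = FALSE) {
  template <- match.arg(template, c("none", "autotrophic", "mixotrophic",
                                    "heterotrophic", "dark"))
  structure(list(name = name, template = template,
                 exchange_lb = exchange_lb, exchange_ub = exchange_ub,
                 disable_reactions = disable_reactions,
                 knockout_genes = knockout_genes,
                 expected_growth = expected_growth,
                 closed_by_default = closed_by_default),
            class = "media_condition")
}

#' @exportS3Method base::print
print.media_condition <- function(x, ...) {
  cat("<media_condition>", x$name, "template:", x$template, "\n")
  invisible(x)
}

# Species-driven classification of exchanges, so templates work on any
# model that carries formulas: organic carbon = exchanged species with >= 2
# carbon atoms (this excludes CO2 and urea, which are a carbon and a
# nitrogen source respectively); photon exchanges by species id/name.
exchange_groups <- function(model) {
  ex <- exchange_ids(model)
  sp <- vapply(ex, function(r) boundary_species(model, r), character(1))
  met <- model$metabolites[match(sp, model$metabolites$id), ]
  carbon <- vapply(met$formula, function(f) {
    cf <- parse_formula(f)
    if (is.null(cf)) 0 else if ("C" %in% names(cf)) cf[["C"]] else 0
  }, numeric(1))
  photon <- grepl("photon|hnu", met$id, ignore.case = TRUE) |
    grepl("photon", met$name, ignore.case = TRUE)
  o2 <- vapply(met$formula, function(f) identical(parse_formula(f), c(O = 2)),
               logical(1))
  list(all = ex,
       organic_carbon = ex[carbon >= 2 & !photon],
       photon = ex[photon],
       o2 = ex[o2])
}

#' Apply a media condition to a model
#'
#' Pure and idempotent: returns a new model, the input is unchanged.
#' Order of application: template constraints, closed-by-default, exchange
#' overrides, disabled reactions, gene knockouts.
#'
#' @param model a [metabolic_model()].
#' @param condition a [media_condition()].
#' @return The constrained model.
#' @export
apply_condition <- function(model, condition) {
  stopifnot(inherits(condition, "media_condition"))
  m <- model
  gr <- exchange_groups(m)
  light_rxns <- m$reactions$id[m$reactions$kind == "light"]
  inhibited <- m$reactions$id[grepl("light-inhibited", m$reactions$subsystem,
                                    fixed = TRUE)]

  close_uptake <- function(m, ids) {
    idx <- match(ids, m$reactions$id)
    m$reactions$lower_bound[idx] <- pmax(m$reactions$lower_bound[idx], 0)
    m
  }
  shut <- function(m, ids) {
    idx <- match(ids, m$reactions$id)
    m$reactions$lower_bound[idx] <- 0
    m$reactions$upper_bound[idx] <- 0
    m
  }

  tpl <- condition$template
  if (tpl %in% c("autotrophic", "mixotrophic")) {
    if (tpl == "autotrophic") m <- close_uptake(m, gr$organic_carbon)
    for (r in gr$o2) {
      i <- match(r, m$reactions$id)
      m$reactions$lower_bound[i] <- max(m$reactions$lower_bound[i], -10)
    }
    m <- shut(m, inhibited)
    # water leaves the chloroplast only
    w <- m$reactions$id[grepl("h2o", m$reactions$id, ignore.case = TRUE) &
                          m$reactions$kind == "transport" &
                          grepl("ch|hc", m$reactions$id)]
    for (r in w) {
      i <- match(r, m$reactions$id)
      m$reactions$lower_bound[i] <- max(m$reactions$lower_bound[i], 0)
    }
  } else if (tpl %in% c("heterotrophic", "dark")) {
    m <- shut(m, c(gr$photon, light_rxns))
  }

  if (isTRUE(condition$closed_by_default))
    m <- close_uptake(m, setdiff(gr$all, names(condition$exchange_lb)))

  ov <- c(names(condition$exchange_lb), names(condition$exchange_ub),
          condition$disable_reactions)
  missing_ids <- setdiff(ov, m$reactions$id)
  if (length(missing_ids))
    stop("condition '", condition$name, "' references unknown reaction(s): ",
         paste(missing_ids, collapse = ", "))
  for (r in names(condition$exchange_lb))
    m <- set_bounds(m, r, lb = condition$exchange_lb[[r]])
  for (r in names(condition$exchange_ub))
    m <- set_bounds(m, r, ub = condition$exchange_ub[[r]])
  m <- shut(m, condition$disable_reactions)
  if (length(condition$knockout_genes))
    m <- knockout_genes(m, condition$knockout_genes)
  m
}

# ---- battery files ---------------------------------------------------------
# One row per condition. Overrides are encoded "EX_a:lb=-4;EX_b:ub=0";
# knockouts and disabled reactions are ";"-separated lists.

fmt_overrides <- function(lbs, ubs) {
  parts <- c(
    if (length(lbs)) paste0(names(lbs), ":lb=", vapply(lbs, format, "")),
    if (length(ubs)) paste0(names(ubs), ":ub=", vapply(ubs, format, "")))
  paste(parts, collapse = ";")
}

parse_overrides <- function(x) {
  lbs <- numeric(); ubs <- numeric()
  if (!is.na(x) && nzchar(x)) {
    for (tok in strsplit(x, ";", fixed = TRUE)[[1]]) {
      m <- regmatches(tok, regexec("^([^:]+):(lb|ub)=(.+)$", tok))[[1]]
      if (length(m) != 4) stop("malformed override: '", tok, "'")
      if (m[3] == "lb") lbs[m[2]] <- as.numeric(m[4]) else
        ubs[m[2]] <- as.numeric(m[4])
    }
  }
  list(lb = lbs, ub = ubs)
}

#' Write a condition battery to a delimited file
#'
#' @param conditions list of [media_condition()] objects.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_battery <- function(conditions, path) {
  rows <- lapply(conditions, function(cd) {
    data.frame(
      name = cd$name, template = cd$template,
      overrides = fmt_overrides(cd$exchange_lb, cd$exchange_ub),
      disable_reactions = paste(cd$disable_reactions, collapse = ";"),
      knockout_genes = paste(cd$knockout_genes, collapse = ";"),
      expected_growth = cd$expected_growth)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a condition battery from a delimited file
#'
#' @param path battery file written by [write_battery()] (tab-separated,
#'   columns `name`, `template`, `overrides`, `disable_reactions`,
#'   `knockout_genes`, `expected_growth`).
#' @return List of [media_condition()] objects.
#' @export
read_battery <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = "character")
  need <- c("name", "template", "overrides", "disable_reactions",
            "knockout_genes", "expected_growth")
  if (!all(need %in% names(tab)))
    stop("battery file lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    ov <- parse_overrides(tab$overrides[i])
    split_list <- function(x) {
      if (is.na(x) || !nzchar(x)) character() else
        strsplit(x, ";", fixed = TRUE)[[1]]
    }
    media_condition(
      name = tab$name[i], template = tab$template[i],
      exchange_lb = ov$lb, exchange_ub = ov$ub,
      disable_reactions = split_list(tab$disable_reactions[i]),
      knockout_genes = split_list(tab$knockout_genes[i]),
      expected_growth = as.logical(tab$expected_growth[i]))
  })
}
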