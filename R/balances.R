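# Elemental formula handling and reaction balance checking.

#' Parse a Hill-notation chemical formula
#'
#' Accepts standard element symbols plus single-letter pseudo-elements
#' (e.g. `R` for a generic acyl rest, `X` for a halide placeholder), which
#' are treated as ordinary atoms.
#'
#' @param formula string such as `"C6H12O6"`; `""` or `NA` mean unknown.
#' @return Named numeric vector of element counts, or `NULL` for unknown.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1
  counts <- tapply(n, el, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Check mass and charge balance of every reaction
#'
#' For each reaction, sums coefficient-weighted elemental compositions and
#' charges of its participants. Light-driven, exchange and demand reactions,
#' and biomass pseudo-reactions, exchange matter with outside the modeled
#' system and are marked `skipped`. A reaction involving a metabolite with
#' unknown formula (or charge) is marked uncheckable rather than unbalanced.
#'
#' @param model a [metabolic_model()].
#' @param tol absolute tolerance on the per-element residual.
#' @return data.frame with one row per reaction: `reaction`, `kind`,
#'   `skipped`, `mass_checked`, `mass_balanced`, `mass_deficit` (formatted
#'   element residual, `""` when balanced), `charge_checked`,
#'   `charge_balanced`. The summary fractions of unbalanced reactions among
#'   those checked are attached as attributes `frac_mass_unbalanced` and
#'   `frac_charge_unbalanced`.
#' @export
check_balances <- function(model, tol = 1e-8) {
  rx <- model$reactions
  skip_kinds <- c("exchange", "demand", "light", "biomass")
  forms <- lapply(model$metabolites$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NULL else parse_formula(f)
  })
  names(forms) <- model$metabolites$id
  charge <- stats::setNames(model$metabolites$charge, model$metabolites$id)

  res <- lapply(seq_len(nrow(rx)), function(j) {
    rid <- rx$id[j]
    kind <- rx$kind[j]
    if (kind %in% skip_kinds)
      return(data.frame(reaction = rid, kind = kind, skipped = TRUE,
                        mass_checked = FALSE, mass_balanced = NA,
                        mass_deficit = "", charge_checked = FALSE,
                        charge_balanced = NA))
    coefs <- model$S[, rid]
    part <- names(coefs)[coefs != 0]
    coefs <- coefs[part]
    mass_checked <- !any(vapply(forms[part], is.null, logical(1)))
    mass_balanced <- NA
    deficit <- ""
    if (mass_checked) {
      total <- numeric()
      for (i in seq_along(part)) {
        f <- forms[[part[i]]]
        for (e in names(f)) total[e] <- (if (e %in% names(total)) total[e] else 0) +
            coefs[i] * f[[e]]
      }
      bad <- total[abs(total) > tol]
      mass_balanced <- length(bad) == 0L
      if (!mass_balanced)
        deficit <- paste(names(bad), signif(unname(bad), 6), sep = ":",
                         collapse = ",")
    }
    charge_checked <- !anyNA(charge[part])
    charge_balanced <- if (charge_checked)
      abs(sum(coefs * charge[part])) <= tol else NA
    data.frame(reaction = rid, kind = kind, skipped = FALSE,
               mass_checked = mass_checked, mass_balanced = mass_balanced,
               mass_deficit = deficit, charge_checked = charge_checked,
               charge_balanced = charge_balanced)
  })
  out <- do.call(rbind, res)
  mc <- out$mass_checked %in% TRUE
  cc <- out$charge_checked %in% TRUE
  attr(out, "frac_mass_unbalanced") <-
    if (any(mc)) mean(!out$mass_balanced[mc]) else NA_real_
  attr(out, "frac_charge_unbalanced") <-
    if (any(cc)) mean(!out$charge_balanced[cc]) else NA_real_
  out
}
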