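# Qualitative growth/no-growth validation and quantitative growth-rate
# prediction.

#' Reference (rich-medium) growth rate
#'
#' FBA optimum in the in silico rich medium used as the reference for
#' growth/no-growth calls. By default the model's own exchange capacities
#' stand — the model is assumed parameterized with its rich-medium uptake
#' limits; passing `uptake_lb` instead opens every exchange to a common
#' uptake bound.
#'
#' @param model a [metabolic_model()].
#' @param uptake_lb optional uptake capacity (positive number `b` sets every
#'   exchange lower bound to `-b`).
#' @return The reference growth rate mu_ref (h^-1).
#' @export
reference_growth <- function(model, uptake_lb = NULL) {
  m <- model
  if (!is.null(uptake_lb)) {
    ex <- m$reactions$kind == "exchange"
    m$reactions$lower_bound[ex] <- -abs(uptake_lb)
  }
  sol <- fba(m)
  if (sol$status != "optimal" || sol$objective_value <= 0)
    stop("model cannot grow in the reference medium (status ",
         sol$status, ")")
  sol$objective_value
}

#' Growth/no-growth call
#'
#' Growth is called when the predicted rate strictly exceeds one third of
#' the reference rate. The call is scale-invariant in (mu, mu_reference).
#'
#' @param mu predicted growth rate (h^-1).
#' @param mu_reference reference growth rate (h^-1), must be positive.
#' @return list with `mu`, `mu_reference`, `call` (logical).
#' @export
growth_call <- function(mu, mu_reference) {
  if (!is.numeric(mu_reference) || mu_reference <= 0)
    stop("mu_reference must be positive")
  list(mu = mu, mu_reference = mu_reference, call = mu > mu_reference / 3)
}

#' Confusion-matrix accuracy summary
#'
#' @param TP,TN,FP,FN counts of true/false positive/negative calls.
#' @return data.frame with the counts, `accuracy_simple` = (TP+TN)/n, and
#'   `accuracy_geometric` = sqrt(sensitivity x specificity). The geometric
#'   mean equals the simple accuracy only in balanced error-free settings;
#'   both are reported, neither replaces the other.
#' @export
confusion_summary <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN, n = n,
             sensitivity = sens, specificity = spec,
             accuracy_simple = (TP + TN) / n,
             accuracy_geometric = sqrt(sens * spec))
}

#' Run a qualitative validation battery
#'
#' Applies each condition (template, overrides, knockouts) to the model,
#' runs FBA, calls growth against one third of the reference rate, and
#' tallies the confusion matrix against the in vivo observations. An
#' infeasible condition is logged and counted as no-growth rather than
#' failing the battery.
#'
#' @param model a [metabolic_model()].
#' @param conditions list of [media_condition()] with `expected_growth` set.
#' @param mu_reference reference rate; computed by [reference_growth()]
#'   when `NULL`.
#' @return list with `calls` (per-condition data.frame: `name`, `mu`,
#'   `call`, `expected`, `label` in TP/TN/FP/FN) and `summary`
#'   (a [confusion_summary()] row).
#' @export
run_battery <- function(model, conditions, mu_reference = NULL) {
  if (is.null(mu_reference)) mu_reference <- reference_growth(model)
  rows <- lapply(conditions, function(cd) {
    if (is.na(cd$expected_growth))
      stop("condition '", cd$name, "' has no expected_growth")
    m <- apply_condition(model, cd)
    sol <- fba(m)
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    if (sol$status != "optimal")
      message("condition '", cd$name, "': ", sol$status,
              "; counted as no growth")
    call <- growth_call(mu, mu_reference)$call
    label <- if (call && cd$expected_growth) "TP"
    else if (!call && !cd$expected_growth) "TN"
    else if (call) "FP" else "FN"
    data.frame(name = cd$name, mu = mu, call = call,
               expected = cd$expected_growth, label = label)
  })
  calls <- do.call(rbind, rows)
  tab <- table(factor(calls$label, levels = c("TP", "TN", "FP", "FN")))
  list(calls = calls,
       summary = confusion_summary(tab[["TP"]], tab[["TN"]],
                                   tab[["FP"]], tab[["FN"]]),
       mu_reference = mu_reference)
}

#' CO2 biofixation and specific uptake rate
#'
#' Biofixation is `C * P * MW_CO2 / MW_C` in g CO2 L^-1 d^-1, where `C` is
#' the carbon mass fraction of biomass and `P` the biomass productivity in
#' g L^-1 d^-1. The specific uptake rate divides by culture concentration
#' `X` (gDW/L) and the molar mass of CO2 and converts days to hours, giving
#' mmol CO2 gDW^-1 h^-1 (the day-to-hour factor 24 is applied here, once).
#'
#' @param C carbon mass fraction of biomass (0..1).
#' @param P biomass productivity (g L^-1 d^-1).
#' @param X cell concentration (gDW/L); required for the specific rate.
#' @param MW_CO2,MW_C molar masses (g/mol).
#' @return list with `biofixation` (g CO2 L^-1 d^-1) and `specific_uptake`
#'   (mmol gDW^-1 h^-1, `NA` if `X` not given).
#' @export
co2_specific_uptake <- function(C, P, X = NULL, MW_CO2 = 44.01,
                                MW_C = 12.011) {
  stopifnot(C >= 0, C <= 1, P >= 0)
  biofix <- C * P * MW_CO2 / MW_C
  specific <- NA_real_
  if (!is.null(X)) {
    if (X <= 0) stop("X must be positive for the specific uptake rate")
    specific <- biofix / X / MW_CO2 * 1000 / 24
  }
  list(biofixation = biofix, specific_uptake = specific)
}

#' Predict the growth rate from measured uptake rates
#'
#' Fixes the named exchange uptake capacities to the measured rates (lower
#' bound `-rate`), closes every other uptake, and maximizes growth. An
#' infeasible problem yields mu = 0 with a warning.
#'
#' @param model a [metabolic_model()].
#' @param measured_uptakes named numeric vector: exchange reaction id ->
#'   uptake rate (positive, mmol gDW^-1 h^-1).
#' @param keep_open exchange ids left open besides the measured ones
#'   (e.g. water, protons, oxygen).
#' @return Predicted mu (h^-1).
#' @export
predict_growth_rate <- function(model, measured_uptakes,
                                keep_open = character()) {
  missing_ids <- setdiff(names(measured_uptakes), model$reactions$id)
  if (length(missing_ids))
    stop("unknown exchange id(s): ", paste(missing_ids, collapse = ", "))
  m <- model
  ex <- exchange_ids(m)
  close <- setdiff(ex, c(names(measured_uptakes), keep_open))
  idx <- match(close, m$reactions$id)
  m$reactions$lower_bound[idx] <- pmax(m$reactions$lower_bound[idx], 0)
  for (r in names(measured_uptakes))
    m <- set_bounds(m, r, lb = -abs(measured_uptakes[[r]]))
  sol <- fba(m)
  if (sol$status != "optimal") {
    warning("prediction problem ", sol$status, "; returning mu = 0")
    return(0)
  }
  sol$objective_value
}

#' Relative errors between experimental and predicted growth rates
#'
#' @param experimental,predicted numeric vectors of equal length; the
#'   experimental value is the denominator.
#' @return data.frame with per-pair `relative_error_pct` and attribute
#'   `mean_error_pct`.
#' @export
error_report <- function(experimental, predicted) {
  stopifnot(length(experimental) == length(predicted))
  if (any(experimental == 0)) stop("experimental rates must be nonzero")
  err <- abs(experimental - predicted) / abs(experimental) * 100
  out <- data.frame(experimental = experimental, predicted = predicted,
                    relative_error_pct = err)
  attr(out, "mean_error_pct") <- mean(err)
  out
}
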