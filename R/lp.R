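# Linear-programming backend.
#
# All flux optimizations in the package reduce to
#   max/min  obj' v   s.t.  S v = 0,  A_ub v <= b_ub,  lb <= v <= ub
# and are solved with HiGHS through scipy.optimize.linprog (reticulate).
# Problems in this package are small (tens to a few hundred reactions), so
# matrices are passed dense.

.lp_env <- new.env(parent = emptyenv())

lp_backend <- function() {
  if (is.null(.lp_env$scipy)) {
    py <- Sys.getenv("PHYCOFLUX_PYTHON", "")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) py <- Sys.which("python")
    if (nzchar(py) && !reticulate::py_available())
      try(reticulate::use_python(py, required = FALSE), silent = TRUE)
    .lp_env$scipy <- reticulate::import("scipy.optimize", delay_load = FALSE)
  }
  .lp_env$scipy
}

# Solve one LP. Returns list(status, objective, x).
# status: "optimal", "infeasible", "unbounded" or "error".
solve_lp <- function(obj, A_eq, b_eq, lb, ub, A_ub = NULL, b_ub = NULL,
                     maximize = TRUE) {
  sp <- lp_backend()
  sense <- if (maximize) -1 else 1
  bounds <- cbind(lb, ub)
  args <- list(c = sense * obj, A_eq = A_eq, b_eq = b_eq, bounds = bounds,
               method = "highs")
  if (!is.null(A_ub)) {
    if (is.null(dim(A_ub))) A_ub <- matrix(A_ub, nrow = 1)
    args$A_ub <- A_ub
    args$b_ub <- b_ub
  }
  res <- do.call(sp$linprog, args)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
                   "error")
  x <- if (status == "optimal") as.numeric(res$x) else rep(NA_real_, length(obj))
  list(status = status,
       objective = if (status == "optimal") sense * res$fun else NA_real_,
       x = x)
}

# Shared assembly of the FBA constraint system from a model.
lp_parts <- function(model) {
  list(S = as.matrix(model$S),
       b = rep(0, nrow(model$S)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

# Objective vector with coefficient 1 on one reaction.
unit_obj <- function(model, reaction_id) {
  obj <- numeric(nrow(model$reactions))
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  obj[i] <- 1
  obj
}

# Maximize (or minimize) the flux of a single reaction, optionally subject
# to extra inequality rows. Returns the objective value or NA.
optimize_flux <- function(model, reaction_id, maximize = TRUE,
                          A_ub = NULL, b_ub = NULL) {
  p <- lp_parts(model)
  sol <- solve_lp(unit_obj(model, reaction_id), p$S, p$b, p$lb, p$ub,
                  A_ub = A_ub, b_ub = b_ub, maximize = maximize)
  if (sol$status == "optimal") sol$objective else NA_real_
}
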