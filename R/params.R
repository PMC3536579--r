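#' Parameter-set helpers
#'
#' Parameters are stored as a named numeric vector of strictly positive
#' values in the order of `model$parameter_names`. Fitting and all
#' information-theoretic quantities work on the natural-log view, which
#' makes positivity automatic and measures relative rather than absolute
#' uncertainty.
#'
#' @param model A `grn_model`.
#' @param values Named numeric vector covering every free parameter.
#' @return `as_parameter_set()` returns the validated, reordered vector.
#' @export
as_parameter_set <- function(model, values) {
  missing <- setdiff(model$parameter_names, names(values))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  v <- values[model$parameter_names]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all parameters must be finite and strictly positive")
  v
}

#' @rdname as_parameter_set
#' @param params Named positive parameter vector.
#' @export
log_parameters <- function(params) log(params)

#' @rdname as_parameter_set
#' @param log_params Named vector of natural-log parameter values.
#' @export
exp_parameters <- function(log_params) exp(log_params)

# Parameter classes used for penalties and sampling ranges: degradation
# rates and Hill exponents are kept within roughly one order of magnitude
# of 1; everything else is allowed a much wider range.
tight_parameter_names <- function(model) {
  c(grep("^h[0-9]+$", model$parameter_names, value = TRUE), "p_deg_rate")
}

#' Sample a synthetic "true" parameter set
#'
#' Draws each parameter log-uniformly from ranges chosen to keep the truth
#' well inside the plausible region enforced by the fitting penalties:
#' `[0.5, 2]` for the protein degradation rate and the Hill exponents,
#' `[0.25, 4]` for promoter strengths, translation strengths and the K
#' constants. The draw is deterministic given `seed`.
#'
#' @param model A `grn_model`.
#' @param seed Integer seed.
#' @param tight_range,wide_range Length-2 positive ranges for the two
#'   parameter classes.
#' @return Named positive parameter vector (length 29 for this model).
#' @export
sample_true_parameters <- function(model, seed,
                                   tight_range = c(0.5, 2),
                                   wide_range = c(0.25, 4)) {
  nm <- model$parameter_names
  with_seed(seed, {
    lo <- ifelse(nm %in% tight_parameter_names(model),
                 log(tight_range[1]), log(wide_range[1]))
    hi <- ifelse(nm %in% tight_parameter_names(model),
                 log(tight_range[2]), log(wide_range[2]))
    v <- exp(stats::runif(length(nm), lo, hi))
    names(v) <- nm
    v
  })
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards so seeded helpers compose predictably.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
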