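#' Solver settings for the network ODE
#'
#' Default tolerances are tight enough that integration error is far below
#' the experimental noise floor of the data generator.
#'
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method Integration method passed to [deSolve::ode()].
#' @param maxsteps Maximum internal steps per output interval.
#' @return A list of solver settings.
#' @export
solver_control <- function(rtol = 1e-8, atol = 1e-10, method = "lsoda",
                           maxsteps = 1000) {
  list(rtol = rtol, atol = atol, method = method, maxsteps = maxsteps)
}

#' Simulate the network model
#'
#' Integrates the 12-state mRNA/protein system from the standard initial
#' condition (all mRNA concentrations 0, all protein concentrations 1),
#' honouring any perturbation carried by `model`. With `sens = TRUE` the
#' forward sensitivity equations are integrated alongside the states,
#' yielding exact derivatives of every state with respect to every natural-log
#' parameter.
#'
#' Integration failures (typical at extreme parameter values during
#' multistart fitting) are reported through the `ok` flag rather than as an
#' error, so callers can count failed attempts.
#'
#' @param model A `grn_model` (possibly perturbed).
#' @param params Named positive parameter vector.
#' @param times Sorted, non-negative time points at which to report states.
#' @param sens Integrate forward sensitivities as well?
#' @param control Solver settings from [solver_control()].
#' @return An object of class `grn_trajectory`: list with `times`, `states`
#'   (matrix, rows = times, columns = state names), `sens` (array
#'   `[time, state, parameter]` of d state / d log theta, or `NULL`), and
#'   `ok` (logical). If `ok` is `FALSE` the other fields may be missing.
#' @export
#' @examples
#' m <- grn_model1()
#' th <- sample_true_parameters(m, seed = 1)
#' tr <- grn_simulate(m, th, seq(0, 20, by = 1))
#' tr$states[1, ]  # mRNA 0, protein 1 at t = 0
grn_simulate <- function(model, params, times, sens = FALSE,
                         control = solver_control()) {
  missing <- setdiff(model$parameter_names, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  params <- params[model$parameter_names]
  stopifnot(!is.unsorted(times), all(times >= 0))
  # numerically unusable values (overflowed trial points during fitting)
  # are a solver-failure signal, not a structural error
  if (any(!is.finite(params)) || any(params <= 0))
    return(structure(list(ok = FALSE, times = times),
                     class = "grn_trajectory"))
  mult <- perturbation_multipliers(model)
  parms <- c(unname(params), mult$pro_mult, mult$rbs_mult, mult$mrna_deg, 0)
  solve_times <- times
  prepend0 <- times[1] > 0
  if (prepend0) solve_times <- c(0, times)

  solve_one <- function(y0, func, parms, method = control$method) {
    out <- try(suppressWarnings(deSolve::ode(
      y = y0, times = solve_times, func = func, parms = parms,
      dllname = "fimdesign", initfunc = "fimdesign_initmod",
      method = method, rtol = control$rtol, atol = control$atol,
      maxsteps = control$maxsteps
    )), silent = TRUE)
    fail <- inherits(out, "try-error") ||
      nrow(out) < length(solve_times) || !all(is.finite(out))
    if (!fail) {
      istate <- attr(out, "istate")
      if (!is.null(istate) && istate[1] < 0) fail <- TRUE
    }
    if (fail) return(NULL)
    if (prepend0) out <- out[-1, , drop = FALSE]
    out
  }
  failed <- structure(list(ok = FALSE, times = times),
                      class = "grn_trajectory")
  y0 <- rep(c(0, 1), 6)
  if (!sens) {
    out <- solve_one(y0, "fimdesign_derivs", parms)
    if (is.null(out)) return(failed)
    states <- out[, 2:13, drop = FALSE]
    colnames(states) <- model$state_names
    return(structure(list(ok = TRUE, times = times, states = states,
                          sens = NULL), class = "grn_trajectory"))
  }
  # Sensitivities: the fully augmented 360-state system with a non-stiff
  # integrator is the fast path (stiff solvers would factorize 360 x 360
  # Jacobians and crawl). Where the problem is genuinely stiff the Adams
  # run fails quickly and one 24-state system per parameter - cheap to
  # factorize - takes over.
  out <- solve_one(c(y0, rep(0, 12 * 29)), "fimdesign_derivs_sens", parms,
                   method = "adams")
  if (!is.null(out)) {
    states <- out[, 2:13, drop = FALSE]
    colnames(states) <- model$state_names
    sens_arr <- array(out[, 14:(13 + 12 * 29), drop = FALSE],
                      dim = c(length(times), 29, 12))
    sens_arr <- aperm(sens_arr, c(1, 3, 2))
    dimnames(sens_arr) <- list(NULL, model$state_names,
                               model$parameter_names)
    return(structure(list(ok = TRUE, times = times, states = states,
                          sens = sens_arr), class = "grn_trajectory"))
  }
  sens_arr <- array(0, dim = c(length(times), 12, 29),
                    dimnames = list(NULL, model$state_names,
                                    model$parameter_names))
  states <- NULL
  for (mu in 1:29) {
    parms[48] <- mu - 1
    out <- solve_one(c(y0, rep(0, 12)), "fimdesign_derivs_sens1", parms)
    if (is.null(out)) return(failed)
    if (is.null(states)) {
      states <- out[, 2:13, drop = FALSE]
      colnames(states) <- model$state_names
    }
    sens_arr[, , mu] <- out[, 14:25]
  }
  structure(list(ok = TRUE, times = times, states = states, sens = sens_arr),
            class = "grn_trajectory")
}

# Extract observed values from a trajectory for (observable, time) pairs,
# clipping small solver-induced negatives at zero. Excursions below -1e-6
# indicate a solver problem and are surfaced as a warning.
traj_values <- function(traj, observables) {
  ti <- match(observables$time, traj$times)
  si <- match(observables$observable, colnames(traj$states))
  if (anyNA(ti) || anyNA(si))
    stop("observable/time not present in trajectory")
  v <- traj$states[cbind(ti, si)]
  if (any(v < -1e-6))
    warning("negative concentrations below -1e-6 clipped to 0")
  pmax(v, 0)
}

# Sensitivity rows (d value / d log theta) for (observable, time) pairs.
traj_sens_rows <- function(traj, observables) {
  ti <- match(observables$time, traj$times)
  si <- match(observables$observable, dimnames(traj$sens)[[2]])
  if (anyNA(ti) || anyNA(si))
    stop("observable/time not present in trajectory")
  out <- matrix(0, nrow(observables), dim(traj$sens)[3],
                dimnames = list(NULL, dimnames(traj$sens)[[3]]))
  for (k in seq_len(nrow(observables)))
    out[k, ] <- traj$sens[ti[k], si[k], ]
  out
}

#' Sensitivities of observables to the log parameters
#'
#' Returns the matrix of derivatives of noiseless model observations with
#' respect to the natural-log parameters, one row per (observable, time)
#' pair and one column per free parameter. The default uses the integrated
#' forward sensitivity equations; `method = "fd"` uses central finite
#' differences in log parameters and serves as an independent cross-check.
#'
#' @param model A `grn_model` (possibly perturbed).
#' @param params Named positive parameter vector.
#' @param observables Data frame with columns `observable` (state name) and
#'   `time`.
#' @param method `"sens"` (forward sensitivities) or `"fd"` (central finite
#'   differences).
#' @param fd_step Log-parameter step for `method = "fd"`. The default
#'   balances truncation error against integrator noise at the default
#'   solver tolerances; much smaller steps amplify solver noise.
#' @param control Solver settings.
#' @return Matrix `length(observables) x 29`, columns ordered and named by
#'   `model$parameter_names`. Errors if the solver fails.
#' @export
observation_jacobian <- function(model, params, observables,
                                 method = c("sens", "fd"), fd_step = 1e-3,
                                 control = solver_control()) {
  method <- match.arg(method)
  params <- as_parameter_set(model, params)
  times <- sort(unique(observables$time))
  if (method == "sens") {
    traj <- grn_simulate(model, params, times, sens = TRUE,
                         control = control)
    if (!traj$ok) stop("solver failed while computing sensitivities")
    return(traj_sens_rows(traj, observables))
  }
  J <- matrix(0, nrow(observables), length(params),
              dimnames = list(NULL, names(params)))
  for (mu in seq_along(params)) {
    for (sgn in c(1, -1)) {
      p2 <- params
      p2[mu] <- p2[mu] * exp(sgn * fd_step)
      traj <- grn_simulate(model, p2, times, control = control)
      if (!traj$ok) stop("solver failed during finite differencing")
      J[, mu] <- J[, mu] + sgn * traj_values(traj, observables)
    }
    J[, mu] <- J[, mu] / (2 * fd_step)
  }
  J
}
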