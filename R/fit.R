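#' Penalty configuration for the fitting cost
#'
#' Each free parameter contributes two penalty residuals `w * theta` and
#' `w / theta`, which together are minimized at `theta = 1`, the natural
#' scale of the problem, and keep search algorithms away from extreme
#' values. The weight is 0.1 for the protein degradation rate and the Hill
#' exponents (confining them to roughly one order of magnitude around 1)
#' and 1e-4 for all other parameters (roughly eight orders of magnitude).
#'
#' @param model A `grn_model`.
#' @param tight_w,wide_w Penalty weights for the two parameter classes.
#' @return Named vector of weights, one per free parameter.
#' @export
penalty_config <- function(model, tight_w = 0.1, wide_w = 1e-4) {
  stopifnot(tight_w > 0, wide_w > 0)
  w <- ifelse(model$parameter_names %in% tight_parameter_names(model),
              tight_w, wide_w)
  names(w) <- model$parameter_names
  w
}

# Range on which multistart draws starting points: where the penalty cost
# for a parameter stays O(1), i.e. [w, 1/w].
penalty_ranges <- function(weights) {
  cbind(lower = pmin(weights, 1 / weights), upper = pmax(1 / weights, weights))
}

#' Penalty residual vector
#'
#' @param params Named positive parameter vector.
#' @param weights Penalty weights from [penalty_config()].
#' @return Vector of length `2 * length(params)`, entries
#'   `(w1*theta1, w1/theta1, w2*theta2, ...)`.
#' @export
penalty_residuals <- function(params, weights) {
  weights <- weights[names(params)]
  as.vector(rbind(weights * params, weights / params))
}

# Derivative of the penalty residual stack with respect to log theta
# (diagonal blocks: d(w*theta)/dlog = w*theta, d(w/theta)/dlog = -w/theta).
penalty_jacobian <- function(params, weights) {
  weights <- weights[names(params)]
  n <- length(params)
  J <- matrix(0, 2 * n, n, dimnames = list(NULL, names(params)))
  J[cbind(2 * seq_len(n) - 1, seq_len(n))] <- weights * params
  J[cbind(2 * seq_len(n), seq_len(n))] <- -weights / params
  J
}

# Pre-group a dataset by perturbation so one ODE solve serves every row of
# the same perturbed model. Assay rows map directly onto parameters.
build_residual_structure <- function(data, model) {
  stopifnot(nrow(data) > 0)
  is_assay <- grepl("^assay_", data$experiment_id)
  groups <- list()
  ts <- data[!is_assay, , drop = FALSE]
  if (nrow(ts)) {
    pert_key <- sub("\\|.*$", "", ts$experiment_id)
    for (key in unique(pert_key)) {
      idx <- which(!is_assay)[pert_key == key]
      e <- parse_experiment_id(data$experiment_id[idx[1]])
      obs <- data.frame(observable = data$observable[idx],
                        time = data$time[idx])
      groups[[key]] <- list(
        idx = idx,
        model = apply_perturbation(model, e$perturbation$kind,
                                   e$perturbation$gene),
        obs = obs,
        times = sort(unique(obs$time))
      )
    }
  }
  assay <- NULL
  if (any(is_assay)) {
    idx <- which(is_assay)
    par_idx <- match(data$observable[idx], model$parameter_names)
    if (anyNA(par_idx)) stop("assay rows with unknown parameter observable")
    assay <- list(idx = idx, par_idx = par_idx,
                  log_obs = log(data$value[idx]), sigma = data$sigma[idx])
  }
  list(groups = groups, assay = assay, n = nrow(data),
       value = data$value, sigma = data$sigma)
}

# Residual vector at a parameter set; returns NULL on solver failure.
eval_residuals <- function(struct, params, control) {
  r <- numeric(struct$n)
  for (g in struct$groups) {
    traj <- grn_simulate(g$model, params, g$times, control = control)
    if (!traj$ok) return(NULL)
    pred <- traj_values(traj, g$obs)
    r[g$idx] <- (struct$value[g$idx] - pred) / struct$sigma[g$idx]
  }
  a <- struct$assay
  if (!is.null(a))
    r[a$idx] <- (a$log_obs - log(params)[a$par_idx]) / a$sigma
  r
}

# Jacobian d r / d log theta of the data residuals; NULL on solver failure.
eval_residual_jacobian <- function(struct, params, control) {
  J <- matrix(0, struct$n, length(params),
              dimnames = list(NULL, names(params)))
  for (g in struct$groups) {
    traj <- grn_simulate(g$model, params, g$times, sens = TRUE,
                         control = control)
    if (!traj$ok) return(NULL)
    J[g$idx, ] <- -traj_sens_rows(traj, g$obs) / struct$sigma[g$idx]
  }
  a <- struct$assay
  if (!is.null(a))
    J[cbind(a$idx, a$par_idx)] <- -1 / a$sigma
  J
}

#' Residuals of a dataset at given parameters
#'
#' One entry per dataset row, in row order: `(y_obs - y_pred) / sigma` for
#' time-series rows, `(log y_obs - log theta) / sigma` for gel-shift assay
#' rows.
#'
#' @param params Named positive parameter vector.
#' @param data A `grn_dataset`.
#' @param model A `grn_model`.
#' @param control Solver settings.
#' @return Residual vector of length `nrow(data)`. Errors if the solver
#'   fails at `params`.
#' @export
dataset_residuals <- function(params, data, model,
                              control = solver_control()) {
  params <- as_parameter_set(model, params)
  r <- eval_residuals(build_residual_structure(data, model), params, control)
  if (is.null(r)) stop("solver failed at the supplied parameters")
  r
}

#' Penalized cost at a parameter set
#'
#' One half the sum of squared data and penalty residuals.
#'
#' @inheritParams dataset_residuals
#' @param weights Penalty weights; `NULL` for data-only cost.
#' @return Scalar cost; `NA` if the solver fails.
#' @export
dataset_cost <- function(params, data, model, weights = penalty_config(model),
                         control = solver_control()) {
  params <- as_parameter_set(model, params)
  r <- eval_residuals(build_residual_structure(data, model), params, control)
  if (is.null(r)) return(NA_real_)
  cost <- 0.5 * sum(r^2)
  if (!is.null(weights))
    cost <- cost + 0.5 * sum(penalty_residuals(params, weights)^2)
  cost
}

#' Fit the model to a dataset by penalized least squares
#'
#' Minimizes half the sum of squared residuals (data residuals plus the
#' penalty residuals of [penalty_config()]) over the natural-log
#' parameters with the Levenberg-Marquardt algorithm, using the integrated
#' forward sensitivities as the exact Jacobian. Working in log parameters
#' keeps all parameters positive and makes the optimization unconstrained.
#'
#' Convergence is monitored through the angle `alpha` between the residual
#' vector and the tangent plane spanned by the Jacobian columns: at a local
#' minimum the residual is orthogonal to the tangent plane and `alpha`
#' approaches 90 degrees. A fit is declared converged when the optimizer
#' reports a relative-reduction/step-size stop or when `cos(alpha)` falls
#' below `angle_tol`. Solver failures at trial points are treated as
#' infinite-cost points so the algorithm can retreat.
#'
#' @param data A `grn_dataset`.
#' @param model A `grn_model` (unperturbed).
#' @param init Named positive starting parameter vector.
#' @param weights Penalty weights.
#' @param control Solver settings.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @param angle_tol Convergence threshold on `cos(alpha)`.
#' @param ftol,ptol Relative cost-reduction and step-size stopping
#'   tolerances of the LM run. Because the cost surface is sloppy, descent
#'   continues making vanishing progress along near-flat directions for
#'   thousands of iterations; the defaults stop once the relative
#'   improvement per step is below 1e-6. The distinct-minimum diagnostics
#'   depend on these tolerances, which is why they are recorded in the
#'   result.
#' @return An object of class `grn_fit` with elements `params`, `cost`,
#'   `data_cost`, `residuals` (data part), `penalty_residuals`,
#'   `convergence_angle` (degrees), `cos_alpha`, `status` (one of
#'   `"converged"`, `"not_converged"`, `"solver_failed"`), `niter`,
#'   `n_solver_failures`, `start`, plus the data and model for downstream
#'   diagnostics.
#' @export
grn_fit <- function(data, model, init, weights = penalty_config(model),
                    control = solver_control(), maxiter = 300,
                    angle_tol = 1e-4, ftol = 1e-6, ptol = 1e-8) {
  init <- as_parameter_set(model, init)
  struct <- build_residual_structure(data, model)
  n_total <- struct$n + 2 * length(init)
  big <- sqrt(2e12 / n_total)  # residual stack of an "infinite cost" point
  nfail <- 0L

  stack_fn <- function(lt) {
    params <- exp_parameters(stats::setNames(lt, names(init)))
    if (any(!is.finite(params)) || any(params <= 0)) {
      nfail <<- nfail + 1L
      return(rep(big, n_total))
    }
    r <- eval_residuals(struct, params, control)
    if (is.null(r)) {
      nfail <<- nfail + 1L
      return(rep(big, n_total))
    }
    r_pen <- c(r, penalty_residuals(params, weights))
    if (any(!is.finite(r_pen))) {
      nfail <<- nfail + 1L
      return(rep(big, n_total))
    }
    r_pen
  }
  stack_jac <- function(lt) {
    params <- exp_parameters(stats::setNames(lt, names(init)))
    if (any(!is.finite(params)) || any(params <= 0))
      return(matrix(0, n_total, length(init)))
    J <- eval_residual_jacobian(struct, params, control)
    if (is.null(J)) J <- matrix(0, struct$n, length(init))
    J <- rbind(J, penalty_jacobian(params, weights))
    J[!is.finite(J)] <- 0
    J
  }

  r0 <- eval_residuals(struct, init, control)
  if (is.null(r0)) {
    fit <- list(params = init, cost = Inf, data_cost = Inf,
                residuals = NULL, penalty_residuals = NULL,
                convergence_angle = NA_real_, cos_alpha = NA_real_,
                status = "solver_failed", niter = 0L,
                n_solver_failures = 1L, start = init,
                data = data, model = model, weights = weights,
                control = control, angle_tol = angle_tol,
                ftol = ftol, ptol = ptol)
    class(fit) <- "grn_fit"
    return(fit)
  }

  res <- suppressWarnings(minpack.lm::nls.lm(
    par = log_parameters(init), fn = stack_fn, jac = stack_jac,
    control = minpack.lm::nls.lm.control(
      maxiter = maxiter, ftol = ftol, ptol = ptol, gtol = 0,
      maxfev = 3000
    )
  ))
  params <- exp_parameters(stats::setNames(res$par, names(init)))
  r <- eval_residuals(struct, params, control)
  if (is.null(r)) {
    # optimizer stopped on a point it could not re-evaluate; report failure
    status <- "solver_failed"
    r_full <- NULL; cosal <- NA_real_; angle <- NA_real_
    cost <- Inf; data_cost <- Inf; pen <- NULL
  } else {
    pen <- penalty_residuals(params, weights)
    r_full <- c(r, pen)
    J_full <- stack_jac(log_parameters(params))
    cosal <- residual_tangent_cos(J_full, r_full)
    angle <- acos(pmin(1, pmax(0, cosal))) * 180 / pi
    cost <- 0.5 * sum(r_full^2)
    data_cost <- 0.5 * sum(r^2)
    status <- if (res$info %in% 1:4 || cosal < angle_tol) "converged"
              else "not_converged"
  }
  fit <- list(params = params, cost = cost, data_cost = data_cost,
              residuals = r, penalty_residuals = pen,
              convergence_angle = angle, cos_alpha = cosal,
              status = status, niter = res$niter,
              n_solver_failures = nfail, start = init,
              lm_info = res$info, data = data, model = model,
              weights = weights, control = control, angle_tol = angle_tol,
              ftol = ftol, ptol = ptol)
  class(fit) <- "grn_fit"
  fit
}

# cos of the angle between the residual vector and the column space of J.
residual_tangent_cos <- function(J, r) {
  nr <- sqrt(sum(r^2))
  if (nr == 0) return(0)
  qrJ <- qr(J)
  proj <- qr.fitted(qrJ, r)
  min(1, sqrt(sum(proj^2)) / nr)
}

#' Multistart fitting
#'
#' Draws starting points log-uniformly over the ranges implied by the
#' penalties (`[0.1, 10]` for degradation rate and Hill exponents,
#' `[1e-4, 1e4]` for the rest) and runs [grn_fit()] from each. All results
#' are returned, including solver failures, so success rates can be
#' computed.
#'
#' @inheritParams grn_fit
#' @param n_starts Number of random starts.
#' @param seed Integer seed for the start draws.
#' @param maxiter Maximum LM iterations per start.
#' @return List of `grn_fit` objects of class `grn_fit_ensemble`.
#' @export
multistart <- function(data, model, n_starts, seed,
                       weights = penalty_config(model),
                       control = solver_control(), maxiter = 300) {
  stopifnot(n_starts >= 1)
  rng <- penalty_ranges(weights)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      v <- exp(stats::runif(nrow(rng), log(rng[, 1]), log(rng[, 2])))
      stats::setNames(v, names(weights))
    })
  })
  fits <- lapply(starts, function(s)
    grn_fit(data, model, s, weights = weights, control = control,
            maxiter = maxiter))
  class(fits) <- "grn_fit_ensemble"
  fits
}

#' Best fit of an ensemble
#'
#' @param fits A `grn_fit_ensemble` or list of `grn_fit` objects.
#' @return The converged fit with the smallest penalized cost, or `NULL` if
#'   none converged.
#' @export
best_fit <- function(fits) {
  conv <- Filter(function(f) f$status == "converged", fits)
  if (!length(conv)) return(NULL)
  conv[[which.min(vapply(conv, function(f) f$cost, numeric(1)))]]
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("Penalized least-squares fit (", x$status, ")\n", sep = "")
  cat("  data cost:", format(x$data_cost, digits = 4),
      "on", length(x$residuals), "observations;",
      "total cost:", format(x$cost, digits = 4), "\n")
  if (!is.na(x$convergence_angle))
    cat("  convergence angle:", format(x$convergence_angle, digits = 4),
        "degrees (cos =", format(x$cos_alpha, digits = 3), ")\n")
  invisible(x)
}

#' @export
coef.grn_fit <- function(object, log = FALSE, ...) {
  if (log) log_parameters(object$params) else object$params
}

#' @export
residuals.grn_fit <- function(object, type = c("data", "penalty", "all"),
                              ...) {
  type <- match.arg(type)
  switch(type,
         data = object$residuals,
         penalty = object$penalty_residuals,
         all = c(object$residuals, object$penalty_residuals))
}

#' @export
deviance.grn_fit <- function(object, ...) 2 * object$data_cost

#' Predictions from a fitted model
#'
#' @param object A `grn_fit`.
#' @param experiment Optional `grn_experiment` (or id string): predict that
#'   experiment's noiseless observables at the fitted parameters. Defaults
#'   to the rows of the fitted dataset.
#' @param ... Unused.
#' @return Data frame with `experiment_id`, `observable`, `time`,
#'   `predicted`.
#' @export
predict.grn_fit <- function(object, experiment = NULL, ...) {
  model <- object$model
  if (is.null(experiment)) {
    ids <- unique(object$data$experiment_id)
    out <- do.call(rbind, lapply(ids, function(id)
      predict(object, experiment = id)))
    return(out)
  }
  if (is.character(experiment)) experiment <- parse_experiment_id(experiment)
  if (experiment$measurement$kind == "gel_shift_assay") {
    j <- experiment$measurement$edge
    nm <- c(paste0("K", j), paste0("h", j))
    return(data.frame(experiment_id = experiment$id, observable = nm,
                      time = NA_real_,
                      predicted = unname(object$params[nm])))
  }
  obs <- experiment_observables(experiment)
  pm <- apply_perturbation(model, experiment$perturbation$kind,
                           experiment$perturbation$gene)
  traj <- grn_simulate(pm, object$params, sort(unique(obs$time)),
                       control = object$control)
  if (!traj$ok) stop("solver failed at the fitted parameters")
  data.frame(experiment_id = experiment$id, observable = obs$observable,
             time = obs$time, predicted = traj_values(traj, obs))
}

#' Simulate new noisy datasets from a fitted model
#'
#' Regenerates the fitted dataset's experiments at the fitted parameters
#' with fresh noise, in the style of parametric-bootstrap draws.
#'
#' @param object A `grn_fit`.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param noise A [noise_model()].
#' @param ... Unused.
#' @return List of `grn_dataset` objects.
#' @export
simulate.grn_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_model(), ...) {
  ids <- unique(object$data$experiment_id)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      do.call(bind_datasets, lapply(ids, function(id)
        generate_experiment_data(object$model, object$params,
                                 parse_experiment_id(id), noise)))
    })
  })
}

#' @export
summary.grn_fit <- function(object, ...) {
  out <- list(status = object$status, cost = object$cost,
              data_cost = object$data_cost, n_obs = length(object$residuals),
              convergence_angle = object$convergence_angle,
              niter = object$niter, params = object$params)
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat("Status:", x$status, "  iterations:", x$niter, "\n")
  cat("Data cost:", format(x$data_cost, digits = 5), "on", x$n_obs,
      "observations\n")
  cat("Convergence angle:", format(x$convergence_angle, digits = 4),
      "degrees\n")
  cat("Parameters:\n")
  print(round(x$params, 4))
  invisible(x)
}

#' Plot fitted time courses against the data
#'
#' @param x A `grn_fit`.
#' @param experiment Experiment id to plot; defaults to the first in the
#'   dataset.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.grn_fit <- function(x, experiment = NULL, ...) {
  if (is.null(experiment)) experiment <- x$data$experiment_id[1]
  rows <- x$data[x$data$experiment_id == experiment &
                   !grepl("^assay_", x$data$experiment_id), , drop = FALSE]
  if (!nrow(rows)) stop("no time-series rows for ", experiment)
  pred <- predict(x, experiment)
  obs_names <- unique(rows$observable)
  times <- sort(unique(rows$time))
  ym <- sapply(obs_names, function(o) rows$value[rows$observable == o])
  pm <- sapply(obs_names, function(o) pred$predicted[pred$observable == o])
  graphics::matplot(times, ym, pch = 1, xlab = "time",
                    ylab = "concentration", main = experiment, ...)
  graphics::matlines(times, pm, lty = 1)
  invisible(x)
}
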