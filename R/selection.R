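#' Score every candidate experiment
#'
#' For each catalog entry, simulates the experiment's noiseless data at the
#' supplied best-fit parameters, appends the corresponding sigma-scaled
#' sensitivity rows to the Jacobian of the current data, and evaluates the
#' selection criterion: the estimated log-parameter uncertainty
#' ([d_param_estimate()]) or, for prediction-targeted designs, the
#' estimated prediction uncertainty ([d_pred_estimate()]). Penalty terms
#' are excluded throughout, so the score reflects only the information
#' content of data. No noise is added during scoring; noise enters only
#' when the chosen experiment's data is actually generated.
#'
#' One sensitivity integration per distinct perturbation serves all
#' candidate measurements, so a full catalog sweep costs 19 ODE solves.
#' Candidates whose simulation fails are scored infinite.
#'
#' @param fit A converged `grn_fit` (its parameters are treated as true).
#' @param data The currently available `grn_dataset`.
#' @param catalog Candidate list from [enumerate_experiments()].
#' @param model A `grn_model`.
#' @param criterion `"parameter"` or `"prediction"`.
#' @param target A [prediction_target()] (required for
#'   `criterion = "prediction"`).
#' @param noise A [noise_model()] (supplies the sigma scale of prospective
#'   observations and the assay noise).
#' @param control Solver settings.
#' @param rank_tol Null-direction threshold passed to the information
#'   summary.
#' @return Data frame with columns `experiment_id`, `D`, `catalog_index`,
#'   sorted by ascending `D` with ties broken by catalog order.
#' @export
score_candidates <- function(fit, data, catalog, model,
                             criterion = c("parameter", "prediction"),
                             target = NULL, noise = noise_model(),
                             control = solver_control(), rank_tol = 1e-12) {
  criterion <- match.arg(criterion)
  if (criterion == "prediction" && is.null(target))
    stop("a prediction target is required for the prediction criterion")
  params <- as_parameter_set(model, fit$params)
  struct <- build_residual_structure(data, model)
  J_data <- eval_residual_jacobian(struct, params, control)
  if (is.null(J_data))
    stop("solver failed on the current data at the fit parameters")
  # QR-compress the data Jacobian: rbind(R, J_cand) has the same singular
  # values as rbind(J_data, J_cand) and keeps every SVD small. qr() may
  # pivot columns, so undo the pivot to keep parameter order.
  if (nrow(J_data) < ncol(J_data))
    J_data <- rbind(J_data, matrix(0, ncol(J_data) - nrow(J_data),
                                   ncol(J_data)))
  qr_data <- qr(J_data)
  R_data <- qr.R(qr_data)[, order(qr_data$pivot), drop = FALSE]
  colnames(R_data) <- colnames(J_data)

  I_pred <- NULL
  if (criterion == "prediction")
    I_pred <- prediction_information(params, target, model, noise, control)

  # one sensitivity solve per distinct perturbation, on the fine grid
  pert_rows <- new.env(parent = emptyenv())
  pert_key <- function(e) sub("\\|.*$", "", e$id)
  get_pert <- function(e) {
    key <- pert_key(e)
    if (is.null(pert_rows[[key]])) {
      pm <- apply_perturbation(model, e$perturbation$kind,
                               e$perturbation$gene)
      traj <- grn_simulate(pm, params, protein_times(), sens = TRUE,
                           control = control)
      pert_rows[[key]] <- if (traj$ok) traj else NA
    }
    pert_rows[[key]]
  }

  score_one <- function(e) {
    if (e$measurement$kind == "gel_shift_assay") {
      j <- e$measurement$edge
      Jc <- matrix(0, 2, length(params),
                   dimnames = list(NULL, names(params)))
      Jc[1, paste0("K", j)] <- 1 / noise$assay_sd
      Jc[2, paste0("h", j)] <- 1 / noise$assay_sd
    } else {
      traj <- get_pert(e)
      if (!is.list(traj)) return(Inf)
      obs <- experiment_observables(e)
      v <- traj_values(traj, obs)
      Jc <- traj_sens_rows(traj, obs) / sigma_for(v, noise)
    }
    info <- information_summary(rbind(R_data, Jc), rank_tol = rank_tol)
    if (criterion == "parameter") d_param_estimate(info)
    else d_pred_estimate(info, I_pred, target$M)
  }

  D <- vapply(catalog, score_one, numeric(1))
  ids <- vapply(catalog, function(e) e$id, character(1))
  ord <- order(D, seq_along(D))
  data.frame(experiment_id = ids[ord], D = D[ord],
             catalog_index = seq_along(D)[ord])
}

#' Pick the winning candidate from a ranking
#'
#' @param ranked Ranking from [score_candidates()].
#' @return The minimum-D `grn_experiment`; ties are already broken by
#'   catalog order. Errors if the ranking is empty or every candidate is
#'   infinite (which indicates a catalog or model problem).
#' @export
select_next <- function(ranked) {
  if (!NROW(ranked)) stop("empty candidate ranking")
  if (!is.finite(ranked$D[1]))
    stop("all candidate scores are infinite; check the catalog and model")
  parse_experiment_id(ranked$experiment_id[1])
}

# Prefer the lowest-cost converged fit; fall back to the lowest finite
# cost if nothing formally converged. Fits stranded at numerically
# unusable parameter values are never eligible.
pick_best_fit <- function(fits) {
  usable <- vapply(fits, function(f)
    all(is.finite(f$params)) && all(f$params > 0) && is.finite(f$cost),
    logical(1))
  fits <- fits[usable]
  if (!length(fits)) return(NULL)
  bf <- best_fit(fits)
  if (!is.null(bf)) return(bf)
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  fits[[which.min(costs)]]
}

# Achieved selection criterion at a fit given the current data.
evaluate_criterion <- function(params, data, model, criterion, target,
                               noise, control, rank_tol) {
  info <- fisher_information(params, data, model, control = control,
                             rank_tol = rank_tol)
  if (criterion == "parameter") {
    d_param_estimate(info)
  } else {
    I_pred <- prediction_information(params, target, model, noise, control)
    d_pred_estimate(info, I_pred, target$M)
  }
}

# Walk the fit candidates from best to worst until one supports the
# criterion evaluation (its sensitivity solve can fail even where the
# plain solve succeeded); returns NULL if none does.
select_usable_fit <- function(fits, data, model, criterion, target, noise,
                              control, rank_tol) {
  usable <- vapply(fits, function(f)
    all(is.finite(f$params)) && all(f$params > 0) && is.finite(f$cost),
    logical(1))
  fits <- fits[usable]
  if (!length(fits)) return(NULL)
  conv <- vapply(fits, function(f) f$status == "converged", logical(1))
  costs <- vapply(fits, function(f) f$cost, numeric(1))
  for (i in order(!conv, costs)) {
    D <- tryCatch(
      evaluate_criterion(fits[[i]]$params, data, model, criterion, target,
                         noise, control, rank_tol),
      error = function(e) NULL)
    if (!is.null(D)) return(list(fit = fits[[i]], D = D))
  }
  NULL
}

design_loop_impl <- function(model, truth, noise, weights, criterion,
                             target, stop_D, max_iters, seed, chooser,
                             n_starts_init, n_restarts, maxiter, control,
                             rank_tol, allow_duplicates, verbose,
                             init_params = NULL) {
  truth <- as_parameter_set(model, truth)
  catalog <- enumerate_experiments(model)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                      2 * max_iters + 2))
  data <- startup_data(model, truth, noise, seed = seeds[1],
                       control = control)
  if (is.null(init_params)) {
    fits <- multistart(data, model, n_starts_init, seed = seeds[2],
                       weights = weights, control = control,
                       maxiter = maxiter)
  } else {
    fits <- list(grn_fit(data, model, init_params, weights = weights,
                         control = control, maxiter = maxiter))
  }
  sel <- select_usable_fit(fits, data, model, criterion, target, noise,
                           control, rank_tol)
  if (is.null(sel))
    stop("no usable fit of the startup data; increase n_starts_init")
  best <- sel$fit
  history <- list()
  fits_by_iter <- list()
  record <- function(it, id, D_pred, D_ach, fit) {
    lab <- format_experiment(parse_experiment_id(id))
    history[[it]] <<- data.frame(
      iteration = it, experiment_id = id,
      perturbation = lab$perturbation, measurement = lab$measurement,
      D_predicted = D_pred, D_achieved = D_ach,
      data_rows = nrow(data), fit_status = fit$status,
      data_cost = fit$data_cost)
    fits_by_iter[[it]] <<- fit
  }

  D <- sel$D
  record(1L, "wild|microarray", NA_real_, D, best)
  if (verbose)
    message(sprintf("iter 1: startup data, D = %.3g", D))
  stopped <- "max_iters"
  if (is.finite(D) && D <= stop_D) stopped <- "threshold"
  it <- 1L
  while (stopped == "max_iters" && it < max_iters) {
    it <- it + 1L
    chosen <- chooser(best, data, catalog, it)
    purchased <- chosen$experiment
    new_rows <- generate_experiment_data(model, truth, purchased, noise,
                                         seed = seeds[2 * it - 1],
                                         control = control)
    data <- bind_datasets(data, new_rows)
    warm <- grn_fit(data, model, best$params, weights = weights,
                    control = control, maxiter = maxiter)
    # fallback evaluated near the previous best in case the warm fit ends
    # at a point whose sensitivity system cannot be integrated
    fallback <- grn_fit(data, model, best$params, weights = weights,
                        control = control, maxiter = 1)
    cand <- list(warm, fallback)
    if (n_restarts > 0) {
      cand <- c(cand, multistart(data, model, n_restarts,
                                 seed = seeds[2 * it], weights = weights,
                                 control = control, maxiter = maxiter))
    }
    sel <- select_usable_fit(cand, data, model, criterion, target, noise,
                             control, rank_tol)
    if (is.null(sel)) {
      # persistent fit failure: close the history with a failure record
      warm$status <- "solver_failed"
      record(it, purchased$id, chosen$D_predicted, NA_real_, warm)
      stopped <- "fit_failure"
      break
    }
    best <- sel$fit
    D <- sel$D
    record(it, purchased$id, chosen$D_predicted, D, best)
    if (verbose)
      message(sprintf("iter %d: %s, D = %.3g (predicted %.3g)", it,
                      purchased$id, D, chosen$D_predicted))
    if (is.finite(D) && D <= stop_D) stopped <- "threshold"
  }
  out <- list(history = do.call(rbind, history), fits = fits_by_iter,
              criterion = criterion, target = target, stop_D = stop_D,
              stop_reason = stopped, final_fit = best, data = data,
              truth = truth, seed = seed)
  class(out) <- "grn_design_history"
  out
}

#' Run the greedy experiment-selection loop
#'
#' Starting from the wild-type microarray startup data, each iteration (i)
#' refits the model (warm start from the previous best fit plus a small
#' multistart), (ii) scores every catalog experiment by the chosen
#' criterion, (iii) purchases the winner, (iv) generates its noisy data at
#' the true parameters, and records the achieved criterion value. The loop
#' stops when the achieved value drops to `stop_D` or after `max_iters`
#' purchases.
#'
#' @param model A `grn_model`.
#' @param truth True parameter vector used to generate data.
#' @param noise A [noise_model()].
#' @param weights Penalty weights.
#' @param criterion `"parameter"` or `"prediction"`.
#' @param target A [prediction_target()] for the prediction criterion.
#' @param stop_D Stop threshold on the achieved criterion (0.01
#'   corresponds to 10% parameter uncertainty; for predictions, 1 is the
#'   experimental-noise level).
#' @param max_iters Maximum number of experiments (including the startup
#'   data).
#' @param seed Integer seed controlling every random element (noise draws,
#'   multistart starting points).
#' @param n_starts_init Multistart size for the initial fit.
#' @param n_restarts Extra random restarts per refit.
#' @param maxiter LM iteration cap per fit.
#' @param control Solver settings.
#' @param rank_tol Null-direction threshold.
#' @param allow_duplicates Allow re-purchasing an experiment already
#'   performed (a fresh noise realization)?
#' @param init_params Optional starting parameter vector: fit the startup
#'   data from this point instead of running the initial multistart (used
#'   to launch the loop from a chosen local minimum).
#' @param verbose Emit progress messages?
#' @return Object of class `grn_design_history`: list with `history` (data
#'   frame mirroring the iteration/perturbation/measurement/estimated-error
#'   table, with both the score predicted at selection time and the value
#'   achieved after refitting), `fits` (best fit per iteration),
#'   `final_fit`, `data`, `criterion`, `stop_reason`.
#' @export
run_design_loop <- function(model, truth, noise = noise_model(),
                            weights = penalty_config(model),
                            criterion = c("parameter", "prediction"),
                            target = NULL, stop_D = 0.01, max_iters = 20,
                            seed = 1, n_starts_init = 20, n_restarts = 10,
                            maxiter = 100, control = solver_control(),
                            rank_tol = 1e-12, allow_duplicates = TRUE,
                            init_params = NULL, verbose = FALSE) {
  criterion <- match.arg(criterion)
  if (criterion == "prediction" && is.null(target))
    target <- prediction_target()
  purchased_ids <- character()
  chooser <- function(best, data, catalog, it) {
    ranked <- score_candidates(best, data, catalog, model,
                               criterion = criterion, target = target,
                               noise = noise, control = control,
                               rank_tol = rank_tol)
    if (!allow_duplicates)
      ranked <- ranked[!ranked$experiment_id %in%
                         c("wild|microarray", purchased_ids), , drop = FALSE]
    e <- select_next(ranked)
    purchased_ids <<- c(purchased_ids, e$id)
    list(experiment = e, D_predicted = ranked$D[1])
  }
  design_loop_impl(model, truth, noise, weights, criterion, target, stop_D,
                   max_iters, seed, chooser, n_starts_init, n_restarts,
                   maxiter, control, rank_tol, allow_duplicates, verbose,
                   init_params = init_params)
}

#' Random experiment selection baseline
#'
#' Identical loop to [run_design_loop()] except that each purchase is drawn
#' uniformly from the catalog; used for comparison statistics only.
#'
#' @inheritParams run_design_loop
#' @return A `grn_design_history`.
#' @export
random_baseline <- function(model, truth, noise = noise_model(),
                            weights = penalty_config(model),
                            criterion = c("parameter", "prediction"),
                            target = NULL, stop_D = 0.01, max_iters = 20,
                            seed = 1, n_starts_init = 20, n_restarts = 10,
                            maxiter = 100, control = solver_control(),
                            rank_tol = 1e-12, verbose = FALSE) {
  criterion <- match.arg(criterion)
  if (criterion == "prediction" && is.null(target))
    target <- prediction_target()
  picks <- with_seed(seed + 1L, sample.int(312, max_iters, replace = TRUE))
  chooser <- function(best, data, catalog, it) {
    idx <- ((picks[it] - 1) %% length(catalog)) + 1
    list(experiment = catalog[[idx]], D_predicted = NA_real_)
  }
  design_loop_impl(model, truth, noise, weights, criterion, target, stop_D,
                   max_iters, seed, chooser, n_starts_init, n_restarts,
                   maxiter, control, rank_tol, TRUE, verbose)
}

#' @export
print.grn_design_history <- function(x, ...) {
  cat("Greedy experiment-selection history (criterion:", x$criterion,
      "; stop:", x$stop_reason, ")\n")
  h <- x$history
  cat(sprintf("%-4s %-12s %-18s %-12s %-12s\n", "It", "Perturbation",
              "Measurement", "Estimated D", "Predicted D"))
  for (i in seq_len(nrow(h)))
    cat(sprintf("%-4d %-12s %-18s %-12.3g %-12.3g\n", h$iteration[i],
                h$perturbation[i], h$measurement[i], h$D_achieved[i],
                h$D_predicted[i]))
  invisible(x)
}

#' @export
plot.grn_design_history <- function(x, ...) {
  h <- x$history
  d <- pmin(h$D_achieved, max(h$D_achieved[is.finite(h$D_achieved)],
                              na.rm = TRUE) * 10)
  graphics::plot(h$iteration, d, log = "y", type = "b",
                 xlab = "experiments", ylab = "estimated D", ...)
  graphics::abline(h = x$stop_D, lty = 2)
  invisible(x)
}
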