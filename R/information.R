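#' Fisher information summary at a parameter set
#'
#' Builds the Jacobian `J` of the data residuals (penalty terms are
#' excluded so the summary measures only the information content of the
#' data) with respect to the natural-log parameters, and summarizes it
#' through the singular values of `J`. The Fisher information matrix is
#' `I = J' J` and its eigenvalues are the squares of the singular values;
#' all derived quantities are computed from the SVD of `J`, which remains
#' stable when the problem is extremely ill-conditioned.
#'
#' @param params Named positive parameter vector (typically a best fit).
#' @param data A `grn_dataset`.
#' @param model A `grn_model`.
#' @param control Solver settings.
#' @param rank_tol Relative threshold below which a singular value is
#'   treated as a numerically null direction.
#' @return Object of class `grn_fim`: list with `jacobian` (rows = data
#'   residuals), `singular_values` (descending), `right_vectors` (columns =
#'   right singular vectors of `J`), `N` (parameter count), `rank_tol`, and
#'   `D_estimate` (see [d_param_estimate()]).
#' @export
fisher_information <- function(params, data, model,
                               control = solver_control(),
                               rank_tol = 1e-12) {
  params <- as_parameter_set(model, params)
  struct <- build_residual_structure(data, model)
  J <- eval_residual_jacobian(struct, params, control)
  if (is.null(J)) stop("solver failed while building the Jacobian")
  information_summary(J, rank_tol = rank_tol)
}

#' Summarize an arbitrary residual Jacobian
#'
#' @param J Jacobian matrix of sigma-scaled residuals with respect to log
#'   parameters.
#' @param rank_tol Relative null-direction threshold.
#' @return A `grn_fim` (see [fisher_information()]).
#' @export
information_summary <- function(J, rank_tol = 1e-12) {
  Jp <- J
  if (nrow(Jp) < ncol(Jp)) {
    # pad with zero rows so the SVD exposes all N right singular vectors
    # (the missing directions are exact nulls)
    Jp <- rbind(Jp, matrix(0, ncol(Jp) - nrow(Jp), ncol(Jp)))
  }
  sv <- svd(Jp, nu = 0)
  out <- list(jacobian = J, singular_values = sv$d, right_vectors = sv$v,
              N = ncol(J), rank_tol = rank_tol)
  out$D_estimate <- d_param_estimate(out)
  class(out) <- "grn_fim"
  out
}

#' @export
print.grn_fim <- function(x, ...) {
  cat("Fisher information summary:", nrow(x$jacobian), "residuals,",
      x$N, "parameters\n")
  cat("  singular values: max", format(max(x$singular_values), digits = 4),
      " min", format(min(x$singular_values), digits = 4), "\n")
  cat("  D_param estimate:", format(x$D_estimate, digits = 4), "\n")
  invisible(x)
}

#' Estimated mean-square log-parameter uncertainty
#'
#' The A-optimality-style criterion `(1/N) trace(I^-1)` evaluated through
#' the singular values of the Jacobian: `(1/N) sum(1/s^2)`. A 10%
#' parameter uncertainty in every direction corresponds to 0.01. When any
#' singular value falls below `rank_tol * max(s)` some parameter
#' combination is unconstrained and the estimate is infinite.
#'
#' @param info A `grn_fim`.
#' @return Scalar estimate (possibly `Inf`).
#' @export
d_param_estimate <- function(info) {
  s <- info$singular_values
  if (!length(s) || any(s <= info$rank_tol * max(s))) return(Inf)
  mean(1 / s^2)
}

#' True mean-square log-parameter error
#'
#' `(1/N) sum(log(estimate/truth)^2)` over the free parameters, in natural
#' logs.
#'
#' @param estimate,truth Named positive parameter vectors over the same
#'   names.
#' @return Scalar error.
#' @export
d_param_true <- function(estimate, truth) {
  if (!setequal(names(estimate), names(truth)) || is.null(names(estimate)))
    stop("parameter names do not match")
  mean(log(estimate[names(truth)] / truth)^2)
}

#' A prediction target
#'
#' Specifies the perturbed condition and the observables whose uncertainty
#' a prediction-targeted design should reduce. The perturbation is a map of
#' multiplicative factors applied to named parameters (for example a
#' ten-fold increase of a promoter strength); the observables are
#' (protein, time) pairs.
#'
#' The default mirrors the challenge-style target for this network: the
#' time series of proteins 2, 4 and 6 on the standard 41-point grid under a
#' strong over-expression of gene 4 together with milder increases in the
#' feedback loop that regulates it. The exact factors are an illustrative
#' choice and can be replaced.
#'
#' @param factors Named numeric vector of multiplicative parameter factors.
#' @param proteins Gene ids whose proteins are predicted.
#' @param times Prediction time points.
#' @return Object of class `prediction_target` with fields `factors`,
#'   `observables` and `M` (number of predictions).
#' @export
prediction_target <- function(factors = c(pro4_strength = 10,
                                          rbs4_strength = 2,
                                          pro5_strength = 3),
                              proteins = c(2, 4, 6),
                              times = protein_times()) {
  stopifnot(all(factors > 0))
  obs <- data.frame(observable = rep(paste0("p", proteins),
                                     each = length(times)),
                    time = rep(times, length(proteins)))
  structure(list(factors = factors, observables = obs, M = nrow(obs)),
            class = "prediction_target")
}

#' Fisher information of a prediction target
#'
#' `I_pred = J_pred' J_pred`, where the rows of `J_pred` are the
#' sensitivities of the predicted values (under the target's perturbed
#' parameters) to the log parameters, scaled by the noise-model uncertainty
#' `sigma_m = sqrt(C1^2 + (C2 * y_m)^2)` of each predicted value.
#'
#' @param params Named positive parameter vector.
#' @param target A [prediction_target()].
#' @param model A `grn_model`.
#' @param noise A [noise_model()].
#' @param control Solver settings.
#' @return Symmetric positive semidefinite matrix `N x N`.
#' @export
prediction_information <- function(params, target, model,
                                   noise = noise_model(),
                                   control = solver_control()) {
  J <- prediction_jacobian(params, target, model, noise, control)
  crossprod(J)
}

# sigma-scaled prediction sensitivity rows for a target.
prediction_jacobian <- function(params, target, model,
                                noise = noise_model(),
                                control = solver_control()) {
  params <- as_parameter_set(model, params)
  if (target$M == 0)
    return(matrix(0, 0, length(params),
                  dimnames = list(NULL, names(params))))
  perturbed <- params
  fnames <- names(target$factors)
  if (!all(fnames %in% names(params)))
    stop("unknown parameters in prediction target")
  perturbed[fnames] <- perturbed[fnames] * target$factors
  times <- sort(unique(target$observables$time))
  traj <- grn_simulate(model, perturbed, times, sens = TRUE,
                       control = control)
  if (!traj$ok) stop("solver failed under the prediction perturbation")
  y <- traj_values(traj, target$observables)
  # multiplicative factors shift log theta, so sensitivities at the
  # perturbed point are the sensitivities to the unperturbed log parameters
  S <- traj_sens_rows(traj, target$observables)
  S / sigma_for(y, noise)
}

#' Estimated prediction uncertainty
#'
#' The linearized estimate `(1/M) trace(I_pred I^-1)` of the noise-scaled
#' mean-square prediction error, evaluated through the pseudo-inverse built
#' from the SVD of the data Jacobian. A value of 1 means the predictions
#' are uncertain at the level of the experimental noise. If the target has
#' appreciable weight along a numerically null direction of the data
#' information the estimate is infinite; null directions the target does
#' not probe are ignored.
#'
#' @param info A `grn_fim` for the current data.
#' @param I_pred Prediction information matrix from
#'   [prediction_information()].
#' @param M Number of predictions.
#' @param null_weight_tol Relative weight above which a null direction
#'   renders the estimate infinite.
#' @return Scalar estimate (possibly `Inf`).
#' @export
d_pred_estimate <- function(info, I_pred, M, null_weight_tol = 1e-8) {
  stopifnot(nrow(I_pred) == info$N, ncol(I_pred) == info$N, M >= 1)
  s <- info$singular_values
  V <- info$right_vectors
  if (!length(s) || max(s) == 0) {
    return(if (sum(diag(I_pred)) > 0) Inf else 0)
  }
  keep <- s > info$rank_tol * max(s)
  W <- crossprod(V, I_pred %*% V)  # target weight in the SVD basis
  wdiag <- pmax(diag(W), 0)
  scale <- max(sum(wdiag), .Machine$double.eps)
  if (any(!keep) && any(wdiag[!keep] > null_weight_tol * scale)) return(Inf)
  sum(wdiag[keep] / s[keep]^2) / M
}

#' True noise-scaled prediction error
#'
#' `(1/M) sum((y_pred - y_true)^2 / (C1^2 + C2^2 y_true^2))`.
#'
#' @param predictions,truth_values Numeric vectors of equal length.
#' @param noise A [noise_model()].
#' @return Scalar error.
#' @export
d_pred_true <- function(predictions, truth_values, noise = noise_model()) {
  if (length(predictions) != length(truth_values))
    stop("prediction and truth vectors differ in length")
  mean((predictions - truth_values)^2 /
         (noise$C1^2 + noise$C2^2 * truth_values^2))
}
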