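#' Classify multistart fits as good or bad
#'
#' A fit is "good" when its data cost lies within `threshold_factor` of the
#' ensemble's best data cost; fits far above the minimum fail to reproduce
#' one or more qualitative features of the data. Only converged fits are
#' classified; failures keep the label `NA`.
#'
#' @param fits A `grn_fit_ensemble` (list of `grn_fit`).
#' @param threshold_factor Multiplicative cost factor defining "good".
#' @return The ensemble with attributes `classification` (character vector
#'   `"good"`/`"bad"`/`NA` per fit) and `min_data_cost`.
#' @export
classify_fits <- function(fits, threshold_factor = 2) {
  stopifnot(length(fits) > 0, threshold_factor >= 1)
  conv <- vapply(fits, function(f) f$status == "converged", logical(1))
  costs <- vapply(fits, function(f) f$data_cost, numeric(1))
  if (!any(conv)) stop("no converged fits to classify")
  cmin <- min(costs[conv])
  cls <- rep(NA_character_, length(fits))
  cls[conv] <- ifelse(costs[conv] <= threshold_factor * cmin, "good", "bad")
  attr(fits, "classification") <- cls
  attr(fits, "min_data_cost") <- cmin
  fits
}

#' Distance between two fits in data space
#'
#' Euclidean distance between the residual vectors (data residuals followed
#' by penalty residuals, the same stack the optimizer sees). Because many
#' near-degenerate parameter sets produce nearly identical predictions,
#' distance on the model manifold in data space, not parameter distance, is
#' the meaningful separation between fits.
#'
#' @param a,b `grn_fit` objects fitted to the identical dataset.
#' @return Scalar distance.
#' @export
residual_distance <- function(a, b) {
  ra <- c(a$residuals, a$penalty_residuals)
  rb <- c(b$residuals, b$penalty_residuals)
  if (length(ra) != length(rb) ||
      !identical(dim(a$data), dim(b$data)) ||
      !identical(a$data$experiment_id, b$data$experiment_id))
    stop("fits are not on identical datasets")
  sqrt(sum((ra - rb)^2))
}

#' Are two fits distinct minima?
#'
#' Two fits are taken to belong to the same minimum when their data-space
#' distance is within the resolution of the search algorithm. Each fit's
#' distance to its true minimum is bounded by `|r| * cos(alpha)` (implied
#' by the convergence angle) plus `sqrt(2 * ftol * cost)` (the residual
#' displacement the relative-cost stopping rule cannot resolve); by the
#' triangle inequality two fits of the same minimum can be separated by at
#' most the sum of their resolutions, so they are called distinct only
#' beyond that.
#'
#' @param a,b `grn_fit` objects on the identical dataset.
#' @param resolution Optional override of the algorithm resolution.
#' @return `TRUE` if the fits are distinct.
#' @export
are_distinct <- function(a, b, resolution = NULL) {
  if (is.null(resolution)) {
    res_one <- function(f) {
      ftol <- if (is.null(f$ftol)) 0 else f$ftol
      sqrt(2 * f$cost) * f$cos_alpha + sqrt(2 * ftol * f$cost)
    }
    resolution <- res_one(a) + res_one(b)
    if (is.na(resolution)) resolution <- 0
  }
  residual_distance(a, b) > resolution
}

#' Count distinct good minima in an ensemble
#'
#' Builds the pairwise indistinctness graph over the good fits and counts
#' its connected components; using components avoids artifacts from the
#' non-transitivity of the pairwise relation.
#'
#' @param fits A classified ensemble from [classify_fits()].
#' @param resolution Optional resolution override passed to
#'   [are_distinct()].
#' @return List with `n_distinct`, `components` (membership per good fit),
#'   and `good_index` (positions of the good fits in the ensemble).
#' @export
distinct_minima <- function(fits, resolution = NULL) {
  cls <- attr(fits, "classification")
  if (is.null(cls)) stop("run classify_fits() first")
  gi <- which(!is.na(cls) & cls == "good")
  n <- length(gi)
  if (n == 0) return(list(n_distinct = 0L, components = integer(0),
                          good_index = gi))
  # union-find over the indistinctness relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!are_distinct(fits[[gi[i]]], fits[[gi[j]]], resolution)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  list(n_distinct = length(unique(comp)),
       components = match(comp, unique(comp)), good_index = gi)
}

#' Cost profile along a straight line between two parameter sets
#'
#' Evaluates the penalized cost at `n_points` equally spaced points along
#' the straight line in natural-log parameter space joining `theta_a` and
#' `theta_b` (endpoints included). Solver failures at interior points are
#' recorded as `NA`.
#'
#' @param theta_a,theta_b Named positive parameter vectors.
#' @param data A `grn_dataset`.
#' @param model A `grn_model`.
#' @param n_points Number of evaluation points (>= 2).
#' @param weights Penalty weights (`NULL` for the bare data cost).
#' @param control Solver settings.
#' @return Data frame with columns `s` (position in [0, 1]) and `cost`.
#' @export
cost_profile <- function(theta_a, theta_b, data, model, n_points = 21,
                         weights = penalty_config(model),
                         control = solver_control()) {
  stopifnot(n_points >= 2)
  la <- log_parameters(as_parameter_set(model, theta_a))
  lb <- log_parameters(as_parameter_set(model, theta_b))
  s <- seq(0, 1, length.out = n_points)
  cost <- vapply(s, function(si) {
    th <- exp_parameters((1 - si) * la + si * lb)
    dataset_cost(th, data, model, weights = weights, control = control)
  }, numeric(1))
  data.frame(s = s, cost = cost)
}

#' Sloppy subspace of an information summary
#'
#' The span of the right singular vectors belonging to the `k` smallest
#' singular values: the least-constrained directions in log-parameter
#' space.
#'
#' @param info A `grn_fim`.
#' @param k Subspace dimension, `1 <= k <= N`.
#' @return `N x k` orthonormal basis matrix.
#' @export
sloppy_subspace <- function(info, k) {
  if (k < 1 || k > info$N) stop("k out of range")
  V <- info$right_vectors
  idx <- order(info$singular_values)[seq_len(k)]
  V[, idx, drop = FALSE]
}

#' Principal components of the good fits
#'
#' PCA of the natural-log parameter vectors of the good fits in an
#' ensemble; the leading components describe the directions along which
#' the ensemble of acceptable fits spreads.
#'
#' @param fits A classified ensemble from [classify_fits()].
#' @param k Number of components to return.
#' @return List with `coordinates` (good fits projected on the first `k`
#'   components), `basis` (`N x k` orthonormal), `sdev` (component standard
#'   deviations), `center`, `good_index`.
#' @export
pca_projection <- function(fits, k = 2) {
  cls <- attr(fits, "classification")
  if (is.null(cls)) stop("run classify_fits() first")
  gi <- which(!is.na(cls) & cls == "good")
  if (length(gi) < 2) stop("need at least 2 good fits for PCA")
  X <- t(vapply(fits[gi], function(f) log_parameters(f$params),
                numeric(length(fits[[gi[1]]]$params))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       basis = pc$rotation[, seq_len(k), drop = FALSE],
       sdev = pc$sdev, center = pc$center, good_index = gi)
}

#' Principal angles between two subspaces
#'
#' Canonical angles computed from the singular values of `t(A) %*% B` for
#' orthonormal bases `A`, `B`; returned ascending, in degrees. The first
#' (smallest) angle measures the closest alignment between the subspaces.
#'
#' @param basis_a,basis_b Orthonormal basis matrices with the same number
#'   of rows.
#' @return Numeric vector of angles in degrees, ascending.
#' @export
principal_angles <- function(basis_a, basis_b) {
  if (nrow(basis_a) != nrow(basis_b))
    stop("bases live in different ambient dimensions")
  d <- svd(crossprod(basis_a, basis_b), nu = 0, nv = 0)$d
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Random-subspace null for the first principal angle
#'
#' Monte-Carlo distribution of the first principal angle between two
#' independent uniformly random `p`-dimensional subspaces of an
#' `ambient`-dimensional space. Subspaces are drawn by orthonormalizing
#' standard Gaussian matrices, which is rotation invariant and hence
#' uniform on the Grassmannian. For five-dimensional subspaces of the
#' 29-dimensional log-parameter space the mean is about 49 degrees with a
#' standard deviation of about 6 degrees, the reference scale against which
#' observed alignments are judged.
#'
#' @param p Subspace dimension.
#' @param ambient Ambient dimension.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with `mean`, `sd` (degrees) and the vector of sampled
#'   `angles`.
#' @export
random_subspace_null <- function(p = 5, ambient = 29, reps = 2000,
                                 seed = 1) {
  stopifnot(p >= 1, p <= ambient, reps >= 1)
  with_seed(seed, {
    angles <- vapply(seq_len(reps), function(i) {
      A <- qr.Q(qr(matrix(stats::rnorm(ambient * p), ambient, p)))
      B <- qr.Q(qr(matrix(stats::rnorm(ambient * p), ambient, p)))
      min(principal_angles(A, B))
    }, numeric(1))
    list(mean = mean(angles), sd = stats::sd(angles), angles = angles)
  })
}

#' Landscape report for a fit ensemble
#'
#' Convenience summary used by the diagnose entry point: good/bad counts,
#' distinct-minimum count, and the principal-angle comparison of the PCA
#' sloppy subspace against the Fisher sloppy subspace at the best fit,
#' with the random-subspace null for reference.
#'
#' @param fits A `grn_fit_ensemble`.
#' @param data The dataset the ensemble was fitted to.
#' @param model A `grn_model`.
#' @param k Sloppy-subspace dimension.
#' @param threshold_factor Cost factor for [classify_fits()].
#' @param null_reps Replicates for the random null.
#' @param seed Seed for the random null.
#' @param control Solver settings.
#' @return List of class `grn_landscape_report`.
#' @export
landscape_report <- function(fits, data, model, k = 5,
                             threshold_factor = 2, null_reps = 2000,
                             seed = 1, control = solver_control()) {
  fits <- classify_fits(fits, threshold_factor)
  cls <- attr(fits, "classification")
  dm <- distinct_minima(fits)
  bf <- best_fit(fits)
  info <- fisher_information(bf$params, data, model, control = control)
  angle <- NA_real_
  if (sum(cls == "good", na.rm = TRUE) >= 2) {
    pca <- pca_projection(fits, k = k)
    angle <- min(principal_angles(pca$basis, sloppy_subspace(info, k)))
  }
  null <- random_subspace_null(k, info$N, reps = null_reps, seed = seed)
  out <- list(n_fits = length(fits),
              n_converged = sum(!is.na(cls)),
              n_good = sum(cls == "good", na.rm = TRUE),
              n_bad = sum(cls == "bad", na.rm = TRUE),
              n_distinct = dm$n_distinct,
              first_principal_angle = angle,
              null_mean = null$mean, null_sd = null$sd,
              best = bf)
  class(out) <- "grn_landscape_report"
  out
}

#' @export
print.grn_landscape_report <- function(x, ...) {
  cat("Cost-landscape report\n")
  cat(sprintf("  fits: %d (%d converged; %d good, %d bad)\n", x$n_fits,
              x$n_converged, x$n_good, x$n_bad))
  cat(sprintf("  distinct good minima: %d\n", x$n_distinct))
  cat(sprintf("  PCA vs Fisher sloppy subspace, first angle: %.1f deg\n",
              x$first_principal_angle))
  cat(sprintf("  random-subspace null: %.1f +/- %.1f deg\n", x$null_mean,
              x$null_sd))
  invisible(x)
}
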