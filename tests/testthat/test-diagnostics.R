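test_that("fit classification separates good from bad by relative cost", {
  fits <- list(toy_fit(c(1, 1)), toy_fit(c(1.2, 1)), toy_fit(c(20, 20)))
  fits[[1]]$status <- fits[[2]]$status <- fits[[3]]$status <- "converged"
  cls <- attr(classify_fits(fits, threshold_factor = 2), "classification")
  expect_equal(cls, c("good", "good", "bad"))
  # invariant to ordering
  cls_rev <- attr(classify_fits(rev(fits), 2), "classification")
  expect_equal(cls_rev, rev(cls))
  # non-converged fits are left unclassified
  fits[[3]]$status <- "solver_failed"
  cls2 <- attr(classify_fits(fits, 2), "classification")
  expect_true(is.na(cls2[3]))
})

test_that("residual distance is a metric on data space", {
  set.seed(31)
  fits <- lapply(1:4, function(i) toy_fit(rnorm(6)))
  a <- fits[[1]]; b <- fits[[2]]; c3 <- fits[[3]]
  expect_equal(residual_distance(a, a), 0)
  expect_equal(residual_distance(a, b), residual_distance(b, a))
  expect_lte(residual_distance(a, c3),
             residual_distance(a, b) + residual_distance(b, c3) + 1e-12)
  bad <- toy_fit(rnorm(3), id = "other")
  expect_error(residual_distance(a, bad), "identical datasets")
})

test_that("distinctness uses the |r| cos(alpha) resolution", {
  # a one-parameter bimodal least-squares toy: r(x) = (x^2 - 1, 0.3 x)
  # has minima near x = +/- 0.95; fits from the two basins are distinct
  r_toy <- function(x) c(x^2 - 1, 0.3 * x)
  fit_from <- function(x0) {
    o <- minpack.lm::nls.lm(x0, fn = r_toy)
    r <- r_toy(o$par)
    J <- matrix(c(2 * o$par, 0.3), 2, 1)
    toy_fit(r, cos_alpha = fimdesign:::residual_tangent_cos(J, r))
  }
  left <- fit_from(-2); right <- fit_from(2)
  expect_true(are_distinct(left, right))
  expect_false(are_distinct(left, fit_from(-1.5)))
  expect_false(are_distinct(left, left))
  # explicit resolution override
  expect_false(are_distinct(left, right, resolution = 10))
})

test_that("distinct-minima counting uses connected components", {
  # indistinctness need not be transitive: a-b close, b-c close, a-c far
  a <- toy_fit(c(10, 0), cos_alpha = 0)
  b <- toy_fit(c(10.9, 0), cos_alpha = 0)
  c3 <- toy_fit(c(11.8, 0), cos_alpha = 0)
  fits <- list(a, b, c3)
  for (i in 1:3) fits[[i]]$status <- "converged"
  fits <- classify_fits(fits, threshold_factor = 2)
  dm <- distinct_minima(fits, resolution = 1)
  # pairwise: d(a,b) = 0.9 < 1, d(b,c) = 0.9 < 1, d(a,c) = 1.8 > 1,
  # but the chain links them into one component
  expect_equal(dm$n_distinct, 1)
  dm2 <- distinct_minima(fits, resolution = 0.5)
  expect_equal(dm2$n_distinct, 3)
})

test_that("cost profiles connect endpoints through log-parameter space", {
  m <- fix_model()
  th <- fix_truth()
  nf <- fix_noise_free_startup()
  other <- th * exp(0.2 * fimdesign:::with_seed(13, rnorm(29)))
  names(other) <- names(th)
  prof <- cost_profile(th, other, nf, m, n_points = 9)
  expect_equal(nrow(prof), 9)
  expect_equal(prof$s[c(1, 9)], c(0, 1))
  expect_equal(prof$cost[1], dataset_cost(th, nf, m), tolerance = 1e-8)
  expect_equal(prof$cost[9], dataset_cost(other, nf, m), tolerance = 1e-8)
  # noise-free data at the truth: cost rises away from the endpoint minimum
  expect_gt(min(prof$cost[2:8]), prof$cost[1])
})

test_that("sloppy subspaces come from the smallest singular directions", {
  J <- matrix(fimdesign:::with_seed(17, rnorm(50 * 29)), 50, 29)
  J <- J %*% diag(exp(seq(0, -8, length.out = 29)))  # sloppy spectrum
  info <- information_summary(J)
  V5 <- sloppy_subspace(info, 5)
  expect_equal(dim(V5), c(29, 5))
  expect_equal(crossprod(V5), diag(5), tolerance = 1e-10)
  # each basis vector maps to its singular value under J
  s_small <- sort(info$singular_values)[1:5]
  lens <- sort(sqrt(colSums((J %*% V5)^2)))
  expect_equal(lens, sort(s_small), tolerance = 1e-8)
  expect_equal(dim(sloppy_subspace(info, 29)), c(29, 29))
  expect_error(sloppy_subspace(info, 0), "range")
  expect_error(sloppy_subspace(info, 30), "range")
})

test_that("PCA of good fits is orthonormal with ordered variance", {
  set.seed(19)
  base <- exp(rnorm(29))
  fits <- lapply(1:12, function(i) {
    f <- toy_fit(rnorm(5))
    f$status <- "converged"
    f$params <- setNames(base * exp(c(rnorm(2, sd = c(2, 1)),
                                      rnorm(27, sd = 0.01))),
                         fix_model()$parameter_names)
    f
  })
  fits <- classify_fits(fits, threshold_factor = 100)
  pca <- pca_projection(fits, k = 3)
  expect_equal(unname(crossprod(pca$basis)), diag(3), tolerance = 1e-10)
  expect_true(all(diff(pca$sdev) <= 1e-12))
  expect_equal(nrow(pca$coordinates), 12)
  # collinear ensemble puts all variance on component 1
  fits2 <- lapply(seq(0, 1, length.out = 6), function(s) {
    f <- toy_fit(rnorm(5)); f$status <- "converged"
    f$params <- setNames(base * exp(s * seq_len(29) / 29),
                         fix_model()$parameter_names)
    f
  })
  fits2 <- classify_fits(fits2, threshold_factor = 1e6)
  pca2 <- pca_projection(fits2, k = 2)
  expect_gt(pca2$sdev[1], 1e3 * pca2$sdev[2])
})

test_that("principal angles behave like canonical subspace angles", {
  A <- qr.Q(qr(matrix(fimdesign:::with_seed(23, rnorm(29 * 5)), 29, 5)))
  expect_equal(principal_angles(A, A), rep(0, 5), tolerance = 1e-6)
  B <- qr.Q(qr(cbind(A[, 1:2], matrix(fimdesign:::with_seed(24, rnorm(29 * 3)),
                                      29, 3))))
  ang <- principal_angles(A, B)
  expect_true(all(diff(ang) >= -1e-10))  # ascending
  expect_equal(ang[1:2], c(0, 0), tolerance = 1e-5)
  # orthogonal subspaces meet at 90 degrees
  C1 <- diag(29)[, 1:3]; C2 <- diag(29)[, 10:12]
  expect_equal(principal_angles(C1, C2), rep(90, 3))
  # invariant under rotations within each subspace
  R1 <- qr.Q(qr(matrix(fimdesign:::with_seed(25, rnorm(25)), 5, 5)))
  expect_equal(min(principal_angles(A %*% R1, B)), min(ang),
               tolerance = 1e-8)
  expect_error(principal_angles(A, diag(10)[, 1:2]), "ambient")
})

test_that("the random-subspace null matches its geometric limits", {
  # coincident subspaces at p = ambient
  null_full <- random_subspace_null(p = 4, ambient = 4, reps = 5, seed = 1)
  expect_equal(null_full$mean, 0, tolerance = 1e-6)
  # the first angle shrinks as the subspace dimension grows
  means <- vapply(c(1, 3, 6, 10), function(p)
    random_subspace_null(p, 29, reps = 120, seed = 3)$mean, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the startup-data landscape shows one broad aligned basin", {
  # scaled-down multistart landscape survey: most converged fits are good,
  # the good fits split into a handful of resolution-limited "minima",
  # and their spread aligns with the sloppy subspace of the Fisher
  # information far better than random subspaces would
  m <- fix_model()
  d <- fix_startup()
  fits <- fixture("landscape_fits",
                  suppressWarnings(multistart(d, m, 24, seed = 31)))
  rep <- landscape_report(fits, d, m, k = 5, null_reps = 300, seed = 5)
  expect_gt(rep$n_converged, 2)
  expect_gte(rep$n_good / rep$n_converged, 0.5)
  expect_gte(rep$n_distinct, 2)
  expect_lte(rep$n_distinct, 100)
  expect_lt(rep$first_principal_angle, rep$null_mean - 2 * rep$null_sd)
  expect_output(print(rep), "distinct good minima")
  # some good-fit pairs are connected by straight-line paths whose cost
  # barrier is far below the cost at typical random parameter values (the
  # canyon winds, so most straight chords leave it; the connected pairs
  # are the signature of the shared basin)
  cls <- attr(classify_fits(fits, 2), "classification")
  gi <- which(!is.na(cls) & cls == "good")
  barriers <- c()
  for (i in gi) for (j in gi) if (i < j) {
    prof <- cost_profile(fits[[i]]$params, fits[[j]]$params, d, m,
                         n_points = 11)
    barriers <- c(barriers, max(prof$cost, na.rm = TRUE) -
                    max(prof$cost[c(1, 11)]))
  }
  random_costs <- vapply(1:15, function(s)
    dataset_cost(sample_true_parameters(m, seed = 4000 + s), d, m),
    numeric(1))
  expect_lt(min(barriers), median(random_costs, na.rm = TRUE))
})
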