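test_that("the uncertainty criterion calibrates as mean 1/s^2", {
  # all singular values 10 <-> 10% uncertainty in every direction -> 0.01
  for (N in c(3, 29, 40)) {
    J <- diag(10, N)
    expect_equal(d_param_estimate(information_summary(J)), 0.01)
  }
  # orthonormal Jacobian -> unit variance in every direction
  Q <- qr.Q(qr(matrix(fimdesign:::with_seed(2, rnorm(40 * 29)), 40, 29)))
  expect_equal(d_param_estimate(information_summary(Q)), 1, tolerance = 1e-10)
  # scaling J by 10 divides the criterion by 100
  J2 <- matrix(fimdesign:::with_seed(3, rnorm(50 * 29)), 50, 29)
  expect_equal(d_param_estimate(information_summary(10 * J2)),
               d_param_estimate(information_summary(J2)) / 100)
  # 30% uncertainty corresponds to about 0.1
  expect_equal(0.3^2, 0.09, tolerance = 1e-12)
  # a zero singular value (here: an all-zero column) is infinite
  J3 <- cbind(J2[, -1], 0)
  expect_equal(d_param_estimate(information_summary(J3)), Inf)
})

test_that("true parameter error is the mean squared log ratio", {
  th <- fix_truth()
  expect_equal(d_param_true(th, th), 0)
  off <- th; off[3] <- off[3] * exp(1)
  expect_equal(d_param_true(off, th), 1 / 29)
  all_off <- th * 1.1
  expect_equal(d_param_true(all_off, th), log(1.1)^2)
  bad <- th; names(bad)[1] <- "nope"
  expect_error(d_param_true(bad, th), "names")
})

test_that("eigenvalues of I equal squared singular values of J", {
  J <- matrix(fimdesign:::with_seed(4, rnorm(60 * 29)), 60, 29)
  info <- information_summary(J)
  ev <- sort(eigen(crossprod(J), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(info$singular_values^2, ev, tolerance = 1e-8)
  # SVD-path trace equals direct inversion on a well-conditioned J
  expect_equal(d_param_estimate(info),
               sum(diag(solve(crossprod(J)))) / 29, tolerance = 1e-8)
})

test_that("startup data leaves the criterion infinite via protein 3", {
  m <- fix_model()
  f <- fix_startup_fit()
  info <- fisher_information(f$params, fix_startup(), m)
  expect_equal(d_param_estimate(info), Inf)
  # the null direction is the translation strength of gene 3, whose
  # protein is unobserved and regulates nothing
  v_null <- info$right_vectors[, which.min(info$singular_values)]
  expect_equal(abs(v_null[match("rbs3_strength", m$parameter_names)]), 1,
               tolerance = 1e-6)
})

test_that("Gauss-Newton I agrees with the cost Hessian at zero residuals", {
  m <- fix_model()
  th <- fix_truth()
  # small noise-free dataset: residuals vanish at the truth, so the
  # dropped second-derivative term vanishes too
  nf <- fix_noise_free_startup()
  keep <- nf$time %in% c(2, 6, 12, 20)
  small <- fimdesign:::as_grn_dataset(nf[keep, ])
  info <- fisher_information(th, small, m)
  I_mat <- crossprod(info$jacobian)
  # finite-difference Hessian of the data cost in log parameters
  struct <- fimdesign:::build_residual_structure(small, m)
  ctl <- solver_control(rtol = 1e-10, atol = 1e-12)
  cost_at <- function(lt) {
    r <- fimdesign:::eval_residuals(struct, setNames(exp(lt), names(th)),
                                    ctl)
    0.5 * sum(r^2)
  }
  lt0 <- log(th)
  eps <- 1e-3
  n <- length(lt0)
  H <- matrix(0, n, n)
  f0 <- cost_at(lt0)
  fp <- numeric(n); fm <- numeric(n)
  for (i in 1:n) {
    ei <- rep(0, n); ei[i] <- eps
    fp[i] <- cost_at(lt0 + ei); fm[i] <- cost_at(lt0 - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / eps^2
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ei <- rep(0, n); ei[i] <- eps
    ej <- rep(0, n); ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (cost_at(lt0 + ei + ej) + cost_at(lt0 - ei - ej) -
         fp[i] - fm[i] - fp[j] - fm[j] + 2 * f0) / (2 * eps^2)
  }
  ev_I <- sort(eigen(I_mat, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  ev_H <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  expect_equal(ev_H[1:5], ev_I[1:5], tolerance = 1e-2)
})

test_that("adding data rows never increases the estimated uncertainty", {
  base <- matrix(fimdesign:::with_seed(6, rnorm(40 * 29)), 40, 29)
  D0 <- d_param_estimate(information_summary(base))
  set.seed(7)
  for (i in 1:100) {
    extra <- matrix(rnorm(5 * 29), 5, 29)
    D1 <- d_param_estimate(information_summary(rbind(base, extra)))
    expect_lte(D1, D0 + 1e-12)
  }
})

test_that("prediction information is a PSD Gram matrix of sensitivities", {
  m <- fix_model()
  th <- fix_truth()
  tgt <- prediction_target()
  expect_equal(tgt$M, 123)  # 3 proteins x 41 time points
  I_pred <- prediction_information(th, tgt, m)
  expect_equal(I_pred, t(I_pred), tolerance = 1e-10)
  ev <- eigen(I_pred, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # empty target -> zero matrix
  tgt0 <- prediction_target(times = numeric(0))
  expect_equal(tgt0$M, 0)
  expect_equal(prediction_information(th, tgt0, m),
               matrix(0, 29, 29, dimnames = list(names(th), names(th))))
})

test_that("estimated prediction uncertainty reduces to known traces", {
  J <- matrix(fimdesign:::with_seed(8, rnorm(60 * 29)), 60, 29)
  info <- information_summary(J)
  # target identical to the data: trace(I I^-1) = N
  expect_equal(d_pred_estimate(info, crossprod(J), M = 60), 29 / 60,
               tolerance = 1e-8)
  # null target -> 0
  expect_equal(d_pred_estimate(info, matrix(0, 29, 29), M = 10), 0)
  # information singular along a direction the target probes -> infinite
  J_sing <- cbind(J[, -1], 0)
  info_s <- information_summary(J_sing)
  I_pred <- diag(1, 29)
  expect_equal(d_pred_estimate(info_s, I_pred, M = 5), Inf)
  # but a target orthogonal to the null direction stays finite
  I_pred2 <- diag(c(rep(1, 28), 0))
  expect_true(is.finite(d_pred_estimate(info_s, I_pred2, M = 5)))
})

test_that("true prediction error is the noise-scaled mean square", {
  n <- noise_model()
  expect_equal(d_pred_true(c(1, 2), c(1, 2), n), 0)
  # single prediction at y_true = 0: error^2 / C1^2
  expect_equal(d_pred_true(0.1, 0, n), 0.1^2 / 0.1^2)
  # quadratic in the errors
  y <- c(0.5, 1, 2); yt <- c(0.4, 1.3, 1.8)
  expect_equal(d_pred_true(yt + 2 * (y - yt), yt, n),
               4 * d_pred_true(y, yt, n))
  expect_error(d_pred_true(1:3, 1:2, n), "length")
})
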