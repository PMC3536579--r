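test_that("model structure has the documented dimensions", {
  m <- fix_model()
  expect_length(m$parameter_names, 29)
  expect_length(m$state_names, 12)
  expect_equal(nrow(m$edges), 8)
  expect_length(m$genes, 6)
  # parameter classes: 6 promoter + 6 RBS strengths, 8 K, 8 h, 1 p_deg
  expect_equal(sum(grepl("^pro", m$parameter_names)), 6)
  expect_equal(sum(grepl("^rbs", m$parameter_names)), 6)
  expect_equal(sum(grepl("^K", m$parameter_names)), 8)
  expect_equal(sum(grepl("^h", m$parameter_names)), 8)
  expect_true("p_deg_rate" %in% m$parameter_names)
  # each edge's K and h appear exactly once among the free parameters
  expect_true(all(table(c(m$edges$K, m$edges$h)) == 1))
  expect_true(all(c(m$edges$K, m$edges$h) %in% m$parameter_names))
  # mRNA degradation is a fixed constant, not a free parameter
  expect_equal(unname(m$fixed_constants["mRNA_deg_rate"]), 1)
  expect_false("mRNA_deg_rate" %in% m$parameter_names)
})

test_that("regulatory wiring matches the network topology", {
  e <- fix_model()$edges
  # gene 1 constitutive: no incoming edges
  expect_false(1 %in% e$target)
  # gene 2: activated by p1 (K2), inhibited by p6 (K5)
  expect_equal(e$regulator[e$target == 2 & e$sign == "activating"], 1L)
  expect_equal(e$K[e$target == 2 & e$sign == "activating"], "K2")
  expect_equal(e$regulator[e$target == 2 & e$sign == "inhibiting"], 6L)
  expect_equal(e$K[e$target == 2 & e$sign == "inhibiting"], "K5")
  # gene 4: activated by p1 (K1), inhibited by p5 (K8)
  expect_equal(e$K[e$target == 4 & e$sign == "activating"], "K1")
  expect_equal(e$regulator[e$target == 4 & e$sign == "inhibiting"], 5L)
  # genes 5 and 6 both inhibited by p4
  expect_equal(e$regulator[e$target == 5], 4L)
  expect_equal(e$regulator[e$target == 6], 4L)
})

test_that("simulation starts at the standard initial condition", {
  tr <- grn_simulate(fix_model(), fix_truth(), seq(0, 20, 1))
  expect_true(tr$ok)
  ic <- tr$states[1, ]
  expect_equal(unname(ic[paste0("mRNA", 1:6)]), rep(0, 6))
  expect_equal(unname(ic[paste0("p", 1:6)]), rep(1, 6))
})

test_that("unregulated gene 1 follows the linear-ODE closed form", {
  m <- fix_model()
  th <- fix_truth()
  t <- seq(0, 20, 0.25)
  tr <- grn_simulate(m, th, t)
  expect_equal(tr$states[, "mRNA1"],
               unname(th["pro1_strength"]) * (1 - exp(-t)),
               tolerance = 1e-6)
  # protein 1 closed form: linear cascade driven by mRNA1
  k <- unname(th["p_deg_rate"]); a <- unname(th["rbs1_strength"])
  pro <- unname(th["pro1_strength"])
  p1 <- exp(-k * t) + a * pro * ((1 - exp(-k * t)) / k -
                                   (exp(-t) - exp(-k * t)) / (k - 1))
  expect_equal(tr$states[, "p1"], p1, tolerance = 1e-6)
})

test_that("perturbations act as delete/knockdown/overexpress semantics", {
  m <- fix_model()
  th <- fix_truth()
  t <- seq(0, 10, 0.5)
  # delete gene 1: production gone, p1 decays from 1
  trd <- grn_simulate(apply_perturbation(m, "delete", 1), th, t)
  expect_equal(trd$states[, "p1"], exp(-unname(th["p_deg_rate"]) * t),
               tolerance = 1e-6)
  expect_equal(max(abs(trd$states[, "mRNA1"])), 0, tolerance = 1e-8)
  # knockdown gene 1: mRNA1 relaxes 5x faster to pro1/5
  trk <- grn_simulate(apply_perturbation(m, "knockdown", 1), th, t)
  expect_equal(trk$states[, "mRNA1"],
               unname(th["pro1_strength"]) / 5 * (1 - exp(-5 * t)),
               tolerance = 1e-6)
  # other genes keep degradation rate 1: gene 5 knockdown leaves mRNA1 alone
  tr <- grn_simulate(m, th, t)
  trk5 <- grn_simulate(apply_perturbation(m, "knockdown", 5), th, t)
  expect_equal(trk5$states[, "mRNA1"], tr$states[, "mRNA1"],
               tolerance = 1e-7)
  # overexpress gene 1 doubles the translation rate: p1 production doubles
  tro <- grn_simulate(apply_perturbation(m, "overexpress", 1), th, t)
  gain_o <- tro$states[, "p1"] - exp(-unname(th["p_deg_rate"]) * t)
  gain_w <- tr$states[, "p1"] - exp(-unname(th["p_deg_rate"]) * t)
  expect_equal(gain_o, 2 * gain_w, tolerance = 1e-6)
  # the free-parameter list is untouched and the input model unmodified
  expect_equal(apply_perturbation(m, "delete", 3)$parameter_names,
               m$parameter_names)
  expect_equal(m$perturbation$kind, "wild")
  expect_error(apply_perturbation(m, "delete", 9), "9")
})

test_that("concentrations stay non-negative across catalog perturbations", {
  m <- fix_model()
  kinds <- list(list("wild", NA), list("delete", 2), list("knockdown", 4),
                list("overexpress", 1), list("delete", 5))
  worst <- 0
  set.seed(99)
  for (i in 1:20) {
    th <- sample_true_parameters(m, seed = 1000 + i)
    for (k in kinds) {
      tr <- grn_simulate(apply_perturbation(m, k[[1]], k[[2]]), th,
                         seq(0, 20, 1))
      expect_true(tr$ok)
      worst <- min(worst, min(tr$states))
    }
  }
  expect_gt(worst, -1e-6)
})

test_that("the model reaches steady state well past t = 20", {
  tr <- grn_simulate(fix_model(), fix_truth(), c(0, 40, 40.5))
  rate <- abs(tr$states[3, ] - tr$states[2, ]) / 0.5
  expect_lt(max(rate), 1e-3)
})

test_that("forward sensitivities agree with finite differences", {
  m <- fix_model()
  th <- sample_true_parameters(m, seed = 5)
  obs <- data.frame(observable = rep(c("mRNA2", "p4", "p6", "mRNA5"),
                                     each = 3),
                    time = rep(c(2, 8, 18), 4))
  ctl <- solver_control(rtol = 1e-10, atol = 1e-12)
  for (pert in list(list("wild", NA), list("knockdown", 5))) {
    pm <- apply_perturbation(m, pert[[1]], pert[[2]])
    Js <- observation_jacobian(pm, th, obs, method = "sens", control = ctl)
    Jf <- observation_jacobian(pm, th, obs, method = "fd", fd_step = 1e-4,
                               control = ctl)
    expect_equal(Js, Jf, tolerance = 1e-4)
  }
})

test_that("parameters without influence have exactly zero sensitivity", {
  # gene 3's protein regulates nothing, so rbs3 cannot affect any mRNA
  obs <- data.frame(observable = rep(paste0("mRNA", 1:6), each = 2),
                    time = rep(c(5, 15), 6))
  J <- observation_jacobian(fix_model(), fix_truth(), obs)
  expect_equal(max(abs(J[, "rbs3_strength"])), 0)
  # mRNA1 is constitutive: only pro1_strength moves it
  J1 <- J[obs$observable == "mRNA1", ]
  expect_equal(max(abs(J1[, setdiff(colnames(J1), "pro1_strength")])), 0)
  expect_gt(min(abs(J1[, "pro1_strength"])), 0)
})

test_that("log-sensitivity of mRNA1 to pro1 approaches pro1 at large t", {
  th <- fix_truth()
  J <- observation_jacobian(fix_model(), th,
                            data.frame(observable = "mRNA1", time = 20))
  expect_equal(unname(J[1, "pro1_strength"]), unname(th["pro1_strength"]),
               tolerance = 1e-6)
})

test_that("solver failure is signalled, not raised", {
  th <- fix_truth()
  th["h1"] <- 50; th["K1"] <- 1e-4; th["pro1_strength"] <- 1e6
  tr <- grn_simulate(fix_model(), th, seq(0, 20, 0.1),
                     control = solver_control(maxsteps = 10))
  expect_false(tr$ok)
})

test_that("the model report lists the structure", {
  lines <- model_report(fix_model())
  expect_true(any(grepl("free parameters \\(29\\)", lines)))
  expect_true(any(grepl("p1 -> gene4", lines)))
  f <- tempfile()
  model_report(fix_model(), f)
  expect_true(file.exists(f))
})
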