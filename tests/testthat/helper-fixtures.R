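# Shared fixtures, computed lazily and cached for the whole test run so
# expensive objects (fits, design loops) are built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fix_model <- function() fixture("model", grn_model1())

fix_truth <- function() fixture("truth",
                                sample_true_parameters(fix_model(), seed = 1))

fix_startup <- function() fixture("startup",
                                  startup_data(fix_model(), fix_truth(),
                                               seed = 42))

# A converged local fit of the startup data, warm-started at the truth
# (fast, and representative of a good local minimum).
fix_startup_fit <- function() fixture("startup_fit",
                                      grn_fit(fix_startup(), fix_model(),
                                              fix_truth()))

# Noise-free dataset: observations equal the noiseless simulation, sigma
# from the noise formula applied to the noiseless values.
noise_free_data <- function(model, truth, e) {
  obs <- fimdesign:::experiment_observables(e)
  pm <- apply_perturbation(model, e$perturbation$kind, e$perturbation$gene)
  traj <- grn_simulate(pm, truth, sort(unique(obs$time)))
  stopifnot(traj$ok)
  v <- fimdesign:::traj_values(traj, obs)
  fimdesign:::as_grn_dataset(
    data.frame(experiment_id = e$id, observable = obs$observable,
               time = obs$time, value = v,
               sigma = fimdesign:::sigma_for(v, noise_model())))
}

fix_noise_free_startup <- function() {
  fixture("noise_free_startup",
          noise_free_data(fix_model(), fix_truth(),
                          parse_experiment_id("wild|microarray")))
}

# Minimal stand-in fit objects for data-space diagnostics on constructed
# toy least-squares problems.
toy_fit <- function(residuals, cost = 0.5 * sum(residuals^2),
                    cos_alpha = 0, id = "toy") {
  structure(list(residuals = residuals, penalty_residuals = numeric(0),
                 cost = cost, cos_alpha = cos_alpha, status = "converged",
                 data_cost = cost,
                 data = data.frame(experiment_id = rep(id,
                                                       length(residuals)))),
            class = "grn_fit")
}
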