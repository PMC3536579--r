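# Time grids of the data generator: mRNA series are sampled at 21 points
# and protein series at 41 points, evenly spaced on [0, 20].
mrna_times <- function() seq(0, 20, length.out = 21)
protein_times <- function() seq(0, 20, length.out = 41)

make_experiment <- function(pert_kind, pert_gene, meas_kind,
                            proteins = NULL, edge = NULL) {
  if (meas_kind == "gel_shift_assay") {
    id <- paste0("assay_", edge)
    pert <- NULL
  } else {
    pid <- if (pert_kind == "wild") "wild" else paste0(pert_kind, "_", pert_gene)
    mid <- if (meas_kind == "microarray") "microarray"
           else paste0("proteins_", proteins[1], "_", proteins[2])
    id <- paste0(pid, "|", mid)
    pert <- list(kind = pert_kind,
                 gene = if (pert_kind == "wild") NA_integer_
                        else as.integer(pert_gene))
  }
  structure(list(id = id, perturbation = pert,
                 measurement = list(kind = meas_kind,
                                    proteins = proteins, edge = edge)),
            class = "grn_experiment")
}

#' Enumerate the candidate experiment catalog
#'
#' The catalog crosses every single-gene perturbation (wild type, deletion,
#' overexpression, and mRNA knockdown of each gene) with every measurement
#' (a microarray returning all six mRNA time series, or a fluorescence
#' measurement of one unordered pair of proteins), and appends one
#' gel-shift assay per regulatory edge, which reports direct estimates of
#' that edge's K and Hill coefficient. Experiments with altered initial
#' conditions or multiple simultaneous perturbations are not part of the
#' catalog. For the six-gene model this yields 19 x 16 + 8 = 312
#' experiments.
#'
#' @param model A `grn_model`.
#' @return List of `grn_experiment` objects; tie-breaking throughout the
#'   package follows this order.
#' @export
enumerate_experiments <- function(model) {
  perts <- list(list("wild", NA_integer_))
  for (kind in c("delete", "overexpress", "knockdown"))
    for (g in model$genes) perts <- c(perts, list(list(kind, g)))
  pairs <- utils::combn(model$genes, 2, simplify = FALSE)
  catalog <- list()
  for (p in perts) {
    catalog <- c(catalog, list(make_experiment(p[[1]], p[[2]], "microarray")))
    for (pr in pairs)
      catalog <- c(catalog, list(make_experiment(p[[1]], p[[2]],
                                                 "protein_pair", proteins = pr)))
  }
  for (e in seq_len(nrow(model$edges)))
    catalog <- c(catalog, list(make_experiment(NA, NA, "gel_shift_assay",
                                               edge = e)))
  catalog
}

#' Parse an experiment id string
#'
#' Experiment ids are self-describing, e.g. `"wild|microarray"`,
#' `"knockdown_5|proteins_1_6"`, `"assay_3"`, so a persisted dataset table
#' fully determines how to re-simulate its predictions.
#'
#' @param id Experiment id string.
#' @return A `grn_experiment`.
#' @export
parse_experiment_id <- function(id) {
  if (grepl("^assay_[0-9]+$", id))
    return(make_experiment(NA, NA, "gel_shift_assay",
                           edge = as.integer(sub("assay_", "", id))))
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed experiment id: ", id)
  if (parts[1] == "wild") {
    kind <- "wild"; gene <- NA_integer_
  } else {
    m <- regmatches(parts[1], regexec("^(delete|overexpress|knockdown)_([1-6])$",
                                      parts[1]))[[1]]
    if (!length(m)) stop("malformed experiment id: ", id)
    kind <- m[2]; gene <- as.integer(m[3])
  }
  if (parts[2] == "microarray")
    return(make_experiment(kind, gene, "microarray"))
  m <- regmatches(parts[2], regexec("^proteins_([1-6])_([1-6])$", parts[2]))[[1]]
  if (!length(m)) stop("malformed experiment id: ", id)
  make_experiment(kind, gene, "protein_pair",
                  proteins = c(as.integer(m[2]), as.integer(m[3])))
}

#' Human-readable label for an experiment
#'
#' @param e A `grn_experiment`.
#' @return List with `perturbation` and `measurement` strings in the style
#'   "Down 5" / "Proteins 1 and 6".
#' @export
format_experiment <- function(e) {
  if (e$measurement$kind == "gel_shift_assay")
    return(list(perturbation = paste("Assay", e$measurement$edge),
                measurement = "n/a"))
  p <- e$perturbation
  pl <- switch(p$kind, wild = "Wild", delete = paste("Delete", p$gene),
               overexpress = paste("Over", p$gene),
               knockdown = paste("Down", p$gene))
  ml <- if (e$measurement$kind == "microarray") "Microarray"
        else paste("Proteins", e$measurement$proteins[1], "and",
                   e$measurement$proteins[2])
  list(perturbation = pl, measurement = ml)
}

# (observable, time) pairs measured by a time-series experiment.
experiment_observables <- function(e) {
  if (e$measurement$kind == "microarray") {
    data.frame(observable = rep(paste0("mRNA", 1:6), each = 21),
               time = rep(mrna_times(), 6))
  } else if (e$measurement$kind == "protein_pair") {
    data.frame(observable = rep(paste0("p", e$measurement$proteins), each = 41),
               time = rep(protein_times(), 2))
  } else {
    stop("assay experiments have no time-series observables")
  }
}

#' Generate noisy data for one experiment
#'
#' Time-series experiments simulate the perturbed model at the true
#' parameters and pass the values through the noise model; a microarray
#' yields 21 time points for each of the 6 mRNA series (126 rows), a
#' protein-pair measurement 41 time points for each of 2 proteins (82
#' rows). A gel-shift assay yields 2 rows: log-normally perturbed
#' observations of the edge's K and h, whose `sigma` column holds the
#' log-scale assay standard deviation.
#'
#' @param model A `grn_model` (unperturbed; the experiment's perturbation is
#'   applied internally).
#' @param truth True parameter vector.
#' @param e A `grn_experiment`.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed for the noise draws.
#' @param control Solver settings.
#' @return A `grn_dataset`: data frame with columns `experiment_id`,
#'   `observable`, `time`, `value`, `sigma`.
#' @export
generate_experiment_data <- function(model, truth, e, noise = noise_model(),
                                     seed = NULL, control = solver_control()) {
  truth <- as_parameter_set(model, truth)
  if (e$measurement$kind == "gel_shift_assay") {
    j <- e$measurement$edge
    true_vals <- truth[c(paste0("K", j), paste0("h", j))]
    draw <- function() true_vals * exp(noise$assay_sd * stats::rnorm(2))
    y <- if (is.null(seed)) draw() else with_seed(seed, draw())
    rows <- data.frame(experiment_id = e$id, observable = names(true_vals),
                       time = NA_real_, value = unname(y),
                       sigma = noise$assay_sd)
    return(as_grn_dataset(rows))
  }
  obs <- experiment_observables(e)
  pm <- apply_perturbation(model, e$perturbation$kind, e$perturbation$gene)
  traj <- grn_simulate(pm, truth, sort(unique(obs$time)), control = control)
  if (!traj$ok) stop("solver failed at the true parameters for ", e$id)
  v <- traj_values(traj, obs)
  y <- add_noise(v, noise, seed = seed)
  rows <- data.frame(experiment_id = e$id, observable = obs$observable,
                     time = obs$time, value = y, sigma = sigma_for(y, noise))
  as_grn_dataset(rows)
}

#' Startup data: the wild-type microarray
#'
#' The noisy wild-type mRNA time courses that every design loop starts
#' from.
#'
#' @inheritParams generate_experiment_data
#' @return A `grn_dataset` of 126 rows.
#' @export
startup_data <- function(model, truth, noise = noise_model(), seed = NULL,
                         control = solver_control()) {
  generate_experiment_data(model, truth,
                           make_experiment("wild", NA, "microarray"),
                           noise, seed, control)
}

as_grn_dataset <- function(df) {
  class(df) <- c("grn_dataset", "data.frame")
  df
}

#' Combine datasets
#'
#' @param ... `grn_dataset` objects.
#' @return The row-bound `grn_dataset`; row order (and therefore residual
#'   order) follows the argument order.
#' @export
bind_datasets <- function(...) {
  as_grn_dataset(do.call(rbind, lapply(list(...), as.data.frame)))
}
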