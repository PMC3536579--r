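#' Read and write datasets
#'
#' Datasets are persisted as tab-delimited tables with the header
#' `experiment_id  observable  time  value  sigma`. Experiment ids are
#' self-describing (see [parse_experiment_id()]), so the table alone
#' reconstructs the fitting problem. For gel-shift assay rows `time` is
#' empty and `sigma` is the log-scale assay standard deviation.
#'
#' @param data A `grn_dataset`.
#' @param file Path.
#' @param provenance Optional list (configuration values, seeds) embedded
#'   as a leading `#`-comment line so every persisted dataset records how
#'   it was produced.
#' @return `read_dataset()` returns a `grn_dataset`.
#' @export
write_dataset <- function(data, file, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste("#", jsonlite::toJSON(provenance, auto_unbox = TRUE)),
               con)
  utils::write.table(as.data.frame(data), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("experiment_id", "observable", "time", "value", "sigma")
  if (!all(need %in% names(df)))
    stop("dataset file lacks required columns")
  as_grn_dataset(df[need])
}

#' Serialize a fit as a structured record
#'
#' Writes parameters (linear scale), the cost breakdown, convergence
#' diagnostics and status as JSON.
#'
#' @param fit A `grn_fit`.
#' @param file Path.
#' @param provenance Optional list embedded in the record.
#' @return `read_fit_record()` returns the parsed record (a list, not a
#'   `grn_fit`).
#' @export
write_fit_record <- function(fit, file, provenance = NULL) {
  rec <- list(params = as.list(fit$params), cost = fit$cost,
              data_cost = fit$data_cost, status = fit$status,
              convergence_angle = fit$convergence_angle,
              cos_alpha = fit$cos_alpha, niter = fit$niter,
              n_solver_failures = fit$n_solver_failures,
              provenance = provenance)
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_fit_record
#' @export
read_fit_record <- function(file) jsonlite::read_json(file, simplifyVector = TRUE)

#' Serialize a design history
#'
#' Writes the iteration table plus the per-iteration best-fit parameter
#' snapshots as JSON.
#'
#' @param history A `grn_design_history`.
#' @param file Path.
#' @param provenance Optional list embedded in the record.
#' @return `read_history_record()` returns the parsed record.
#' @export
write_history_record <- function(history, file, provenance = NULL) {
  rec <- list(criterion = history$criterion, stop_D = history$stop_D,
              stop_reason = history$stop_reason, seed = history$seed,
              provenance = provenance,
              history = history$history,
              best_fits = lapply(history$fits,
                                 function(f) as.list(f$params)))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "string")
  invisible(file)
}

#' @rdname write_history_record
#' @export
read_history_record <- function(file)
  jsonlite::read_json(file, simplifyVector = TRUE)

#' Run configuration
#'
#' Reads a YAML key-value file describing a run: noise constants, penalty
#' weights, solver tolerances, sampler ranges, seeds, and selection
#' settings. Missing keys take the package defaults.
#'
#' @param file Optional YAML path.
#' @return List of class `run_config` with components `noise`, `weights`
#'   settings, `control`, `seeds`, `selection`.
#' @export
read_run_config <- function(file = NULL) {
  raw <- if (is.null(file)) list() else yaml::read_yaml(file)
  pick <- function(name, default) {
    v <- raw[[name]]
    if (is.null(v)) default else v
  }
  cfg <- list(
    C1 = pick("C1", 0.1),
    C2 = pick("C2", 0.2),
    assay_sd = pick("assay_sd", 0.1),
    tight_w = pick("tight_w", 0.1),
    wide_w = pick("wide_w", 1e-4),
    rtol = pick("rtol", 1e-8),
    atol = pick("atol", 1e-10),
    truth_seed = pick("truth_seed", 1L),
    seed = pick("seed", 1L),
    criterion = pick("criterion", "parameter"),
    stop_D = pick("stop_D", 0.01),
    max_iters = pick("max_iters", 20L),
    n_starts_init = pick("n_starts_init", 20L),
    n_restarts = pick("n_restarts", 10L),
    allow_duplicates = pick("allow_duplicates", TRUE),
    tight_range = pick("tight_range", c(0.5, 2)),
    wide_range = pick("wide_range", c(0.25, 4))
  )
  bad <- c("rtol", "atol", "tight_w", "wide_w", "C1", "C2", "assay_sd")
  if (any(unlist(cfg[bad]) < 0))
    stop("negative tolerance, weight or noise constant in config")
  class(cfg) <- "run_config"
  cfg
}

config_noise <- function(cfg) noise_model(cfg$C1, cfg$C2, cfg$assay_sd)
config_control <- function(cfg) solver_control(rtol = cfg$rtol,
                                               atol = cfg$atol)
config_weights <- function(cfg, model) penalty_config(model, cfg$tight_w,
                                                      cfg$wide_w)
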