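#' The six-gene regulatory network model
#'
#' Constructs the six-gene, eight-edge gene regulatory network used
#' throughout the package. Each gene `j` is described by two dynamical
#' variables, its mRNA and its protein concentration, giving 12 states.
#' Transcription of a regulated gene is modulated by Hill functions of the
#' regulating proteins; translation is linear in the mRNA. All mRNA species
#' degrade at the fixed rate 1 (which sets the time unit) and all proteins
#' share a single unknown degradation rate, so the free parameters are the
#' six promoter strengths, six translation (RBS) strengths, eight
#' Michaelis-Menten-like constants K, eight Hill exponents h, and the common
#' protein degradation rate: 29 in total.
#'
#' @return An object of class `grn_model`: a list with elements
#'   `genes` (integer ids 1:6), `edges` (data frame with columns
#'   `regulator`, `target`, `sign`, `K`, `h`, ordered by edge index),
#'   `parameter_names` (length 29), `fixed_constants`
#'   (`mRNA_deg_rate = 1`), `state_names` (length 12, mRNA and protein
#'   interleaved per gene), and `perturbation` (initially the wild type).
#' @seealso [apply_perturbation()], [grn_simulate()]
#' @export
#' @examples
#' m <- grn_model1()
#' length(m$parameter_names)  # 29
#' nrow(m$edges)              # 8
grn_model1 <- function() {
  edges <- data.frame(
    regulator = c(1L, 1L, 1L, 2L, 6L, 4L, 4L, 5L),
    target    = c(4L, 2L, 3L, 3L, 2L, 5L, 6L, 4L),
    sign      = c("activating", "activating", "activating", "inhibiting",
                  "inhibiting", "inhibiting", "inhibiting", "inhibiting"),
    K         = paste0("K", 1:8),
    h         = paste0("h", 1:8),
    stringsAsFactors = FALSE
  )
  state_names <- as.vector(rbind(paste0("mRNA", 1:6), paste0("p", 1:6)))
  model <- list(
    genes = 1:6,
    edges = edges,
    parameter_names = c(paste0("pro", 1:6, "_strength"),
                        paste0("rbs", 1:6, "_strength"),
                        paste0("K", 1:8), paste0("h", 1:8), "p_deg_rate"),
    fixed_constants = c(mRNA_deg_rate = 1),
    state_names = state_names,
    perturbation = list(kind = "wild", gene = NA_integer_)
  )
  class(model) <- "grn_model"
  model
}

#' Apply a single perturbation to the network model
#'
#' Perturbations are applied at evaluation time and do not change the free
#' parameter list: deletion forces the gene's promoter and RBS strengths to
#' zero, knockdown raises that gene's mRNA degradation rate five-fold, and
#' overexpression doubles the gene's translation rate.
#'
#' @param model A `grn_model`.
#' @param kind One of `"wild"`, `"delete"`, `"overexpress"`, `"knockdown"`.
#' @param gene Gene id (1-6); ignored for `"wild"`.
#' @return A new `grn_model` carrying the perturbation; the input is not
#'   modified.
#' @export
apply_perturbation <- function(model, kind = c("wild", "delete",
                                               "overexpress", "knockdown"),
                               gene = NA_integer_) {
  kind <- match.arg(kind)
  if (kind != "wild") {
    if (is.na(gene) || !gene %in% model$genes)
      stop("unknown gene for perturbation: ", gene)
    gene <- as.integer(gene)
  } else {
    gene <- NA_integer_
  }
  model$perturbation <- list(kind = kind, gene = gene)
  model
}

# Perturbation multipliers consumed by the compiled right-hand side:
# per-gene promoter multiplier, RBS multiplier, and mRNA degradation rate.
perturbation_multipliers <- function(model) {
  pro_mult <- rep(1, 6)
  rbs_mult <- rep(1, 6)
  mrna_deg <- rep(unname(model$fixed_constants["mRNA_deg_rate"]), 6)
  p <- model$perturbation
  if (p$kind == "delete") {
    pro_mult[p$gene] <- 0
    rbs_mult[p$gene] <- 0
  } else if (p$kind == "overexpress") {
    rbs_mult[p$gene] <- 2
  } else if (p$kind == "knockdown") {
    mrna_deg[p$gene] <- 5 * mrna_deg[p$gene]
  }
  list(pro_mult = pro_mult, rbs_mult = rbs_mult, mrna_deg = mrna_deg)
}

#' @export
print.grn_model <- function(x, ...) {
  cat("Gene regulatory network model:", length(x$genes), "genes,",
      nrow(x$edges), "edges,", length(x$state_names), "states,",
      length(x$parameter_names), "free parameters\n")
  p <- x$perturbation
  if (p$kind == "wild") {
    cat("Perturbation: wild type\n")
  } else {
    cat("Perturbation:", p$kind, "gene", p$gene, "\n")
  }
  invisible(x)
}

#' Plain-text report of the model structure
#'
#' Writes (or returns) a human-readable description of the network: the
#' gene list, the regulatory edges with their K and h parameter names, the
#' free parameters, and the fixed constants.
#'
#' @param model A `grn_model`.
#' @param file Optional path; if `NULL` the lines are returned invisibly.
#' @return Character vector of report lines, invisibly.
#' @export
model_report <- function(model, file = NULL) {
  lines <- c(
    sprintf("genes: %s", paste(model$genes, collapse = " ")),
    "edges (regulator -> target, sign, K, h):",
    sprintf("  p%d -> gene%d  %s  %s %s",
            model$edges$regulator, model$edges$target, model$edges$sign,
            model$edges$K, model$edges$h),
    sprintf("free parameters (%d): %s", length(model$parameter_names),
            paste(model$parameter_names, collapse = " ")),
    sprintf("fixed: %s = %g", names(model$fixed_constants),
            model$fixed_constants)
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
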