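#' Configuration for synthetic expression data
#'
#' Describes a genes x samples microarray-like design with four treatment
#' groups (control, trastuzumab, pertuzumab, combination), per-gene
#' planted linear fold changes, a log-normal baseline intensity
#' distribution and additive Gaussian noise on the log2 scale.
#'
#' @param n_genes gene universe size.
#' @param n_reps replicates per group (>= 2).
#' @param folds named list: gene -> numeric fold-change vector with
#'   entries trastuzumab, pertuzumab, combination (linear scale, > 0);
#'   genes not listed are planted at 1.0.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale parameters of
#'   the baseline intensity distribution.
#' @param noise_sd measurement noise SD on the log2 scale.
#' @param seed integer seed; generation is fully deterministic given the
#'   seed (Mersenne-Twister).
#' @export
synthetic_expression_config <- function(n_genes = 1000, n_reps = 5,
                                        folds = list(),
                                        baseline_log2_mean = 8,
                                        baseline_log2_sd = 1.5,
                                        noise_sd = 0.25, seed = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (noise_sd < 0 || baseline_log2_sd <= 0) stop("SDs must be positive")
  for (g in names(folds)) {
    f <- folds[[g]]
    if (!all(c("trastuzumab", "pertuzumab", "combination") %in% names(f))) {
      stop("fold entry for ", g,
           " must name trastuzumab, pertuzumab and combination")
    }
    if (any(f <= 0)) stop("planted folds must be > 0 (gene ", g, ")")
  }
  structure(list(n_genes = n_genes, n_reps = n_reps, folds = folds,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_expression_config")
}

#' Default planted fold changes
#'
#' The reference planting used throughout: HER3 up-regulated 1.3-fold
#' under trastuzumab, 1.1 under pertuzumab and 1.8 under the combination;
#' HER2 1.1 / 1.1 / 1.2; the HER3-ligand gene NRG4 1.3 / 1.0 / 1.2. All
#' other genes are null (fold 1.0).
#'
#' @param n_genes gene universe size including the planted genes.
#' @param ... overrides passed to [synthetic_expression_config()].
#' @export
default_planting <- function(n_genes = 1000, ...) {
  folds <- list(
    HER3 = c(trastuzumab = 1.3, pertuzumab = 1.1, combination = 1.8),
    HER2 = c(trastuzumab = 1.1, pertuzumab = 1.1, combination = 1.2),
    NRG4 = c(trastuzumab = 1.3, pertuzumab = 1.0, combination = 1.2))
  synthetic_expression_config(n_genes = n_genes, folds = folds, ...)
}

.GROUPS <- c("control", "trastuzumab", "pertuzumab", "combination")

#' Generate a synthetic expression matrix
#'
#' Per gene g and group k, log2 intensity = baseline_g +
#' log2(planted fold_{g,k}) + N(0, noise_sd); the control fold is 1.
#' Planted genes occupy the first rows (fixed positions) followed by
#' GENE0001, GENE0002, ... null genes. Output is linear-scale.
#'
#' @param cfg a [synthetic_expression_config()].
#' @return an [expression_matrix()]; the sample sheet is available via
#'   `attr(, "sample_sheet")`.
#' @export
generate_expression <- function(cfg) {
  if (!inherits(cfg, "synthetic_expression_config")) {
    stop("cfg must be a synthetic_expression_config")
  }
  planted <- names(cfg$folds)
  if (length(planted) > cfg$n_genes) {
    stop("more planted genes than n_genes")
  }
  n_null <- cfg$n_genes - length(planted)
  genes <- c(planted,
             if (n_null) sprintf("GENE%04d", seq_len(n_null)))
  samples <- as.vector(vapply(.GROUPS, function(g) {
    paste0(g, "_", seq_len(cfg$n_reps))
  }, character(cfg$n_reps)))
  groups <- rep(.GROUPS, each = cfg$n_reps)

  lfc <- matrix(0, length(genes), length(.GROUPS),
                dimnames = list(genes, .GROUPS))
  for (g in planted) lfc[g, names(cfg$folds[[g]])] <- log2(cfg$folds[[g]])

  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  baseline <- stats::rnorm(length(genes), cfg$baseline_log2_mean,
                           cfg$baseline_log2_sd)
  noise <- matrix(stats::rnorm(length(genes) * length(samples),
                               sd = cfg$noise_sd),
                  length(genes), length(samples))
  log2x <- baseline + lfc[, groups] + noise
  vals <- 2^log2x
  dimnames(vals) <- list(genes, samples)
  out <- expression_matrix(vals, stats::setNames(groups, samples))
  attr(out, "sample_sheet") <- data.frame(sample = samples, group = groups,
                                          stringsAsFactors = FALSE)
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Null expression dataset
#'
#' All genes planted at fold 1.0; used for type-I-error calibration of
#' the per-gene t-test.
#'
#' @param n_genes,n_reps design size.
#' @param seed integer seed.
#' @export
null_dataset <- function(n_genes = 10000, n_reps = 5, seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  generate_expression(synthetic_expression_config(
    n_genes = n_genes, n_reps = n_reps, folds = list(), seed = seed))
}

#' Synthetic reference inhibition observations
#'
#' Gaussian perturbation of supplied per-scenario mean percent
#' inhibitions, standing in for experimental pAKT/pERK inhibition bars.
#' The object is labelled synthetic; no experimental values are shipped.
#'
#' @param scenario_means named list: scenario -> list(pAKT =, pERK =)
#'   mean percent inhibition in [-100, 100].
#' @param sds list of the same shape giving the SDs (>= 0), or a single
#'   number recycled everywhere.
#' @param seed integer seed.
#' @param cell_context free-text label of the emulated cell context.
#' @return a `reference_inhibition` object.
#' @export
generate_reference_inhibition <- function(scenario_means, sds = 5,
                                          seed = 1,
                                          cell_context = "synthetic") {
  if (!length(scenario_means)) stop("no scenarios supplied")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  scen <- list()
  for (sc in names(scenario_means)) {
    m <- scenario_means[[sc]]
    if (any(unlist(m) < -100 | unlist(m) > 100)) {
      stop("means must lie in [-100, 100] (scenario ", sc, ")")
    }
    s <- if (is.numeric(sds) && length(sds) == 1) {
      list(pAKT = sds, pERK = sds)
    } else sds[[sc]]
    if (any(unlist(s) < 0)) stop("SDs must be >= 0")
    scen[[sc]] <- list(
      pAKT = list(mean = m$pAKT + stats::rnorm(1, sd = s$pAKT),
                  sd = s$pAKT),
      pERK = list(mean = m$pERK + stats::rnorm(1, sd = s$pERK),
                  sd = s$pERK))
  }
  structure(list(scenarios = scen, cell_context = cell_context,
                 seed = seed),
            class = "reference_inhibition")
}
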