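#' Expression matrix container
#'
#' A genes x samples matrix of strictly positive linear-scale intensities
#' together with a sample sheet mapping samples to treatment groups
#' (control, trastuzumab, pertuzumab, combination).
#'
#' @param values numeric matrix, rownames = gene identifiers, colnames =
#'   sample identifiers, all entries > 0.
#' @param groups named character or factor: sample -> group, or a
#'   data.frame with columns `sample` and `group`.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("gene identifiers must be unique and present",
         if (length(dup)) paste0("; duplicated: ",
                                 paste(dup, collapse = ", ")))
  }
  if (is.null(colnames(values))) stop("sample identifiers missing")
  if (!all(colnames(values) %in% names(groups))) {
    stop("sample sheet is missing groups for: ",
         paste(setdiff(colnames(values), names(groups)), collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)[1, ]
    stop("intensities must be finite and strictly positive (gene ",
         rownames(values)[bad[1]], ", sample ", colnames(values)[bad[2]],
         ")")
  }
  structure(list(values = values,
                 groups = as.character(groups[colnames(values)])),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; groups:",
      paste(sprintf("%s(%d)", names(table(x$groups)), table(x$groups)),
            collapse = " "), "\n")
  invisible(x)
}

group_columns <- function(mat, group) {
  idx <- which(mat$groups == group)
  if (length(idx) < 2) {
    stop("group '", group, "' needs at least 2 samples (has ",
         length(idx), ")")
  }
  idx
}

#' Per-gene linear fold changes between two groups
#'
#' fold = mean(treated) / mean(control) on the linear intensity scale;
#' the log2 of the ratio is returned alongside.
#'
#' @param mat an [expression_matrix()].
#' @param treated_group,control_group group labels.
#' @return data.frame: gene, fold, log2fc.
#' @export
fold_changes <- function(mat, treated_group, control_group = "control") {
  it <- group_columns(mat, treated_group)
  ic <- group_columns(mat, control_group)
  fold <- rowMeans(mat$values[, it, drop = FALSE]) /
    rowMeans(mat$values[, ic, drop = FALSE])
  data.frame(gene = rownames(mat$values), fold = unname(fold),
             log2fc = unname(log2(fold)), stringsAsFactors = FALSE)
}

#' Per-gene Student's t-test on log2 intensities
#'
#' Two-sided pooled-variance (Student's) t-test comparing log2-transformed
#' intensities of the treated against the control group, vectorised over
#' genes. Degenerate genes follow the convention: zero pooled variance
#' with equal means gives p = 1; zero pooled variance with unequal means
#' gives p = 0 (with a warning naming the genes).
#'
#' @inheritParams fold_changes
#' @return data.frame: gene, t, p.
#' @export
student_ttest <- function(mat, treated_group, control_group = "control") {
  it <- group_columns(mat, treated_group)
  ic <- group_columns(mat, control_group)
  x <- log2(mat$values[, it, drop = FALSE])
  y <- log2(mat$values[, ic, drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2); v2 <- rowSums((y - m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    tt[eq] <- 0; p[eq] <- 1
    ne <- zero & (m1 != m2)
    if (any(ne)) {
      warning("zero pooled variance with unequal means; p = 0 by ",
              "convention for: ",
              paste(rownames(mat$values)[ne], collapse = ", "))
      tt[ne] <- sign(m1[ne] - m2[ne]) * Inf
      p[ne] <- 0
    }
  }
  data.frame(gene = rownames(mat$values), t = unname(tt), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Full differential result for one contrast
#'
#' Combines fold changes and t-test p-values; a gene is significant when
#' p < `p_thresh` (no multiple-testing correction is applied, matching
#' the raw p < 0.05 convention of the analysis this package reproduces),
#' and its direction is "up" when the linear fold change exceeds 1.
#'
#' @inheritParams fold_changes
#' @param p_thresh significance threshold on the raw p-value.
#' @return data.frame: gene, fold, log2fc, t, p, significant, direction.
#' @export
differential_result <- function(mat, treated_group,
                                control_group = "control",
                                p_thresh = 0.05) {
  fc <- fold_changes(mat, treated_group, control_group)
  tt <- student_ttest(mat, treated_group, control_group)
  out <- merge(fc, tt, by = "gene", sort = FALSE)
  out <- out[match(fc$gene, out$gene), ]
  out$significant <- out$p < p_thresh
  out$direction <- ifelse(out$fold > 1, "up", "down")
  rownames(out) <- NULL
  out
}

#' Volcano-plot categories
#'
#' Partitions genes into the three volcano classes: "high-fold" when
#' |log2FC| >= `fc_thresh` (regardless of p), otherwise "significant"
#' when p < `p_thresh`, otherwise "non-significant".
#'
#' @param results a [differential_result()] data.frame.
#' @param p_thresh p-value threshold (default 0.05).
#' @param fc_thresh |log2FC| threshold for the high-fold class (default 1,
#'   i.e. two-fold).
#' @return character vector of categories aligned with `results`.
#' @export
volcano_classify <- function(results, p_thresh = 0.05, fc_thresh = 1) {
  if (p_thresh <= 0 || fc_thresh <= 0) stop("thresholds must be positive")
  ifelse(abs(results$log2fc) >= fc_thresh, "high-fold",
         ifelse(results$p < p_thresh, "significant", "non-significant"))
}

#' Three-set Venn region counts
#'
#' Exclusive counts of the 7 regions of a three-set Venn diagram.
#'
#' @param setA,setB,setC vectors of gene identifiers.
#' @return named integer vector with regions A_only, B_only, C_only, AB,
#'   AC, BC, ABC; the attribute `union_size` carries the union size.
#' @export
venn_counts <- function(setA, setB, setC) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  u <- union(union(setA, setB), setC)
  inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
  out <- c(
    A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
  attr(out, "union_size") <- length(u)
  out
}

#' Up/down regulation imbalance
#'
#' 100 * |n_up - n_down| / (n_up + n_down) over the regulated
#' (significant) genes of a differential result.
#'
#' @param results a [differential_result()] data.frame.
#' @return percent imbalance.
#' @export
updown_imbalance <- function(results) {
  reg <- results[results$significant, ]
  n_up <- sum(reg$direction == "up")
  n_down <- sum(reg$direction == "down")
  if (n_up + n_down == 0) {
    stop("imbalance undefined: no significantly regulated genes")
  }
  100 * abs(n_up - n_down) / (n_up + n_down)
}

#' Pathway gene sets
#'
#' Loads the pathway -> gene-symbol table shipped with the package
#' (PI3K/AKT and ERK1/2 membership lists curated from the published
#' pathway figures), or a user-supplied TSV with columns `pathway` and
#' `symbol`.
#'
#' @param path TSV file.
#' @return named list of character vectors (upper-case symbols).
#' @export
gene_sets <- function(path = system.file("extdata", "gene_sets.tsv",
                                         package = "erbbcombo")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway", "symbol") %in% names(tab))) {
    stop("gene-set table needs columns 'pathway' and 'symbol'")
  }
  sets <- split(toupper(tab$symbol), tab$pathway)
  if (any(!lengths(sets))) stop("empty gene set in ", path)
  sets
}

#' Heatmap matrix of significant pathway genes
#'
#' For a gene set, returns the log2 fold changes across the three
#' treatments of every member gene that is significant (p < `p_thresh`)
#' in at least one treatment. Rows are ordered by decreasing
#' combination-group log2FC (a deterministic stand-in for clustering
#' order).
#'
#' @param results_list named list of [differential_result()] data.frames,
#'   one per treatment; names are used as column names (conventionally
#'   Tr, Per, Com with the combination last).
#' @param gene_set character vector of member gene symbols.
#' @param p_thresh significance threshold.
#' @return numeric matrix (genes x treatments) of log2 fold changes;
#'   empty (0-row) with a warning when no member gene qualifies.
#' @export
pathway_heatmap_matrix <- function(results_list, gene_set,
                                   p_thresh = 0.05) {
  if (length(results_list) != 3) {
    stop("results for all three treatments are required")
  }
  gene_set <- toupper(gene_set)
  genes <- results_list[[1]]$gene
  keep <- genes %in% gene_set
  sig <- Reduce(`|`, lapply(results_list, function(d) d$p < p_thresh))
  rows <- genes[keep & sig]
  if (!length(rows)) {
    warning("no significant genes from the set are present in the data")
    return(matrix(numeric(), 0, length(results_list),
                  dimnames = list(NULL, names(results_list))))
  }
  m <- vapply(results_list,
              function(d) d$log2fc[match(rows, d$gene)],
              numeric(length(rows)))
  m <- matrix(m, nrow = length(rows),
              dimnames = list(rows, names(results_list)))
  m[order(m[, ncol(m)], decreasing = TRUE), , drop = FALSE]
}
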