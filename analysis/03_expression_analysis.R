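#!/usr/bin/env Rscript

# Differential-expression stage on synthetic microarray-like data: fold
# changes and Student's t-tests per treatment, volcano categories, Venn
# counts of significant genes, the up/down imbalance, pathway heatmap
# matrices and a node-attribute table for network-visualisation tools.
#
# The matrix is synthetic: the reference planting (HER3 1.3/1.1/1.8,
# HER2 1.1/1.1/1.2, NRG4 1.3/1.0/1.2) plus a demonstration block of
# regulated pathway genes so that the Venn/heatmap summaries are
# non-trivial. Seeded and fully reproducible.

suppressPackageStartupMessages(library(erbbcombo))

dir.create("results", showWarnings = FALSE)
set <- gene_sets()

cfg <- default_planting(n_genes = 1000, seed = 7)
demo <- list(
  FOXO1 = c(1.6, 1.3, 2.0), PIK3R2 = c(1.2, 1.2, 1.3),
  AKT1 = c(1.1, 1.1, 1.2), CDKN1A = c(1.5, 1.2, 1.9),
  JUN = c(1.4, 1.1, 1.7), RAC1 = c(1.2, 1.1, 1.4),
  TGFA = c(0.8, 0.9, 0.6), IGF1 = c(0.85, 0.9, 0.7),
  EPHA2 = c(0.8, 0.85, 0.65), SRC = c(0.9, 0.95, 0.8),
  HSPB1 = c(1.3, 1.1, 1.6), ARAF = c(1.2, 1.1, 1.4),
  MAPK10 = c(1.1, 1.0, 1.5), FOS = c(0.9, 0.95, 0.55),
  JUNB = c(0.9, 0.9, 0.6), DUSP1 = c(0.95, 0.9, 0.7),
  IL6 = c(0.85, 0.9, 0.6), THBS1 = c(0.9, 0.95, 0.65))
for (g in names(demo)) {
  cfg$folds[[g]] <- stats::setNames(demo[[g]],
                                    c("trastuzumab", "pertuzumab",
                                      "combination"))
}
mat <- generate_expression(cfg)
write_expression_tsv(mat, "results/expression_matrix.tsv",
                     "results/sample_sheet.tsv")

res <- list(Tr = differential_result(mat, "trastuzumab"),
            Per = differential_result(mat, "pertuzumab"),
            Com = differential_result(mat, "combination"))
for (nm in names(res)) {
  out <- res[[nm]]
  out$volcano <- volcano_classify(out)
  write_differential_csv(out, sprintf("results/de_%s.csv", nm),
                         paste0(nm, ":control"))
}

cat("Differential expression on the synthetic matrix",
    sprintf("(%d genes, 5 replicates/group):\n", cfg$n_genes))
for (nm in names(res)) {
  n_sig <- sum(res[[nm]]$significant)
  cat(sprintf(" - %-4s %4d significant genes (raw p < 0.05), imbalance %.1f%%\n",
              nm, n_sig, updown_imbalance(res[[nm]])))
}
cat(sprintf(" - HER3 fold change: %.2f (Tr), %.2f (Per), %.2f (Com)\n",
            res$Tr$fold[res$Tr$gene == "HER3"],
            res$Per$fold[res$Per$gene == "HER3"],
            res$Com$fold[res$Com$gene == "HER3"]))

sig <- lapply(res, function(d) d$gene[d$significant])
up <- lapply(res, function(d) d$gene[d$significant & d$direction == "up"])
down <- lapply(res, function(d) d$gene[d$significant & d$direction == "down"])
venn_all <- venn_counts(sig$Tr, sig$Per, sig$Com)
venn_up <- venn_counts(up$Tr, up$Per, up$Com)
venn_down <- venn_counts(down$Tr, down$Per, down$Com)
venn_tab <- data.frame(region = names(venn_all),
                       all = as.integer(venn_all),
                       up = as.integer(venn_up),
                       down = as.integer(venn_down))
write.csv(venn_tab, "results/venn_counts.csv", row.names = FALSE)
cat(sprintf(" - combination-specific significant genes: %d (of %d union)\n",
            venn_tab$all[venn_tab$region == "C_only"],
            attr(venn_all, "union_size")))

for (pw in names(set)) {
  hm <- pathway_heatmap_matrix(res, set[[pw]])
  write.csv(as.data.frame(hm), sprintf("results/heatmap_%s.csv", pw))
  cat(sprintf(" - %s heatmap: %d significant pathway genes\n", pw, nrow(hm)))
}

node_attr <- data.frame(gene = res$Tr$gene,
                        log2fc_Tr = res$Tr$log2fc,
                        log2fc_Per = res$Per$log2fc,
                        log2fc_Com = res$Com$log2fc)
node_attr <- node_attr[node_attr$gene %in% toupper(unlist(set)), ]
write.table(node_attr, "results/node_attributes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Tables written to results/ (de_*.csv, venn_counts.csv,",
    "heatmap_*.csv, node_attributes.tsv)\n")
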