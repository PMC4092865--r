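make_matrix <- function(values, groups) {
  expression_matrix(values, groups)
}

toy_3v3 <- function() {
  vals <- rbind(GENE1 = c(10, 12, 11, 20, 22, 24),
                GENE2 = c(5, 5, 5, 5, 5, 5))
  colnames(vals) <- c(paste0("c", 1:3), paste0("t", 1:3))
  make_matrix(vals, stats::setNames(rep(c("control", "combination"),
                                        each = 3), colnames(vals)))
}

test_that("expression matrix enforces its invariants", {
  vals <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(make_matrix(vals, c(s1 = "control", s2 = "combination")),
               "unique")
  vals2 <- matrix(c(1, -1, 2, 3), 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(make_matrix(vals2, c(s1 = "control", s2 = "combination")),
               "positive")
  vals3 <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(make_matrix(vals3, c(s1 = "control")), "missing groups")
})

test_that("fold changes are ratios of group means with hand-checked values", {
  mat <- toy_3v3()
  fc <- fold_changes(mat, "combination", "control")
  expect_equal(fc$fold[fc$gene == "GENE1"], 22 / 11)
  expect_equal(fc$log2fc[fc$gene == "GENE1"], 1)
  expect_equal(fc$fold[fc$gene == "GENE2"], 1)
  expect_equal(fc$log2fc[fc$gene == "GENE2"], 0)
})

test_that("fold changes are invariant to global intensity rescaling", {
  mat <- toy_3v3()
  for (c0 in c(0.01, 3.7, 1000)) {
    scaled <- make_matrix(mat$values * c0,
                          stats::setNames(mat$groups,
                                          colnames(mat$values)))
    expect_equal(fold_changes(scaled, "combination")$fold,
                 fold_changes(mat, "combination")$fold)
  }
})

test_that("Student's t-test matches stats::t.test and its conventions", {
  set.seed(3)
  vals <- matrix(2^(rnorm(40, 8, 1)), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  groups <- stats::setNames(rep(c("control", "trastuzumab"), each = 5),
                            colnames(vals))
  mat <- make_matrix(vals, groups)
  res <- student_ttest(mat, "trastuzumab", "control")
  for (g in rownames(vals)) {
    ref <- stats::t.test(log2(vals[g, 6:10]), log2(vals[g, 1:5]),
                         var.equal = TRUE)
    expect_equal(res$p[res$gene == g], ref$p.value, tolerance = 1e-12)
    expect_equal(res$t[res$gene == g], unname(ref$statistic),
                 tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1 (zero-variance convention)
  const <- make_matrix(matrix(4, 1, 10,
                              dimnames = list("g", paste0("s", 1:10))),
                       groups)
  cr <- student_ttest(const, "trastuzumab", "control")
  expect_equal(cr$t, 0)
  expect_equal(cr$p, 1)
  # zero variance with unequal means: p = 0, logged
  sep <- matrix(rep(c(2, 8), each = 5), 1, dimnames = list("g", NULL))
  colnames(sep) <- paste0("s", 1:10)
  expect_warning(sr <- student_ttest(make_matrix(sep, groups),
                                     "trastuzumab", "control"),
                 "zero pooled variance")
  expect_equal(sr$p, 0)
  # extreme separation: essentially zero p
  far <- make_matrix(matrix(c(rep(2, 5), rep(2000, 5)) *
                              exp(rnorm(10, 0, 1e-4)), 1,
                            dimnames = list("g", paste0("s", 1:10))),
                     groups)
  expect_lt(student_ttest(far, "trastuzumab", "control")$p, 1e-6)
})

test_that("t-test p-values agree with a permutation oracle", {
  n <- 12
  perms <- 10000
  set.seed(17)
  for (case in 1:3) {
    x <- rnorm(n, 0.45 * (case - 1), 1)
    y <- rnorm(n, 0, 1)
    vals <- matrix(2^c(y, x), 1,
                   dimnames = list("g", paste0("s", 1:(2 * n))))
    groups <- stats::setNames(rep(c("control", "pertuzumab"), each = n),
                              colnames(vals))
    pt_ <- student_ttest(make_matrix(vals, groups), "pertuzumab")$p
    tstat <- function(a, b) {
      sp <- sqrt(((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2))
      (mean(a) - mean(b)) / (sp * sqrt(2 / n))
    }
    obs <- abs(tstat(x, y))
    pool <- c(x, y)
    hits <- replicate(perms, {
      idx <- sample(2 * n, n)
      abs(tstat(pool[idx], pool[-idx])) >= obs
    })
    p_perm <- mean(hits)
    se <- sqrt(p_perm * (1 - p_perm) / perms)
    expect_lt(abs(pt_ - p_perm), 3 * max(se, 0.005),
              label = paste("case", case, "p_t", signif(pt_, 3),
                            "p_perm", signif(p_perm, 3)))
  }
})

test_that("volcano categories partition the gene list", {
  res <- data.frame(
    gene = paste0("g", 1:4),
    log2fc = c(0.1, 0.05, 2.1, -1.5),
    p = c(0.04, 0.5, 0.2, 0.01))
  cat <- volcano_classify(res, p_thresh = 0.05, fc_thresh = 1)
  expect_equal(cat, c("significant", "non-significant",
                      "high-fold", "high-fold"))
  expect_equal(length(cat), nrow(res))  # every gene in exactly one class
  expect_error(volcano_classify(res, p_thresh = -1), "positive")
})

test_that("venn counts match brute-force enumeration", {
  z <- venn_counts(character(), character(), character())
  expect_true(all(z == 0))
  same <- venn_counts(c("g1", "g2"), c("g1", "g2"), c("g1", "g2"))
  expect_equal(unname(same["ABC"]), 2)
  expect_equal(sum(same), 2)
  v <- venn_counts(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"))
  expect_equal(unname(v[c("A_only", "B_only", "C_only",
                          "AB", "BC", "AC", "ABC")]),
               c(1, 0, 1, 1, 1, 0, 1))
  # regions are disjoint and sum to the union size, on random sets
  set.seed(5)
  for (i in 1:10) {
    A <- sample(letters, sample(0:20, 1))
    B <- sample(letters, sample(0:20, 1))
    C <- sample(letters, sample(0:20, 1))
    v <- venn_counts(A, B, C)
    expect_equal(sum(v), length(union(union(A, B), C)))
    expect_equal(unname(v["A_only"] + v["AB"] + v["AC"] + v["ABC"]),
                 length(unique(A)))
  }
})

test_that("up/down imbalance follows its definition", {
  mk <- function(nu, nd) {
    data.frame(gene = paste0("g", seq_len(nu + nd)),
               significant = TRUE,
               direction = c(rep("up", nu), rep("down", nd)))
  }
  expect_equal(updown_imbalance(mk(50, 50)), 0)
  expect_equal(updown_imbalance(mk(53, 47)), 6)
  expect_equal(updown_imbalance(mk(10, 0)), 100)
  none <- data.frame(gene = "g", significant = FALSE, direction = "up")
  expect_error(updown_imbalance(none), "no significantly regulated")
})

test_that("heatmap matrix keeps genes significant in any treatment, ordered", {
  cfg <- default_planting(n_genes = 60, seed = 42)
  # plant five extra strongly regulated pathway genes
  for (g in c("AKT1", "PIK3R2", "FOXO1", "JUN", "CDKN1A")) {
    cfg$folds[[g]] <- c(trastuzumab = 2.2, pertuzumab = 2.0,
                        combination = 3.0)
  }
  mat <- generate_expression(cfg)
  res <- list(Tr = differential_result(mat, "trastuzumab"),
              Per = differential_result(mat, "pertuzumab"),
              Com = differential_result(mat, "combination"))
  sets <- gene_sets()
  hm <- pathway_heatmap_matrix(res, sets$PI3K_AKT)
  expect_true(all(c("AKT1", "PIK3R2", "FOXO1", "JUN", "CDKN1A") %in%
                    rownames(hm)))
  expect_equal(colnames(hm), c("Tr", "Per", "Com"))
  expect_true(!is.unsorted(rev(hm[, "Com"])))  # descending combination FC
  # genes inside the set but never significant are excluded
  expect_true(all(rownames(hm) %in% toupper(sets$PI3K_AKT)))
  # empty result warns
  null_res <- lapply(res, function(d) { d$p <- 1; d })
  expect_warning(empty <- pathway_heatmap_matrix(null_res, sets$PI3K_AKT),
                 "no significant")
  expect_equal(nrow(empty), 0)
})
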