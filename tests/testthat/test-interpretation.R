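# Interpretation statistics: Spearman evaluation, exact tests, attention
# aggregation, knockout, associations, clustering.

test_that("per-tumor Spearman hits the exact limits and the brute-force ranks", {
  set.seed(1)
  Y <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(unname(spearman_per_tumor(Y, Y)$per_tumor), rep(1, 5))
  expect_equal(unname(spearman_per_tumor(Y, -Y)$per_tumor), rep(-1, 5))
  # toy vectors with ties vs exhaustive average-rank computation
  y <- rbind(c(1, 2, 2, 3, 5))
  yh <- rbind(c(2, 1, 4, 4, 6))
  expect_equal(unname(spearman_per_tumor(y, yh)$per_tumor),
               bf_spearman(y[1, ], yh[1, ]))
  for (i in 1:20) {
    a <- rbind(sample(1:6, 7, TRUE)); b <- rbind(rnorm(7))
    expect_equal(unname(spearman_per_tumor(a, b)$per_tumor),
                 bf_spearman(a[1, ], b[1, ]))
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(2)
  y <- rbind(rnorm(12)); yh <- rbind(rnorm(12))
  base <- spearman_per_tumor(y, yh)$per_tumor
  expect_equal(spearman_per_tumor(exp(y), yh)$per_tumor, base)
  expect_equal(spearman_per_tumor(y, yh^3)$per_tumor, base)
})

test_that("constant profiles yield NA with a warning and are excluded from the mean", {
  Y <- rbind(c(1, 2, 3), c(4, 4, 4))
  Yh <- rbind(c(1, 3, 2), c(1, 2, 3))
  expect_warning(sp <- spearman_per_tumor(Y, Yh), "constant")
  expect_true(is.na(sp$per_tumor[2]))
  expect_equal(sp$mean, sp$per_tumor[[1]])
})

test_that("Fisher exact p matches the classical implementation and its closed forms", {
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_p(5, 0, 0, 5), 2 / choose(10, 5))
  set.seed(3)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(5:60, 1), runif(4)))
    expect_equal(fisher_exact_p(cells[1], cells[2], cells[3], cells[4]),
                 stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("BH and Bonferroni adjustments follow the step-up arithmetic", {
  expect_equal(adjust_pvalues(0.037), 0.037)             # single test unchanged
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.6, "bonferroni"), 0.6)
  expect_equal(adjust_pvalues(c(0.6, 0.7, 0.8), "bonferroni")[1], 1) # clipped
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_pvalues(p), bf_bh(p))
  }
  expect_true(is.na(adjust_pvalues(c(0.1, NA))[2]))
  expect_error(adjust_pvalues(1.2), "outside")
})

test_that("attention aggregation sums carrier weights and matches manual totals", {
  model <- random_model(seed = 31)
  alt <- random_profiles_matrix(model, 3, min_m = 1, max_m = 4, seed = 32)
  alt[, 1] <- 0L                          # a gene altered nowhere
  co <- cohort_for_model(model, alt, rep("ct1", 3))
  summ <- aggregate_attention(model, co)
  expect_equal(summ$attention[summ$gene == model$vocab$alt_genes[1]], 0)
  long <- citrus_forward(model, co)$attention
  manual <- tapply(long$weight, long$gene, sum)
  for (g in names(manual))
    expect_equal(summ$attention[summ$gene == g], unname(manual[g]))
  expect_equal(summ$frequency, unname(colMeans(alt != 0)))
  # a single-gene tumor concentrates all h heads on that gene
  alt1 <- alt; alt1[] <- 0L; alt1[1, 5] <- 1L
  co1 <- cohort_for_model(model, alt1, rep("ct1", 3))
  s1 <- aggregate_attention(model, co1)
  expect_equal(s1$attention[s1$gene == model$vocab$alt_genes[5]],
               model$config$attention_heads)
})

test_that("driver enrichment builds the 2x2 table and flags empty high groups", {
  summ <- data.frame(gene = sprintf("g%02d", 1:10),
                     attention = c(rep(20, 5), rep(0.5, 5)),
                     carriers = 5, frequency = runif(10))
  dr <- sprintf("g%02d", 1:5)             # exactly the attended half
  en <- driver_enrichment(summ, dr, threshold = 2)
  expect_equal(unname(en$table), matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(en$p_value, 2 / choose(10, 5))
  summ$attention <- 0.1
  expect_warning(en0 <- driver_enrichment(summ, dr), "high-attention")
  expect_equal(en0$p_value, 1)
  # top-frequent variant restricts the universe first
  summ2 <- data.frame(gene = sprintf("g%02d", 1:10),
                      attention = c(rep(20, 5), rep(0.5, 5)),
                      carriers = 5, frequency = seq(1, 0.1, length.out = 10))
  en2 <- driver_enrichment(summ2, dr, top_frequent = 4)
  expect_equal(sum(en2$table), 4)
})

test_that("driver enrichment p-values are calibrated under a null assignment", {
  set.seed(5)
  ps <- replicate(400, {
    summ <- data.frame(gene = sprintf("g%02d", 1:40),
                       attention = sample(c(rep(20, 10), rep(0.5, 30))),
                       carriers = 5, frequency = 0.1)
    driver_enrichment(summ, sprintf("g%02d", sample(40, 8)))$p_value
  })
  # discrete and conservative: P(p <= a) <= a at conventional cutoffs
  expect_lte(mean(ps <= 0.05), 0.05 + 0.03)
  expect_lte(mean(ps <= 0.2), 0.2 + 0.05)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("knocking out a non-carrier gene changes nothing", {
  model <- random_model(seed = 41)
  alt <- random_profiles_matrix(model, 6, min_m = 1, max_m = 4, seed = 42)
  alt[, 2] <- 0L
  co <- cohort_for_model(model, alt, rep("ct1", 6))
  base <- infer_tf_activities(model, co)
  ko <- infer_tf_activities(model, co, drop_gene = model$vocab$alt_genes[2])
  expect_identical(base, ko)
})

test_that("knockout recovers a planted driver-TF effect with the smallest FDR", {
  co <- small_cohort()
  fit <- small_fit()
  gt <- co$ground_truth
  d <- gt$drivers[1]
  truth <- colnames(gt$driver_effects)[gt$driver_effects[d, ] != 0]
  res <- insilico_knockout(fit$model, co, d)
  expect_setequal(res$tf, colnames(co$prior))
  expect_true(all(res$fdr >= res$p - 1e-15))
  top <- res$tf[which.min(res$fdr)]
  expect_true(top %in% truth)
  # errors: absent gene, too few carriers
  expect_error(insilico_knockout(fit$model, co, "nope"), "nope")
  rare <- colnames(co$alterations)[which.min(colSums(co$alterations))]
  expect_error(
    insilico_knockout(fit$model, co, rare,
                      min_carriers = max(colSums(co$alterations)) + 1),
    "min_carriers")
})

test_that("TF / tumor-type association flags a planted shift and is null on identical types", {
  set.seed(6)
  act <- matrix(rnorm(90 * 6), 90, 6,
                dimnames = list(sprintf("t%02d", 1:90), sprintf("tf%d", 1:6)))
  ty <- rep(c("A", "B", "C"), each = 30)
  act[ty == "B", 4] <- act[ty == "B", 4] + 3   # +3 sd shift
  res <- tf_tumortype_association(act, ty)
  expect_equal(res$cancer_type[which.min(res$fdr)], "B")
  expect_equal(res$tf[which.min(res$fdr)], "tf4")
  expect_equal(res$direction[res$cancer_type == "B" & res$tf == "tf4"], 1L)
  # identical distributions: p far from significant on average
  act0 <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res0 <- tf_tumortype_association(act0, rep(c("A", "B"), each = 30))
  expect_gt(min(res0$fdr), 0.01)
  # tiny types are skipped with a warning
  expect_warning(tf_tumortype_association(act, c(rep("A", 88), "D", "D")), "D")
})

test_that("BH of a single test equals its raw p within the association table", {
  set.seed(7)
  act <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("tfA", "tfB")))
  res <- tf_tumortype_association(act[, 1, drop = FALSE],
                                  rep(c("A", "B"), each = 10))
  expect_equal(res$fdr, res$p)
})

test_that("subtype clustering separates planted blobs and orders deterministically", {
  set.seed(8)
  act <- rbind(matrix(rnorm(40 * 5, mean = 2), 40, 5),
               matrix(rnorm(40 * 5, mean = -2), 40, 5))
  rownames(act) <- sprintf("t%02d", 1:80)
  colnames(act) <- sprintf("tf%d", 1:5)
  truth <- rep(1:2, each = 40)
  cl <- subtype_clustering(act, k = 2, seed = 9)
  expect_equal(bf_ari(cl$labels, truth), 1)
  # duplicates share a label
  act2 <- act; act2[2, ] <- act2[1, ]
  cl2 <- subtype_clustering(act2, k = 2, seed = 9)
  expect_equal(unname(cl2$labels[1]), unname(cl2$labels[2]))
  # degenerate k = 1
  cl1 <- subtype_clustering(act, k = 1)
  expect_equal(unname(cl1$means[1, ]), unname(colMeans(act)))
  expect_error(subtype_clustering(act[1:3, ], k = 5), "exceeds")
  # silhouette scan prefers the true k
  sil <- silhouette_scan(act, ks = 2:4, seed = 9)
  expect_equal(sil$k[which.max(sil$mean_silhouette)], 2)
})

test_that("association scores are signed -log10 FDR and antisymmetric for two subtypes", {
  alt <- matrix(0L, 40, 3, dimnames = list(sprintf("t%02d", 1:40),
                                           c("gA", "gB", "gC")))
  sub <- stats::setNames(rep(c("s1", "s2"), each = 20), rownames(alt))
  alt[1:10, "gA"] <- 1L                  # exclusive to s1
  alt[c(1:5, 21:25), "gB"] <- 1L         # balanced
  res <- alteration_subtype_association(alt, sub)
  expect_false("gC" %in% res$gene)       # no carriers: skipped
  a1 <- res[res$gene == "gA" & res$subtype == "s1", ]
  expect_equal(a1$p, fisher_exact_p(10, 10, 0, 20))
  expect_gt(a1$score, 0)
  b <- res[res$gene == "gB", ]
  expect_equal(b$fdr, rep(1, 2))
  expect_equal(b$score, rep(0, 2))
  expect_equal(abs(a1$score), -log10(a1$fdr))
  # complementing the labels flips every score
  sub2 <- stats::setNames(ifelse(sub == "s1", "s2", "s1"), names(sub))
  res2 <- alteration_subtype_association(alt, sub2)
  m <- merge(res, res2, by = c("gene", "subtype"))
  expect_equal(m$score.x, -m$score.y)
})
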