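# Downstream statistics: evaluation metrics, attention aggregation and
# driver enrichment, in silico knockout, TF / tumor-type association,
# subtype clustering, and signed association scores.

# ---- metrics ------------------------------------------------------------

#' Per-tumor Spearman correlation between measured and predicted expression
#'
#' @param Y,Yhat tumors x genes matrices with matched rows/columns (at
#'   least 3 genes). Ties receive average ranks.
#' @return list with `per_tumor` (named numeric; `NA` for tumors whose
#'   measured or predicted profile is constant, reported with a warning)
#'   and `mean` (across tumors, `NA`s excluded).
#' @export
spearman_per_tumor <- function(Y, Yhat) {
  stopifnot(identical(dim(Y), dim(Yhat)), ncol(Y) >= 3)
  rho <- vapply(seq_len(nrow(Y)), function(i) {
    if (stats::sd(Y[i, ]) == 0 || stats::sd(Yhat[i, ]) == 0) return(NA_real_)
    stats::cor(Y[i, ], Yhat[i, ], method = "spearman")
  }, numeric(1))
  names(rho) <- rownames(Y)
  if (anyNA(rho))
    warning(sum(is.na(rho)), " tumor(s) with a constant profile excluded from the mean")
  list(per_tumor = rho, mean = mean(rho, na.rm = TRUE))
}

#' Evaluate a trained model on a tumor subset
#'
#' Computes per-tumor Spearman correlation and MSE between the (per-gene
#' z-scored, training statistics) measured expression and the model's
#' predictions.
#'
#' @param fit a `citrus_fit` (its held-out `split$test` is the default
#'   subset) or a trained `citrus_model` (then `tumors` is required).
#' @param cohort a `citrus_cohort`.
#' @param tumors tumor ids to evaluate.
#' @return list with `per_tumor`, `mean_spearman`, `mse`, and `by_type`
#'   (mean Spearman per cancer type).
#' @export
evaluate_model <- function(fit, cohort, tumors = NULL) {
  if (inherits(fit, "citrus_fit")) {
    if (is.null(tumors)) tumors <- fit$split$test
    model <- fit$model
  } else model <- fit
  if (is.null(tumors)) stop("tumors must be given when evaluating a bare model")
  if (is.null(model$norm)) stop("model carries no normalization statistics")
  Y <- cohort$expression[tumors, , drop = FALSE]
  Yn <- sweep(sweep(Y, 2, model$norm$center), 2, model$norm$scale, "/")
  Yhat <- stats::predict(model, cohort, tumors = tumors)
  sp <- spearman_per_tumor(Yn, Yhat)
  types <- as.character(cohort$cancer_type[match(tumors, rownames(cohort$alterations))])
  by_type <- tapply(sp$per_tumor, types, mean, na.rm = TRUE)
  list(per_tumor = sp$per_tumor, mean_spearman = sp$mean,
       mse = mse_loss(Yn, Yhat), by_type = by_type)
}

# ---- exact tests and multiple-testing adjustment -------------------------

#' Two-sided Fisher exact p for 2x2 tables, vectorized
#'
#' Enumerates the hypergeometric support of each table
#' `[[a, b], [c, d]]` (margins fixed) and sums the probabilities of all
#' tables at most as probable as the observed one (with the customary
#' `1 + 1e-7` relative slack on the comparison, so results agree with
#' [stats::fisher.test()] to machine precision).
#'
#' @param a,b,c,d integer vectors of cell counts (recycled to a common
#'   length): `a` = in-group successes, `b` = in-group failures, `c` =
#'   out-group successes, `d` = out-group failures.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
    lo <- max(0L, k - nn); hi <- min(k, m)
    dens <- stats::dhyper(lo:hi, m, nn, k)
    p <- sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)])
    min(p, 1)
  }, numeric(1))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni with clipping at 1;
#' `NA` p-values propagate as `NA`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same length and names as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = method)
}

# ---- attention aggregation and driver enrichment -------------------------

#' Aggregate attention weights across a cohort
#'
#' For each alteration gene, sums (default) or averages the per-tumor
#' summed attention weight over all carrier tumors, and reports the
#' alteration frequency. With an ensemble (list of models) the per-tumor
#' weights are first averaged across models.
#'
#' @param model a trained `citrus_model` or a list of them.
#' @param cohort a `citrus_cohort`.
#' @param tumors optional subset of tumor ids.
#' @param stat `"sum"` for cumulative attention (default) or `"mean"` per
#'   carrier.
#' @return data.frame (one row per alteration gene in the cohort panel):
#'   `gene`, `attention` (cumulative or mean), `carriers`, `frequency`.
#' @export
aggregate_attention <- function(model, cohort, tumors = NULL,
                                stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (inherits(model, "citrus_model")) model <- list(model)
  if (is.null(tumors)) tumors <- rownames(cohort$alterations)
  long <- NULL
  for (mod in model) {
    att <- citrus_forward(mod, cohort, tumors = tumors)$attention
    if (is.null(long)) { long <- att; long$weight <- att$weight / length(model) }
    else long$weight <- long$weight + att$weight / length(model)
  }
  genes <- colnames(cohort$alterations)
  cum <- stats::setNames(numeric(length(genes)), genes)
  agg <- tapply(long$weight, long$gene, if (stat == "sum") sum else mean)
  cum[names(agg)] <- agg
  carriers <- colSums(cohort$alterations[tumors, , drop = FALSE] != 0)
  data.frame(gene = genes, attention = unname(cum),
             carriers = unname(carriers),
             frequency = unname(carriers) / length(tumors),
             stringsAsFactors = FALSE)
}

#' Driver enrichment among highly attended genes
#'
#' Splits genes into a more-attended group (`log(attention + 1) >=
#' threshold`) and a less-attended group, cross-tabulates against driver
#' membership, and computes a two-sided Fisher exact p. With `top_frequent`
#' the analysis is restricted to the top-N most frequently altered genes
#' first (the frequent-gene variant).
#'
#' @param summary attention summary from [aggregate_attention()].
#' @param driver_set character vector of known driver gene ids.
#' @param threshold cut on `log(attention + 1)` (default 2).
#' @param log_base base of the log (default natural).
#' @param top_frequent optional N: restrict to the N most frequently
#'   altered genes before splitting.
#' @return list with `table` (2x2: attention group x driver status),
#'   `p_value`, `high_genes`.
#' @export
driver_enrichment <- function(summary, driver_set, threshold = 2,
                              log_base = exp(1), top_frequent = NULL) {
  df <- summary
  if (!is.null(top_frequent))
    df <- df[order(-df$frequency), ][seq_len(min(top_frequent, nrow(df))), ]
  high <- log(df$attention + 1, base = log_base) >= threshold
  is_driver <- df$gene %in% driver_set
  tab <- matrix(c(sum(high & is_driver), sum(high & !is_driver),
                  sum(!high & is_driver), sum(!high & !is_driver)),
                2, 2, byrow = TRUE,
                dimnames = list(attention = c("high", "low"),
                                driver = c("driver", "other")))
  if (sum(high) == 0) {
    warning("no genes in the high-attention group; p = 1")
    p <- 1
  } else {
    p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  list(table = tab, p_value = p, high_genes = df$gene[high])
}

# ---- in silico knockout --------------------------------------------------

#' In silico knockout of one somatic alteration
#'
#' Deletes alteration `g` from every carrier tumor, recomputes TF
#' activities with the (optionally ensembled) model, and compares the
#' original carrier activities (the mutant group) against the knocked-out
#' corpus per TF with a two-sample t-test. With `wildtype = "cohort"`
#' (default) the wild-type group is the whole cohort after the knockout
#' (knocked-out carriers plus unchanged non-carriers); with `"carriers"` it
#' is the knocked-out carriers alone. Deleting `g` from a non-carrier
#' changes nothing by construction. P-values are FDR-adjusted across the
#' TFs of this alteration's model (BH).
#'
#' @param model trained `citrus_model` or list of models (ensemble:
#'   activities averaged).
#' @param cohort a `citrus_cohort`.
#' @param gene alteration gene id to knock out (must be carried by at least
#'   `min_carriers` tumors).
#' @param min_carriers minimum carrier count (default 5).
#' @param wildtype wild-type group definition (see above).
#' @param var_equal use the pooled-variance (Student) form instead of the
#'   Welch default.
#' @param baseline optional precomputed tumors x TFs activity matrix for
#'   the unperturbed cohort (saves refitting the forward pass when scanning
#'   many genes).
#' @return data.frame, one row per TF: `gene`, `tf`, `t`, `p`, `fdr`,
#'   `mean_mutant`, `mean_wildtype`, `diff` (mutant minus wild type),
#'   `direction`.
#' @export
insilico_knockout <- function(model, cohort, gene, min_carriers = 5L,
                              wildtype = c("cohort", "carriers"),
                              var_equal = FALSE, baseline = NULL) {
  wildtype <- match.arg(wildtype)
  if (!gene %in% colnames(cohort$alterations))
    stop("alteration not present in the cohort: ", gene)
  carriers <- rownames(cohort$alterations)[cohort$alterations[, gene] != 0]
  if (length(carriers) < min_carriers)
    stop(gene, " carried by ", length(carriers), " tumors (< min_carriers = ",
         min_carriers, ")")
  if (is.null(baseline)) baseline <- infer_tf_activities(model, cohort)
  ko_carriers <- infer_tf_activities(model, cohort, tumors = carriers,
                                     drop_gene = gene)
  mut <- baseline[carriers, , drop = FALSE]
  wt <- if (wildtype == "carriers") ko_carriers
        else rbind(ko_carriers,
                   baseline[setdiff(rownames(baseline), carriers), , drop = FALSE])
  tfs <- colnames(baseline)
  res <- lapply(tfs, function(tf) {
    x <- mut[, tf]; y <- wt[, tf]
    tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt))
      data.frame(gene = gene, tf = tf, t = 0, p = 1,
                 mean_mutant = mean(x), mean_wildtype = mean(y),
                 stringsAsFactors = FALSE)
    else
      data.frame(gene = gene, tf = tf, t = unname(tt$statistic), p = tt$p.value,
                 mean_mutant = mean(x), mean_wildtype = mean(y),
                 stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$diff <- res$mean_mutant - res$mean_wildtype
  res$direction <- ifelse(res$diff >= 0, 1L, -1L)
  res$fdr <- adjust_pvalues(res$p, "BH")
  res[, c("gene", "tf", "t", "p", "fdr", "mean_mutant", "mean_wildtype",
          "diff", "direction")]
}

#' Knockout scan over all sufficiently frequent alterations
#'
#' Runs [insilico_knockout()] for every alteration gene carried by at least
#' `min_carriers` tumors. FDR is adjusted per alteration across TFs
#' (default, each alteration's model is its own family of tests) or
#' globally over the pooled scan.
#'
#' @inheritParams insilico_knockout
#' @param genes optional subset of alteration genes (default: all frequent
#'   enough).
#' @param fdr_scope `"per_alteration"` (default) or `"global"`.
#' @return combined data.frame of [insilico_knockout()] rows.
#' @export
knockout_scan <- function(model, cohort, genes = NULL, min_carriers = 5L,
                          wildtype = c("cohort", "carriers"),
                          var_equal = FALSE,
                          fdr_scope = c("per_alteration", "global")) {
  wildtype <- match.arg(wildtype); fdr_scope <- match.arg(fdr_scope)
  counts <- colSums(cohort$alterations != 0)
  if (is.null(genes)) genes <- colnames(cohort$alterations)[counts >= min_carriers]
  baseline <- infer_tf_activities(model, cohort)
  out <- do.call(rbind, lapply(genes, function(g)
    insilico_knockout(model, cohort, g, min_carriers = min_carriers,
                      wildtype = wildtype, var_equal = var_equal,
                      baseline = baseline)))
  if (fdr_scope == "global") out$fdr <- adjust_pvalues(out$p, "BH")
  rownames(out) <- NULL
  out
}

# ---- TF / tumor-type association ----------------------------------------

#' TF activity association with tumor type (one-vs-rest t-tests)
#'
#' For each cancer type with at least `min_samples` tumors, each TF's
#' inferred activity in that type is compared against all other types with
#' a two-sample t-test; p-values are BH-adjusted within each type's TF
#' family, and the direction is the sign of the mean difference.
#'
#' @param activities tumors x TFs matrix (e.g. an ensemble average).
#' @param cancer_type per-tumor labels aligned with the rows.
#' @param min_samples types with fewer tumors are skipped with a warning.
#' @param var_equal pooled-variance form instead of Welch.
#' @return data.frame: `cancer_type`, `tf`, `t`, `p`, `fdr`, `mean_in`,
#'   `mean_out`, `diff`, `direction`.
#' @export
tf_tumortype_association <- function(activities, cancer_type,
                                     min_samples = 3L, var_equal = FALSE) {
  cancer_type <- as.character(cancer_type)
  stopifnot(length(cancer_type) == nrow(activities))
  types <- sort(unique(cancer_type))
  if (length(types) < 2) stop("at least 2 cancer types required")
  small <- types[table(cancer_type)[types] < min_samples]
  if (length(small)) {
    warning("type(s) with fewer than ", min_samples, " tumors skipped: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  out <- list()
  for (ty in types) {
    inn <- activities[cancer_type == ty, , drop = FALSE]
    outg <- activities[cancer_type != ty, , drop = FALSE]
    rows <- lapply(colnames(activities), function(tf) {
      tt <- tryCatch(stats::t.test(inn[, tf], outg[, tf], var.equal = var_equal),
                     error = function(e) NULL)
      data.frame(cancer_type = ty, tf = tf,
                 t = if (is.null(tt)) 0 else unname(tt$statistic),
                 p = if (is.null(tt)) 1 else tt$p.value,
                 mean_in = mean(inn[, tf]), mean_out = mean(outg[, tf]),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$fdr <- adjust_pvalues(rows$p, "BH")
    out[[ty]] <- rows
  }
  out <- do.call(rbind, out)
  out$diff <- out$mean_in - out$mean_out
  out$direction <- ifelse(out$diff >= 0, 1L, -1L)
  rownames(out) <- NULL
  out
}

# ---- subtype clustering and association scores --------------------------

#' k-means subtypes of TF activity, ordered by hierarchical clustering
#'
#' Clusters the tumors of one cancer type by their inferred TF activities
#' (k-means, `n_init` restarts, fixed seed); the resulting subtype mean
#' activities and the TFs are then ordered by hierarchical clustering
#' (Euclidean distance, average linkage) for display.
#'
#' @param activities tumors x TFs matrix (one cancer type).
#' @param k number of subtypes (>= 1; must not exceed the tumor count).
#' @param n_init number of k-means restarts.
#' @param seed integer seed.
#' @return list with `labels` (named subtype per tumor), `means` (k x TFs
#'   mean activity), `subtype_order`, `tf_order`.
#' @export
subtype_clustering <- function(activities, k, n_init = 20L, seed = 1L) {
  if (k > nrow(activities)) stop("k exceeds the number of tumors")
  set.seed(seed)
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, nrow(activities)), rownames(activities))
    means <- matrix(colMeans(activities), 1,
                    dimnames = list("1", colnames(activities)))
    return(list(labels = labels, means = means, subtype_order = 1L,
                tf_order = seq_len(ncol(activities))))
  }
  km <- stats::kmeans(activities, centers = k, nstart = n_init, iter.max = 100)
  means <- km$centers
  rownames(means) <- seq_len(k)
  subtype_order <- stats::hclust(stats::dist(means), method = "average")$order
  tf_order <- stats::hclust(stats::dist(t(means)), method = "average")$order
  list(labels = stats::setNames(km$cluster, rownames(activities)),
       means = means, subtype_order = subtype_order, tf_order = tf_order)
}

#' Mean silhouette scan to suggest k
#'
#' @param activities tumors x TFs matrix.
#' @param ks candidate subtype counts.
#' @param n_init,seed passed to [subtype_clustering()].
#' @return data.frame `k`, `mean_silhouette`; the maximum suggests k.
#' @export
silhouette_scan <- function(activities, ks = 2:6, n_init = 20L, seed = 1L) {
  D <- as.matrix(stats::dist(activities))
  res <- vapply(ks, function(k) {
    lab <- subtype_clustering(activities, k, n_init = n_init, seed = seed)$labels
    s <- vapply(seq_along(lab), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(D[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(D[i, lab == l]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}

#' Association scores between alterations and subtypes
#'
#' For every (alteration, subtype) pair, carriers inside the subtype are
#' compared against carriers elsewhere with a two-sided Fisher exact test;
#' p-values are BH-adjusted across subtypes within each alteration, and the
#' association score is `direction * -log10(FDR)` with direction +1 when
#' the within-subtype carrier frequency exceeds the outside frequency and
#' -1 otherwise.
#'
#' @param alterations binary tumors x genes matrix.
#' @param subtypes named subtype labels (names = tumor ids, at least 2
#'   distinct values).
#' @return data.frame: `gene`, `subtype`, `p`, `fdr`, `freq_in`,
#'   `freq_out`, `direction`, `score`. Alterations with no carriers among
#'   the labelled tumors are skipped.
#' @export
alteration_subtype_association <- function(alterations, subtypes) {
  ids <- names(subtypes)
  if (is.null(ids)) stop("subtypes must be named by tumor id")
  if (length(unique(subtypes)) < 2) stop("at least 2 subtypes required")
  alt <- alterations[ids, , drop = FALSE]
  genes <- colnames(alt)[colSums(alt != 0) > 0]
  subs <- sort(unique(as.character(subtypes)))
  out <- list()
  for (g in genes) {
    carrier <- alt[, g] != 0
    rows <- lapply(subs, function(s) {
      inn <- subtypes == s
      a <- sum(carrier & inn); b <- sum(carrier & !inn)
      cc <- sum(!carrier & inn); dd <- sum(!carrier & !inn)
      fi <- a / sum(inn); fo <- b / sum(!inn)
      data.frame(gene = g, subtype = s,
                 p = fisher_exact_p(a, cc, b, dd),
                 freq_in = fi, freq_out = fo,
                 direction = ifelse(fi > fo, 1L, -1L),
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$fdr <- adjust_pvalues(rows$p, "BH")
    rows$score <- rows$direction * -log10(rows$fdr)
    out[[g]] <- rows
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("gene", "subtype", "p", "fdr", "freq_in", "freq_out",
          "direction", "score")]
}
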