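# ---- cohort simulation --------------------------------------------------

#' Simulation configuration for synthetic cohorts
#'
#' Defines a desk-scale cohort with known ground truth. Background
#' alteration rates are drawn per gene from a long-tailed lognormal
#' (mutation and copy-number frequencies in real cohorts are long-tailed),
#' so that the pre-processing frequency filter (`min_alteration_freq`,
#' emulating the 4% rule) retains a realistic fraction of non-driver genes.
#' Driver genes get per-cancer-type carrier frequencies drawn from
#' `driver_frequency`, and each driver shifts `n_targets_per_driver` TF
#' activities by `effect_size` (random sign) in its carriers.
#'
#' @param n_tumors,n_genes,n_alteration_genes,n_tfs,n_cancer_types,n_drivers
#'   cohort dimensions.
#' @param driver_frequency length-2 range of per-type driver carrier
#'   frequencies.
#' @param background_density median per-gene background alteration rate.
#' @param background_dispersion lognormal sdlog of per-gene rates.
#' @param min_alteration_freq frequency filter applied to the realized
#'   cohort-wide alteration frequency (genes below it are dropped).
#' @param prior_density density of the binary TF-target prior.
#' @param n_targets_per_driver TFs affected by each driver.
#' @param effect_size driver-to-TF shift on the pre-activation scale.
#' @param type_offset_sd sd of per-(type, TF) activity offsets.
#' @param decoder_weight_range range of the non-negative true decoder
#'   weights on masked-in entries.
#' @param gene_baseline_sd sd of per-gene expression baselines.
#' @param noise_sd sd of the additive Gaussian expression noise.
#' @param misspecify add a nonlinear gene-gene interaction term to the
#'   expression readout to probe robustness outside the model class.
#' @param seed integer; fixes all randomness.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 600L, n_genes = 400L,
                       n_alteration_genes = 200L, n_tfs = 30L,
                       n_cancer_types = 6L, n_drivers = 6L,
                       driver_frequency = c(0.1, 0.4),
                       background_density = 0.03,
                       background_dispersion = 1.0,
                       min_alteration_freq = 0.04,
                       prior_density = 0.15,
                       n_targets_per_driver = 3L,
                       effect_size = 1.5,
                       type_offset_sd = 0.7,
                       decoder_weight_range = c(0.2, 1.0),
                       gene_baseline_sd = 1.0,
                       noise_sd = 0.5,
                       misspecify = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_tumors >= 1, cfg$n_genes >= 1, cfg$n_tfs >= 1,
            cfg$n_cancer_types >= 1, cfg$n_drivers >= 0,
            cfg$prior_density > 0, cfg$prior_density < 1,
            cfg$background_density > 0, cfg$background_density < 1,
            cfg$noise_sd >= 0, cfg$effect_size >= 0)
  if (cfg$n_drivers > cfg$n_alteration_genes)
    stop("infeasible config: more drivers than alteration genes")
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic tumor cohort with known ground truth
#'
#' The generative process mirrors the model class: per-tumor true TF
#' activity is `tanh(mu[type, ] + sum of carried driver effects)`, and
#' expression is a non-negative, prior-masked linear readout of the
#' activities plus a per-gene baseline and Gaussian noise. Alterations are
#' binary; background carriers are i.i.d. Bernoulli with long-tailed
#' per-gene rates, drivers have per-type frequencies in the configured
#' range. Genes below the cohort-wide `min_alteration_freq` are removed
#' from the alteration panel, emulating the pre-processing frequency
#' filter.
#'
#' @param cfg a [sim_config()].
#' @return a `citrus_cohort`: list with `alterations` (tumors x surviving
#'   alteration genes, binary), `expression` (tumors x genes), `cancer_type`
#'   (factor), `prior` (genes x TFs binary), and `ground_truth` (driver ids,
#'   driver effect map, true activities, true decoder, type offsets, clean
#'   expression).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_tumors
  tumor_ids <- sprintf("T%04d", seq_len(n))
  types <- sprintf("CT%d", seq_len(cfg$n_cancer_types))
  cancer_type <- factor(sample(types, n, replace = TRUE), levels = types)
  alt_genes <- sprintf("AG%03d", seq_len(cfg$n_alteration_genes))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))

  drivers <- if (cfg$n_drivers > 0) sort(sample(alt_genes, cfg$n_drivers)) else character(0)

  # alteration matrix: long-tailed background rates, per-type driver rates
  rate <- stats::rlnorm(cfg$n_alteration_genes,
                        meanlog = log(cfg$background_density),
                        sdlog = cfg$background_dispersion)
  rate <- pmin(rate, 0.95)
  alt <- matrix(stats::rbinom(n * cfg$n_alteration_genes, 1L,
                              rep(rate, each = n)),
                n, cfg$n_alteration_genes,
                dimnames = list(tumor_ids, alt_genes))
  driver_freq <- matrix(stats::runif(cfg$n_drivers * cfg$n_cancer_types,
                                     cfg$driver_frequency[1], cfg$driver_frequency[2]),
                        cfg$n_drivers, cfg$n_cancer_types,
                        dimnames = list(drivers, types))
  for (d in drivers) {
    pr <- driver_freq[d, as.integer(cancer_type)]
    alt[, d] <- stats::rbinom(n, 1L, pr)
  }

  # ground-truth regulatory layer
  prior <- matrix(stats::rbinom(cfg$n_genes * cfg$n_tfs, 1L, cfg$prior_density),
                  cfg$n_genes, cfg$n_tfs, dimnames = list(genes, tfs))
  effects <- matrix(0, cfg$n_drivers, cfg$n_tfs, dimnames = list(drivers, tfs))
  for (d in seq_len(cfg$n_drivers)) {
    tgt <- sample(cfg$n_tfs, cfg$n_targets_per_driver)
    effects[d, tgt] <- cfg$effect_size * sample(c(-1, 1), cfg$n_targets_per_driver,
                                                replace = TRUE)
  }
  mu <- matrix(stats::rnorm(cfg$n_cancer_types * cfg$n_tfs, sd = cfg$type_offset_sd),
               cfg$n_cancer_types, cfg$n_tfs, dimnames = list(types, tfs))

  z <- mu[as.integer(cancer_type), , drop = FALSE]
  if (cfg$n_drivers > 0)
    z <- z + alt[, drivers, drop = FALSE] %*% effects
  activities <- tanh(z)
  dimnames(activities) <- list(tumor_ids, tfs)

  Wtrue <- matrix(stats::runif(cfg$n_genes * cfg$n_tfs,
                               cfg$decoder_weight_range[1], cfg$decoder_weight_range[2]),
                  cfg$n_genes, cfg$n_tfs) * prior
  btrue <- stats::rnorm(cfg$n_genes, sd = cfg$gene_baseline_sd)
  clean <- tcrossprod(activities, Wtrue) +
    matrix(btrue, n, cfg$n_genes, byrow = TRUE)
  if (cfg$misspecify && cfg$n_drivers >= 2) {
    # pairwise driver interaction feeding a random gene subset, outside the
    # linear-readout model class
    inter <- alt[, drivers[1]] * alt[, drivers[2]]
    hit <- sample(cfg$n_genes, max(1L, cfg$n_genes %/% 10L))
    clean[, hit] <- clean[, hit] + outer(inter, rep(cfg$effect_size / 2, length(hit)))
  }
  expr <- clean + matrix(stats::rnorm(n * cfg$n_genes, sd = cfg$noise_sd),
                         n, cfg$n_genes)
  dimnames(expr) <- dimnames(clean) <- list(tumor_ids, genes)

  # frequency filter on the realized cohort-wide alteration frequency
  freq <- colMeans(alt)
  keep <- freq >= cfg$min_alteration_freq
  alt <- alt[, keep, drop = FALSE]

  structure(list(
    alterations = alt, expression = expr, cancer_type = cancer_type,
    prior = prior,
    ground_truth = list(drivers = drivers, driver_effects = effects,
                        driver_freq = driver_freq,
                        activities = activities, W = Wtrue, b = btrue,
                        type_offsets = mu, expression_clean = clean,
                        background_rate = stats::setNames(rate, alt_genes),
                        config = cfg)),
    class = "citrus_cohort")
}

#' @export
print.citrus_cohort <- function(x, ...) {
  cat("citrus cohort:", nrow(x$alterations), "tumors,",
      ncol(x$expression), "expression genes,",
      ncol(x$alterations), "alteration genes,",
      ncol(x$prior), "TFs,", nlevels(factor(x$cancer_type)), "cancer types\n")
  invisible(x)
}

#' Assemble a cohort from matrices
#'
#' @param alterations binary tumors x genes matrix (dimnames required).
#' @param expression tumors x genes matrix, log-scale, same tumor order.
#' @param cancer_type per-tumor labels (vector or factor).
#' @param prior binary genes x TFs matrix covering `expression`'s genes.
#' @return a `citrus_cohort`.
#' @export
citrus_cohort <- function(alterations, expression, cancer_type, prior) {
  stopifnot(nrow(alterations) == nrow(expression),
            nrow(alterations) == length(cancer_type),
            identical(rownames(alterations), rownames(expression)),
            all(alterations %in% c(0, 1)), all(prior %in% c(0, 1)))
  if (!all(colnames(expression) %in% rownames(prior)))
    stop("prior is missing expression genes")
  prior <- prior[colnames(expression), , drop = FALSE]
  structure(list(alterations = alterations, expression = expression,
                 cancer_type = factor(cancer_type), prior = prior,
                 ground_truth = NULL),
            class = "citrus_cohort")
}

# ---- prior-builder input simulation -------------------------------------

#' Simulate toy inputs for the prior-construction pipeline
#'
#' Lays out `n_genes` genes far apart on synthetic chromosomes, places one
#' accessible peak inside each gene body plus intergenic decoy peaks outside
#' every assignment window, and plants motif hits so that running
#' [build_prior_pipeline()] on the outputs reproduces a target binary prior
#' exactly. The planted prior is generated with bounded pairwise Jaccard
#' overlap between TF target sets so that deduplication removes nothing,
#' unless `duplicate_tf = TRUE`, which appends a TF whose hits duplicate the
#' first TF's (forcing exactly one removal).
#'
#' @param n_genes,n_tfs panel sizes.
#' @param density density of the planted prior.
#' @param flank assignment window flank in bp.
#' @param n_decoys intergenic decoy peaks carrying random motif hits.
#' @param duplicate_tf append a duplicated TF to exercise deduplication.
#' @param seed integer seed.
#' @return list with `peaks` (data.frame: chrom, start, end, peak_id),
#'   `hits` (FIMO-style data.frame), `genes` (annotation data.frame),
#'   `presence` (TF x tumor-type matrix), and `planted_prior`.
#' @export
simulate_prior_inputs <- function(n_genes = 12L, n_tfs = 5L, density = 0.35,
                                  flank = 1e5, n_decoys = 4L,
                                  duplicate_tf = FALSE, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  tfs <- sprintf("TF%02d", seq_len(n_tfs))

  # plant a prior whose TF target sets have pairwise Jaccard <= 0.5
  repeat {
    C <- matrix(stats::rbinom(n_genes * n_tfs, 1L, density), n_genes, n_tfs,
                dimnames = list(genes, tfs))
    if (any(colSums(C) == 0)) next
    ok <- TRUE
    for (a in seq_len(n_tfs - 1)) for (b in seq(a + 1, n_tfs)) {
      j <- sum(C[, a] & C[, b]) / max(1, sum(C[, a] | C[, b]))
      if (j > 0.5) ok <- FALSE
    }
    if (ok) break
  }

  # genome layout: one gene per 2*flank + gene length + spacer
  gene_len <- 20000L
  spacer <- as.integer(2 * flank + 50000L)
  per_chrom <- ceiling(n_genes / 2)
  ann <- data.frame(gene_id = genes,
                    chrom = rep(c("chr1", "chr2"), each = per_chrom)[seq_len(n_genes)],
                    stringsAsFactors = FALSE)
  pos_in_chrom <- stats::ave(seq_len(n_genes), ann$chrom, FUN = seq_along)
  start <- (pos_in_chrom - 1L) * (gene_len + spacer) + flank + 1000L
  strand <- rep(c("+", "-"), length.out = n_genes)
  ann$tss <- ifelse(strand == "+", start, start + gene_len)
  ann$three_prime_end <- ifelse(strand == "+", start + gene_len, start)
  ann$strand <- strand

  # one peak centered in each gene body
  peaks <- data.frame(chrom = ann$chrom,
                      start = as.integer(start + gene_len / 2 - 250L),
                      end = as.integer(start + gene_len / 2 + 250L),
                      peak_id = sprintf("peak_%s", genes),
                      stringsAsFactors = FALSE)
  # decoys in gene deserts at the far end of chr2
  far <- (per_chrom + 1L) * (gene_len + spacer) + 10 * flank
  if (n_decoys > 0) {
    decoys <- data.frame(chrom = "chr2",
                         start = as.integer(far + seq_len(n_decoys) * (2 * flank + 1e5)),
                         end = as.integer(far + seq_len(n_decoys) * (2 * flank + 1e5) + 500L),
                         peak_id = sprintf("decoy_%02d", seq_len(n_decoys)),
                         stringsAsFactors = FALSE)
    peaks <- rbind(peaks, decoys)
  }

  hit_rows <- which(C == 1, arr.ind = TRUE)
  hits <- data.frame(motif_id = tfs[hit_rows[, 2]],
                     peak_id = sprintf("peak_%s", genes[hit_rows[, 1]]),
                     score = round(stats::runif(nrow(hit_rows), 5, 15), 3),
                     p_value = 10^stats::runif(nrow(hit_rows), -9, -5.2),
                     stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    dhits <- data.frame(motif_id = sample(tfs, n_decoys, replace = TRUE),
                        peak_id = sprintf("decoy_%02d", seq_len(n_decoys)),
                        score = round(stats::runif(n_decoys, 5, 15), 3),
                        p_value = 10^stats::runif(n_decoys, -9, -5.2),
                        stringsAsFactors = FALSE)
    hits <- rbind(hits, dhits)
  }
  if (duplicate_tf) {
    extra <- sprintf("TF%02d", n_tfs + 1L)
    dup <- hits[hits$motif_id == tfs[1], ]
    dup$motif_id <- extra
    hits <- rbind(hits, dup)
    tfs <- c(tfs, extra)
  }

  presence <- matrix(stats::runif(length(tfs) * 3, 0.6, 0.95), length(tfs), 3,
                     dimnames = list(tfs, c("CT1", "CT2", "CT3")))

  list(peaks = peaks, hits = hits, genes = ann, presence = presence,
       planted_prior = C)
}
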