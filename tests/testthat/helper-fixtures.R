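# Shared fixtures, built once per test run and memoized. Sizes are kept
# small so the whole unit suite stays fast; the acceptance suite builds the
# full-scale study cohorts itself.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_cohort <- function() memo("small_cohort", function()
  simulate_cohort(sim_config(
    n_tumors = 180, n_genes = 80, n_alteration_genes = 60, n_tfs = 8,
    n_cancer_types = 3, n_drivers = 2, noise_sd = 0.3, seed = 5)))

small_config <- function(...) citrus_config(
  embedding_dim = 24, attention_size = 12, attention_heads = 4,
  batch_size = 60, warmup_eval_steps = 5, patience = 8,
  max_iterations = 60, seed = 5, ...)

small_fit <- function() memo("small_fit", function()
  citrus_train(small_cohort(), small_config()))

# a random untrained model over an ad-hoc vocabulary, for forward-pass tests
random_model <- function(n_genes = 12, n_tfs = 5, n_alt = 20, n_types = 3,
                         M = 8, A = 6, h = 3, seed = 1, density = 0.5) {
  set.seed(seed)
  prior <- matrix(rbinom(n_genes * n_tfs, 1, density), n_genes, n_tfs,
                  dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                  sprintf("tf%02d", seq_len(n_tfs))))
  cfg <- citrus_config(embedding_dim = M, attention_size = A,
                       attention_heads = h, dropout = 0)
  m <- citrus_model(prior, sprintf("ag%02d", seq_len(n_alt)),
                    sprintf("ct%d", seq_len(n_types)), cfg, seed = seed)
  # break the near-zero initialization so outputs are generic
  m$params$W <- m$params$W + 0.5 * prior
  m$params$bf <- rnorm(n_tfs, sd = 0.3)
  m$params$br <- rnorm(n_genes, sd = 0.3)
  m
}

# wrap a bare alteration matrix into a cohort compatible with `model`
cohort_for_model <- function(model, alt, types, expr = NULL) {
  n <- nrow(alt)
  genes <- model$vocab$genes
  if (is.null(expr)) {
    expr <- matrix(rnorm(n * length(genes)), n, length(genes),
                   dimnames = list(rownames(alt), genes))
  }
  structure(list(alterations = alt, expression = expr,
                 cancer_type = factor(types), prior = model$mask,
                 ground_truth = NULL),
            class = "citrus_cohort")
}

random_profiles_matrix <- function(model, n, min_m = 0, max_m = 8, seed = 1) {
  set.seed(seed)
  alt_genes <- model$vocab$alt_genes
  alt <- matrix(0L, n, length(alt_genes),
                dimnames = list(sprintf("s%04d", seq_len(n)), alt_genes))
  for (i in seq_len(n)) {
    m <- sample(min_m:max_m, 1)
    if (m > 0) alt[i, sample(length(alt_genes), m)] <- 1L
  }
  alt
}
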