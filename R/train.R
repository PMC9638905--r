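# ---- data splitting -----------------------------------------------------

#' Stratified train/test split
#'
#' Holds out `test_fraction` of tumors, preserving the per-cancer-type
#' proportions: the total test size is `round(test_fraction * n)` and is
#' apportioned across types by largest-remainder rounding of
#' `test_fraction * n_type` (ties broken toward the larger type, then by
#' label). Deterministic given `seed`.
#'
#' @param labels cancer type per tumor: a named character vector or factor
#'   (names = tumor ids).
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by tumor id")
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 5))
    warning("cancer type(s) with fewer than 5 samples: ",
            paste(names(tab)[tab < 5], collapse = ", "))
  ideal <- test_fraction * as.numeric(tab)
  base <- floor(ideal)
  total <- round(test_fraction * length(labels))
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(ideal - base, as.numeric(tab), names(tab),
                 decreasing = c(TRUE, TRUE, FALSE), method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  set.seed(seed)
  test <- character(0)
  for (k in seq_along(tab)) {
    pool <- ids[labels == names(tab)[k]]
    n_take <- base[k]
    if (n_take > 0) test <- c(test, sample(pool, n_take))
  }
  list(train = setdiff(ids, test), test = test)
}

#' Stratified k-fold assignment
#'
#' @param labels named cancer-type vector (names = tumor ids).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return named integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  ids <- names(labels)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    warning("cancer type(s) with fewer than k samples are pooled across folds: ",
            paste(names(tab)[tab < k], collapse = ", "))
  set.seed(seed)
  fold <- integer(length(ids)); names(fold) <- ids
  for (ty in names(tab)) {
    pool <- sample(ids[labels == ty])
    fold[pool] <- rep_len(sample(k), length(pool))
  }
  fold
}

#' Split a cohort into train / validation / test tumor ids
#'
#' First holds out `test_fraction` of tumors (stratified by cancer type),
#' then carves `val_fraction` of the remainder as a validation set with the
#' same stratification.
#'
#' @param cohort a `citrus_cohort`.
#' @param test_fraction,val_fraction fractions in (0, 1).
#' @param seed integer seed.
#' @return list of character vectors `train`, `val`, `test`.
#' @export
citrus_split <- function(cohort, test_fraction = 0.2, val_fraction = 0.2,
                         seed = 1L) {
  labels <- stats::setNames(as.character(cohort$cancer_type),
                            rownames(cohort$alterations))
  s1 <- stratified_split(labels, test_fraction, seed)
  s2 <- stratified_split(labels[s1$train], val_fraction, seed + 1L)
  list(train = s2$train, val = s2$test, test = s1$test)
}

# ---- expression normalization ------------------------------------------

#' Per-gene z-score normalization fit on the training split
#'
#' Gene-wise mean and standard deviation are estimated on the training
#' tumors only and applied unchanged to any other split. Constant genes
#' (sd = 0) are centered only (sd treated as 1).
#'
#' @param Y_train tumors x genes matrix (training split), log-scale.
#' @param Y_other optional matrix with the same gene columns
#'   (validation/test), normalized with the training statistics.
#' @return list with `train`, `other` (or NULL), `center`, `scale`.
#' @export
normalize_expression <- function(Y_train, Y_other = NULL) {
  if (anyNA(Y_train) || (!is.null(Y_other) && anyNA(Y_other)))
    stop("NA/NaN in expression input")
  center <- colMeans(Y_train)
  scale <- apply(Y_train, 2, stats::sd)
  scale[scale == 0] <- 1
  norm <- function(Y) sweep(sweep(Y, 2, center), 2, scale, "/")
  list(train = norm(Y_train),
       other = if (is.null(Y_other)) NULL else norm(Y_other),
       center = center, scale = scale)
}

# ---- early stopping -----------------------------------------------------

#' Early-stopping rule replay
#'
#' Given a sequence of validation losses (one per evaluation), returns the
#' evaluation at which training stops: the first evaluation `e` past the
#' warm-up (`e > warmup`) with no improvement over the running best for
#' `patience` consecutive evaluations (`e - best >= patience`). The best
#' evaluation is tracked from the start, including the warm-up.
#'
#' @param val_losses numeric vector of validation losses per evaluation.
#' @param patience number of evaluations without improvement tolerated.
#' @param warmup evaluations during which stopping is disabled.
#' @return list with `stop_at` (evaluation index, or `NA` if the sequence
#'   ends first) and `best` (index of the lowest loss seen before stopping).
#' @export
early_stop_index <- function(val_losses, patience, warmup = 0L) {
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) best <- e
    if (e > warmup && (e - best) >= patience)
      return(list(stop_at = e, best = best))
  }
  list(stop_at = NA_integer_, best = best)
}

# ---- Adam optimizer -----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# L2 weight decay is added to the gradient (the coupled form used by the
# reference optimizer); biases are exempt, and masked decoder entries have
# zero weight, zero gradient and zero moments, so decay never touches them.
adam_step <- function(params, grads, state, lr, wd,
                      decay_on = c("E", "S", "W0", "Theta", "Wf", "W"),
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (wd > 0 && nm %in% decay_on) g <- g + wd * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- training loop ------------------------------------------------------

eval_mse <- function(params, cfg, profiles, type_idx, Yn, rows) {
  slots <- build_slots(profiles[rows])
  out <- forward_batch(params, cfg, slots, type_idx[rows], training = FALSE)
  mse_loss(Yn[rows, , drop = FALSE], out$Yhat)
}

#' Train a CITRUS model
#'
#' Minimizes the mean squared error between predicted and (per-gene
#' z-scored) measured expression with Adam, evaluating validation loss every
#' `eval_every` epochs. Early stopping fires `patience` evaluations after
#' the best validation point, never within the first `warmup_eval_steps`
#' evaluations; the best-validation parameters are restored at the end.
#' After every optimizer step the decoder is projected onto its constraint
#' set (`W <- pmax(W, 0) * C`), so masked-out entries are exactly zero and
#' all decoder weights non-negative at all times.
#'
#' @param cohort a `citrus_cohort` carrying alterations, expression, cancer
#'   types and the prior.
#' @param config a [citrus_config()].
#' @param split list with `train` and `val` tumor ids (e.g. from
#'   [citrus_split()]); its `test` component, if present, is not touched.
#' @param init_seed seed for parameter initialization and the training RNG
#'   stream (dropout, shuffling); defaults to `config$seed`. Ensemble runs
#'   vary this seed while sharing the split.
#' @param gene_embedding optional pre-trained embedding matrix/TSV passed to
#'   [citrus_model()].
#' @param verbose print progress every 25 evaluations.
#' @return object of class `citrus_fit`: list with `model` (best
#'   parameters, normalization statistics attached), `log` (data.frame:
#'   eval, epoch, step, train_mse, val_mse), `best_eval`, `n_evals`,
#'   `stopped_early`, `split`.
#' @export
citrus_train <- function(cohort, config = citrus_config(),
                         split = citrus_split(cohort, seed = config$seed),
                         init_seed = config$seed, gene_embedding = NULL,
                         verbose = FALSE) {
  ids <- rownames(cohort$alterations)
  train_rows <- match(split$train, ids)
  val_rows <- match(split$val, ids)
  if (anyNA(train_rows) || anyNA(val_rows)) stop("split ids not found in cohort")
  if (length(intersect(split$train, split$val))) stop("train/val overlap")

  nrm <- normalize_expression(cohort$expression[train_rows, , drop = FALSE])
  Yn <- sweep(sweep(cohort$expression, 2, nrm$center), 2, nrm$scale, "/")

  model <- citrus_model(cohort$prior, colnames(cohort$alterations),
                        levels(factor(cohort$cancer_type)), config,
                        seed = init_seed, gene_embedding = gene_embedding)
  model$norm <- list(center = nrm$center, scale = nrm$scale)
  type_idx <- match(as.character(cohort$cancer_type), model$vocab$cancer_types)
  profiles <- profiles_from_matrix(cohort$alterations, model)

  params <- model$params
  maskC <- model$mask
  state <- adam_init(params)
  set.seed(init_seed)

  log_rows <- list()
  best_val <- Inf; best_eval <- 0L; best_params <- params
  n_evals <- 0L; step <- 0L; stopped <- FALSE

  for (epoch in seq_len(config$max_iterations)) {
    perm <- sample(train_rows)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    tr_losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      slots <- build_slots(profiles[rows])
      cache <- forward_batch(params, config, slots, type_idx[rows], training = TRUE)
      Yb <- Yn[rows, , drop = FALSE]
      tr_losses[bi] <- mse_loss(Yb, cache$Yhat)
      grads <- backward_batch(params, config, cache, Yb)
      grads$W <- grads$W * maskC
      upd <- adam_step(params, grads, state, config$learning_rate, config$weight_decay)
      params <- upd$params; state <- upd$state
      params$W <- pmax(params$W, 0) * maskC
      step <- step + 1L
    }
    if (epoch %% config$eval_every == 0L) {
      n_evals <- n_evals + 1L
      val <- eval_mse(params, config, profiles, type_idx, Yn, val_rows)
      if (!is.finite(val))
        stop("training diverged: validation loss is not finite at epoch ", epoch)
      log_rows[[n_evals]] <- data.frame(eval = n_evals, epoch = epoch, step = step,
                                        train_mse = mean(tr_losses), val_mse = val)
      if (val < best_val) {
        best_val <- val; best_eval <- n_evals; best_params <- params
      }
      if (verbose && n_evals %% 25L == 0L)
        message(sprintf("eval %d (epoch %d): train %.4f val %.4f (best %.4f @ %d)",
                        n_evals, epoch, mean(tr_losses), val, best_val, best_eval))
      if (n_evals > config$warmup_eval_steps &&
          (n_evals - best_eval) >= config$patience) {
        stopped <- TRUE
        break
      }
    }
  }
  model$params <- best_params
  structure(list(model = model, log = do.call(rbind, log_rows),
                 best_eval = best_eval, n_evals = n_evals,
                 stopped_early = stopped, split = split, config = config),
            class = "citrus_fit")
}

#' @export
print.citrus_fit <- function(x, ...) {
  cat("CITRUS fit:", x$n_evals, "evaluations,",
      if (x$stopped_early) "early-stopped," else "ran to max iterations,",
      "best validation MSE",
      format(x$log$val_mse[x$best_eval], digits = 4),
      "at evaluation", x$best_eval, "\n")
  invisible(x)
}

# ---- cross-validation ---------------------------------------------------

#' Stratified k-fold cross-validation over hyperparameter settings
#'
#' Each candidate configuration is trained on k-1 folds of the training
#' pool, using the held fold as the validation set (for both early stopping
#' and the selection metric); the setting with the lowest mean validation
#' MSE is selected.
#'
#' @param cohort a `citrus_cohort`.
#' @param configs list of [citrus_config()] objects (or lists of overrides).
#' @param pool character vector of tumor ids to cross-validate within
#'   (typically the non-test 80%); defaults to all tumors.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @return list with `results` (data.frame: setting, fold, val_mse),
#'   `summary` (mean/sd per setting), `best` (index of the selected
#'   setting) and `best_config`.
#' @export
citrus_cv <- function(cohort, configs, pool = NULL, k = 5L, seed = 1L) {
  if (is.null(pool)) pool <- rownames(cohort$alterations)
  configs <- lapply(configs, function(cf)
    if (inherits(cf, "citrus_config")) cf else do.call(citrus_config, cf))
  labels <- stats::setNames(
    as.character(cohort$cancer_type[match(pool, rownames(cohort$alterations))]), pool)
  fold <- stratified_folds(labels, k, seed)
  res <- list()
  for (si in seq_along(configs)) {
    for (f in seq_len(k)) {
      spl <- list(train = pool[fold != f], val = pool[fold == f])
      fit <- citrus_train(cohort, configs[[si]], split = spl)
      res[[length(res) + 1L]] <- data.frame(
        setting = si, fold = f, val_mse = fit$log$val_mse[fit$best_eval])
    }
  }
  res <- do.call(rbind, res)
  agg <- stats::aggregate(val_mse ~ setting, data = res,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  means <- agg$val_mse[, "mean"]
  best <- which.min(means)
  list(results = res,
       summary = data.frame(setting = agg$setting, mean_val_mse = means,
                            sd_val_mse = agg$val_mse[, "sd"]),
       best = best, best_config = configs[[best]])
}

# ---- ensembling ---------------------------------------------------------

#' Train an ensemble of models differing only in initialization
#'
#' Runs [citrus_train()] `n_runs` times with the same split and data but
#' different initialization/dropout seeds, and averages the inferred TF
#' activity matrices.
#'
#' @inheritParams citrus_train
#' @param n_runs number of runs (10 in the reference protocol).
#' @param seeds integer seeds, one per run; defaults to
#'   `config$seed + 0:(n_runs-1)`.
#' @param tumors tumors over which activities are inferred (default: all).
#' @return list with `fits` (list of `citrus_fit`), `models`, and the
#'   [ensemble_tf_activities()] result (`activity` mean matrix, `sd`,
#'   `runs`, `n_runs`).
#' @export
citrus_ensemble <- function(cohort, config = citrus_config(),
                            split = citrus_split(cohort, seed = config$seed),
                            n_runs = 10L, seeds = NULL, tumors = NULL) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  fits <- lapply(seeds, function(s)
    citrus_train(cohort, config, split = split, init_seed = s))
  models <- lapply(fits, `[[`, "model")
  ens <- ensemble_tf_activities(models, cohort, tumors = tumors)
  c(list(fits = fits, models = models), ens)
}

#' Average TF activities across an ensemble of trained models
#'
#' @param models list of trained `citrus_model`s sharing the TF panel and
#'   tumor set.
#' @param cohort a `citrus_cohort`.
#' @param tumors optional subset of tumor ids.
#' @return list with `activity` (elementwise mean, tumors x TFs), `sd`
#'   (per-TF across-run standard deviation of the tumor-mean activity),
#'   `runs` (list of per-run matrices), `n_runs`.
#' @export
ensemble_tf_activities <- function(models, cohort, tumors = NULL) {
  if (inherits(models, "citrus_model")) models <- list(models)
  tfs <- models[[1]]$vocab$tfs
  runs <- lapply(models, function(mod) {
    if (!identical(mod$vocab$tfs, tfs)) stop("models disagree on the TF panel")
    citrus_forward(mod, cohort, tumors = tumors)$tf_activities
  })
  avg <- Reduce(`+`, runs) / length(runs)
  per_run_mean <- do.call(rbind, lapply(runs, colMeans))
  list(activity = avg,
       sd = apply(per_run_mean, 2, stats::sd),
       runs = runs, n_runs = length(runs))
}
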