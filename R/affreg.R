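# Regularized bilinear (affinity) regression baseline: D W P' ~ Y, solved
# through the Kronecker reformulation (P (x) D) vec(W) ~ vec(Y) without ever
# materializing the Kronecker product.

#' Fit the ridge-regularized bilinear system D W P' ~ Y
#'
#' Solves `min_W ||Y - D W P'||_F^2 + lambda ||W||_F^2` through the normal
#' equations in factored form: with eigendecompositions `D'D = U L U'` and
#' `P'P = V M V'`, the solution is
#' `W = U [ (U' D'Y P V) / (L_i M_j + lambda) ] V'`. Equivalent to the ridge
#' solution of the vectorized system `(P (x) D) vec(W) = vec(Y)` but never
#' forms the Kronecker product. Deterministic.
#'
#' @param Y genes (N) x tumors (M) expression matrix.
#' @param D genes (N) x TFs (Q) binary TF-attribute matrix (e.g. the
#'   TF-target prior).
#' @param P tumors (M) x alterations (S) binary attribute matrix.
#' @param lambda ridge penalty (> 0; `lambda = 0` is allowed only when the
#'   design is nonsingular, otherwise an error is raised).
#' @return W, a TFs (Q) x alterations (S) matrix of class `ar_weights`.
#' @export
ar_fit <- function(Y, D, P, lambda) {
  stopifnot(nrow(Y) == nrow(D), ncol(Y) == nrow(P), lambda >= 0)
  eD <- eigen(crossprod(D), symmetric = TRUE)
  eP <- eigen(crossprod(P), symmetric = TRUE)
  denom <- outer(eD$values, eP$values) + lambda
  if (any(denom < .Machine$double.eps * max(denom)))
    stop("singular design with lambda = 0; use a positive ridge penalty")
  Tm <- crossprod(eD$vectors, crossprod(D, Y) %*% P %*% eP$vectors)
  W <- eD$vectors %*% (Tm / denom) %*% t(eP$vectors)
  dimnames(W) <- list(colnames(D), colnames(P))
  structure(W, class = c("ar_weights", class(W)))
}

#' Predict expression from bilinear weights
#'
#' @param W TFs x alterations weight matrix from [ar_fit()].
#' @param D genes x TFs attribute matrix.
#' @param P tumors x alterations attribute matrix.
#' @return genes x tumors predicted matrix `D W P'`.
#' @export
ar_predict <- function(W, D, P) {
  D %*% W %*% t(P)
}

#' Evaluate the affinity-regression baseline per cancer type
#'
#' For each cancer type, tumors are split into train/test, the ridge
#' penalty is tuned by k-fold cross-validation on the training pool
#' (selecting the lambda with the highest mean per-tumor Spearman on the
#' held folds), the model is refit on the full training split, and the
#' held-out per-tumor Spearman between predicted and measured expression is
#' reported — the same metric as the CITRUS evaluation. Expression enters
#' the bilinear fit on its input (log) scale: the model has no per-gene
#' intercept, so gene-wise re-scaling would push the target outside the
#' bilinear family.
#'
#' @param cohort a `citrus_cohort` (`prior` is used as D, `alterations` as
#'   P, `expression` transposed as Y).
#' @param lambda_grid candidate ridge penalties.
#' @param test_fraction held-out fraction per type.
#' @param cv_k folds for the lambda tuning.
#' @param seed integer seed (splits).
#' @return list with `by_type` (data.frame: cancer_type, lambda,
#'   mean_spearman, n_test), `per_tumor` (named vector over all test
#'   tumors), `mean_spearman` (grand mean).
#' @export
ar_evaluate <- function(cohort, lambda_grid = 10^seq(-2, 4, by = 1),
                        test_fraction = 0.2, cv_k = 5L, seed = 1L) {
  types <- levels(factor(cohort$cancer_type))
  D <- cohort$prior[colnames(cohort$expression), , drop = FALSE]
  all_rho <- numeric(0)
  rows <- list()
  for (ty in types) {
    ids <- rownames(cohort$alterations)[cohort$cancer_type == ty]
    labels <- stats::setNames(rep(ty, length(ids)), ids)
    spl <- suppressWarnings(stratified_split(labels, test_fraction, seed))
    tr <- spl$train; te <- spl$test
    Ytr <- t(cohort$expression[tr, , drop = FALSE])  # genes x tumors
    Yte <- t(cohort$expression[te, , drop = FALSE])
    Ptr <- cohort$alterations[tr, , drop = FALSE]
    Pte <- cohort$alterations[te, , drop = FALSE]

    lam <- if (length(lambda_grid) == 1L) lambda_grid else {
      fold <- suppressWarnings(stratified_folds(labels[tr], cv_k, seed + 1L))
      cvmean <- vapply(lambda_grid, function(lm) {
        rho <- vapply(seq_len(cv_k), function(f) {
          itr <- tr[fold != f]; iva <- tr[fold == f]
          W <- ar_fit(Ytr[, match(itr, tr), drop = FALSE], D,
                      Ptr[match(itr, tr), , drop = FALSE], lm)
          pred <- ar_predict(W, D, Ptr[match(iva, tr), , drop = FALSE])
          mean(spearman_per_tumor(t(Ytr[, match(iva, tr), drop = FALSE]),
                                  t(pred))$per_tumor, na.rm = TRUE)
        }, numeric(1))
        mean(rho)
      }, numeric(1))
      lambda_grid[which.max(cvmean)]
    }
    W <- ar_fit(Ytr, D, Ptr, lam)
    pred <- ar_predict(W, D, Pte)
    sp <- spearman_per_tumor(t(Yte), t(pred))
    all_rho <- c(all_rho, sp$per_tumor)
    rows[[ty]] <- data.frame(cancer_type = ty, lambda = lam,
                             mean_spearman = sp$mean, n_test = length(te))
  }
  list(by_type = do.call(rbind, rows), per_tumor = all_rho,
       mean_spearman = mean(all_rho, na.rm = TRUE))
}
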