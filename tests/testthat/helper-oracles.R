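# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-implementations that share no code with the package.

# O(peaks x genes) interval-overlap assignment (0-based half-open coords)
bf_assign <- function(peaks, ann, flank) {
  out <- stats::setNames(vector("list", nrow(ann)), ann$gene_id)
  for (g in seq_len(nrow(ann))) {
    lo <- max(min(ann$tss[g], ann$three_prime_end[g]) - flank, 0)
    hi <- max(ann$tss[g], ann$three_prime_end[g]) + flank
    hit <- character(0)
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != ann$chrom[g]) next
      if (peaks$start[p] < hi && peaks$end[p] > lo)  # >=1 bp overlap
        hit <- c(hit, peaks$peak_id[p])
    }
    out[[g]] <- hit
  }
  out
}

# exhaustive per-pair max-pooling of motif scores
bf_max_scores <- function(assignment, hits) {
  motifs <- sort(unique(hits$motif_id))
  m <- matrix(0, length(assignment), length(motifs),
              dimnames = list(names(assignment), motifs))
  for (g in names(assignment)) for (mo in motifs) {
    sc <- hits$score[hits$motif_id == mo & hits$peak_id %in% assignment[[g]]]
    if (length(sc)) m[g, mo] <- max(sc)
  }
  m
}

bf_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

# replay of the deduplication rule: highest-Jaccard offending pair first
# (ties: lexicographically smallest pair), drop the member with the larger
# mean Jaccard against the other survivors (ties: lexicographically larger)
bf_dedup <- function(sets, cutoff) {
  alive <- names(sets)
  removed <- character(0)
  repeat {
    if (length(alive) < 2) break
    pairs <- t(utils::combn(sort(alive), 2))
    jv <- apply(pairs, 1, function(pr) bf_jaccard(sets[[pr[1]]], sets[[pr[2]]]))
    bad <- which(jv > cutoff)
    if (!length(bad)) break
    pick <- bad[order(-jv[bad], pairs[bad, 1], pairs[bad, 2])[1]]
    a <- pairs[pick, 1]; b <- pairs[pick, 2]
    mj <- function(x) mean(vapply(setdiff(alive, x),
                                  function(o) bf_jaccard(sets[[x]], sets[[o]]),
                                  numeric(1)))
    drop_tf <- if (mj(a) > mj(b)) a else if (mj(b) > mj(a)) b else max(a, b)
    removed <- c(removed, drop_tf)
    alive <- setdiff(alive, drop_tf)
  }
  removed
}

# two-sided Fisher exact p by direct combinatorial enumeration (lchoose),
# same relative-slack convention as the classical implementation
bf_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
}

# average ranks by counting, then the Pearson formula written out
bf_spearman <- function(x, y) {
  rk <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# BH step-up arithmetic
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# explicit Kronecker-product ridge solve of (P (x) D) vec(W) = vec(Y)
bf_kron_ridge <- function(Y, D, P, lambda) {
  A <- kronecker(P, D)
  w <- solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, as.vector(Y)))
  matrix(w, ncol(D), ncol(P))
}

# direct single-tumor evaluation of the attention/embedding formulas
bf_forward_tumor <- function(e_genes, e_type, W0, Theta, Wf, bf_, W, br) {
  m <- nrow(e_genes); h <- ncol(Theta)
  beta <- matrix(0, m, h)
  for (g in seq_len(m)) for (j in seq_len(h))
    beta[g, j] <- sum(Theta[, j] * tanh(W0 %*% e_genes[g, ]))
  ah <- apply(beta, 2, function(col) exp(col) / sum(exp(col)))
  ah <- matrix(ah, m, h)
  alpha <- rowSums(ah)
  et <- e_type
  for (g in seq_len(m)) et <- et + alpha[g] * e_genes[g, ]
  ef <- tanh(as.vector(Wf %*% et) + bf_)
  yhat <- as.vector(W %*% ef) + br
  list(beta = beta, per_head = ah, alpha = alpha, et = et, ef = ef, yhat = yhat)
}

# adjusted Rand index (contingency form)
bf_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
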