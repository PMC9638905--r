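# ---- low-level operations (single tumor) -------------------------------

#' Unnormalized attention logits for one tumor
#'
#' For each altered gene g and head j, the logit is
#' `theta_j' tanh(W0 e_g)`.
#'
#' @param gene_emb numeric matrix (m altered genes x embedding dim M), one
#'   row per altered gene.
#' @param W0 attention projection, attention_size x M.
#' @param Theta head parameters, attention_size x h (one column per head).
#' @return m x h matrix of logits.
#' @export
attention_logits <- function(gene_emb, W0, Theta) {
  gene_emb <- rbind(gene_emb)
  stopifnot(ncol(gene_emb) == ncol(W0), nrow(W0) == nrow(Theta))
  tanh(tcrossprod(gene_emb, W0)) %*% Theta
}

#' Normalized attention weights
#'
#' Per head, a softmax over the tumor's altered genes; the summed weight of
#' a gene is its per-head weight summed across heads, so per-head weights
#' sum to 1 and summed weights sum to the number of heads.
#'
#' @param logits m x h matrix from [attention_logits()].
#' @return list with `per_head` (m x h) and `summed` (length m).
#' @export
attention_weights <- function(logits) {
  logits <- rbind(logits)
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  per_head <- sweep(z, 2, colSums(z), "/")
  list(per_head = per_head, summed = rowSums(per_head))
}

#' Tumor embedding
#'
#' `e_t = e_s + sum_g alpha_g e_g`: the cancer-type embedding plus the
#' attention-weighted sum of altered-gene embeddings. A tumor without
#' alterations returns the cancer-type embedding alone.
#'
#' @param cancer_emb cancer-type embedding vector (length M).
#' @param gene_emb m x M matrix of altered-gene embeddings (may have 0 rows).
#' @param alpha summed (across-head) attention weights, length m.
#' @return numeric vector of length M.
#' @export
tumor_embedding <- function(cancer_emb, gene_emb, alpha) {
  if (is.null(gene_emb) || NROW(gene_emb) == 0L) return(cancer_emb)
  gene_emb <- rbind(gene_emb)
  stopifnot(nrow(gene_emb) == length(alpha), ncol(gene_emb) == length(cancer_emb))
  cancer_emb + as.vector(crossprod(gene_emb, alpha))
}

#' TF activities from a tumor embedding
#'
#' `e_f = act(W_f e_t + b_f)`, elementwise; with the default tanh the
#' activities are bounded in (-1, 1).
#'
#' @param et tumor embedding: vector of length M or matrix (tumors x M).
#' @param Wf TF-layer weights, k_TF x M.
#' @param bf TF-layer bias, length k_TF.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @return vector of length k_TF (or matrix tumors x k_TF).
#' @export
tf_activities <- function(et, Wf, bf, activation = "tanh") {
  one <- is.null(dim(et))
  et <- rbind(et)
  z <- sweep(tcrossprod(et, Wf), 2, bf, "+")
  out <- switch(activation, tanh = tanh(z), relu = pmax(z, 0),
                stop("unknown activation: ", activation))
  if (one) drop(out) else out
}

#' Predicted expression from TF activities
#'
#' `yhat = W e_f + b_r`, where the decoder weights `W` (genes x TFs) must be
#' non-negative and zero wherever the prior mask is zero. A violation of
#' either constraint is an invariant breach and raises an error.
#'
#' @param ef TF activities: vector of length k_TF or matrix (tumors x k_TF).
#' @param W decoder weights, genes x TFs.
#' @param br per-gene intercept, length genes.
#' @param mask optional binary prior matrix (genes x TFs) to validate
#'   against.
#' @return vector of length genes (or matrix tumors x genes).
#' @export
predict_expression <- function(ef, W, br, mask = NULL) {
  if (!is.null(mask)) {
    if (any(W[mask == 0] != 0)) stop("decoder mask violation: nonzero weight on a masked-out entry")
    if (min(W) < 0) stop("decoder non-negativity violation")
  }
  one <- is.null(dim(ef))
  ef <- rbind(ef)
  out <- sweep(tcrossprod(ef, W), 2, br, "+")
  if (one) drop(out) else out
}

#' Mean squared error loss
#'
#' Mean over all entries (genes, and tumors when matrices are given).
#'
#' @param y,yhat numeric vectors or matrices of equal shape.
#' @return non-negative scalar; 0 iff `y == yhat`.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length")
  if (anyNA(y) || anyNA(yhat)) stop("NaN/NA in loss inputs")
  mean((y - yhat)^2)
}

# ---- model construction -------------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Construct an untrained CITRUS model
#'
#' Parameters are initialized at random (Glorot uniform for the attention
#' and TF-layer weights; normal, sd `embedding_init_sd`, for gene and
#' cancer-type embeddings; uniform on `[0, decoder_init_eps]` for masked-in
#' decoder entries). Externally trained gene embeddings can be supplied via
#' `gene_embedding` (a matrix or TSV path with rownames/first column = gene
#' ids); rows present there override the random initialization.
#'
#' @param prior binary genes x TFs prior matrix `C` with dimnames; decoder
#'   weights are constrained to `C`'s support.
#' @param alt_genes character vector of alteration-gene ids in the model's
#'   vocabulary.
#' @param cancer_types character vector of known cancer-type labels.
#' @param config a [citrus_config()].
#' @param seed integer seed for the initialization RNG.
#' @param gene_embedding optional matrix (genes x embedding_dim) or TSV path.
#' @return object of class `citrus_model`.
#' @export
citrus_model <- function(prior, alt_genes, cancer_types,
                         config = citrus_config(), seed = config$seed,
                         gene_embedding = NULL) {
  stopifnot(is.matrix(prior), !is.null(rownames(prior)), !is.null(colnames(prior)))
  if (!all(prior %in% c(0, 1))) stop("prior entries must be 0/1")
  cancer_types <- as.character(unique(cancer_types))
  alt_genes <- as.character(alt_genes)
  if (anyDuplicated(alt_genes)) stop("duplicate alteration gene ids")
  M <- config$embedding_dim; A <- config$attention_size; h <- config$attention_heads
  K <- ncol(prior); G <- nrow(prior)
  set.seed(seed)
  params <- list(
    E  = matrix(stats::rnorm(length(alt_genes) * M, sd = config$embedding_init_sd),
                length(alt_genes), M),
    S  = matrix(stats::rnorm(length(cancer_types) * M, sd = config$embedding_init_sd),
                length(cancer_types), M),
    W0 = glorot(A, M),
    Theta = glorot(A, h),
    Wf = glorot(K, M),
    bf = numeric(K),
    W  = matrix(stats::runif(G * K, 0, config$decoder_init_eps), G, K) * prior,
    br = numeric(G)
  )
  rownames(params$E) <- alt_genes
  rownames(params$S) <- cancer_types
  if (!is.null(gene_embedding)) {
    if (is.character(gene_embedding)) {
      tab <- utils::read.delim(gene_embedding, row.names = 1, check.names = FALSE)
      gene_embedding <- as.matrix(tab)
    }
    if (ncol(gene_embedding) != M) stop("gene_embedding has wrong dimension")
    hit <- intersect(rownames(gene_embedding), alt_genes)
    params$E[hit, ] <- gene_embedding[hit, , drop = FALSE]
  }
  structure(list(params = params, mask = prior, config = config,
                 vocab = list(alt_genes = alt_genes, cancer_types = cancer_types,
                              genes = rownames(prior), tfs = colnames(prior)),
                 norm = NULL),
            class = "citrus_model")
}

# ---- batched forward / backward ----------------------------------------

# Convert a binary alteration matrix (tumors x alt genes) into canonical
# per-tumor index lists into the model's embedding rows. Profiles are sets:
# indices are sorted so that the forward pass is invariant (bitwise) to the
# order in which alterations are listed.
profiles_from_matrix <- function(alt, model, unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  map <- match(colnames(alt), model$vocab$alt_genes)
  if (anyNA(map)) {
    miss <- colnames(alt)[is.na(map)]
    if (unknown == "error")
      stop("alteration genes missing from the model vocabulary: ",
           paste(utils::head(miss, 5), collapse = ", "))
    warning(length(miss), " alteration genes not in the model vocabulary; skipped")
  }
  lapply(seq_len(nrow(alt)), function(i) {
    idx <- map[which(alt[i, ] != 0)]
    sort(idx[!is.na(idx)])
  })
}

build_slots <- function(profiles) {
  m <- lengths(profiles)
  keep <- which(m > 0L)
  genes_flat <- unlist(profiles[keep], use.names = FALSE)
  grp_id <- rep.int(seq_along(keep), m[keep])
  list(genes_flat = genes_flat, grp_id = grp_id, row_of_group = keep,
       n_tumors = length(profiles), nslots = length(genes_flat),
       idx_split = split(seq_along(genes_flat), grp_id))
}

group_max <- function(x, idx_split) {
  vapply(idx_split, function(ii) max(x[ii]), numeric(1))
}

add_row_vec <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

# One forward pass over a batch. `type_idx` indexes params$S rows. Returns
# outputs plus the cache needed by backward_batch. Dropout (training mode)
# is applied at the three sites used in training: embedded alteration slots
# after the input layer, the tumor embedding, and the TF layer.
forward_batch <- function(params, cfg, slots, type_idx, training = FALSE) {
  B <- slots$n_tumors; M <- ncol(params$E); h <- ncol(params$Theta)
  p <- if (training) cfg$dropout else 0
  ns <- slots$nslots

  X <- params$E[slots$genes_flat, , drop = FALSE]
  keep_slot <- if (p > 0 && ns > 0) stats::rbinom(ns, 1L, 1 - p) / (1 - p) else NULL
  if (!is.null(keep_slot)) X <- X * keep_slot

  if (ns > 0) {
    H <- tanh(tcrossprod(X, params$W0))              # slots x A
    L <- H %*% params$Theta                          # slots x h
    gmax <- vapply(seq_len(h), function(j) group_max(L[, j], slots$idx_split),
                   numeric(length(slots$idx_split)))
    gmax <- rbind(gmax)                              # groups x h
    EX <- exp(L - gmax[slots$grp_id, , drop = FALSE])
    den <- rowsum(EX, slots$grp_id)                  # groups x h, ordered 1..n_groups
    AH <- EX / den[slots$grp_id, , drop = FALSE]     # per-head weights per slot
    alpha <- rowSums(AH)
    WS <- rowsum(X * alpha, slots$grp_id)            # groups x M
  } else {
    H <- L <- AH <- NULL; alpha <- numeric(0); WS <- NULL
  }

  Et <- params$S[type_idx, , drop = FALSE]
  if (ns > 0) Et[slots$row_of_group, ] <- Et[slots$row_of_group, , drop = FALSE] + WS

  mask_et <- if (p > 0) matrix(stats::rbinom(B * M, 1L, 1 - p) / (1 - p), B, M) else NULL
  Et_d <- if (is.null(mask_et)) Et else Et * mask_et

  Z <- add_row_vec(tcrossprod(Et_d, params$Wf), params$bf)
  Ef <- if (cfg$activation == "tanh") tanh(Z) else pmax(Z, 0)
  K <- ncol(Ef)
  mask_ef <- if (p > 0) matrix(stats::rbinom(B * K, 1L, 1 - p) / (1 - p), B, K) else NULL
  Ef_d <- if (is.null(mask_ef)) Ef else Ef * mask_ef

  Yhat <- add_row_vec(tcrossprod(Ef_d, params$W), params$br)

  list(X = X, keep_slot = keep_slot, H = H, AH = AH, alpha = alpha,
       Et = Et, Et_d = Et_d, mask_et = mask_et, Z = Z, Ef = Ef, Ef_d = Ef_d,
       mask_ef = mask_ef, Yhat = Yhat, type_idx = type_idx, slots = slots)
}

backward_batch <- function(params, cfg, cache, Y) {
  slots <- cache$slots
  B <- slots$n_tumors; ns <- slots$nslots
  dYhat <- 2 * (cache$Yhat - Y) / length(Y)

  gW <- crossprod(dYhat, cache$Ef_d)
  gbr <- colSums(dYhat)
  dEf <- dYhat %*% params$W
  if (!is.null(cache$mask_ef)) dEf <- dEf * cache$mask_ef
  dZ <- if (cfg$activation == "tanh") dEf * (1 - cache$Ef^2) else dEf * (cache$Z > 0)
  gWf <- crossprod(dZ, cache$Et_d)
  gbf <- colSums(dZ)
  dEt <- dZ %*% params$Wf
  if (!is.null(cache$mask_et)) dEt <- dEt * cache$mask_et

  gS <- matrix(0, nrow(params$S), ncol(params$S))
  rs <- rowsum(dEt, cache$type_idx)
  gS[as.integer(rownames(rs)), ] <- rs

  gE <- matrix(0, nrow(params$E), ncol(params$E))
  gW0 <- matrix(0, nrow(params$W0), ncol(params$W0))
  gTheta <- matrix(0, nrow(params$Theta), ncol(params$Theta))

  if (ns > 0) {
    dWS <- dEt[slots$row_of_group, , drop = FALSE]       # groups x M
    dWS_slot <- dWS[slots$grp_id, , drop = FALSE]
    dalpha <- rowSums(cache$X * dWS_slot)
    dX <- cache$alpha * dWS_slot
    dAH <- matrix(dalpha, ns, ncol(cache$AH))
    sb <- rowsum(cache$AH * dAH, slots$grp_id)
    dL <- cache$AH * (dAH - sb[slots$grp_id, , drop = FALSE])
    gTheta <- crossprod(cache$H, dL)
    dH <- tcrossprod(dL, params$Theta)
    dPre <- dH * (1 - cache$H^2)
    gW0 <- crossprod(dPre, cache$X)
    dX <- dX + dPre %*% params$W0
    if (!is.null(cache$keep_slot)) dX <- dX * cache$keep_slot
    rs <- rowsum(dX, slots$genes_flat)
    gE[as.integer(rownames(rs)), ] <- rs
  }

  list(E = gE, S = gS, W0 = gW0, Theta = gTheta, Wf = gWf, bf = gbf,
       W = gW, br = gbr)
}

# ---- inference ----------------------------------------------------------

#' Run the model forward in inference mode
#'
#' Deterministic (no dropout). Profiles are treated as sets: the outputs are
#' invariant to the order in which a tumor's altered genes are listed.
#'
#' @param model a `citrus_model`.
#' @param cohort a `citrus_cohort` (see [simulate_cohort()] or
#'   [read_cohort()]).
#' @param tumors optional character/integer subset of tumors.
#' @param drop_gene optional alteration-gene id deleted from every profile
#'   before the forward pass (in silico knockout input).
#' @param unknown_genes how to treat cohort alteration genes absent from
#'   the model vocabulary: `"error"` (strict, default) or `"skip"`
#'   (lenient, drops them with one warning).
#' @return list with `tf_activities` (tumors x TFs), `predicted` (tumors x
#'   genes, on the model's training scale), `tumor_embedding`, and
#'   `attention`: a data.frame (tumor, gene, weight, per-head columns) of
#'   summed attention weights over each tumor's altered genes.
#' @export
citrus_forward <- function(model, cohort, tumors = NULL, drop_gene = NULL,
                           unknown_genes = c("error", "skip")) {
  alt <- cohort$alterations
  if (!is.null(tumors)) alt <- alt[tumors, , drop = FALSE]
  types <- as.character(cohort$cancer_type[match(rownames(alt), rownames(cohort$alterations))])
  type_idx <- match(types, model$vocab$cancer_types)
  if (anyNA(type_idx))
    stop("unknown cancer type(s): ", paste(unique(types[is.na(type_idx)]), collapse = ", "),
         "; known types: ", paste(model$vocab$cancer_types, collapse = ", "))
  profiles <- profiles_from_matrix(alt, model, unknown = match.arg(unknown_genes))
  if (!is.null(drop_gene)) {
    gi <- match(drop_gene, model$vocab$alt_genes)
    if (is.na(gi)) stop("gene not in model vocabulary: ", drop_gene)
    profiles <- lapply(profiles, function(v) v[v != gi])
  }
  if (any(lengths(profiles) > model$config$max_alterations))
    stop("a profile exceeds max_alterations (", model$config$max_alterations, ")")
  slots <- build_slots(profiles)
  out <- forward_batch(model$params, model$config, slots, type_idx, training = FALSE)
  act <- out$Ef
  dimnames(act) <- list(rownames(alt), model$vocab$tfs)
  pred <- out$Yhat
  dimnames(pred) <- list(rownames(alt), model$vocab$genes)
  attn <- data.frame(
    tumor = rownames(alt)[slots$row_of_group][slots$grp_id],
    gene = model$vocab$alt_genes[slots$genes_flat],
    weight = out$alpha, stringsAsFactors = FALSE)
  list(tf_activities = act, predicted = pred, tumor_embedding = out$Et,
       attention = attn, per_head = out$AH)
}

#' Inferred TF activities for a cohort
#'
#' Convenience wrapper around [citrus_forward()]; with a list of models (an
#' ensemble) the activities are averaged elementwise.
#'
#' @inheritParams citrus_forward
#' @param model a `citrus_model` or a list of them sharing the TF panel.
#' @return tumors x TFs matrix.
#' @export
infer_tf_activities <- function(model, cohort, tumors = NULL, drop_gene = NULL) {
  if (inherits(model, "citrus_model")) model <- list(model)
  tfs <- model[[1]]$vocab$tfs
  acts <- lapply(model, function(mod) {
    if (!identical(mod$vocab$tfs, tfs)) stop("models disagree on the TF panel")
    citrus_forward(mod, cohort, tumors = tumors, drop_gene = drop_gene)$tf_activities
  })
  Reduce(`+`, acts) / length(acts)
}

#' Predict expression for a cohort
#'
#' @param object a trained `citrus_model`.
#' @param cohort a `citrus_cohort`.
#' @param tumors optional subset of tumor ids.
#' @param denormalize if `TRUE` and the model stores per-gene normalization
#'   statistics, predictions are mapped back to the input expression scale.
#' @param ... unused.
#' @return tumors x genes matrix.
#' @export
predict.citrus_model <- function(object, cohort, tumors = NULL,
                                 denormalize = FALSE, ...) {
  pred <- citrus_forward(object, cohort, tumors = tumors)$predicted
  if (denormalize && !is.null(object$norm))
    pred <- sweep(sweep(pred, 2, object$norm$scale, "*"), 2, object$norm$center, "+")
  pred
}

#' @export
print.citrus_model <- function(x, ...) {
  cat("CITRUS model:", length(x$vocab$genes), "genes x", length(x$vocab$tfs),
      "TFs;", length(x$vocab$alt_genes), "alteration genes;",
      length(x$vocab$cancer_types), "cancer types\n")
  cat("  embedding", x$config$embedding_dim, "| attention", x$config$attention_size,
      "x", x$config$attention_heads, "heads | activation", x$config$activation, "\n")
  invisible(x)
}
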