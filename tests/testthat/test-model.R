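# Network forward pass: attention, embeddings, TF layer, masked decoder,
# loss, determinism, permutation invariance, gradient correctness.

test_that("attention logits follow theta' tanh(W0 e_g)", {
  set.seed(1)
  W0 <- matrix(rnorm(6 * 8), 6, 8)
  Theta <- matrix(rnorm(6 * 2), 6, 2)
  E <- matrix(rnorm(3 * 8), 3, 8)
  expect_equal(attention_logits(E, matrix(0, 6, 8), Theta),
               matrix(0, 3, 2))
  got <- attention_logits(E, W0, Theta)
  want <- matrix(0, 3, 2)
  for (g in 1:3) for (j in 1:2)
    want[g, j] <- sum(Theta[, j] * tanh(W0 %*% E[g, ]))
  expect_equal(got, want)
})

test_that("attention weights are per-head softmaxes with head-summed totals", {
  w <- attention_weights(matrix(1.7, 4, 1))
  expect_equal(w$per_head, matrix(0.25, 4, 1))
  w1 <- attention_weights(matrix(0, 1, 3))
  expect_equal(w1$summed, 3)            # m = 1: weight 1 per head
  wl <- attention_weights(matrix(c(0, log(3)), 2, 1))
  expect_equal(as.vector(wl$per_head), c(0.25, 0.75))
  set.seed(2)
  L <- matrix(rnorm(12), 4, 3)
  w <- attention_weights(L)
  expect_equal(colSums(w$per_head), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(w$summed), 3)
})

test_that("tumor embedding is e_s plus the weighted gene sum; m = 0 falls back to e_s", {
  set.seed(3)
  es <- rnorm(5); E <- matrix(rnorm(15), 3, 5); a <- runif(3)
  expect_equal(tumor_embedding(es, E, a), es + colSums(a * E))
  expect_equal(tumor_embedding(es, NULL, numeric(0)), es)
  expect_equal(tumor_embedding(es, E[0, , drop = FALSE], numeric(0)), es)
})

test_that("TF activities are bounded tanh responses", {
  set.seed(4)
  Wf <- matrix(rnorm(4 * 6), 4, 6); bf_ <- rnorm(4); et <- rnorm(6)
  expect_equal(tf_activities(et, matrix(0, 4, 6), rep(0, 4)), rep(0, 4))
  expect_equal(tf_activities(et, matrix(0, 4, 6), rep(50, 4)), rep(1, 4))
  got <- tf_activities(et, Wf, bf_)
  expect_equal(got, tanh(as.vector(Wf %*% et) + bf_))
  expect_true(all(abs(got) < 1))
  # relu variant
  expect_equal(tf_activities(et, Wf, bf_, activation = "relu"),
               pmax(as.vector(Wf %*% et) + bf_, 0))
})

test_that("masked decoder prediction equals the dense product and enforces its invariants", {
  set.seed(5)
  mask <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3)
  W <- matrix(runif(24), 8, 3) * mask
  br <- rnorm(8); ef <- runif(3, -1, 1)
  expect_equal(predict_expression(rep(0, 3), W, br), br)
  expect_equal(predict_expression(ef, W, br, mask = mask),
               as.vector(W %*% ef) + br)
  # single-entry column: active TF contributes exactly its weight
  W1 <- matrix(0, 2, 1); W1[1, 1] <- 0.7
  expect_equal(predict_expression(1, W1, c(0.1, 0.2)), c(0.8, 0.2))
  Wbad <- W; Wbad[which(mask == 0)[1]] <- 0.5
  expect_error(predict_expression(ef, Wbad, br, mask = mask), "mask violation")
  Wneg <- W; Wneg[which(mask == 1)[1]] <- -0.1
  expect_error(predict_expression(ef, Wneg, br, mask = mask), "non-negativity")
})

test_that("mse loss matches its formula and rejects NaN", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  set.seed(6)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(mse_loss(y, yh), mean((y - yh)^2))
  expect_error(mse_loss(c(1, NaN), c(1, 2)), "NaN")
})

test_that("the batched forward pass matches a direct single-tumor evaluation", {
  model <- random_model(seed = 11)
  p <- model$params
  alt <- random_profiles_matrix(model, 6, min_m = 1, max_m = 6, seed = 12)
  co <- cohort_for_model(model, alt, rep(c("ct1", "ct2", "ct3"), 2))
  out <- citrus_forward(model, co)
  for (i in seq_len(nrow(alt))) {
    gi <- which(alt[i, ] != 0)
    ref <- bf_forward_tumor(p$E[gi, , drop = FALSE],
                            p$S[as.integer(co$cancer_type[i]), ],
                            p$W0, p$Theta, p$Wf, p$bf, p$W, p$br)
    expect_equal(unname(out$tf_activities[i, ]), ref$ef, tolerance = 1e-12)
    expect_equal(unname(out$predicted[i, ]), ref$yhat, tolerance = 1e-12)
    w <- out$attention$weight[out$attention$tumor == rownames(alt)[i]]
    expect_equal(w, ref$alpha, tolerance = 1e-12)
  }
})

test_that("inference is deterministic and dropout-0 training equals inference", {
  model <- random_model(seed = 13)
  alt <- random_profiles_matrix(model, 5, min_m = 0, max_m = 6, seed = 14)
  co <- cohort_for_model(model, alt, rep("ct1", 5))
  a <- citrus_forward(model, co)
  b <- citrus_forward(model, co)
  expect_identical(a$predicted, b$predicted)
  slots <- citrus:::build_slots(citrus:::profiles_from_matrix(alt, model))
  ti <- rep(1L, 5)
  tr <- citrus:::forward_batch(model$params, model$config, slots, ti, training = TRUE)
  inf <- citrus:::forward_batch(model$params, model$config, slots, ti, training = FALSE)
  expect_identical(tr$Yhat, inf$Yhat)   # config dropout is 0
  # training mode with fixed seed is reproducible
  cfg <- model$config; cfg$dropout <- 0.3
  set.seed(99); t1 <- citrus:::forward_batch(model$params, cfg, slots, ti, training = TRUE)
  set.seed(99); t2 <- citrus:::forward_batch(model$params, cfg, slots, ti, training = TRUE)
  expect_identical(t1$Yhat, t2$Yhat)
  expect_false(identical(t1$Yhat, inf$Yhat))
})

test_that("permuting a tumor's altered genes leaves outputs unchanged bitwise", {
  model <- random_model(seed = 15)
  alt <- random_profiles_matrix(model, 8, min_m = 2, max_m = 8, seed = 16)
  co <- cohort_for_model(model, alt, rep(c("ct1", "ct2"), 4))
  base <- citrus_forward(model, co)
  set.seed(17)
  perm <- sample(ncol(alt))
  alt2 <- alt[, perm]
  co2 <- cohort_for_model(model, alt2, rep(c("ct1", "ct2"), 4), expr = co$expression)
  got <- citrus_forward(model, co2)
  expect_identical(got$predicted, base$predicted)
  expect_identical(got$tf_activities, base$tf_activities)
  # attention weights permute with the genes
  for (i in rownames(alt)) {
    a1 <- base$attention[base$attention$tumor == i, ]
    a2 <- got$attention[got$attention$tumor == i, ]
    expect_identical(stats::setNames(a1$weight, a1$gene)[sort(a1$gene)],
                     stats::setNames(a2$weight, a2$gene)[sort(a1$gene)])
  }
})

test_that("tumors without alterations use the cancer-type embedding alone", {
  model <- random_model(seed = 18)
  alt <- random_profiles_matrix(model, 3, min_m = 0, max_m = 0, seed = 19)
  co <- cohort_for_model(model, alt, c("ct1", "ct2", "ct1"))
  out <- citrus_forward(model, co)
  expect_equal(out$tumor_embedding[1, ], model$params$S[1, ])
  expect_equal(out$tf_activities[1, ], out$tf_activities[3, ])
})

test_that("unknown cancer types are rejected with the known list", {
  model <- random_model(seed = 20)
  alt <- random_profiles_matrix(model, 2, seed = 21)
  co <- cohort_for_model(model, alt, c("ct1", "nope"))
  expect_error(citrus_forward(model, co), "nope")
  expect_error(citrus_forward(model, co), "ct1")  # lists known types
})

test_that("alteration genes outside the vocabulary error strictly or skip leniently", {
  model <- random_model(seed = 22)
  alt <- random_profiles_matrix(model, 4, min_m = 1, max_m = 4, seed = 23)
  colnames(alt)[1] <- "not_in_vocab"
  alt[, 1] <- 1L
  co <- cohort_for_model(model, alt, rep("ct1", 4))
  expect_error(citrus_forward(model, co), "not_in_vocab")
  expect_warning(out <- citrus_forward(model, co, unknown_genes = "skip"),
                 "skipped")
  expect_false("not_in_vocab" %in% out$attention$gene)
})

test_that("analytic gradients agree with finite differences on a tiny instance", {
  set.seed(30)
  prior <- matrix(rbinom(7 * 4, 1, 0.5), 7, 4,
                  dimnames = list(paste0("g", 1:7), paste0("tf", 1:4)))
  cfg <- citrus_config(embedding_dim = 5, attention_size = 3,
                       attention_heads = 2, dropout = 0)
  model <- citrus_model(prior, paste0("ag", 1:6), c("t1", "t2"), cfg, seed = 3)
  profiles <- list(c(1L, 3L, 5L), c(2L, 4L), integer(0))
  type_idx <- c(1L, 2L, 1L)
  Y <- matrix(rnorm(3 * 7), 3, 7)
  slots <- citrus:::build_slots(profiles)
  cache <- citrus:::forward_batch(model$params, cfg, slots, type_idx, FALSE)
  grads <- citrus:::backward_batch(model$params, cfg, cache, Y)
  loss_at <- function(params) {
    out <- citrus:::forward_batch(params, cfg, citrus:::build_slots(profiles),
                                  type_idx, FALSE)
    mean((out$Yhat - Y)^2)
  }
  eps <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(10, length(p)))) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      ana <- grads[[nm]][i]
      if (abs(num) < 1e-7 && abs(ana) < 1e-7) next  # below FD resolution
      expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4)
    }
  }
})
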