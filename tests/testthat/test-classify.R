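fixture_preds <- function(scores_list) {
  tibble::tibble(id = paste0("x", seq_along(scores_list)),
                 pred = vapply(scores_list, function(s)
                   names(s)[which.max(s)], character(1)),
                 scores = scores_list)
}

test_that("the oracle returns the gold class and rejects unlabelled input", {
  ex <- tibble::tibble(id = c("a", "b"), step = "entity",
                       gold = c("X", "neg"),
                       features = list("f", "f"), anchor = list(NULL, NULL))
  p <- oracle_classify(ex)
  expect_equal(p$pred, ex$gold)
  expect_equal(p$scores[[1]][["X"]], 1)
  expect_equal(p$scores[[1]][["neg"]], 0)
  ex$gold[2] <- NA
  expect_error(oracle_classify(ex), "gold classes")
})

test_that("recall adjustment scales the negative class and recomputes the argmax", {
  p <- fixture_preds(list(c(neg = 0.8, pos = 0.5), c(neg = 0.9, pos = 0.1)))
  # beta = 1 is the identity
  same <- adjust_recall(p, 1)
  expect_equal(same$pred, p$pred)
  expect_equal(same$scores, p$scores)
  # beta = 0.5 flips neg 0.8 vs pos 0.5 (0.4 < 0.5)
  half <- adjust_recall(p, 0.5)
  expect_equal(half$pred[1], "pos")
  expect_equal(half$pred[2], "neg")
  # beta = 0 assigns every example its best positive class
  zero <- adjust_recall(p, 0)
  expect_equal(zero$pred, c("pos", "pos"))
  expect_error(adjust_recall(p, 1.5), "\\[0,1\\]")
  expect_error(adjust_recall(p, -0.1), "\\[0,1\\]")
})

test_that("positive predictions are non-increasing in beta", {
  set.seed(7)
  scores <- lapply(1:60, function(i) {
    s <- stats::runif(3)
    names(s) <- c("neg", "A", "B")
    s
  })
  p <- fixture_preds(scores)
  betas <- seq(0, 1, length.out = 21)
  pos_counts <- vapply(betas, function(b)
    sum(adjust_recall(p, b)$pred != "neg"), integer(1))
  expect_true(all(diff(pos_counts) <= 0))
  expect_equal(pos_counts[1], 60)  # beta = 0: everything positive
})

test_that("grid search picks the winner deterministically", {
  # linearly separable fixture
  mk_ex <- function(n, seed) {
    set.seed(seed)
    cls <- rep(c("A", "neg"), length.out = n)
    tibble::tibble(
      id = paste0("e", seed, "_", seq_len(n)), step = "entity", gold = cls,
      features = lapply(cls, function(cl)
        c(if (cl == "A") "isA" else "isNeg", paste0("noise_", sample(5, 1)))),
      anchor = replicate(n, NULL, simplify = FALSE))
  }
  tr <- mk_ex(40, 1); dv <- mk_ex(20, 2)
  # single-point grid returns that point
  tn <- tune_parameters(adapter_glmnet(), tr, dv,
                        param_grid = list(list(lambda = 0.01)), betas = 1)
  expect_equal(tn$best_params$lambda, 0.01)
  expect_equal(tn$best_beta, 1)
  # a grid containing a separating configuration reaches devel F = 100
  tn2 <- tune_parameters(adapter_glmnet(), tr, dv,
                         param_grid = list(list(lambda = 1), list(lambda = 0.001)),
                         betas = c(0.5, 1))
  expect_equal(tn2$best_score, 100)
  # objective monotone increasing in beta returns the boundary beta
  tn3 <- tune_parameters(adapter_glmnet(), tr, dv,
                         param_grid = list(list(lambda = 0.01)),
                         betas = c(0.2, 0.6, 1),
                         objective = function(preds, ex) 1)
  expect_equal(tn3$best_beta, 1)  # ties break toward the largest beta
  expect_error(tune_parameters(adapter_glmnet(), tr, dv,
                               param_grid = list(), betas = 1),
               "non-empty")
})

test_that("feature importances are normalized, ordered and grouped exhaustively", {
  mk_ex <- function(n, seed) {
    set.seed(seed)
    cls <- rep(c("A", "neg"), length.out = n)
    tibble::tibble(
      id = paste0("e", seq_len(n)), step = "entity", gold = cls,
      features = lapply(cls, function(cl)
        c(if (cl == "A") "txt_hit" else "txt_miss",
          paste0("bow_w", sample(4, 1)))),
      anchor = replicate(n, NULL, simplify = FALSE))
  }
  m <- train_classifier(adapter_forest(num_trees = 50), mk_ex(60, 3),
                        seed = 11)
  imp <- rank_feature_importances(m)
  expect_true(all(diff(imp$weight) <= 0))
  expect_true(all(imp$weight >= 0))
  expect_equal(sum(imp$weight), 1, tolerance = 1e-8)
  expect_true(all(imp$group %in% c("token", "bow")))
  # per-group summary partitions every feature into exactly one group
  smry <- tidy(imp)
  expect_equal(sum(smry$n), nrow(imp))
  # the discriminative feature dominates
  expect_equal(imp$feature[1], "txt_hit")
  # adapters without the capability refuse
  m2 <- train_classifier(adapter_oracle(), mk_ex(10, 4))
  expect_error(rank_feature_importances(m2), "importances")
})

test_that("adapters are substitutable without changing example content", {
  g <- gen_corpus(3, seed = 91)
  sc <- learn_scheme(g$corpus)
  ex1 <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                 build_entity_examples, scheme = sc))
  ex2 <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                 build_entity_examples, scheme = sc))
  # hashing the example set is independent of which adapter consumes it
  expect_identical(serialize_examples <- ex1$features, ex2$features)
  for (ad in list(adapter_glmnet(), adapter_oracle())) {
    m <- suppressWarnings(train_classifier(ad, ex1, params = list(lambda = 0.01)))
    expect_identical(ex1$features, ex2$features)
  }
})
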