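# CRF correctness against enumeration, Viterbi determinism, training-loop
# contracts and ensembling.

test_that("forward logZ and Viterbi agree with exhaustive enumeration", {
  set.seed(1234)
  for (trial in 1:60) {
    inst <- random_crf_instance()
    oracle <- crf_enumerate(inst$emissions, inst$crf)
    expect_equal(medlinkr:::crf_forward_logz(inst$emissions, inst$crf),
                 oracle$logz, tolerance = 1e-9)
    vit <- viterbi_decode(inst$emissions, inst$crf)
    vit_score <- medlinkr:::crf_path_score(inst$emissions, inst$crf,
                                           match(vit, inst$crf$labels))
    expect_equal(vit_score, oracle$best, tolerance = 1e-9)
  }
})

test_that("CRF NLL is non-negative and degenerate cases behave analytically", {
  set.seed(2)
  # single-label CRF: only one path, NLL is exactly zero
  crf1 <- list(transitions = matrix(rnorm(1)), start_scores = rnorm(1),
               stop_scores = rnorm(1), labels = "L1")
  em1 <- matrix(rnorm(5), 5, 1)
  expect_equal(crf_neg_log_likelihood(em1, crf1, rep("L1", 5)), 0)
  # all scores zero: logZ == T * log(L)
  L <- 4L; Tn <- 3L
  crf0 <- list(transitions = matrix(0, L, L), start_scores = numeric(L),
               stop_scores = numeric(L), labels = paste0("L", 1:L))
  em0 <- matrix(0, Tn, L)
  expect_equal(medlinkr:::crf_forward_logz(em0, crf0), Tn * log(L))
  # NLL >= 0 on random instances; gold outside label set errors
  inst <- random_crf_instance()
  gold <- sample(inst$crf$labels, nrow(inst$emissions), replace = TRUE)
  expect_gte(crf_neg_log_likelihood(inst$emissions, inst$crf, gold), 0)
  expect_error(crf_neg_log_likelihood(inst$emissions, inst$crf,
                                      rep("nope", nrow(inst$emissions))),
               "label")
  # Viterbi path NLL is minimal among sampled paths
  vit <- viterbi_decode(inst$emissions, inst$crf)
  nll_vit <- crf_neg_log_likelihood(inst$emissions, inst$crf, vit)
  for (k in 1:10) {
    other <- sample(inst$crf$labels, nrow(inst$emissions), replace = TRUE)
    expect_lte(nll_vit,
               crf_neg_log_likelihood(inst$emissions, inst$crf, other) + 1e-9)
  }
})

test_that("Viterbi breaks ties toward the lowest label index", {
  L <- 3L
  crf0 <- list(transitions = matrix(0, L, L), start_scores = numeric(L),
               stop_scores = numeric(L), labels = paste0("L", 1:L))
  em <- matrix(0, 4, L)
  expect_identical(viterbi_decode(em, crf0), rep("L1", 4L))
  # T = 1: label maximizing start + emission + stop
  crf1 <- crf0
  crf1$start_scores <- c(0, 1, 0)
  crf1$stop_scores <- c(0, 0, 0.5)
  expect_identical(viterbi_decode(matrix(0, 1, L), crf1), "L2")
})

test_that("emissions are deterministic, shaped T x 33, and empty for empty docs", {
  docs <- small_corpus(6L, seed = 31L)
  cfg <- repr_config("RIWE", word_dim = 10L, lstm_hidden = 6L, max_epochs = 1L)
  m <- train_ner(docs[1:4], dev_docs = docs[5:6], config = cfg, seed = 3L)
  em <- emissions(m, docs[[1L]])
  expect_identical(dim(em), c(nrow(docs[[1L]]$tokens), 33L))
  expect_identical(em, emissions(m, docs[[1L]]))
  empty <- ann_doc("e", "")
  expect_identical(nrow(emissions(m, empty)), 0L)
  expect_identical(predict_entities(m, empty), medlinkr:::empty_entities())
})

test_that("training respects patience, is seed-reproducible, and memorizes a tiny fixture", {
  docs <- small_corpus(8L, seed = 77L)
  cfg <- repr_config("RIWE", word_dim = 16L, lstm_hidden = 12L,
                     max_epochs = 40L, patience = 0L)
  m1 <- train_ner(docs[1:6], dev_docs = docs[7:8], config = cfg, seed = 5L)
  expect_identical(nrow(m1$history), 1L)  # patience 0 -> exactly 1 epoch
  cfg$patience <- 2L
  cfg$max_epochs <- 3L
  m2 <- train_ner(docs[1:6], dev_docs = docs[7:8], config = cfg, seed = 5L)
  m3 <- train_ner(docs[1:6], dev_docs = docs[7:8], config = cfg, seed = 5L)
  expect_identical(m2$history, m3$history)
  expect_identical(m2$params, m3$params)
  # empty training set errors
  expect_error(train_ner(list(), dev_docs = docs[7:8], config = cfg), "empty")
  # memorization: training on five sentences reaches perfect lenient F
  memo <- small_corpus(2L, seed = 12L)
  cfgm <- repr_config("RIWE", word_dim = 24L, lstm_hidden = 24L,
                      max_epochs = 60L, patience = 60L, dropout = 0,
                      lr = 0.05, batch_size = 8L)
  mm <- train_ner(memo, dev_docs = memo, config = cfgm, seed = 11L)
  pred <- medlinkr:::predict_corpus(mm, memo)
  expect_equal(evaluate_ner(memo, pred, "lenient")$micro[["f1"]], 1.0)
  # predicted entities come back sorted by start offset
  p1 <- predict_entities(mm, memo[[1L]])
  expect_false(is.unsorted(p1$start))
})

test_that("model checkpoints round-trip exactly", {
  docs <- small_corpus(6L, seed = 41L)
  cfg <- repr_config("RIWE", word_dim = 8L, lstm_hidden = 5L, max_epochs = 1L)
  m <- train_ner(docs[1:4], dev_docs = docs[5:6], config = cfg, seed = 2L)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$config, m2$config)
  expect_identical(predict_entities(m, docs[[1L]]),
                   predict_entities(m2, docs[[1L]]))
})

test_that("ensemble voting keeps exactly the majority entities", {
  e <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(id = "x", type = r[[1L]], start = r[[2L]], end = r[[3L]],
                 surface = NA_character_, stringsAsFactors = FALSE)
    }))
  }
  a <- e(list("Drug", 0L, 7L), list("Strength", 8L, 13L))
  b <- e(list("Drug", 0L, 7L), list("Strength", 8L, 13L))
  c_ <- e(list("Drug", 0L, 7L), list("Reason", 20L, 24L))
  # all identical -> identity
  all3 <- ensemble_vote(list(a, b, a))
  expect_identical(all3[, c("type", "start", "end")],
                   a[, c("type", "start", "end")])
  # 2-of-3 kept, 1-of-3 dropped
  v <- ensemble_vote(list(a, b, c_))
  expect_identical(v$type, c("Drug", "Strength"))
  # k = 1 is the identity
  v1 <- ensemble_vote(list(c_))
  expect_identical(v1[, c("type", "start", "end")],
                   c_[, c("type", "start", "end")])
  # 2-model tie: an entity in exactly 1 of 2 sets is NOT a majority
  v2 <- ensemble_vote(list(a, c_))
  expect_identical(v2$type, "Drug")
  # empty input sets
  expect_identical(nrow(ensemble_vote(list(e(list("Drug", 0L, 1L))[0, ]))), 0L)
})
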