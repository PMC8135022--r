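# Candidate generation, marker encoding, the softmax head and relation
# model training.

test_that("candidate generation pairs every attribute with in-scope drugs", {
  # one sentence, 2 drugs x 3 attributes -> 6 candidates
  txt <- "Adolol 25mg PO and Benzonol daily."
  d <- ann_doc("c", txt, data.frame(
    id = paste0("T", 1:5),
    type = c("Drug", "Strength", "Route", "Drug", "Frequency"),
    start = c(0L, 7L, 12L, 19L, 28L), end = c(6L, 11L, 14L, 27L, 33L),
    surface = NA_character_))
  cands <- generate_candidates(d)
  expect_length(cands, 6L)
  # no drugs in scope -> no candidates
  d0 <- ann_doc("c0", "pain for weeks", data.frame(
    id = "T1", type = "Reason", start = 0L, end = 4L,
    surface = NA_character_))
  expect_length(generate_candidates(d0), 0L)
  # cross-sentence scope: every attribute in the titration passage pairs
  # with the single drug two sentences back
  dt <- doc_topiramate()
  ct <- generate_candidates(dt)
  expect_length(ct, 8L)
  expect_true(all(vapply(ct, `[[`, character(1L), "drug_id") == "T1"))
  # scope coverage: every gold relation with both entities in scope is a
  # positively labelled candidate
  docs <- generate_corpus(generator_config(n_docs = 15L, seed = 23L))
  for (dd in docs) {
    cands <- generate_candidates(dd)
    pos <- vapply(cands, `[[`, logical(1L), "related")
    keys <- paste(vapply(cands, `[[`, character(1L), "attr_id"),
                  vapply(cands, `[[`, character(1L), "drug_id"))
    gold <- paste(dd$relations$attr_id, dd$relations$drug_id)
    expect_true(all(gold %in% keys[pos]))
    expect_identical(sort(keys[pos]), sort(gold))
  }
})

test_that("marker labels mark exactly the candidate's entities as targets", {
  d <- doc_guaifenesin()
  cands <- generate_candidates(d)
  # the reason/first-drug candidate: markers include TARGET_ATTR over the
  # reason tokens, TARGET_DRUG over that drug, OTHER_DRUG over the other
  cd <- Filter(function(x) x$attr_id == "T4" && x$drug_id == "T1", cands)[[1L]]
  toks <- d$tokens$surface[cd$range]
  m <- medlinkr:::MARKER_LEVELS[cd$marker]
  expect_identical(unique(m[toks == "cough"]), "TARGET_ATTR")
  expect_identical(unique(m[toks %in% c("Guaifensin", "codeine")]),
                   "TARGET_DRUG")
  expect_identical(unique(m[toks == "Benzonatate"]), "OTHER_DRUG")
  expect_identical(unique(m[toks == "needed"]), "OTHER")
})

test_that("candidate encoding is deterministic, zero under zero parameters, marker-sensitive", {
  docs <- small_corpus(4L, seed = 9L)
  cfg <- repr_config("RIWE", word_dim = 10L, marker_dim = 4L,
                     lstm_hidden = 7L, max_epochs = 1L, patience = 0L)
  m <- train_re(docs[1:3], docs[4], config = cfg, seed = 21L)
  d <- docs[[1L]]
  cands <- generate_candidates(d)
  skip_if(length(cands) < 2L)
  v1 <- encode_candidate(m, d, cands[[1L]])
  expect_length(v1, cfg$lstm_hidden)
  expect_identical(v1, encode_candidate(m, d, cands[[1L]]))
  # zero parameters -> zero encoding
  m0 <- m
  m0$params$E_word <- m0$params$E_word * 0
  m0$params$E_marker <- m0$params$E_marker * 0
  for (nm in c("Wx", "Wh", "b"))
    m0$params$lstm[[nm]] <- m0$params$lstm[[nm]] * 0
  expect_equal(encode_candidate(m0, d, cands[[1L]]), numeric(cfg$lstm_hidden))
  # moving the target-attribute marker changes the encoding
  cd2 <- cands[[1L]]
  cd2$marker[cd2$marker == 2L] <- 4L
  cd2$marker[length(cd2$marker)] <- 2L
  expect_false(isTRUE(all.equal(v1, encode_candidate(m, d, cd2))))
})

test_that("the softmax head is a proper two-way classifier over pair and context", {
  docs <- small_corpus(4L, seed = 9L)
  cfg <- repr_config("RIWE", word_dim = 10L, marker_dim = 4L,
                     lstm_hidden = 7L, max_epochs = 1L, patience = 0L)
  m <- train_re(docs[1:3], docs[4], config = cfg, seed = 21L)
  r <- rnorm(7)
  p_nocontext <- classify_pair(m, r)
  expect_gte(p_nocontext, 0)
  expect_lte(p_nocontext, 1)
  # no context pairs: the context block is the zero vector
  expect_equal(p_nocontext, classify_pair(m, r, matrix(0, 2, 7)))
  # context shifts the decision
  ctx <- matrix(rnorm(14), 2, 7)
  expect_false(isTRUE(all.equal(p_nocontext, classify_pair(m, r, ctx))))
})

test_that("relation training stops per patience, reproduces by seed, learns a separable toy", {
  docs <- small_corpus(8L, seed = 61L)
  cfg <- repr_config("RIWE", word_dim = 12L, marker_dim = 4L,
                     lstm_hidden = 8L, max_epochs = 6L, patience = 0L)
  m1 <- train_re(docs[1:6], docs[7:8], config = cfg, seed = 4L)
  expect_identical(nrow(m1$history), 1L)
  cfg$patience <- 2L
  m2 <- train_re(docs[1:6], docs[7:8], config = cfg, seed = 4L)
  m3 <- train_re(docs[1:6], docs[7:8], config = cfg, seed = 4L)
  expect_identical(m2$history, m3$history)
  # no positive candidates is an error
  unrel <- list(ann_doc("u", "Adolol daily.", data.frame(
    id = c("T1", "T2"), type = c("Drug", "Frequency"),
    start = c(0L, 7L), end = c(6L, 12L), surface = NA_character_)))
  expect_error(train_re(unrel, unrel, config = cfg, seed = 1L),
               "no positively labelled")
  # linearly separable toy with two candidate patterns -- attributes
  # refer to the nearer of two drugs, so related candidates have
  # one-sentence-shorter scopes than unrelated ones -- reaches perfect
  # accuracy when overfit
  mk <- function(i, n1, n2) {
    txt <- sprintf("%s given. %s held. Then 25mg daily.", n1, n2)
    d2s <- nchar(n1) + 8L
    ts <- d2s + nchar(n2) + 7L
    ss <- ts + 5L
    fs <- ss + 5L
    ann_doc(paste0("t", i), txt,
            data.frame(id = c("T1", "T2", "T3", "T4"),
                       type = c("Drug", "Drug", "Strength", "Frequency"),
                       start = c(0L, d2s, ss, fs),
                       end = c(nchar(n1), d2s + nchar(n2), ss + 4L, fs + 5L),
                       surface = NA_character_),
            data.frame(id = c("R1", "R2"),
                       type = c("Strength-Drug", "Frequency-Drug"),
                       attr_id = c("T3", "T4"), drug_id = c("T2", "T2")))
  }
  toy <- Map(mk, 1:4, c("Adolol", "Kerpril", "Zolmab", "Trictin"),
             c("Benzonol", "Flumycin", "Gabazole", "Normab"))
  # each doc yields two related and two unrelated candidates
  labs <- vapply(generate_candidates(toy[[1L]]), `[[`, logical(1L), "related")
  expect_identical(sum(labs), 2L)
  expect_identical(sum(!labs), 2L)
  cfgo <- repr_config("RIWE", word_dim = 24L, lstm_hidden = 24L,
                      max_epochs = 60L, patience = 60L, lr = 0.05)
  mo <- train_re(toy, toy, config = cfgo, seed = 2L)
  pred <- lapply(toy, function(d) {
    pd <- ann_doc(d$doc_id, d$text, d$entities)
    pd$relations <- predict_relations(mo, d)
    pd
  })
  expect_equal(evaluate_relations(toy, pred, "lenient")$micro[["f1"]], 1.0)
})

test_that("the relation model generalizes to held-out synthetic documents", {
  docs <- generate_corpus(generator_config(n_docs = 80L, seed = 11L))
  cfg <- repr_config("RIWE", word_dim = 100L, lstm_hidden = 300L,
                     max_epochs = 15L, patience = 5L)
  m <- train_re(docs[1:40], docs[41:50], config = cfg, seed = 42L)
  test <- docs[51:80]
  pred <- lapply(test, function(d) {
    pd <- ann_doc(d$doc_id, d$text, d$entities)
    pd$relations <- predict_relations(m, d)
    pd
  })
  rep <- evaluate_relations(test, pred, "lenient")
  expect_gte(rep$micro[["f1"]], 0.85)
  # probabilities are well-formed on a held-out document
  cands <- generate_candidates(test[[1L]])
  if (length(cands)) {
    r <- encode_candidate(m, test[[1L]], cands[[1L]])
    p <- classify_pair(m, r)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})
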