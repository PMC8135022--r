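# Matching, micro/macro algebra, confusion matrices and the paired test.

test_that("strict and lenient entity matching follow their definitions", {
  g <- data.frame(id = "G1", type = "Drug", start = 0L, end = 7L,
                  surface = NA_character_)
  p <- data.frame(id = "P1", type = "Drug", start = 0L, end = 7L,
                  surface = NA_character_)
  for (mode in c("lenient", "strict"))
    expect_identical(match_entities(g, p, mode)$tp, 1L)
  # overlapping but not identical: lenient tp, strict fp+fn
  g2 <- data.frame(id = "G1", type = "Reason", start = 10L, end = 20L,
                   surface = NA_character_)
  p2 <- data.frame(id = "P1", type = "Reason", start = 12L, end = 25L,
                   surface = NA_character_)
  expect_identical(match_entities(g2, p2, "lenient")$tp, 1L)
  ms <- match_entities(g2, p2, "strict")
  expect_identical(c(ms$tp, ms$fp, ms$fn), c(0L, 1L, 1L))
  # type must match even leniently
  p3 <- p2; p3$type <- "Duration"
  expect_identical(match_entities(g2, p3, "lenient")$tp, 0L)
})

test_that("lenient matching equals brute-force maximum bipartite matching", {
  set.seed(808)
  for (trial in 1:120) {
    gold <- random_span_set()
    pred <- random_span_set()
    m <- match_entities(gold, pred, "lenient")
    oracle <- if (nrow(gold) && nrow(pred)) {
      brute_force_matching(lenient_compat(gold, pred))
    } else 0L
    expect_identical(m$tp, as.integer(oracle))
    # contingency identities
    expect_identical(m$tp + m$fn, nrow(gold))
    expect_identical(m$tp + m$fp, nrow(pred))
    # one-to-one
    expect_false(anyDuplicated(m$matched_pairs$gold_idx) > 0L)
    expect_false(anyDuplicated(m$matched_pairs$pred_idx) > 0L)
    # strict tp never exceeds lenient tp
    expect_lte(match_entities(gold, pred, "strict")$tp, m$tp)
  }
})

test_that("greedy-suboptimal crossing overlaps are still matched maximally", {
  # g1 overlaps p1 (big) and p2; g2 overlaps only p1: maximum matching
  # is 2 even though the largest single overlap pairs g1 with p1.
  gold <- data.frame(id = c("G1", "G2"), type = "Drug",
                     start = c(0L, 8L), end = c(10L, 12L),
                     surface = NA_character_)
  pred <- data.frame(id = c("P1", "P2"), type = "Drug",
                     start = c(1L, 9L), end = c(10L, 14L),
                     surface = NA_character_)
  expect_identical(match_entities(gold, pred, "lenient")$tp, 2L)
})

test_that("micro pools counts while macro averages per-document metrics", {
  mk <- function(id, ents) ann_doc(id, paste(rep("x", 60), collapse = " "), ents)
  span <- function(id, type, s, e) data.frame(
    id = id, type = type, start = s, end = e, surface = NA_character_,
    stringsAsFactors = FALSE)
  # doc A: perfect on 4 entities; doc B: all wrong on 1 entity
  gold <- list(mk("a", rbind(span("T1", "Drug", 0L, 5L),
                             span("T2", "Drug", 10L, 15L),
                             span("T3", "Route", 20L, 25L),
                             span("T4", "Form", 30L, 35L))),
               mk("b", span("T1", "Drug", 0L, 5L)))
  pred <- list(mk("a", rbind(span("T1", "Drug", 0L, 5L),
                             span("T2", "Drug", 10L, 15L),
                             span("T3", "Route", 20L, 25L),
                             span("T4", "Form", 30L, 35L))),
               mk("b", span("T1", "Drug", 50L, 55L)))
  r <- evaluate_ner(gold, pred, "lenient")
  expect_equal(unname(r$macro[["f1"]]), 0.5)       # mean of 1 and 0
  expect_equal(unname(r$micro[["precision"]]), 4 / 5)
  expect_equal(unname(r$micro[["recall"]]), 4 / 5)
  # hand-computed micro: tp=2,fp=1,fn=1 -> P=R=F=2/3
  gold2 <- list(mk("c", rbind(span("T1", "Drug", 0L, 5L),
                              span("T2", "Drug", 10L, 15L),
                              span("T3", "Route", 20L, 25L))))
  pred2 <- list(mk("c", rbind(span("T1", "Drug", 0L, 5L),
                              span("T2", "Drug", 10L, 15L),
                              span("T3", "Route", 40L, 45L))))
  r2 <- evaluate_ner(gold2, pred2, "lenient")
  expect_equal(unname(r2$micro), c(2 / 3, 2 / 3, 2 / 3))
  # identical corpora -> all 1; empty docs score (1,1,1) into the macro
  r3 <- evaluate_ner(gold, gold, "lenient")
  expect_equal(unname(r3$micro[["f1"]]), 1)
  r4 <- evaluate_ner(list(mk("e", NULL)), list(mk("e", NULL)), "lenient")
  expect_equal(unname(r4$macro[["f1"]]), 1)
  # mismatched ids error
  expect_error(evaluate_ner(gold, rev(pred), "lenient"), "ids")
})

test_that("relation evaluation matches endpoints under the mode, one-to-one", {
  d <- doc_bisacodyl()
  pd <- ann_doc(d$doc_id, d$text, d$entities, d$relations)
  r <- evaluate_relations(list(d), list(pd), "lenient")
  expect_equal(unname(r$micro[["f1"]]), 1)
  # an attribute typed wrongly upstream turns the relation into fp + fn
  ents2 <- d$entities
  ents2$type[ents2$id == "T2"] <- "Dosage"
  rels2 <- d$relations
  rels2$type[rels2$attr_id == "T2"] <- "Dosage-Drug"
  pd2 <- ann_doc(d$doc_id, d$text, ents2, rels2)
  r2 <- evaluate_relations(list(d), list(pd2), "lenient")
  pt <- r2$per_type
  expect_identical(pt$fp[pt$type == "Dosage-Drug"], 1L)
  expect_identical(pt$fn[pt$type == "Strength-Drug"], 1L)
  # dangling entity references error
  pd3 <- pd
  pd3$relations$attr_id[1L] <- "T99"
  expect_error(evaluate_relations(list(d), list(pd3), "lenient"), "missing")
  # end-to-end evaluation shares the relation contract
  e2e <- evaluate_end_to_end(list(d), list(pd), "lenient")
  expect_equal(unname(e2e$micro[["f1"]]), 1)
})

test_that("relation counts agree with a brute-force matcher on random instances", {
  set.seed(606)
  for (trial in 1:40) {
    txt <- paste(rep("w", 50), collapse = " ")
    ents <- random_span_set(5L, types = c("Drug", "Reason", "Route"))
    if (!nrow(ents) || !any(ents$type == "Drug") || all(ents$type == "Drug"))
      next
    d <- ann_doc("r", txt, ents)
    drugs <- ents$id[ents$type == "Drug"]
    attrs <- ents$id[ents$type != "Drug"]
    rel_of <- function(n_max) {
      n <- sample(0:min(n_max, length(attrs) * length(drugs)), 1L)
      if (n == 0L) return(medlinkr:::empty_relations())
      pairs <- unique(data.frame(a = sample(attrs, n, replace = TRUE),
                                 dr = sample(drugs, n, replace = TRUE)))
      data.frame(id = paste0("R", seq_len(nrow(pairs))),
                 type = paste0(ents$type[match(pairs$a, ents$id)], "-Drug"),
                 attr_id = pairs$a, drug_id = pairs$dr,
                 stringsAsFactors = FALSE)
    }
    gd <- ann_doc("r", txt, ents, rel_of(4L))
    pd <- ann_doc("r", txt, ents, rel_of(4L))
    counts <- medlinkr:::relation_counts(gd, pd, "strict")
    # same entity set on both sides: a relation matches iff identical
    # (type, attr, drug); oracle tp = |intersection|
    key <- function(r) paste(r$type, r$attr_id, r$drug_id)
    tp_oracle <- length(intersect(key(gd$relations), key(pd$relations)))
    expect_identical(sum(counts[, "tp"]), tp_oracle)
    expect_identical(sum(counts[, "tp"] + counts[, "fn"]), nrow(gd$relations))
    expect_identical(sum(counts[, "tp"] + counts[, "fp"]), nrow(pd$relations))
  }
})

test_that("swapping gold and predictions swaps precision and recall", {
  docs <- generate_corpus(generator_config(n_docs = 6L, seed = 3L))
  pred <- lapply(docs, function(d) {
    pd <- ann_doc(d$doc_id, d$text,
                  d$entities[seq_len(max(0L, nrow(d$entities) - 2L)), ,
                             drop = FALSE])
    pd
  })
  a <- evaluate_ner(docs, pred, "lenient")
  b <- evaluate_ner(pred, docs, "lenient")
  expect_equal(a$micro[["precision"]], b$micro[["recall"]])
  expect_equal(a$micro[["recall"]], b$micro[["precision"]])
})

test_that("token confusion matrix tabulates per-token type decisions", {
  d <- doc_aspirin()
  cm <- token_confusion_matrix(list(d), list(d))
  expect_identical(sum(cm) , nrow(d$tokens))
  expect_identical(attr(cm, "total_errors"), 0L)
  # one token flipped from Strength to Dosage
  ents2 <- d$entities
  ents2$type[2L] <- "Dosage"
  d2 <- ann_doc(d$doc_id, d$text, ents2)
  cm2 <- token_confusion_matrix(list(d), list(d2))
  expect_identical(cm2["Strength", "Dosage"], 2L)  # "81" and "mg"
  expect_identical(sum(cm2), nrow(d$tokens))
  # token count mismatch errors
  d3 <- ann_doc("asp", "Different text entirely .")
  expect_error(token_confusion_matrix(list(d), list(d3)), "token count")
})

test_that("paired t test matches the closed-form computation and flags degeneracy", {
  # (0.5, 0.6, 0.7) vs (0.4, 0.5, 0.6) has constant differences, so the
  # closed-form denominator sd(d) is zero: the degenerate path, not a crash
  a <- c(0.5, 0.6, 0.7)
  b <- c(0.4, 0.5, 0.6)
  r <- paired_ttest(a, b)
  expect_true(r$degenerate)
  expect_true(is.na(r$t) && is.na(r$p))
  expect_equal(r$mean_diff, 0.1)
  # a == b elementwise is likewise degenerate
  expect_true(paired_ttest(a, a)$degenerate)
  # non-degenerate vectors agree with the closed-form paired formula
  x <- c(0.50, 0.62, 0.71, 0.66)
  y <- c(0.45, 0.60, 0.69, 0.55)
  rr <- paired_ttest(x, y)
  d <- x - y
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  p_closed <- 2 * pt(-abs(t_closed), length(d) - 1L)
  expect_equal(rr$t, t_closed)
  expect_equal(rr$p, p_closed)
  expect_false(rr$degenerate)
  # swapping the samples negates t and leaves p unchanged
  r2 <- paired_ttest(y, x)
  expect_equal(r2$t, -rr$t)
  expect_equal(r2$p, rr$p)
  # random vectors agree with the closed form too
  set.seed(17)
  u <- runif(12); v <- runif(12)
  ru <- paired_ttest(u, v)
  du <- u - v
  expect_equal(ru$t, mean(du) / (sd(du) / sqrt(12)))
})
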