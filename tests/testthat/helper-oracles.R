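# Shared fixtures and independent oracles used across test files.
#
# The oracles deliberately re-derive quantities by brute force (path
# enumeration, exhaustive assignment search) so they stay independent of
# the implementation paths they check.

# ---- tiny document builders -------------------------------------------------

# A one-line annotated prescription document.
doc_aspirin <- function() {
  ann_doc("asp", "Aspirin 81 mg daily.",
          entities = data.frame(
            id = c("T1", "T2", "T3"),
            type = c("Drug", "Strength", "Frequency"),
            start = c(0L, 8L, 14L), end = c(7L, 13L, 19L),
            surface = NA_character_),
          relations = data.frame(
            id = c("R1", "R2"),
            type = c("Strength-Drug", "Frequency-Drug"),
            attr_id = c("T2", "T3"), drug_id = c("T1", "T1")))
}

# The three-sentence dose-titration passage: drug only in sentence 1,
# attributes in sentences 2 and 3 refer back to it.
doc_topiramate <- function() {
  txt <- paste0("Patient will be on Topiramate 25mg PO BID until 22/3 PM. ",
                "Then increase to 50mg po BID for seven days. ",
                "Then increase to 75mg ongoing.")
  ents <- data.frame(
    id = paste0("T", 1:9),
    type = c("Drug", "Strength", "Route", "Frequency",
             "Strength", "Route", "Frequency", "Duration",
             "Strength"),
    start = c(19L, 30L, 35L, 38L, 74L, 79L, 82L, 86L, 119L),
    end = c(29L, 34L, 37L, 41L, 78L, 81L, 85L, 100L, 123L),
    surface = NA_character_)
  rels <- data.frame(
    id = paste0("R", 1:8),
    type = paste0(ents$type[-1], "-Drug"),
    attr_id = ents$id[-1], drug_id = "T1")
  ann_doc("topi", txt, ents, rels)
}

# Single-drug "Sig:" line with two form mentions, all attributes linked to
# the one drug.
doc_bisacodyl <- function() {
  txt <- "Bisacodyl 5 mg Tablet Sig: 1-2 Tablets PO once a day as needed for constipation."
  ents <- data.frame(
    id = paste0("T", 1:8),
    type = c("Drug", "Strength", "Form", "Dosage", "Form", "Route",
             "Frequency", "Reason"),
    start = c(0L, 10L, 15L, 27L, 31L, 39L, 42L, 67L),
    end = c(9L, 14L, 21L, 30L, 38L, 41L, 52L, 79L),
    surface = NA_character_)
  rels <- data.frame(
    id = paste0("R", 1:7),
    type = paste0(ents$type[-1], "-Drug"),
    attr_id = ents$id[-1], drug_id = "T1")
  ann_doc("bisa", txt, ents, rels)
}

# Two drugs, reason at the end shared by both in the gold standard -- the
# configuration segmentation rules cannot fully recover.
doc_guaifenesin <- function() {
  txt <- "START: Guaifensin with codeine QHS and Benzonatate as needed for cough."
  ents <- data.frame(
    id = paste0("T", 1:4),
    type = c("Drug", "Frequency", "Drug", "Reason"),
    start = c(7L, 31L, 39L, 65L), end = c(30L, 34L, 50L, 70L),
    surface = NA_character_)
  rels <- data.frame(
    id = paste0("R", 1:3),
    type = c("Frequency-Drug", "Reason-Drug", "Reason-Drug"),
    attr_id = c("T2", "T4", "T4"), drug_id = c("T1", "T1", "T3"))
  ann_doc("guaf", txt, ents, rels)
}

# ---- CRF oracles ------------------------------------------------------------

# Exhaustive enumeration of all L^T paths: log-partition and best score.
crf_enumerate <- function(emissions, crf) {
  Tlen <- nrow(emissions)
  L <- length(crf$labels)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), Tlen)))
  scores <- apply(paths, 1L, function(p) {
    s <- crf$start_scores[p[1L]] + crf$stop_scores[p[Tlen]] +
      sum(emissions[cbind(seq_len(Tlen), p)])
    if (Tlen > 1L) s <- s + sum(crf$transitions[cbind(p[-Tlen], p[-1L])])
    s
  })
  m <- max(scores)
  list(logz = m + log(sum(exp(scores - m))), best = m,
       best_path = paths[which.max(scores), ])
}

random_crf_instance <- function(max_t = 6L, max_l = 5L) {
  L <- sample(2:max_l, 1L)
  Tlen <- sample(1:max_t, 1L)
  labels <- paste0("L", seq_len(L))
  crf <- list(transitions = matrix(rnorm(L * L), L, L),
              start_scores = rnorm(L), stop_scores = rnorm(L),
              labels = labels)
  list(crf = crf, emissions = matrix(rnorm(Tlen * L), Tlen, L))
}

# ---- matching oracle --------------------------------------------------------

# Brute-force maximum one-to-one matching size over a boolean
# compatibility matrix (golds x preds), by recursive assignment search.
brute_force_matching <- function(compat) {
  ng <- nrow(compat); np <- ncol(compat)
  if (ng == 0L || np == 0L) return(0L)
  best <- 0L
  rec <- function(g, used, count) {
    if (count + (ng - g + 1L) <= best) return()
    if (g > ng) { best <<- max(best, count); return() }
    rec(g + 1L, used, count)  # leave gold g unmatched
    for (p in which(compat[g, ] & !used)) {
      used2 <- used; used2[p] <- TRUE
      rec(g + 1L, used2, count + 1L)
    }
  }
  rec(1L, rep(FALSE, np), 0L)
  best
}

random_span_set <- function(n_max = 6L, types = c("Drug", "Reason")) {
  n <- sample(0:n_max, 1L)
  if (n == 0L) return(empty_span_df())
  start <- sample(0:40, n, replace = TRUE)
  len <- sample(1:8, n, replace = TRUE)
  data.frame(id = paste0("T", seq_len(n)),
             type = sample(types, n, replace = TRUE),
             start = start, end = start + len, surface = NA_character_,
             stringsAsFactors = FALSE)
}

empty_span_df <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), surface = character(), stringsAsFactors = FALSE)
}

lenient_compat <- function(gold, pred) {
  outer(seq_len(nrow(gold)), seq_len(nrow(pred)),
        Vectorize(function(g, p) {
          gold$type[g] == pred$type[p] &&
            max(gold$start[g], pred$start[p]) < min(gold$end[g], pred$end[p])
        }))
}

# ---- misc -------------------------------------------------------------------

# Write a plain-text embedding vector file.
write_embedding_file <- function(vectors, path, header = FALSE) {
  lines <- vapply(names(vectors), function(tok) {
    paste(c(tok, format(vectors[[tok]], digits = 10)), collapse = " ")
  }, character(1L))
  if (header) {
    dims <- length(vectors[[1L]])
    lines <- c(paste(length(vectors), dims), lines)
  }
  writeLines(lines, path)
  path
}

# A deterministic pretrained-embedding file covering a corpus vocabulary.
pretrained_file_for <- function(docs, dim, path, seed = 99L) {
  vocab <- build_vocab(docs)
  toks <- setdiff(names(vocab$token_to_index), c("<PAD>", "<UNK>"))
  set.seed(seed)
  vecs <- setNames(lapply(toks, function(t) round(runif(dim, -0.5, 0.5), 6L)),
                   toks)
  write_embedding_file(vecs, path)
}

# Tiny corpora for model tests.
small_corpus <- function(n, seed) {
  generate_corpus(generator_config(n_docs = n, seed = seed,
                                   sentences_per_doc = c(3L, 5L)))
}
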