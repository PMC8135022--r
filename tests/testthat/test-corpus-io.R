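# Tokenization, sentence splitting, standoff I/O and BIOES coding.

test_that("tokenizer splits punctuation and letter/digit boundaries with exact offsets", {
  expect_identical(tokenize("1-2 Tablets PO")$surface,
                   c("1", "-", "2", "Tablets", "PO"))
  expect_identical(tokenize("aspirin325")$surface, c("aspirin", "325"))
  expect_identical(nrow(tokenize("")), 0L)
  expect_identical(nrow(tokenize("   \n\t ")), 0L)
  toks <- tokenize("Sig: 1-2 Tablets")
  expect_identical(toks$surface,
                   substring("Sig: 1-2 Tablets", toks$start + 1L, toks$end))
})

test_that("tokenization reconstructs the input from surfaces and gaps", {
  set.seed(404)
  texts <- c(
    "Bisacodyl 5 mg Tablet Sig: 1-2 Tablets PO once a day.",
    "Dig level 2.1 -- check q8h!\n\nNext  line\twith   tabs.",
    vapply(1:40, function(i) {
      paste(sample(c("mg", "25mg", "(1)", "q.d.", "x7d", "alpha-2", "\n",
                     "  ", "Aspirin325", ".", "?!"),
                   sample(1:12, 1L), replace = TRUE), collapse = " ")
    }, character(1L)))
  for (txt in texts) {
    toks <- tokenize(txt)
    rebuilt <- ""
    pos <- 0L
    for (i in seq_len(nrow(toks))) {
      rebuilt <- paste0(rebuilt, substring(txt, pos + 1L, toks$start[i]),
                        toks$surface[i])
      pos <- toks$end[i]
    }
    rebuilt <- paste0(rebuilt, substring(txt, pos + 1L, nchar(txt)))
    expect_identical(rebuilt, txt)
    # tokens non-overlapping and sorted
    if (nrow(toks) > 1L)
      expect_true(all(toks$start[-1L] >= toks$end[-nrow(toks)]))
  }
})

test_that("sentence splitting handles terminators, blank lines and list lines", {
  d <- doc_topiramate()
  expect_identical(nrow(d$sentences), 3L)
  # no terminators -> one sentence
  t1 <- tokenize("no terminator here at all")
  expect_identical(nrow(split_sentences("no terminator here at all", t1)), 1L)
  # blank line forces a boundary even without punctuation
  txt <- "first line no period\n\nSecond line"
  t2 <- tokenize(txt)
  expect_identical(nrow(split_sentences(txt, t2)), 2L)
  # numbered list lines split
  txt3 <- "Meds:\n1. Aspirin 81 mg daily\n2. Lisinopril 10 mg daily"
  t3 <- tokenize(txt3)
  s3 <- split_sentences(txt3, t3)
  expect_identical(nrow(s3), 3L)
  # sentences partition the tokens in order
  expect_identical(s3$first, c(1L, head(s3$last, -1L) + 1L))
  expect_identical(s3$last[nrow(s3)], nrow(t3))
})

test_that("read_standoff parses entities and relations and validates offsets", {
  txt <- "Aspirin 81 mg daily"
  ann <- paste0("T1\tDrug 0 7\tAspirin\n",
                "T2\tStrength 8 13\t81 mg\n",
                "T3\tFrequency 14 19\tdaily\n",
                "R1\tStrength-Drug Arg1:T2 Arg2:T1\n")
  d <- read_standoff(txt, ann, "x")
  expect_identical(nrow(d$entities), 3L)
  expect_identical(nrow(d$relations), 1L)
  expect_identical(d$entities$surface[d$entities$id == "T2"], "81 mg")
  # empty annotation content
  d0 <- read_standoff(txt, "", "x")
  expect_identical(nrow(d0$entities), 0L)
  expect_identical(nrow(d0$relations), 0L)
  # out-of-range offset is a format error
  expect_error(read_standoff(txt, "T1\tDrug 0 99\tAspirin", "x"),
               "out of range")
  # unknown entity type is a format error
  expect_error(read_standoff(txt, "T1\tGizmo 0 7\tAspirin", "x"), "unknown")
  # surface mismatch warns and trusts offsets
  expect_warning(d2 <- read_standoff(txt, "T1\tDrug 0 7\tNotThis", "x"),
                 "surface mismatch")
  expect_identical(d2$entities$surface, "Aspirin")
})

test_that("discontinuous standoff spans collapse to their envelope and are flagged", {
  txt <- "Aspirin 81 mg daily"
  d <- read_standoff(txt, "T1\tDrug 0 7;14 19\tAspirin daily", "x")
  expect_identical(d$entities$start, 0L)
  expect_identical(d$entities$end, 19L)
  expect_identical(attr(d, "load_report")$discontinuous, "T1")
})

test_that("standoff write/read round trip preserves annotations", {
  d <- doc_bisacodyl()
  out <- write_standoff(d)
  d2 <- read_standoff(out$txt_content, out$ann_content, d$doc_id)
  expect_identical(d$entities[, c("type", "start", "end")],
                   d2$entities[, c("type", "start", "end")])
  expect_identical(nrow(d$relations), nrow(d2$relations))
  # document with no entities writes an empty annotation file
  plain <- ann_doc("p", "No annotations here.")
  expect_identical(write_standoff(plain)$ann_content, "")
})

test_that("standoff round trip holds over many generated documents", {
  docs <- generate_corpus(generator_config(n_docs = 60L, seed = 321L))
  for (d in docs) {
    out <- write_standoff(d)
    d2 <- read_standoff(out$txt_content, out$ann_content, d$doc_id)
    expect_identical(d$entities[, c("type", "start", "end")],
                     d2$entities[, c("type", "start", "end")])
    key <- function(doc) {
      e <- doc$entities
      r <- doc$relations
      sort(paste(r$type,
                 e$start[match(r$attr_id, e$id)],
                 e$start[match(r$drug_id, e$id)]))
    }
    expect_identical(key(d), key(d2))
  }
})

test_that("BIOES encoding follows the scheme and resolves overlaps deterministically", {
  d <- doc_bisacodyl()
  labs <- encode_bioes(d)
  toks <- d$tokens
  expect_identical(length(labs), nrow(toks))
  expect_true(bioes_valid(labs))
  expect_identical(unname(labs[toks$surface == "Bisacodyl"]), "S-Drug")
  # "once a day" spans three tokens -> B/I/E
  i <- which(toks$surface == "once")
  expect_identical(unname(labs[i + 0:2]),
                   c("B-Frequency", "I-Frequency", "E-Frequency"))
  # overlap: longer span wins, loser logged
  d2 <- ann_doc("ov", "Aspirin extended release",
                data.frame(id = c("A", "B"), type = c("Drug", "Form"),
                           start = c(0L, 8L), end = c(24L, 16L),
                           surface = NA_character_))
  labs2 <- encode_bioes(d2)
  expect_identical(as.character(labs2), c("B-Drug", "I-Drug", "E-Drug"))
  expect_identical(attr(labs2, "conflicts"), "B")
})

test_that("BIOES decoding inverts encoding and repairs ill-formed fragments", {
  # encode -> decode round trip over generated documents
  docs <- generate_corpus(generator_config(n_docs = 40L, seed = 99L))
  for (d in docs) {
    ents <- decode_bioes(encode_bioes(d), d$tokens)
    expect_identical(ents[, c("type", "start", "end")],
                     d$entities[order(d$entities$start, d$entities$end),
                                c("type", "start", "end")],
                     info = d$doc_id)
  }
  toks <- tokenize("a b c d")
  # orphan I alone becomes an entity over its own extent
  e1 <- decode_bioes(c("O", "I-Route", "O", "O"), toks)
  expect_identical(e1[, c("type", "start", "end")],
                   data.frame(type = "Route", start = 2L, end = 3L))
  # unclosed B..I run ends at the last same-type tag
  e2 <- decode_bioes(c("B-Drug", "I-Drug", "O", "O"), toks)
  expect_identical(e2[, c("type", "start", "end")],
                   data.frame(type = "Drug", start = 0L, end = 3L))
  # valid pair decodes to a single two-token entity
  e3 <- decode_bioes(c("O", "B-Drug", "E-Drug", "O"), toks)
  expect_identical(e3[, c("type", "start", "end")],
                   data.frame(type = "Drug", start = 2L, end = 5L))
})
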