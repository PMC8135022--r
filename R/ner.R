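# BiLSTM-CRF named-entity recognizer.
#
# Pipeline per sentence: compose per-token representation vectors (word
# embedding, optionally character-BiLSTM feature, optionally
# semantic-feature embedding) -> bidirectional LSTM (300 hidden units per
# direction) -> linear projection to the 33 BIOES label scores -> CRF.
# Training is plain minibatch SGD (batch 32, lr 0.005) with dropout 0.5 on
# the composed token embeddings, early-stopped on development-set lenient
# micro-F with patience 10.  Sentences are batched and right-padded;
# padding is masked out of both the recurrence and the loss.

# ---- sentence preparation --------------------------------------------------

# Flatten documents into per-sentence items carrying everything training
# and prediction need.
prepare_sentences <- function(docs, vocab, config, tagger = lexicon_tagger,
                              with_gold = TRUE) {
  items <- list()
  use_sfe <- config$mode == "PWE+SFE"
  for (doc in docs) {
    labels <- if (with_gold) encode_bioes(doc) else NULL
    sfe <- if (use_sfe) sfe_index(tag_semantics(doc, tagger)) else NULL
    sents <- doc$sentences
    for (si in seq_len(nrow(sents))) {
      rng <- sents$first[si]:sents$last[si]
      items[[length(items) + 1L]] <- list(
        doc_id = doc$doc_id, sentence = si,
        word_idx = vocab_lookup(vocab, doc$tokens$surface[rng]),
        surfaces = doc$tokens$surface[rng],
        sfe_idx = if (use_sfe) sfe[rng] else NULL,
        gold = if (with_gold) as.character(labels[rng]) else NULL)
    }
  }
  items
}

# ---- batched encoder forward/backward -------------------------------------

# Forward pass over a batch of sentence items.  Returns per-step hidden
# states and emissions plus all caches needed for the backward pass.
ner_batch_forward <- function(mp, batch, config, training = FALSE) {
  B <- length(batch)
  lens <- vapply(batch, function(it) length(it$word_idx), integer(1L))
  Tmax <- max(lens)
  mask <- matrix(0, B, Tmax)
  widx <- matrix(1L, B, Tmax)  # pad row of E_word is zero
  for (k in seq_len(B)) {
    mask[k, seq_len(lens[k])] <- 1
    widx[k, seq_len(lens[k])] <- batch[[k]]$word_idx
  }
  use_char <- config$mode == "PWE+CE"
  use_sfe <- config$mode == "PWE+SFE"
  char_cache <- NULL; char_out <- NULL
  if (use_char) {
    surf <- character(B * Tmax)  # column-major: (t-1)*B + k
    for (k in seq_len(B))
      surf[(seq_len(lens[k]) - 1L) * B + k] <- batch[[k]]$surfaces
    char_cache <- char_encode_batch(surf, mp$char, config, keep_cache = TRUE)
    char_out <- char_cache$out
  }
  sidx <- NULL
  if (use_sfe) {
    sidx <- matrix(1L, B, Tmax)
    for (k in seq_len(B)) sidx[k, seq_len(lens[k])] <- batch[[k]]$sfe_idx
  }
  X <- vector("list", Tmax)
  drop_masks <- if (training && config$dropout > 0) vector("list", Tmax) else NULL
  keep <- 1 - config$dropout
  for (t in seq_len(Tmax)) {
    xt <- mp$E_word[widx[, t], , drop = FALSE]
    if (use_char)
      xt <- cbind(xt, char_out[(t - 1L) * B + seq_len(B), , drop = FALSE] * mask[, t])
    if (use_sfe)
      xt <- cbind(xt, mp$E_sfe[sidx[, t], , drop = FALSE] * mask[, t])
    if (!is.null(drop_masks)) {
      dm <- matrix(rbinom(length(xt), 1L, keep), nrow(xt), ncol(xt)) / keep
      drop_masks[[t]] <- dm
      xt <- xt * dm
    }
    X[[t]] <- xt
  }
  bi <- bilstm_forward(X, mask, mp$lstm_f, mp$lstm_b)
  E <- lapply(bi$H, function(h) sweep(h %*% mp$W, 2L, mp$b, "+"))
  list(B = B, lens = lens, Tmax = Tmax, mask = mask, widx = widx,
       sidx = sidx, X = X, bi = bi, E = E, char_cache = char_cache,
       drop_masks = drop_masks)
}

# Emission matrix (T x L) for sentence k of a forward pass.
emissions_of <- function(fw, k) {
  Tk <- fw$lens[k]
  t(vapply(seq_len(Tk), function(t) fw$E[[t]][k, ], numeric(ncol(fw$E[[1L]]))))
}

# Backward pass: dE is a list over t of B x L gradients on the emissions
# (zero rows at padded positions).  Returns gradient list mirroring mp.
ner_batch_backward <- function(mp, fw, config, dE) {
  Tmax <- fw$Tmax
  B <- fw$B
  dW <- mp$W * 0
  db <- mp$b * 0
  dH <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    dW <- dW + crossprod(fw$bi$H[[t]], dE[[t]])
    db <- db + colSums(dE[[t]])
    dH[[t]] <- dE[[t]] %*% t(mp$W)
  }
  bb <- bilstm_backward(fw$bi, mp$lstm_f, mp$lstm_b, dH)
  dX <- bb$dX
  if (!is.null(fw$drop_masks))
    dX <- Map(`*`, dX, fw$drop_masks)
  wd <- config$word_dim
  dE_word <- mp$E_word * 0
  use_char <- config$mode == "PWE+CE"
  use_sfe <- config$mode == "PWE+SFE"
  dChar_out <- if (use_char)
    matrix(0, B * Tmax, 2L * config$char_lstm_hidden) else NULL
  dE_sfe <- if (use_sfe) mp$E_sfe * 0 else NULL
  for (t in seq_len(Tmax)) {
    live <- which(fw$mask[, t] > 0)
    if (!length(live)) next
    dxt <- dX[[t]]
    agg <- rowsum(dxt[live, seq_len(wd), drop = FALSE],
                  group = fw$widx[live, t])
    rows <- as.integer(rownames(agg))
    dE_word[rows, ] <- dE_word[rows, , drop = FALSE] + agg
    if (use_char) {
      dChar_out[(t - 1L) * B + live, ] <-
        dxt[live, wd + seq_len(2L * config$char_lstm_hidden), drop = FALSE]
    }
    if (use_sfe) {
      aggs <- rowsum(dxt[live, wd + seq_len(config$sfe_dim), drop = FALSE],
                     group = fw$sidx[live, t])
      rs <- as.integer(rownames(aggs))
      dE_sfe[rs, ] <- dE_sfe[rs, , drop = FALSE] + aggs
    }
  }
  out <- list(E_word = dE_word, W = dW, b = db,
              lstm_f = bb$grads_fwd, lstm_b = bb$grads_bwd)
  if (use_char)
    out$char <- char_encode_backward(fw$char_cache, mp$char, config, dChar_out)
  if (use_sfe) out$E_sfe <- dE_sfe
  out
}

# ---- model construction ----------------------------------------------------

init_ner_params <- function(vocab, char_vocab, config, seed,
                            pretrained = NULL) {
  with_rng_seed(seed, {
    labels <- bioes_labels()
    d_in <- repr_dim(config)
    H <- config$lstm_hidden
    E_word <- if (config$mode == "RIWE" || is.null(pretrained)) {
      m <- matrix(runif(vocab$size * config$word_dim, -0.25, 0.25),
                  vocab$size, config$word_dim)
      m[vocab$pad_index, ] <- 0
      m
    } else pretrained
    mp <- list(E_word = E_word,
               lstm_f = lstm_params(d_in, H),
               lstm_b = lstm_params(d_in, H),
               W = glorot_init(2L * H, length(labels)),
               b = numeric(length(labels)),
               crf = crf_params(labels))
    if (config$mode == "PWE+CE")
      mp$char <- char_encoder_params(char_vocab, config,
                                     seed = sample.int(2^30, 1L))
    if (config$mode == "PWE+SFE")
      mp$E_sfe <- matrix(runif(length(sfe_levels()) * config$sfe_dim,
                               -0.25, 0.25),
                         length(sfe_levels()), config$sfe_dim)
    mp
  })
}

apply_ner_grads <- function(mp, grads, lr, scale) {
  s <- lr / scale
  mp$E_word <- mp$E_word - s * grads$E_word
  mp$W <- mp$W - s * grads$W
  mp$b <- mp$b - s * grads$b
  for (dir in c("lstm_f", "lstm_b")) {
    for (nm in c("Wx", "Wh", "b"))
      mp[[dir]][[nm]] <- mp[[dir]][[nm]] - s * grads[[dir]][[nm]]
  }
  mp$crf$transitions <- mp$crf$transitions - s * grads$crf_trans
  mp$crf$start_scores <- mp$crf$start_scores - s * grads$crf_start
  mp$crf$stop_scores <- mp$crf$stop_scores - s * grads$crf_stop
  if (!is.null(grads$char)) {
    mp$char$E <- mp$char$E - s * grads$char$dE
    for (dir in c("fwd", "bwd")) {
      gd <- if (dir == "fwd") grads$char$d_fwd else grads$char$d_bwd
      for (nm in c("Wx", "Wh", "b"))
        mp$char[[dir]][[nm]] <- mp$char[[dir]][[nm]] - s * gd[[nm]]
    }
  }
  if (!is.null(grads$E_sfe)) mp$E_sfe <- mp$E_sfe - s * grads$E_sfe
  mp
}

#' Train a BiLSTM-CRF entity recognizer
#'
#' @param train_docs List of gold-annotated [ann_doc()] objects.
#' @param dev_docs Validation documents for early stopping; if `NULL`,
#'   `dev_doc_count` documents are drawn from `train_docs` (seeded) and
#'   removed from the training split.
#' @param config A [repr_config()].
#' @param seed Integer seed controlling initialization, the dev split,
#'   shuffling and dropout; training is reproducible end to end.
#' @param dev_doc_count Development-set size when `dev_docs` is `NULL`.
#' @param embeddings Optional pretrained embedding matrix or path to a
#'   vector file (required meaning for PWE modes; ignored for RIWE).
#' @param tagger Semantic tagger for `PWE+SFE` mode (see
#'   [tag_semantics()]).
#' @param verbose Print per-epoch progress.
#' @return An object of class `ner_model` (parameters at the best dev
#'   epoch, vocabularies, config and training history).
#' @export
train_ner <- function(train_docs, dev_docs = NULL, config = repr_config(),
                      seed = 42L, dev_doc_count = 30L, embeddings = NULL,
                      tagger = lexicon_tagger, verbose = FALSE) {
  if (!length(train_docs)) stop("empty training set")
  if (is.null(dev_docs)) {
    if (length(train_docs) <= dev_doc_count)
      stop("training set too small to carve out ", dev_doc_count,
           " development documents")
    pick <- with_rng_seed(seed, sample.int(length(train_docs), dev_doc_count))
    dev_docs <- train_docs[pick]
    train_docs <- train_docs[-pick]
  }
  vocab <- build_vocab(train_docs)
  char_vocab <- build_char_vocab(train_docs)
  pretrained <- NULL
  if (config$mode != "RIWE") {
    if (is.null(embeddings))
      stop("mode ", config$mode, " needs pretrained embeddings ",
           "(matrix or vector-file path)")
    pretrained <- if (is.character(embeddings)) {
      load_pretrained_embeddings(embeddings, vocab, seed = seed)
    } else embeddings
    if (nrow(pretrained) != vocab$size)
      stop("pretrained embedding matrix does not cover the vocabulary")
    config$word_dim <- ncol(pretrained)
  }
  mp <- init_ner_params(vocab, char_vocab, config, seed, pretrained)
  items <- prepare_sentences(train_docs, vocab, config, tagger)
  if (!length(items)) stop("training set contains no sentences")
  model <- structure(list(params = mp, config = config, vocab = vocab,
                          char_vocab = char_vocab, seed = seed,
                          tagger = tagger),
                     class = "ner_model")
  best <- list(f = -Inf, params = mp, epoch = 0L)
  since_improve <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_micro_f = numeric())
  with_rng_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(items))
      total_nll <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        batch <- items[bs]
        fw <- ner_batch_forward(mp, batch, config, training = TRUE)
        L <- length(mp$crf$labels)
        dE <- lapply(seq_len(fw$Tmax), function(t) matrix(0, fw$B, L))
        g_trans <- mp$crf$transitions * 0
        g_start <- mp$crf$start_scores * 0
        g_stop <- mp$crf$stop_scores * 0
        for (k in seq_along(batch)) {
          em <- emissions_of(fw, k)
          gold_idx <- match(batch[[k]]$gold, mp$crf$labels)
          cg <- crf_nll_grad(em, mp$crf, gold_idx)
          total_nll <- total_nll + cg$nll
          for (t in seq_len(fw$lens[k])) dE[[t]][k, ] <- cg$d_emissions[t, ]
          g_trans <- g_trans + cg$d_transitions
          g_start <- g_start + cg$d_start
          g_stop <- g_stop + cg$d_stop
        }
        grads <- ner_batch_backward(mp, fw, config, dE)
        grads$crf_trans <- g_trans
        grads$crf_start <- g_start
        grads$crf_stop <- g_stop
        # Batch loss is the SUM of sentence NLLs (the usual convention for
        # CRF sequence trainers), so the step size is lr per batch.
        mp <- apply_ner_grads(mp, grads, config$lr, scale = 1)
      }
      model$params <- mp
      dev_pred <- lapply(dev_docs, function(d) {
        pd <- ann_doc(d$doc_id, d$text)
        pd$entities <- predict_entities(model, d)
        pd
      })
      dev_f <- evaluate_ner(dev_docs, dev_pred, "lenient")$micro[["f1"]]
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = total_nll / length(items),
        dev_micro_f = dev_f))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dev micro-F %.4f", epoch,
                        total_nll / length(items), dev_f))
      if (dev_f > best$f) {
        best <- list(f = dev_f, params = mp, epoch = epoch)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      if (since_improve >= config$patience) break
      if (best$f >= 1) break  # perfect dev score: no improvement possible
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$dev_micro_f <- best$f
  model
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model mode=%s vocab=%d best_epoch=%d dev micro-F=%.3f>\n",
              x$config$mode, x$vocab$size, x$best_epoch %||% NA,
              x$dev_micro_f %||% NA))
  invisible(x)
}

#' Per-token label scores for a document
#'
#' Runs the encoder (no dropout) over every sentence and stacks the label
#' score rows for all tokens in document order.
#'
#' @param model A trained `ner_model`.
#' @param doc An [ann_doc()].
#' @return `n_tokens` x 33 matrix (0-row for an empty document).
#' @export
emissions <- function(model, doc) {
  L <- length(model$params$crf$labels)
  if (!nrow(doc$tokens))
    return(matrix(0, 0L, L, dimnames = list(NULL, model$params$crf$labels)))
  items <- prepare_sentences(list(doc), model$vocab, model$config,
                             model$tagger %||% lexicon_tagger,
                             with_gold = FALSE)
  fw <- ner_batch_forward(model$params, items, model$config, training = FALSE)
  out <- do.call(rbind, lapply(seq_along(items),
                               function(k) emissions_of(fw, k)))
  colnames(out) <- model$params$crf$labels
  out
}

#' Predict entities in a document
#'
#' Viterbi decoding per sentence followed by BIOES span decoding; the
#' result is sorted by start offset.
#'
#' @param model A trained `ner_model`.
#' @param doc An [ann_doc()] (annotations, if any, are ignored).
#' @return Entity data.frame.
#' @export
predict_entities <- function(model, doc) {
  if (!nrow(doc$tokens)) return(empty_entities())
  items <- prepare_sentences(list(doc), model$vocab, model$config,
                             model$tagger %||% lexicon_tagger,
                             with_gold = FALSE)
  fw <- ner_batch_forward(model$params, items, model$config, training = FALSE)
  labels <- unlist(lapply(seq_along(items), function(k) {
    viterbi_decode(emissions_of(fw, k), model$params$crf)
  }), use.names = FALSE)
  decode_bioes_doc(labels, doc)
}

# Predict a parallel corpus of documents carrying predicted entities.
predict_corpus <- function(model, docs) {
  lapply(docs, function(d) {
    pd <- ann_doc(d$doc_id, d$text)
    pd$entities <- predict_entities(model, d)
    pd
  })
}

#' Majority-vote ensemble over entity prediction sets
#'
#' An entity `(type, start, end)` is kept iff it appears identically in
#' more than half of the prediction sets.  Overlapping winners are all
#' kept (no suppression); output is sorted by start, end, then type.
#'
#' @param predictions List of k entity data.frames over the same document.
#' @return Entity data.frame of majority entities.
#' @export
ensemble_vote <- function(predictions) {
  k <- length(predictions)
  stopifnot(k >= 1L)
  keys <- lapply(predictions, function(p) {
    if (!nrow(p)) return(character(0L))
    unique(paste(p$type, p$start, p$end, sep = "\r"))
  })
  tab <- table(unlist(keys, use.names = FALSE))
  win <- names(tab)[as.integer(tab) > k / 2]
  if (!length(win)) return(empty_entities())
  parts <- strsplit(win, "\r", fixed = TRUE)
  out <- data.frame(type = vapply(parts, `[`, character(1L), 1L),
                    start = as.integer(vapply(parts, `[`, character(1L), 2L)),
                    end = as.integer(vapply(parts, `[`, character(1L), 3L)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$type), , drop = FALSE]
  data.frame(id = paste0("T", seq_len(nrow(out))), type = out$type,
             start = out$start, end = out$end, surface = NA_character_,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter set plus config and vocabularies; the
#' round trip is exact.
#'
#' @param model A `ner_model` or `re_model`.
#' @param path File path.
#' @return `save_model` the path (invisibly); `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Composed per-token representation vectors
#'
#' The embedding-layer output actually fed to the BiLSTM (no dropout):
#' word vector, plus the character feature in `PWE+CE` mode, plus the
#' semantic-feature embedding in `PWE+SFE` mode.
#'
#' @param model A trained `ner_model`.
#' @param doc An [ann_doc()].
#' @return `n_tokens` x `repr_dim(config)` matrix.
#' @export
compose_representation <- function(model, doc) {
  d <- repr_dim(model$config)
  if (!nrow(doc$tokens)) return(matrix(0, 0L, d))
  items <- prepare_sentences(list(doc), model$vocab, model$config,
                             model$tagger %||% lexicon_tagger,
                             with_gold = FALSE)
  fw <- ner_batch_forward(model$params, items, model$config, training = FALSE)
  do.call(rbind, lapply(seq_along(items), function(k) {
    t(vapply(seq_len(fw$lens[k]), function(t) fw$X[[t]][k, ], numeric(d)))
  }))
}
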