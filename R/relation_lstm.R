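# Context-aware LSTM relation classifier.
#
# Every (attribute, drug) pair whose drug lies in the attribute's sentence
# or the two preceding sentences is a candidate.  The scope text covering
# both entities is encoded token by token as [word embedding | marker
# embedding] -- markers distinguish the target attribute, the target
# drug, other drug tokens, and everything else -- through a unidirectional
# LSTM whose final hidden state represents the pair.  The
# representations of the other candidates in the same scope are averaged
# into a context vector, and [pair | context] feeds a two-way softmax
# (related / unrelated).  Training uses the same SGD regime as the entity
# recognizer, with inverse-class-frequency loss weights because unrelated
# candidates dominate.

MARKER_LEVELS <- c("TARGET_DRUG", "TARGET_ATTR", "OTHER_DRUG", "OTHER")

#' Generate candidate attribute-drug pairs
#'
#' @param doc An [ann_doc()].
#' @param entities Entity set to pair (defaults to the document's own,
#'   i.e. gold; pass predicted entities for end-to-end use).
#' @param window How many sentences before the attribute's the drug may
#'   lie in.
#' @param label_from_gold Attach training labels (`related` iff the pair
#'   is among `doc$relations`).
#' @return List of candidate records: `attr_id`, `drug_id`, `rtype`,
#'   `group` (scope group key), token `range` (first:last token index of
#'   the scope), `marker` (marker level index per scope token) and
#'   `related` (logical or `NA`).
#' @export
generate_candidates <- function(doc, entities = doc$entities, window = 2L,
                                label_from_gold = TRUE) {
  if (!nrow(entities)) return(list())
  toks <- doc$tokens; sents <- doc$sentences
  ent_sent <- vapply(seq_len(nrow(entities)), function(k) {
    sentence_of_offset(toks, sents, entities$start[k])
  }, integer(1L))
  ent_tokens <- lapply(seq_len(nrow(entities)), function(k) {
    which(toks$start < entities$end[k] & toks$end > entities$start[k])
  })
  gold_keys <- if (label_from_gold && nrow(doc$relations)) {
    paste(doc$relations$attr_id, doc$relations$drug_id)
  } else character(0L)
  attrs <- which(entities$type != "Drug")
  drugs <- which(entities$type == "Drug")
  out <- list()
  for (a in attrs) {
    sa <- ent_sent[a]
    in_scope <- drugs[ent_sent[drugs] <= sa & ent_sent[drugs] >= sa - window]
    for (d in in_scope) {
      s_lo <- min(sa, ent_sent[d])
      rng <- sents$first[s_lo]:sents$last[sa]
      marker <- rep(4L, length(rng))  # OTHER
      for (od in drugs) {
        hit <- intersect(ent_tokens[[od]], rng)
        if (length(hit)) marker[match(hit, rng)] <- 3L  # OTHER_DRUG
      }
      marker[match(intersect(ent_tokens[[d]], rng), rng)] <- 1L
      marker[match(intersect(ent_tokens[[a]], rng), rng)] <- 2L
      out[[length(out) + 1L]] <- list(
        attr_id = entities$id[a], drug_id = entities$id[d],
        rtype = rtype_for(entities$type[a]),
        group = paste0(doc$doc_id, "#", sa),
        range = rng, marker = marker,
        related = if (label_from_gold) {
          paste(entities$id[a], entities$id[d]) %in% gold_keys
        } else NA)
    }
  }
  out
}

init_re_params <- function(vocab, config, seed) {
  with_rng_seed(seed, {
    H <- config$lstm_hidden
    E_word <- matrix(runif(vocab$size * config$word_dim, -0.25, 0.25),
                     vocab$size, config$word_dim)
    E_word[vocab$pad_index, ] <- 0
    list(E_word = E_word,
         E_marker = matrix(runif(length(MARKER_LEVELS) * config$marker_dim,
                                 -0.25, 0.25),
                           length(MARKER_LEVELS), config$marker_dim),
         lstm = lstm_params(config$word_dim + config$marker_dim, H),
         U = glorot_init(2L * H, 2L),
         b = numeric(2L))
  })
}

# Forward over a batch of candidate items (lists with word_idx, marker).
# Returns pair representations (B x H) plus caches.
re_batch_encode <- function(mp, batch, config) {
  B <- length(batch)
  lens <- vapply(batch, function(it) length(it$word_idx), integer(1L))
  Tmax <- max(lens)
  mask <- matrix(0, B, Tmax)
  widx <- matrix(1L, B, Tmax)
  midx <- matrix(1L, B, Tmax)
  for (k in seq_len(B)) {
    mask[k, seq_len(lens[k])] <- 1
    widx[k, seq_len(lens[k])] <- batch[[k]]$word_idx
    midx[k, seq_len(lens[k])] <- batch[[k]]$marker
  }
  X <- lapply(seq_len(Tmax), function(t) {
    cbind(mp$E_word[widx[, t], , drop = FALSE],
          mp$E_marker[midx[, t], , drop = FALSE] * mask[, t])
  })
  fwd <- lstm_forward(X, mask, mp$lstm, reverse = FALSE)
  list(R = fwd$final_h, fwd = fwd, mask = mask, widx = widx, midx = midx,
       B = B, Tmax = Tmax, lens = lens)
}

# Context means and softmax probabilities for one batch (whole groups).
re_batch_head <- function(mp, enc, groups) {
  B <- enc$B
  H <- ncol(enc$R)
  ctx <- matrix(0, B, H)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      s <- colSums(enc$R[idx, , drop = FALSE])
      ctx[idx, ] <- (matrix(s, length(idx), H, byrow = TRUE) -
                       enc$R[idx, , drop = FALSE]) / (length(idx) - 1L)
    }
  }
  feat <- cbind(enc$R, ctx)
  logits <- sweep(feat %*% mp$U, 2L, mp$b, "+")
  mx <- pmax(logits[, 1L], logits[, 2L])
  ez <- exp(logits - mx)
  probs <- ez / rowSums(ez)  # column 1 = related, column 2 = unrelated
  list(feat = feat, ctx = ctx, probs = probs)
}

# Backward from d(logits) through the head, context sharing, encoder and
# embeddings.  Returns parameter gradients.
re_batch_backward <- function(mp, enc, head, groups, dlogits, config) {
  B <- enc$B
  H <- ncol(enc$R)
  dU <- crossprod(head$feat, dlogits)
  db <- colSums(dlogits)
  dfeat <- dlogits %*% t(mp$U)
  dR <- dfeat[, seq_len(H), drop = FALSE]
  dctx <- dfeat[, H + seq_len(H), drop = FALSE]
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      s <- colSums(dctx[idx, , drop = FALSE])
      dR[idx, ] <- dR[idx, , drop = FALSE] +
        (matrix(s, length(idx), H, byrow = TRUE) -
           dctx[idx, , drop = FALSE]) / (length(idx) - 1L)
    }
  }
  bk <- lstm_backward(enc$fwd, mp$lstm, dfinal = dR)
  dE_word <- mp$E_word * 0
  dE_marker <- mp$E_marker * 0
  wd <- config$word_dim
  for (t in seq_len(enc$Tmax)) {
    live <- which(enc$mask[, t] > 0)
    if (!length(live)) next
    dxt <- bk$dX[[t]]
    agg <- rowsum(dxt[live, seq_len(wd), drop = FALSE],
                  group = enc$widx[live, t])
    rows <- as.integer(rownames(agg))
    dE_word[rows, ] <- dE_word[rows, , drop = FALSE] + agg
    aggm <- rowsum(dxt[live, wd + seq_len(config$marker_dim), drop = FALSE],
                   group = enc$midx[live, t])
    rm_ <- as.integer(rownames(aggm))
    dE_marker[rm_, ] <- dE_marker[rm_, , drop = FALSE] + aggm
  }
  list(E_word = dE_word, E_marker = dE_marker, lstm = bk$grads, U = dU, b = db)
}

apply_re_grads <- function(mp, grads, lr) {
  mp$E_word <- mp$E_word - lr * grads$E_word
  mp$E_marker <- mp$E_marker - lr * grads$E_marker
  for (nm in c("Wx", "Wh", "b"))
    mp$lstm[[nm]] <- mp$lstm[[nm]] - lr * grads$lstm[[nm]]
  mp$U <- mp$U - lr * grads$U
  mp$b <- mp$b - lr * grads$b
  mp
}

# Attach word indices to candidate items.
re_items <- function(doc, cands, vocab) {
  lapply(cands, function(cd) {
    cd$word_idx <- vocab_lookup(vocab, doc$tokens$surface[cd$range])
    cd
  })
}

# Pack candidate groups into batches of roughly batch_size without ever
# splitting a scope group (context means must see the whole group).
pack_group_batches <- function(groups, batch_size) {
  out <- list(); cur <- integer(0L)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(cur) && length(cur) + length(idx) > batch_size) {
      out[[length(out) + 1L]] <- cur
      cur <- integer(0L)
    }
    cur <- c(cur, idx)
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  out
}

#' Train the context-aware LSTM relation model
#'
#' Candidates are generated from gold entities and labelled from gold
#' relations; loss weights are inverse class frequencies.  Early stopping
#' monitors dev relation micro-F (lenient) with the configured patience.
#'
#' @param train_docs,dev_docs Gold-annotated [ann_doc()] lists.
#' @param config A [repr_config()] (`word_dim`, `marker_dim`,
#'   `lstm_hidden`, `lr`, `batch_size`, `max_epochs`, `patience` are
#'   used).
#' @param seed Integer seed; training is reproducible.
#' @param window Candidate scope window (sentences before the
#'   attribute's).
#' @param verbose Print per-epoch progress.
#' @return An object of class `re_model`.
#' @export
train_re <- function(train_docs, dev_docs, config = repr_config("RIWE"),
                     seed = 42L, window = 2L, verbose = FALSE) {
  if (!length(train_docs)) stop("empty training set")
  vocab <- build_vocab(train_docs)
  all_items <- list(); groups <- character(0L); labels <- logical(0L)
  for (doc in train_docs) {
    cands <- re_items(doc, generate_candidates(doc, window = window), vocab)
    for (cd in cands) {
      all_items[[length(all_items) + 1L]] <- cd
      groups <- c(groups, cd$group)
      labels <- c(labels, cd$related)
    }
  }
  if (!any(labels)) stop("no positively labelled candidate pairs in training data")
  n <- length(labels)
  w_pos <- n / (2 * sum(labels))
  w_neg <- n / (2 * sum(!labels))
  mp <- init_re_params(vocab, config, seed)
  model <- structure(list(params = mp, config = config, vocab = vocab,
                          seed = seed, window = window,
                          class_weights = c(related = w_pos,
                                            unrelated = w_neg)),
                     class = "re_model")
  best <- list(f = -Inf, params = mp, epoch = 0L)
  since_improve <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_micro_f = numeric())
  batches <- pack_group_batches(groups, config$batch_size)
  with_rng_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(batches))
      total_loss <- 0
      for (bi in ord) {
        idx <- batches[[bi]]
        batch <- all_items[idx]
        enc <- re_batch_encode(mp, batch, config)
        head_ <- re_batch_head(mp, enc, groups[idx])
        y <- ifelse(labels[idx], 1L, 2L)  # column of the true class
        w <- ifelse(labels[idx], w_pos, w_neg)
        p_true <- head_$probs[cbind(seq_along(idx), y)]
        total_loss <- total_loss + sum(-w * log(pmax(p_true, 1e-12)))
        dlogits <- head_$probs
        dlogits[cbind(seq_along(idx), y)] <-
          dlogits[cbind(seq_along(idx), y)] - 1
        dlogits <- dlogits * w
        grads <- re_batch_backward(mp, enc, head_, groups[idx], dlogits,
                                   config)
        mp <- apply_re_grads(mp, grads, config$lr)
      }
      model$params <- mp
      dev_pred <- lapply(dev_docs, function(d) {
        pd <- ann_doc(d$doc_id, d$text, d$entities)
        pd$relations <- predict_relations(model, d)
        pd
      })
      dev_f <- evaluate_relations(dev_docs, dev_pred, "lenient")$micro[["f1"]]
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = total_loss / n, dev_micro_f = dev_f))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dev micro-F %.4f", epoch,
                        total_loss / n, dev_f))
      if (dev_f > best$f) {
        best <- list(f = dev_f, params = mp, epoch = epoch)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      if (since_improve >= config$patience) break
      if (best$f >= 1) break
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$dev_micro_f <- best$f
  model
}

#' @export
print.re_model <- function(x, ...) {
  cat(sprintf("<re_model vocab=%d best_epoch=%d dev micro-F=%.3f>\n",
              x$vocab$size, x$best_epoch %||% NA, x$dev_micro_f %||% NA))
  invisible(x)
}

#' Encode one candidate pair
#'
#' The final LSTM hidden state over the candidate's scope (word plus
#' marker embeddings); deterministic given parameters.
#'
#' @param model A trained `re_model`.
#' @param doc The candidate's document.
#' @param candidate One record from [generate_candidates()].
#' @return Numeric vector of length `lstm_hidden`.
#' @export
encode_candidate <- function(model, doc, candidate) {
  it <- re_items(doc, list(candidate), model$vocab)
  enc <- re_batch_encode(model$params, it, model$config)
  drop(enc$R)
}

#' Classify a candidate pair given its context
#'
#' @param model A trained `re_model`.
#' @param pair_repr Encoding of the target pair.
#' @param context_reprs Matrix (rows = encodings of the other candidates
#'   in the same scope) or `NULL`; with no context the context block is
#'   the zero vector.
#' @return Probability that the pair is related (the two softmax outputs
#'   sum to one).
#' @export
classify_pair <- function(model, pair_repr, context_reprs = NULL) {
  H <- length(pair_repr)
  ctx <- if (is.null(context_reprs) || NROW(context_reprs) == 0L) {
    numeric(H)
  } else colMeans(matrix(context_reprs, ncol = H))
  logits <- drop(c(pair_repr, ctx) %*% model$params$U) + model$params$b
  ez <- exp(logits - max(logits))
  unname((ez / sum(ez))[1L])
}

#' Predict relations for a document
#'
#' @param model A trained `re_model`.
#' @param doc An [ann_doc()].
#' @param entities Entity set to link (defaults to the document's own).
#' @return Relation data.frame (pairs with p(related) > 0.5).
#' @export
predict_relations <- function(model, doc, entities = doc$entities) {
  cands <- generate_candidates(doc, entities, window = model$window,
                               label_from_gold = FALSE)
  if (!length(cands)) return(empty_relations())
  items <- re_items(doc, cands, model$vocab)
  groups <- vapply(cands, `[[`, character(1L), "group")
  enc <- re_batch_encode(model$params, items, model$config)
  head_ <- re_batch_head(model$params, enc, groups)
  keep <- which(head_$probs[, 1L] > 0.5)
  if (!length(keep)) return(empty_relations())
  data.frame(id = paste0("R", seq_along(keep)),
             type = vapply(cands[keep], `[[`, character(1L), "rtype"),
             attr_id = vapply(cands[keep], `[[`, character(1L), "attr_id"),
             drug_id = vapply(cands[keep], `[[`, character(1L), "drug_id"),
             stringsAsFactors = FALSE)
}
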