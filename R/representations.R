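# Token representations: vocabulary, word embeddings (random or
# pretrained), character-BiLSTM features, and semantic-feature embeddings.
#
# Word lookup is lower-cased; the character channel sees the original
# surface, since capitalization carries signal there.  All initialization
# is seeded, so vocabularies and matrices are bit-reproducible.

PAD_TOKEN <- "<PAD>"
UNK_TOKEN <- "<UNK>"

#' Representation configuration
#'
#' Defaults are the hyperparameters the models train with: 100-dimensional
#' random word embeddings (600 when pretrained vectors are supplied),
#' 25-dimensional character embeddings into a character BiLSTM with 25
#' hidden units per direction (so a 50-dimensional character feature),
#' 50-dimensional semantic-feature embeddings, a 300-per-direction token
#' BiLSTM, dropout 0.5 on composed token embeddings, SGD with learning
#' rate 0.005, batch size 32, at most 100 epochs with early-stopping
#' patience 10.
#'
#' @param mode One of `"RIWE"` (random word embeddings only), `"PWE"`
#'   (pretrained), `"PWE+CE"` (pretrained + character), `"PWE+SFE"`
#'   (pretrained + semantic features).
#' @param word_dim Word-embedding dimension; default 100 for RIWE and 600
#'   for pretrained modes (overridden by the pretrained file's dimension).
#' @param char_emb_dim,char_lstm_hidden Character channel sizes.
#' @param sfe_dim Semantic-feature embedding dimension.
#' @param lstm_hidden Token BiLSTM hidden size per direction.
#' @param dropout Dropout rate on composed token embeddings (training
#'   only).
#' @param lr,batch_size,max_epochs,patience SGD training controls.
#' @param marker_dim Marker-embedding dimension (relation model).
#' @return An object of class `repr_config`.
#' @export
repr_config <- function(mode = c("RIWE", "PWE", "PWE+CE", "PWE+SFE"),
                        word_dim = NULL, char_emb_dim = 25L,
                        char_lstm_hidden = 25L, sfe_dim = 50L,
                        lstm_hidden = 300L, dropout = 0.5, lr = 0.005,
                        batch_size = 32L, max_epochs = 100L, patience = 10L,
                        marker_dim = 10L) {
  mode <- match.arg(mode)
  if (is.null(word_dim)) word_dim <- if (mode == "RIWE") 100L else 600L
  stopifnot(word_dim > 0L, char_emb_dim > 0L, char_lstm_hidden > 0L,
            sfe_dim > 0L, lstm_hidden > 0L, dropout >= 0, dropout < 1,
            lr > 0, batch_size >= 1L, max_epochs >= 1L, patience >= 0L)
  structure(list(mode = mode, word_dim = as.integer(word_dim),
                 char_emb_dim = as.integer(char_emb_dim),
                 char_lstm_hidden = as.integer(char_lstm_hidden),
                 sfe_dim = as.integer(sfe_dim),
                 lstm_hidden = as.integer(lstm_hidden), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 marker_dim = as.integer(marker_dim)),
            class = "repr_config")
}

# Feature dimension of the composed token representation.
repr_dim <- function(config) {
  d <- config$word_dim
  if (config$mode == "PWE+CE") d <- d + 2L * config$char_lstm_hidden
  if (config$mode == "PWE+SFE") d <- d + config$sfe_dim
  d
}

#' Build a word vocabulary from a corpus
#'
#' Tokens are lower-cased; entries are ordered by frequency (descending)
#' then lexicographically, after the `<PAD>` and `<UNK>` specials, so the
#' vocabulary is deterministic.
#'
#' @param corpus List of [ann_doc()] objects.
#' @param min_count Tokens rarer than this map to `<UNK>` at lookup.
#' @return An object of class `vocabulary` (named index map; 1-based).
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  surf <- unlist(lapply(corpus, function(d) tolower(d$tokens$surface)),
                 use.names = FALSE)
  items <- character(0L)
  if (length(surf)) {
    tab <- table(surf)
    tab <- tab[tab >= min_count]
    if (length(tab)) {
      ord <- order(-as.integer(tab), names(tab), method = "radix")
      items <- names(tab)[ord]
    }
  }
  all_items <- c(PAD_TOKEN, UNK_TOKEN, items)
  structure(list(token_to_index = setNames(seq_along(all_items), all_items),
                 pad_index = 1L, unk_index = 2L, size = length(all_items)),
            class = "vocabulary")
}

#' Look up token indices in a vocabulary
#'
#' @param vocab A `vocabulary`.
#' @param surfaces Character vector of token surfaces.
#' @return Integer indices; unseen tokens map to `<UNK>`.
#' @export
vocab_lookup <- function(vocab, surfaces) {
  idx <- vocab$token_to_index[tolower(surfaces)]
  idx[is.na(idx)] <- vocab$unk_index
  unname(idx)
}

# Character vocabulary over surfaces seen in training (plus <UNK>).
build_char_vocab <- function(corpus) {
  chars <- unique(unlist(strsplit(
    unlist(lapply(corpus, function(d) d$tokens$surface), use.names = FALSE),
    "", fixed = TRUE), use.names = FALSE))
  all_items <- c(UNK_TOKEN, sort(chars, method = "radix"))
  structure(list(token_to_index = setNames(seq_along(all_items), all_items),
                 unk_index = 1L, size = length(all_items)),
            class = "vocabulary")
}

char_lookup <- function(char_vocab, surface) {
  if (!nzchar(surface)) return(integer(0L))
  idx <- char_vocab$token_to_index[strsplit(surface, "", fixed = TRUE)[[1L]]]
  idx[is.na(idx)] <- char_vocab$unk_index
  unname(idx)
}

#' Initialize a word-embedding matrix
#'
#' Uniform(-0.25, 0.25) entries under a fixed seed; the pad row is zero.
#'
#' @param vocab A `vocabulary`.
#' @param dim Embedding dimension.
#' @param seed RNG seed.
#' @return `vocab$size` x `dim` numeric matrix.
#' @export
random_embeddings <- function(vocab, dim, seed = 1L) {
  with_rng_seed(seed, {
    m <- matrix(runif(vocab$size * dim, -0.25, 0.25), vocab$size, dim)
    m[vocab$pad_index %||% 0L, ] <- 0
    m
  })
}

#' Load pretrained word embeddings from a plain-text vector file
#'
#' The file may open with a "count dim" header line; every other line is a
#' token followed by `dim` whitespace-separated numbers.  Vocabulary
#' tokens found in the file get the file's vector; absent tokens get small
#' uniform(-0.25, 0.25) vectors under the given seed.
#'
#' @param path Path to the vector file.
#' @param vocab A `vocabulary`.
#' @param seed Seed for the unknown-word vectors.
#' @return Embedding matrix with attribute `coverage` (fraction of
#'   non-special vocabulary tokens found in the file).
#' @export
load_pretrained_embeddings <- function(path, vocab, seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]  # header "count dim"
    if (!length(lines)) stop("embedding file has a header but no vectors")
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  dims <- vapply(parts, length, integer(1L)) - 1L
  if (length(unique(dims)) != 1L)
    stop("inconsistent embedding dimensionality across lines (",
         paste(unique(dims), collapse = ", "), ")")
  dim <- dims[1L]
  if (dim < 1L) stop("embedding file lines carry no vector components")
  toks <- tolower(vapply(parts, `[`, character(1L), 1L))
  vecs <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
                 ncol = dim, byrow = TRUE)
  if (anyNA(vecs)) stop("non-numeric vector components in embedding file")
  emb <- with_rng_seed(seed,
    matrix(runif(vocab$size * dim, -0.25, 0.25), vocab$size, dim))
  emb[vocab$pad_index, ] <- 0
  vnames <- names(vocab$token_to_index)
  hit <- match(vnames, toks)
  found <- which(!is.na(hit))
  emb[found, ] <- vecs[hit[found], , drop = FALSE]
  non_special <- setdiff(seq_len(vocab$size), c(vocab$pad_index, vocab$unk_index))
  coverage <- if (length(non_special)) {
    mean(!is.na(hit[non_special]))
  } else 1
  structure(emb, coverage = coverage)
}

# ---- character encoder -----------------------------------------------------

# Seeded parameter bundle for the character channel.
char_encoder_params <- function(char_vocab, config, seed = 1L) {
  with_rng_seed(seed, {
    list(E = matrix(runif(char_vocab$size * config$char_emb_dim, -0.25, 0.25),
                    char_vocab$size, config$char_emb_dim),
         fwd = lstm_params(config$char_emb_dim, config$char_lstm_hidden),
         bwd = lstm_params(config$char_emb_dim, config$char_lstm_hidden),
         char_vocab = char_vocab)
  })
}

# Batched character encoding: surfaces -> n x 2*char_hidden matrix of
# concatenated final forward/backward states.  Returns the caches needed
# for backprop when `keep_cache`.
char_encode_batch <- function(surfaces, cp, config, keep_cache = FALSE) {
  n <- length(surfaces)
  H <- config$char_lstm_hidden
  idx <- lapply(surfaces, function(s) char_lookup(cp$char_vocab, s))
  lens <- vapply(idx, length, integer(1L))
  Tmax <- max(lens, 1L)
  mask <- matrix(0, n, Tmax)
  im <- matrix(1L, n, Tmax)  # char row indices into E (1 = arbitrary pad)
  for (k in seq_len(n)) {
    if (lens[k]) {
      im[k, seq_len(lens[k])] <- idx[[k]]
      mask[k, seq_len(lens[k])] <- 1
    }
  }
  X <- lapply(seq_len(Tmax), function(t) cp$E[im[, t], , drop = FALSE] * mask[, t])
  fwd <- lstm_forward(X, mask, cp$fwd, reverse = FALSE)
  bwd <- lstm_forward(X, mask, cp$bwd, reverse = TRUE)
  out <- cbind(fwd$final_h, bwd$final_h)
  if (!keep_cache) return(out)
  list(out = out, fwd = fwd, bwd = bwd, im = im, mask = mask, n = n,
       Tmax = Tmax)
}

# Backward through the character channel; dOut is n x 2H.  Returns grads
# for E, fwd, bwd.
char_encode_backward <- function(cache, cp, config, dOut) {
  H <- config$char_lstm_hidden
  bf <- lstm_backward(cache$fwd, cp$fwd,
                      dfinal = dOut[, seq_len(H), drop = FALSE])
  bb <- lstm_backward(cache$bwd, cp$bwd,
                      dfinal = dOut[, H + seq_len(H), drop = FALSE])
  dE <- cp$E * 0
  for (t in seq_len(cache$Tmax)) {
    dXt <- (bf$dX[[t]] + bb$dX[[t]]) * cache$mask[, t]
    live <- which(cache$mask[, t] > 0)
    if (!length(live)) next
    agg <- rowsum(dXt[live, , drop = FALSE], group = cache$im[live, t])
    rows <- as.integer(rownames(agg))
    dE[rows, ] <- dE[rows, , drop = FALSE] + agg
  }
  list(dE = dE, d_fwd = bf$grads, d_bwd = bb$grads)
}

#' Encode a token surface with the character BiLSTM
#'
#' Concatenation of the final forward and backward hidden states (so a
#' vector of twice the character-LSTM hidden size).  Deterministic given
#' parameters; an empty surface yields the zero vector.
#'
#' @param token_surface A single string.
#' @param char_params Parameter bundle (embedding matrix plus forward and
#'   backward character LSTM parameters) as produced during training.
#' @param config A [repr_config()].
#' @return Numeric vector of length `2 * char_lstm_hidden`.
#' @export
char_encode <- function(token_surface, char_params, config = repr_config("PWE+CE")) {
  if (!nzchar(token_surface))
    return(numeric(2L * config$char_lstm_hidden))
  drop(char_encode_batch(token_surface, char_params, config))
}
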