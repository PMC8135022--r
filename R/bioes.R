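# BIOES tag encoding/decoding.
#
# Entities become per-token label sequences (B/I/E/S-<type> or O) and model
# output label sequences are folded back into character-offset entities.
# The decoder accepts ill-formed sequences (a CRF is not hard-constrained
# to emit valid BIOES) and repairs them conservatively.

#' Encode entity spans as a BIOES tag sequence
#'
#' An entity claims every token it overlaps (entity boundaries are expanded
#' to token boundaries).  When two entities claim the same token the longer
#' span wins, ties going to the earlier start; dropped entities are listed
#' in the `conflicts` attribute.
#'
#' @param doc An [ann_doc()].
#' @return Character vector of labels, one per token, with attribute
#'   `conflicts` (ids of entities dropped by overlap resolution).
#' @export
encode_bioes <- function(doc) {
  toks <- doc$tokens
  labels <- rep("O", nrow(toks))
  ents <- doc$entities
  conflicts <- character(0L)
  if (nrow(ents)) {
    ord <- order(-(ents$end - ents$start), ents$start)
    claimed <- logical(nrow(toks))
    for (k in ord) {
      cover <- which(toks$start < ents$end[k] & toks$end > ents$start[k])
      if (!length(cover)) next
      if (any(claimed[cover])) {
        conflicts <- c(conflicts, ents$id[k])
        next
      }
      claimed[cover] <- TRUE
      ty <- ents$type[k]
      if (length(cover) == 1L) {
        labels[cover] <- paste0("S-", ty)
      } else {
        labels[cover[1L]] <- paste0("B-", ty)
        labels[cover[length(cover)]] <- paste0("E-", ty)
        if (length(cover) > 2L)
          labels[cover[-c(1L, length(cover))]] <- paste0("I-", ty)
      }
    }
  }
  structure(labels, conflicts = conflicts)
}

#' Check BIOES validity of a label sequence
#'
#' Valid sequences contain only `O`, `S-type`, or `B-type (I-type)* E-type`
#' groups; `I`/`E` must continue a same-type open group.
#'
#' @param labels Character vector of labels.
#' @return `TRUE` or `FALSE`.
#' @export
bioes_valid <- function(labels) {
  open_type <- NA_character_
  for (lab in labels) {
    pre <- label_prefix(lab)
    ty <- label_type(lab)
    if (!is.na(open_type)) {
      if (pre == "I" && identical(ty, open_type)) next
      if (pre == "E" && identical(ty, open_type)) { open_type <- NA_character_; next }
      return(FALSE)  # open group interrupted
    }
    if (pre == "O" || pre == "S") next
    if (pre == "B") { open_type <- ty; next }
    return(FALSE)  # orphan I or E
  }
  is.na(open_type)
}

#' Decode a BIOES tag sequence into entities
#'
#' Valid `B..E` and `S` groups become entities spanning from the first
#' token's start to the last token's end.  Ill-formed fragments are
#' repaired conservatively: an orphan `I`/`E` run becomes an entity over
#' its own extent, and an unclosed `B I..` run ends at the last same-type
#' tag.
#'
#' @param labels Character vector of labels aligned to `tokens`.
#' @param tokens Token table from [tokenize()].
#' @return Entity data.frame (`id`, `type`, `start`, `end`, `surface` =
#'   `NA`) sorted by start offset.
#' @export
decode_bioes <- function(labels, tokens) {
  stopifnot(length(labels) == nrow(tokens))
  out <- list()
  t <- 1L
  n <- length(labels)
  while (t <= n) {
    lab <- labels[t]
    if (lab == "O") { t <- t + 1L; next }
    pre <- label_prefix(lab)
    ty <- label_type(lab)
    if (pre == "S" || pre == "E") {
      j <- t
    } else {  # B or orphan I: absorb following same-type I's, then one E
      j <- t
      while (j < n && labels[j + 1L] == paste0("I-", ty)) j <- j + 1L
      if (j < n && labels[j + 1L] == paste0("E-", ty)) j <- j + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      type = ty, start = tokens$start[t], end = tokens$end[j],
      stringsAsFactors = FALSE)
    t <- j + 1L
  }
  if (!length(out)) return(empty_entities())
  ents <- do.call(rbind, out)
  ents <- ents[order(ents$start, ents$end), , drop = FALSE]
  data.frame(id = paste0("T", seq_len(nrow(ents))), type = ents$type,
             start = ents$start, end = ents$end, surface = NA_character_,
             stringsAsFactors = FALSE)
}

# Decode and attach surfaces from the document text.
decode_bioes_doc <- function(labels, doc) {
  ents <- decode_bioes(labels, doc$tokens)
  if (nrow(ents)) ents$surface <- substr0(doc$text, ents$start, ents$end)
  ents
}
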