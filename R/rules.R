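# Deterministic drug-attribute linker.
#
# Within a sentence: one drug gets every attribute; several drugs split the
# sentence into segments starting at each drug name, and each segment's
# attributes link to its anchor drug (text before the first drug belongs to
# the first segment).  A sentence with attributes but no drug looks back up
# to `window` previous sentences and links everything to the closest
# preceding drug.  This reproduces the behaviour -- and the known blind
# spot -- of segmentation rules: a reason shared by two drugs in one
# sentence yields only the link to the nearer drug.

#' Split one sentence into drug-anchored segments
#'
#' @param doc An [ann_doc()].
#' @param sentence_index 1-based sentence index.
#' @return data.frame with columns `sentence_index`, `start`, `end`
#'   (character span of the segment) and `anchor_id` (drug entity id or
#'   `NA` when the sentence has no drug).
#' @export
segment_sentence_by_drugs <- function(doc, sentence_index) {
  sp <- sentence_char_span(doc$tokens, doc$sentences, sentence_index)
  ents <- entities_in_span(doc$entities, sp)
  drugs <- ents[ents$type == "Drug", , drop = FALSE]
  drugs <- drugs[order(drugs$start), , drop = FALSE]
  n <- nrow(drugs)
  if (n == 0L) {
    return(data.frame(sentence_index = sentence_index, start = sp[1L],
                      end = sp[2L], anchor_id = NA_character_,
                      stringsAsFactors = FALSE))
  }
  # Segment i runs from drug i's start (segment 1 from the sentence start,
  # so pre-first-drug attributes attach to drug 1) to drug i+1's start.
  seg_start <- c(sp[1L], drugs$start[-1L])
  seg_end <- c(drugs$start[-1L], sp[2L])
  data.frame(sentence_index = sentence_index, start = seg_start,
             end = seg_end, anchor_id = drugs$id, stringsAsFactors = FALSE)
}

entities_in_span <- function(entities, span) {
  if (!nrow(entities)) return(entities)
  entities[entities$start >= span[1L] & entities$start < span[2L], ,
           drop = FALSE]
}

#' Link attributes to drugs with sentence segmentation and lookback
#'
#' @param doc An [ann_doc()] carrying the entities to link (gold or
#'   predicted).
#' @param window Number of previous sentences searched when the current
#'   sentence has attributes but no drug.
#' @return Relation data.frame (`id`, `type`, `attr_id`, `drug_id`).
#' @export
link_with_lookback <- function(doc, window = 2L) {
  ents <- doc$entities
  out <- list()
  n_sent <- nrow(doc$sentences)
  for (si in seq_len(n_sent)) {
    sp <- sentence_char_span(doc$tokens, doc$sentences, si)
    here <- entities_in_span(ents, sp)
    attrs <- here[here$type != "Drug", , drop = FALSE]
    if (!nrow(attrs)) next
    has_drug <- any(here$type == "Drug")
    if (has_drug) {
      segs <- segment_sentence_by_drugs(doc, si)
      for (k in seq_len(nrow(attrs))) {
        seg <- which(segs$start <= attrs$start[k] & attrs$start[k] < segs$end)
        if (!length(seg)) next
        out[[length(out) + 1L]] <- c(attr = attrs$id[k],
                                     drug = segs$anchor_id[seg[1L]])
      }
    } else {
      # Lookback: closest preceding drug within `window` sentences,
      # distance measured from attribute start to drug end.
      lo <- max(1L, si - window)
      if (lo > si - 1L) next
      prev_span <- c(sentence_char_span(doc$tokens, doc$sentences, lo)[1L],
                     sp[1L])
      cand <- entities_in_span(ents, prev_span)
      cand <- cand[cand$type == "Drug", , drop = FALSE]
      if (!nrow(cand)) next
      for (k in seq_len(nrow(attrs))) {
        dist <- attrs$start[k] - cand$end
        dist[dist < 0] <- Inf  # only preceding drugs
        if (all(!is.finite(dist))) next
        out[[length(out) + 1L]] <- c(attr = attrs$id[k],
                                     drug = cand$id[which.min(dist)])
      }
    }
  }
  if (!length(out)) return(empty_relations())
  pairs <- unique(do.call(rbind, out))
  attr_ty <- ents$type[match(pairs[, "attr"], ents$id)]
  data.frame(id = paste0("R", seq_len(nrow(pairs))),
             type = rtype_for(attr_ty),
             attr_id = unname(pairs[, "attr"]),
             drug_id = unname(pairs[, "drug"]),
             stringsAsFactors = FALSE)
}

#' Rule-based relation extraction
#'
#' Deterministic in (text, entities); the entity list order does not
#' affect the result.
#'
#' @param doc An [ann_doc()] with entities (gold or predicted).
#' @param window Lookback window in sentences.
#' @return Relation data.frame with no duplicate (attribute, drug) pairs.
#' @export
extract_relations_rules <- function(doc, window = 2L) {
  link_with_lookback(doc, window = window)
}
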