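# Offset-faithful tokenization and sentence splitting.
#
# The contract that matters downstream is offset fidelity: every token
# records the exact 0-based half-open character span it came from, so
# entity spans predicted over tokens can be projected back onto the raw
# text.  The rule set (split punctuation, split letter/digit boundaries) is
# deliberately simple and swappable: any tokenizer producing exact offsets
# can be substituted.

#' Tokenize text with exact character offsets
#'
#' Tokens are maximal runs of letters, maximal runs of digits, or single
#' punctuation characters; whitespace separates but never appears inside a
#' token.  Letter/digit boundaries are split, so glued forms like
#' `"aspirin325"` become two tokens.
#'
#' @param text A single string.
#' @return A data.frame with columns `index` (1-based), `start`, `end`
#'   (0-based half-open character offsets) and `surface`.  Empty text gives
#'   zero rows.
#' @examples
#' tokenize("1-2 Tablets PO")$surface
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alpha:]]+|[[:digit:]]+|[^[:alnum:][:space:]]", text,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(index = seq_along(starts), start = starts,
             end = starts + lens,
             surface = substring(text, starts + 1L, starts + lens),
             stringsAsFactors = FALSE)
}

#' Split a tokenized text into sentences
#'
#' Boundaries are placed after sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace and an uppercase letter or digit, at blank lines,
#' and before list-item line starts (`-`, `*`, or `1.` / `1)` at the start
#' of a line) -- discharge-summary medication lists are line-oriented and
#' rarely carry periods.
#'
#' @param text The raw text.
#' @param tokens Token table from [tokenize()] on the same text.
#' @return A data.frame with columns `index`, `first` and `last` (1-based
#'   token indices, inclusive).  Sentences partition the token sequence.
#' @export
split_sentences <- function(text, tokens) {
  n <- nrow(tokens)
  empty <- data.frame(index = integer(), first = integer(), last = integer())
  if (n == 0L) return(empty)
  boundary_after <- logical(n)  # boundary between token i and i+1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gap <- substr0(text, tokens$end[i], tokens$start[i + 1L])
      nxt <- tokens$surface[i + 1L]
      list_marker_dot <- tokens$surface[i] == "." && i >= 2L &&
        is_list_item_start(tokens, i - 1L) &&
        (i == 2L || grepl("\n", substr0(text, tokens$end[i - 2L],
                                        tokens$start[i - 1L]), fixed = TRUE))
      if (tokens$surface[i] %in% c(".", "!", "?") && !list_marker_dot &&
          grepl("^[[:space:]]", gap) && grepl("^[A-Z0-9]", nxt)) {
        boundary_after[i] <- TRUE
      } else if (grepl("\n[ \t]*\n", gap)) {
        boundary_after[i] <- TRUE
      } else if (grepl("\n", gap, fixed = TRUE) && is_list_item_start(tokens, i + 1L)) {
        boundary_after[i] <- TRUE
      }
    }
  }
  last <- c(which(boundary_after[-n]), n)
  last <- sort(unique(last))
  first <- c(1L, head(last, -1L) + 1L)
  data.frame(index = seq_along(first), first = first, last = last)
}

# A token opens a list item if it is a bullet, or a number followed by "."
# or ")" (e.g. "1. Aspirin ...").
is_list_item_start <- function(tokens, i) {
  s <- tokens$surface[i]
  if (s %in% c("-", "*")) return(TRUE)
  if (grepl("^[0-9]+$", s) && i < nrow(tokens) &&
      tokens$surface[i + 1L] %in% c(".", ")") &&
      tokens$end[i] == tokens$start[i + 1L]) {
    return(TRUE)
  }
  FALSE
}

# Sentence char span (0-based half-open), covering first token start to
# last token end.
sentence_char_span <- function(tokens, sentences, si) {
  c(tokens$start[sentences$first[si]], tokens$end[sentences$last[si]])
}

# Sentence index containing char offset `pos` (start offset of an entity).
sentence_of_offset <- function(tokens, sentences, pos) {
  for (si in seq_len(nrow(sentences))) {
    sp <- sentence_char_span(tokens, sentences, si)
    if (pos >= sp[1L] && pos < sp[2L]) return(si)
  }
  # Offsets in inter-sentence gaps attach to the following sentence.
  after <- which(tokens$start[sentences$first] > pos)
  if (length(after)) after[1L] else nrow(sentences)
}
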