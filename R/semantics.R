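# Token-level clinical semantic tags feeding the semantic-feature
# embeddings.  Two sources: a built-in lexicon/regex tagger (drug
# morphemes -> Medication, problem word lists -> Problem/DiseaseDisorder/
# SignSymptom, date-time patterns -> Temporal) and a TSV adapter for tags
# produced by external clinical pipelines.  Tags from two taggers are
# merged per token with a fixed specificity precedence.

semantic_categories <- function() {
  c("O", "Problem", "Treatment", "Temporal", "Medication",
    "DiseaseDisorder", "SignSymptom")
}

# More specific clinical category wins on conflict.
semantic_precedence <- c(Medication = 6, DiseaseDisorder = 5, SignSymptom = 4,
                         Problem = 3, Treatment = 2, Temporal = 1, O = 0)

semantic_tags_frame <- function(category, assertion = NULL) {
  if (is.null(assertion)) assertion <- rep("none", length(category))
  stopifnot(all(category %in% semantic_categories()),
            all(assertion %in% c("present", "absent", "none")))
  # Only Problem carries assertions.
  assertion[category != "Problem"] <- "none"
  data.frame(category = category, assertion = assertion,
             stringsAsFactors = FALSE)
}

# Built-in lexicon content --------------------------------------------------

sem_drug_suffixes <- c("olol", "pril", "mycin", "cillin", "statin", "azole",
                       "azepam", "profen", "sartan", "mab", "oxetine",
                       "idone", "amine", "afil", "icin", "dine", "zide")
sem_medication_words <- c("aspirin", "insulin", "warfarin", "heparin",
                          "tylenol", "ibuprofen", "acetaminophen")
sem_sign_symptom <- c("pain", "cough", "fever", "nausea", "wheezing",
                      "agitation", "dizziness", "fatigue", "rash",
                      "headache", "vomiting")
sem_disease_disorder <- c("hypertension", "diabetes", "infection",
                          "pneumonia", "anemia", "sepsis", "copd",
                          "asthma", "seizures", "afib", "insomnia",
                          "constipation", "anxiety")
sem_problem_words <- c("problem", "complaint", "bleeding", "swelling",
                       "weakness", "distress", "failure", "breath")
sem_treatment_words <- c("surgery", "therapy", "transfusion", "dialysis",
                         "procedure", "operation", "chemo", "radiation")
sem_temporal_words <- c("today", "tomorrow", "yesterday", "daily", "weeks",
                        "week", "days", "day", "months", "month", "hours",
                        "years", "am", "pm", "morning", "evening", "night",
                        "january", "february", "march", "april", "may",
                        "june", "july", "august", "september", "october",
                        "november", "december")
sem_negation_words <- c("no", "denies", "without", "not")

#' Tag document tokens with the built-in semantic lexicon
#'
#' A light stand-in for a full clinical tagging pipeline: drug morphemes
#' and common medication words map to `Medication`, disease/sign word
#' lists to `DiseaseDisorder`/`SignSymptom`, generic problem words to
#' `Problem` (with `absent` assertion when a negation word appears within
#' the three preceding tokens, `present` otherwise), treatment words to
#' `Treatment`, and date/time words or numeric date patterns to
#' `Temporal`.  Unknown tokens are `O`.
#'
#' @param doc An [ann_doc()].
#' @return data.frame with one row per token: `category`, `assertion`.
#' @export
lexicon_tagger <- function(doc) {
  surf <- doc$tokens$surface
  low <- tolower(surf)
  n <- length(surf)
  cat <- rep("O", n)
  assertion <- rep("none", n)
  date_re <- "^[0-9]{1,2}/[0-9]{1,4}$"
  for (k in seq_len(n)) {
    w <- low[k]
    if (w %in% sem_medication_words ||
        (nchar(w) >= 6L && any(endsWith(w, sem_drug_suffixes)))) {
      cat[k] <- "Medication"
    } else if (w %in% sem_disease_disorder) {
      cat[k] <- "DiseaseDisorder"
    } else if (w %in% sem_sign_symptom) {
      cat[k] <- "SignSymptom"
    } else if (w %in% sem_problem_words) {
      cat[k] <- "Problem"
      ctx <- low[max(1L, k - 3L):k]
      assertion[k] <- if (any(ctx %in% sem_negation_words)) "absent" else "present"
    } else if (w %in% sem_treatment_words) {
      cat[k] <- "Treatment"
    } else if (w %in% sem_temporal_words || grepl(date_re, w)) {
      cat[k] <- "Temporal"
    }
  }
  semantic_tags_frame(cat, assertion)
}

#' Read per-token semantic tags from a TSV file
#'
#' Expected format: one `token<TAB>category<TAB>assertion` line per token
#' (assertion column optional; blank lines between sentences are
#' ignored).  The token count must match the document's tokenization.
#'
#' @param doc An [ann_doc()].
#' @param path TSV path.
#' @return data.frame of `category`, `assertion`, one row per token.
#' @export
read_semantic_tsv <- function(doc, path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) != nrow(doc$tokens))
    stop("semantic TSV has ", length(parts), " tokens but document '",
         doc$doc_id, "' has ", nrow(doc$tokens))
  cat <- vapply(parts, `[`, character(1L), 2L)
  assertion <- vapply(parts, function(p) {
    if (length(p) >= 3L && nzchar(p[3L])) p[3L] else "none"
  }, character(1L))
  semantic_tags_frame(cat, assertion)
}

#' Merge two aligned semantic tag sequences
#'
#' Per token: if both are `O` the result is `O`; if exactly one is non-`O`
#' that tag wins; if both are non-`O` the more specific clinical category
#' wins (Medication > DiseaseDisorder > SignSymptom > Problem > Treatment >
#' Temporal), carrying the winner's assertion.
#'
#' @param tags_a,tags_b data.frames from a tagger, aligned to the same
#'   token sequence.
#' @return Merged tag data.frame.
#' @export
merge_semantic_tags <- function(tags_a, tags_b) {
  if (nrow(tags_a) != nrow(tags_b))
    stop("semantic tag sequences have different lengths")
  if (!nrow(tags_a)) return(semantic_tags_frame(character(0L)))
  a_wins <- semantic_precedence[tags_a$category] >=
    semantic_precedence[tags_b$category]
  semantic_tags_frame(ifelse(a_wins, tags_a$category, tags_b$category),
                      ifelse(a_wins, tags_a$assertion, tags_b$assertion))
}

#' Tag a document's tokens with semantic features
#'
#' @param doc An [ann_doc()].
#' @param tagger Either a function `doc -> tag data.frame` (default the
#'   built-in [lexicon_tagger()]) or a path to a semantic TSV file.
#' @return data.frame of `category`, `assertion`, one row per token.
#' @export
tag_semantics <- function(doc, tagger = lexicon_tagger) {
  tags <- if (is.character(tagger)) read_semantic_tsv(doc, tagger)
          else tagger(doc)
  if (nrow(tags) != nrow(doc$tokens))
    stop("tagger returned ", nrow(tags), " tags for ", nrow(doc$tokens),
         " tokens")
  tags
}

# Index of each (category, assertion) combination in the SFE embedding
# matrix: O, Medication, DiseaseDisorder, SignSymptom, Treatment,
# Temporal, Problem:present, Problem:absent.
sfe_levels <- function() {
  c("O", "Medication", "DiseaseDisorder", "SignSymptom", "Treatment",
    "Temporal", "Problem:present", "Problem:absent")
}

sfe_index <- function(tags) {
  key <- ifelse(tags$category == "Problem",
                paste0("Problem:",
                       ifelse(tags$assertion == "absent", "absent", "present")),
                tags$category)
  match(key, sfe_levels())
}
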