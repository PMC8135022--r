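# Synthetic discharge-summary corpus generator.
#
# Emulates the annotation structure this package is built for: prescription
# list lines ("Drug 325 mg Tablet Sig: 1-2 Tablet PO BID as needed for
# pain."), narrative prescription sentences, multi-drug sentences with
# per-segment attributes, reasons shared across two drugs, and follow-up
# sentences whose attributes refer back to a drug one or two sentences
# earlier.  Drug names are composed from random stems plus common
# pharmaceutical suffixes so that they are novel strings (the character
# channel has to generalize, not memorize).  Gold relations are derived
# from the generating template, never from the rule linker, so rule-based
# relation extraction can be scored honestly against them.

#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the corpus structure the package assumes: the eight
#' entity types in proportions close to large annotated prescription
#' corpora (drugs roughly a third of entities; duration rare), 17% of
#' reason entities shared between two drugs, and a mix of list-style and
#' narrative sentences with occasional cross-sentence attribute placement.
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed; the generated corpus is byte-identical across
#'   runs with the same seed.
#' @param sentences_per_doc Inclusive range (length-2 integer) of content
#'   sentences per document.
#' @param p_list_line Probability that a single-drug sentence is a
#'   structured "Sig:" list line rather than narrative.
#' @param p_multi_drug_sentence Probability of a two-drug segmented
#'   sentence.
#' @param p_shared_reason Probability that a sentence carrying a reason
#'   shares that reason between two drugs.
#' @param p_lookback Probability that a sentence following a drug-bearing
#'   sentence is an attribute-only continuation linking back to that drug.
#' @param type_mix Named numeric vector of target entity-type proportions
#'   (normalized internally).
#' @param noise List with elements `abbreviation` (rate of abbreviated
#'   route/frequency variants), `misspelling` (rate of single-character
#'   drug-name mutations) and `glue` (rate of glued drug+strength tokens
#'   such as "aspirin325").
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_docs = 300L,
                             seed = 20180101L,
                             sentences_per_doc = c(4L, 7L),
                             p_list_line = 0.6,
                             p_multi_drug_sentence = 0.12,
                             p_shared_reason = 0.17,
                             p_lookback = 0.18,
                             type_mix = default_type_mix(),
                             noise = list(abbreviation = 0.35,
                                          misspelling = 0.04,
                                          glue = 0.05)) {
  stopifnot(n_docs >= 0L, length(sentences_per_doc) == 2L,
            sentences_per_doc[1L] >= 1L,
            sentences_per_doc[2L] >= sentences_per_doc[1L])
  probs <- c(p_list_line, p_multi_drug_sentence, p_shared_reason, p_lookback)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(entity_types() %in% names(type_mix)))
    stop("type_mix must name all eight entity types")
  if (sum(type_mix) <= 0) stop("type_mix must have positive mass")
  type_mix <- type_mix[entity_types()] / sum(type_mix[entity_types()])
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 p_list_line = p_list_line,
                 p_multi_drug_sentence = p_multi_drug_sentence,
                 p_shared_reason = p_shared_reason,
                 p_lookback = p_lookback,
                 type_mix = type_mix, noise = noise),
            class = "generator_config")
}

#' Default entity-type proportions
#'
#' Drug about a third of all entities; form/strength/frequency each about
#' an eighth; duration rare.
#' @return Named numeric vector summing to 1.
#' @export
default_type_mix <- function() {
  mix <- c(Drug = 32.57, Form = 13.38, Strength = 13.27, Frequency = 12.51,
           Route = 10.92, Dosage = 8.39, Reason = 7.78, Duration = 1.2)
  mix / sum(mix)
}

# ---- template bank ---------------------------------------------------------

tb_strength_nums <- c("5", "10", "20", "25", "40", "50", "75", "81", "100",
                      "150", "200", "250", "325", "500", "650", "1000")
tb_strength_units <- c("mg", "mg", "mg", "mg", "mcg", "units", "mEq", "g")
tb_dosages <- c("1-2", "One (1)", "2", "one", "1/2", "Two (2)", "3", "0.5")
tb_forms <- c("Tablet", "Tablets", "Capsule", "tablet", "capsules",
              "Solution", "Patch", "puffs")
tb_routes_full <- c("Intravenous", "by mouth", "topical", "per os",
                    "subcutaneous", "inhalation")
tb_routes_abbr <- c("PO", "po", "IV", "SC", "PR", "SL")
tb_freq_full <- c("once a day", "twice a day", "every eight (8) hours",
                  "every 4 hours", "at bedtime", "three times a day",
                  "every morning")
tb_freq_abbr <- c("BID", "QHS", "TID", "QID", "daily", "q8h", "qAM", "od")
tb_durations <- c("for 5 days", "for seven days", "x7d", "for 2 weeks",
                  "for the first four weeks", "for 10 days", "for 3 months")
tb_reasons <- c("pain", "constipation", "cough", "anxiety", "fever",
                "nausea", "insomnia", "infection", "hypertension",
                "high blood pressure", "shortness of breath", "seizures",
                "agitation", "wheezing")
tb_drug_stems <- c("lor", "met", "ato", "flu", "cef", "pro", "ami", "ker",
                   "dol", "vax", "zol", "tri", "ban", "sel", "nor", "pir",
                   "gab", "ral", "tem", "car", "fen", "lev", "ox", "dar")
tb_drug_mids <- c("a", "o", "i", "e", "ti", "ro", "mi", "va", "le", "",
                  "do", "ne")
tb_drug_suffixes <- c("olol", "pril", "mycin", "cillin", "statin", "azole",
                      "azepam", "profen", "sartan", "mab", "oxetine",
                      "idone", "amine", "afil")
tb_fillers <- c("He was seen in clinic today.",
                "She tolerated the procedure well.",
                "Follow up with primary care in two weeks.",
                "Vital signs were stable on discharge.")
tb_narrative_prefixes <- c("Patient will be on ", "He was started on ",
                           "She was given ", "Continue ", "Will start ",
                           "Started on ")
tb_lookback_prefixes <- c("Then increase to ", "Then decrease to ",
                          "May increase to ", "Titrate to ")

gen_drug_name <- function(noise) {
  name <- paste0(sample(tb_drug_stems, 1L), sample(tb_drug_mids, 1L),
                 sample(tb_drug_suffixes, 1L))
  if (runif(1L) < noise$misspelling && nchar(name) > 4L) {
    pos <- sample(2:(nchar(name) - 1L), 1L)
    substr(name, pos, pos) <- sample(letters, 1L)
  }
  paste0(toupper(substr(name, 1L, 1L)), substring(name, 2L))
}

gen_strength <- function(glued = FALSE) {
  num <- sample(tb_strength_nums, 1L)
  if (glued) paste0(num, "mg") else paste(num, sample(tb_strength_units, 1L))
}

gen_route <- function(noise) {
  if (runif(1L) < noise$abbreviation) sample(tb_routes_abbr, 1L)
  else sample(tb_routes_full, 1L)
}

gen_freq <- function(noise) {
  if (runif(1L) < noise$abbreviation) sample(tb_freq_abbr, 1L)
  else sample(tb_freq_full, 1L)
}

# ---- sentence assembly -----------------------------------------------------

# A sentence under construction: text chunks plus entities with offsets
# relative to the sentence start, and relations over local entity indices.
new_sentence <- function() {
  list(chunks = character(0L), len = 0L,
       ents = data.frame(type = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE),
       rels = data.frame(attr = integer(), drug = integer()))
}

sent_add <- function(sent, text, type = NA_character_) {
  sent$chunks <- c(sent$chunks, text)
  start <- sent$len
  sent$len <- sent$len + nchar(text)
  if (!is.na(type)) {
    sent$ents <- rbind(sent$ents, data.frame(
      type = type, start = start, end = sent$len, stringsAsFactors = FALSE))
    attr(sent, "last_ent") <- nrow(sent$ents)
  }
  sent
}

last_ent <- function(sent) nrow(sent$ents)

sent_link <- function(sent, attr_idx, drug_idx) {
  sent$rels <- rbind(sent$rels, data.frame(attr = attr_idx, drug = drug_idx))
  sent
}

# Which attribute slots accompany one drug occurrence.  Base probabilities
# are the per-drug attribute rates implied by `type_mix` (attribute share /
# drug share); a fixed calibration factor corrects for template dilution
# (continuation lines carry attributes but no drug or reason, shared-reason
# lines carry two drugs but few attributes, and "Sig:" fallback slots add
# dosage/route/frequency mass), so realized corpus proportions track the
# configured mix.
attr_flag_calibration <- c(Strength = 0.90, Dosage = 0.84, Frequency = 0.77,
                           Duration = 0.95, Route = 0.80, Form = 0.85,
                           Reason = 1.15)

draw_attr_flags <- function(cfg) {
  mix <- cfg$type_mix
  ratio <- mix[attribute_types()] / mix[["Drug"]]
  ratio <- ratio * attr_flag_calibration[attribute_types()]
  flags <- runif(length(ratio)) < pmin(ratio, 1)
  names(flags) <- attribute_types()
  flags
}

# Render one prescription clause (drug + selected attributes) into `sent`,
# linking every attribute to the drug.  `style` governs surface grammar.
add_prescription_clause <- function(sent, cfg, style = c("list", "narrative"),
                                    include_reason = TRUE) {
  style <- match.arg(style)
  noise <- cfg$noise
  flags <- draw_attr_flags(cfg)
  if (!include_reason) flags[["Reason"]] <- FALSE
  if (style == "list" && !any(flags[c("Dosage", "Route", "Frequency")]))
    flags[[sample(c("Dosage", "Route", "Frequency"), 1L)]] <- TRUE
  glue <- flags[["Strength"]] && runif(1L) < noise$glue
  sent <- sent_add(sent, gen_drug_name(noise), "Drug")
  drug <- last_ent(sent)
  half <- function(p) runif(1L) < 0.5
  if (flags[["Strength"]]) {
    if (!glue) sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_strength(glued = glue), "Strength")
    sent <- sent_link(sent, last_ent(sent), drug)
  }
  if (style == "list") {
    if (flags[["Form"]] && half()) {
      sent <- sent_add(sent, " ")
      sent <- sent_add(sent, sample(tb_forms, 1L), "Form")
      sent <- sent_link(sent, last_ent(sent), drug)
    }
    sent <- sent_add(sent, " Sig:")
    if (flags[["Dosage"]]) {
      sent <- sent_add(sent, " ")
      sent <- sent_add(sent, sample(tb_dosages, 1L), "Dosage")
      sent <- sent_link(sent, last_ent(sent), drug)
    }
    if (flags[["Form"]]) {
      sent <- sent_add(sent, " ")
      sent <- sent_add(sent, sample(tb_forms, 1L), "Form")
      sent <- sent_link(sent, last_ent(sent), drug)
    }
  } else {
    if (flags[["Dosage"]]) {
      sent <- sent_add(sent, " ")
      sent <- sent_add(sent, sample(tb_dosages, 1L), "Dosage")
      sent <- sent_link(sent, last_ent(sent), drug)
      if (flags[["Form"]]) {
        sent <- sent_add(sent, " ")
        sent <- sent_add(sent, sample(tb_forms, 1L), "Form")
        sent <- sent_link(sent, last_ent(sent), drug)
      }
    } else if (flags[["Form"]]) {
      sent <- sent_add(sent, " ")
      sent <- sent_add(sent, sample(tb_forms, 1L), "Form")
      sent <- sent_link(sent, last_ent(sent), drug)
    }
  }
  if (flags[["Route"]]) {
    sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_route(noise), "Route")
    sent <- sent_link(sent, last_ent(sent), drug)
  }
  if (flags[["Frequency"]]) {
    sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_freq(noise), "Frequency")
    sent <- sent_link(sent, last_ent(sent), drug)
  }
  if (flags[["Reason"]]) {
    sent <- sent_add(sent, if (style == "list") " as needed for " else " for ")
    sent <- sent_add(sent, sample(tb_reasons, 1L), "Reason")
    sent <- sent_link(sent, last_ent(sent), drug)
  }
  if (flags[["Duration"]]) {
    sent <- sent_add(sent, " ")
    sent <- sent_add(sent, sample(tb_durations, 1L), "Duration")
    sent <- sent_link(sent, last_ent(sent), drug)
  }
  sent
}

gen_single_drug_sentence <- function(cfg, style) {
  sent <- new_sentence()
  if (style == "narrative")
    sent <- sent_add(sent, sample(tb_narrative_prefixes, 1L))
  sent <- add_prescription_clause(sent, cfg, style)
  sent_add(sent, ".")
}

# Two drugs, attributes per segment; reasons only single-linked here.
gen_multi_drug_sentence <- function(cfg) {
  sent <- new_sentence()
  sent <- sent_add(sent, "START: ")
  sent <- add_prescription_clause(sent, cfg, "narrative", include_reason = FALSE)
  sent <- sent_add(sent, " and ")
  sent <- add_prescription_clause(sent, cfg, "narrative")
  sent_add(sent, ".")
}

# "DrugA <freq> and DrugB as needed for <reason>." -- the reason links to
# BOTH drugs; segmentation-style rule linkers provably miss the first link.
gen_shared_reason_sentence <- function(cfg) {
  sent <- new_sentence()
  sent <- sent_add(sent, "START: ")
  sent <- sent_add(sent, gen_drug_name(cfg$noise), "Drug")
  drug_a <- last_ent(sent)
  if (runif(1L) < 0.4) {
    sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_freq(cfg$noise), "Frequency")
    sent <- sent_link(sent, last_ent(sent), drug_a)
  }
  sent <- sent_add(sent, " and ")
  sent <- sent_add(sent, gen_drug_name(cfg$noise), "Drug")
  drug_b <- last_ent(sent)
  sent <- sent_add(sent, " as needed for ")
  sent <- sent_add(sent, sample(tb_reasons, 1L), "Reason")
  reason <- last_ent(sent)
  sent <- sent_link(sent, reason, drug_a)
  sent <- sent_link(sent, reason, drug_b)
  dur_ratio <- cfg$type_mix[["Duration"]] / cfg$type_mix[["Drug"]]
  if (runif(1L) < 2 * dur_ratio) {  # two drugs in this sentence
    sent <- sent_add(sent, " ")
    sent <- sent_add(sent, sample(tb_durations, 1L), "Duration")
    sent <- sent_link(sent, last_ent(sent), drug_b)
  }
  sent_add(sent, ".")
}

# Attribute-only continuation; relations filled in at document level
# (attributes link back to the most recent preceding drug).
gen_lookback_sentence <- function(cfg) {
  flags <- draw_attr_flags(cfg)[c("Strength", "Route", "Frequency", "Duration")]
  if (!any(flags)) flags[[sample(c("Strength", "Route"), 1L)]] <- TRUE
  sent <- new_sentence()
  sent <- sent_add(sent, sample(tb_lookback_prefixes, 1L))
  first <- TRUE
  if (flags[["Strength"]]) {
    sent <- sent_add(sent, gen_strength(glued = runif(1L) < 0.4), "Strength")
    first <- FALSE
  }
  if (flags[["Route"]]) {
    if (!first) sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_route(cfg$noise), "Route")
    first <- FALSE
  }
  if (flags[["Frequency"]]) {
    if (!first) sent <- sent_add(sent, " ")
    sent <- sent_add(sent, gen_freq(cfg$noise), "Frequency")
    first <- FALSE
  }
  if (flags[["Duration"]]) {
    if (!first) sent <- sent_add(sent, " ")
    sent <- sent_add(sent, sample(tb_durations, 1L), "Duration")
  }
  sent_add(sent, ".")
}

# ---- document and corpus assembly ------------------------------------------

gen_document <- function(cfg, doc_id) {
  n_sent <- sample(seq(cfg$sentences_per_doc[1L], cfg$sentences_per_doc[2L]), 1L)
  sents <- list()
  kinds <- character(0L)
  if (runif(1L) < 0.3) {
    hdr <- new_sentence()
    hdr <- sent_add(hdr, "Discharge Medications:")
    sents[[length(sents) + 1L]] <- hdr
    kinds <- c(kinds, "header")
  }
  for (i in seq_len(n_sent)) {
    prev_has_drug <- length(kinds) &&
      tail(kinds, 1L) %in% c("single", "multi", "shared")
    if (prev_has_drug && runif(1L) < cfg$p_lookback) {
      sents[[length(sents) + 1L]] <- gen_lookback_sentence(cfg)
      kinds <- c(kinds, "lookback")
    } else if (runif(1L) < cfg$p_multi_drug_sentence) {
      sent <- gen_multi_drug_sentence(cfg)
      # Any sentence that drew a reason becomes a shared-reason sentence
      # with probability p_shared_reason, so the realized fraction of
      # multiply-linked reasons tracks the configured rate.
      if (any(sent$ents$type == "Reason") && runif(1L) < cfg$p_shared_reason) {
        sents[[length(sents) + 1L]] <- gen_shared_reason_sentence(cfg)
        kinds <- c(kinds, "shared")
      } else {
        sents[[length(sents) + 1L]] <- sent
        kinds <- c(kinds, "multi")
      }
    } else if (runif(1L) < 0.08) {
      flr <- sent_add(new_sentence(), sample(tb_fillers, 1L))
      sents[[length(sents) + 1L]] <- flr
      kinds <- c(kinds, "filler")
    } else {
      style <- if (runif(1L) < cfg$p_list_line) "list" else "narrative"
      sent <- gen_single_drug_sentence(cfg, style)
      if (any(sent$ents$type == "Reason") && runif(1L) < cfg$p_shared_reason) {
        sents[[length(sents) + 1L]] <- gen_shared_reason_sentence(cfg)
        kinds <- c(kinds, "shared")
      } else {
        sents[[length(sents) + 1L]] <- sent
        kinds <- c(kinds, "single")
      }
    }
  }
  # Assemble text; header separated by a blank line, list lines by
  # newlines, narrative continuations by spaces.
  text <- ""
  offsets <- integer(length(sents))
  for (i in seq_along(sents)) {
    stext <- paste0(sents[[i]]$chunks, collapse = "")
    if (i > 1L) {
      sep <- if (kinds[i - 1L] == "header") "\n\n"
             else if (kinds[i] == "lookback") " " else "\n"
      text <- paste0(text, sep)
    }
    offsets[i] <- nchar(text)
    text <- paste0(text, stext)
  }
  # Globalize entities and relations.
  ents <- list(); rels <- list()
  ent_base <- 0L
  global_id <- function(k) paste0("T", k)
  drug_stack <- list()  # per sentence: global indices of its drugs
  for (i in seq_along(sents)) {
    se <- sents[[i]]$ents
    sr <- sents[[i]]$rels
    if (nrow(se)) {
      se$start <- se$start + offsets[i]
      se$end <- se$end + offsets[i]
      se$gidx <- ent_base + seq_len(nrow(se))
      ents[[length(ents) + 1L]] <- se
    }
    if (nrow(sr)) {
      rels[[length(rels) + 1L]] <- data.frame(
        attr = ent_base + sr$attr, drug = ent_base + sr$drug)
    }
    if (kinds[i] == "lookback" && nrow(se)) {
      # Link every attribute to the closest drug in the two previous
      # sentences (drugs always exist by construction).
      prev_drugs <- unlist(drug_stack[max(1L, i - 2L):(i - 1L)])
      if (length(prev_drugs)) {
        target <- max(prev_drugs)  # most recent drug
        rels[[length(rels) + 1L]] <- data.frame(
          attr = ent_base + seq_len(nrow(se)), drug = target)
      }
    }
    drug_stack[[i]] <- if (nrow(se)) se$gidx[se$type == "Drug"] else integer(0L)
    ent_base <- ent_base + nrow(se)
  }
  ents <- if (length(ents)) do.call(rbind, ents) else NULL
  if (is.null(ents)) {
    return(ann_doc(doc_id, text))
  }
  edf <- data.frame(id = global_id(seq_len(nrow(ents))), type = ents$type,
                    start = ents$start, end = ents$end,
                    surface = NA_character_, stringsAsFactors = FALSE)
  rdf <- empty_relations()
  if (length(rels)) {
    rr <- do.call(rbind, rels)
    rdf <- data.frame(id = paste0("R", seq_len(nrow(rr))),
                      type = rtype_for(ents$type[rr$attr]),
                      attr_id = global_id(rr$attr),
                      drug_id = global_id(rr$drug),
                      stringsAsFactors = FALSE)
  }
  ann_doc(doc_id, text, edf, rdf)
}

#' Generate a synthetic annotated corpus
#'
#' @param config A [generator_config()].
#' @return Named list of [ann_doc()] objects (`doc-001`, `doc-002`, ...),
#'   deterministic given `config$seed`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_docs == 0L) return(list())
  with_rng_seed(config$seed, {
    docs <- lapply(seq_len(config$n_docs), function(i) {
      gen_document(config, sprintf("doc-%03d", i))
    })
    names(docs) <- vapply(docs, `[[`, character(1L), "doc_id")
    docs
  })
}

#' Descriptive statistics of an annotated corpus
#'
#' Mirrors the usual corpus summary for this task: per-type entity counts
#' and shares, per-type relation counts, and how many attributes link to
#' more than one drug.
#'
#' @param docs List of `ann_doc` objects.
#' @return List with data.frames `entities` (type, count, share,
#'   links_to_one_drug, links_to_multiple_drugs, max_drug_links) and
#'   `relations` (type, count), plus `reason_shared_fraction` (fraction of
#'   Reason entities linked to more than one drug).
#' @export
corpus_statistics <- function(docs) {
  etypes <- entity_types()
  ecount <- setNames(integer(length(etypes)), etypes)
  one_link <- setNames(integer(length(etypes)), etypes)
  multi_link <- setNames(integer(length(etypes)), etypes)
  max_links <- setNames(integer(length(etypes)), etypes)
  rcount <- setNames(integer(length(relation_types())), relation_types())
  for (doc in docs) {
    ents <- doc$entities
    rels <- doc$relations
    if (nrow(ents)) {
      tab <- table(ents$type)
      ecount[names(tab)] <- ecount[names(tab)] + as.integer(tab)
    }
    if (nrow(rels)) {
      tab <- table(rels$type)
      rcount[names(tab)] <- rcount[names(tab)] + as.integer(tab)
      deg <- table(rels$attr_id)
      ty <- ents$type[match(names(deg), ents$id)]
      for (k in seq_along(deg)) {
        if (deg[k] == 1L) one_link[ty[k]] <- one_link[ty[k]] + 1L
        else multi_link[ty[k]] <- multi_link[ty[k]] + 1L
        max_links[ty[k]] <- max(max_links[ty[k]], as.integer(deg[k]))
      }
    }
  }
  total <- sum(ecount)
  reason_frac <- if (one_link[["Reason"]] + multi_link[["Reason"]] > 0) {
    multi_link[["Reason"]] / (one_link[["Reason"]] + multi_link[["Reason"]])
  } else NA_real_
  list(
    entities = data.frame(
      type = etypes, count = as.integer(ecount),
      share = if (total > 0) as.numeric(ecount) / total else 0,
      links_to_one_drug = as.integer(one_link),
      links_to_multiple_drugs = as.integer(multi_link),
      max_drug_links = as.integer(max_links),
      stringsAsFactors = FALSE),
    relations = data.frame(type = relation_types(),
                           count = as.integer(rcount),
                           stringsAsFactors = FALSE),
    reason_shared_fraction = reason_frac)
}
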