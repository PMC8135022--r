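# BRAT-style standoff corpus input/output and the annotated-document
# container used throughout the package.
#
# Conventions: UTF-8 "<id>.txt" (raw text) plus "<id>.ann" with tab-delimited
# records.  Entity records are "T<k>\t<Type> <start> <end>\t<surface>";
# relation records are "R<k>\t<Type> Arg1:T<i> Arg2:T<j>" where Arg1 is the
# attribute and Arg2 the drug.  All offsets are 0-based half-open,
# both on disk and in memory.

#' Construct an annotated document
#'
#' Bundles raw text with its tokenization, sentence segmentation, typed
#' entity spans and attribute->drug relations, validating the joint
#' invariants (offsets in range, surfaces consistent with offsets, relation
#' endpoints resolving to entities of the right types).
#'
#' @param doc_id Document identifier.
#' @param text Raw text; never modified after construction.
#' @param entities data.frame with columns `id`, `type`, `start`, `end`,
#'   `surface` (surface may be `NA`, in which case it is filled from the
#'   text).
#' @param relations data.frame with columns `id`, `type`, `attr_id`,
#'   `drug_id`.
#' @return An object of class `ann_doc`.
#' @export
ann_doc <- function(doc_id, text, entities = empty_entities(),
                    relations = empty_relations()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(entities)) {
    entities$start <- as.integer(entities$start)
    entities$end <- as.integer(entities$end)
    if (is.null(entities$surface)) entities$surface <- NA_character_
    fill <- is.na(entities$surface)
    if (any(fill)) {
      entities$surface[fill] <-
        substr0(text, entities$start[fill], entities$end[fill])
    }
    entities <- entities[order(entities$start, entities$end), , drop = FALSE]
    rownames(entities) <- NULL
  } else {
    entities <- empty_entities()
  }
  if (!nrow(relations)) relations <- empty_relations()
  tokens <- tokenize(text)
  doc <- structure(list(doc_id = doc_id, text = text, tokens = tokens,
                        sentences = split_sentences(text, tokens),
                        entities = entities, relations = relations),
                   class = "ann_doc")
  validate_ann_doc(doc)
  doc
}

validate_ann_doc <- function(doc) {
  ents <- doc$entities
  n <- nchar(doc$text)
  if (nrow(ents)) {
    if (anyDuplicated(ents$id))
      stop("duplicate entity ids in document '", doc$doc_id, "'")
    bad <- !(ents$type %in% entity_types())
    if (any(bad))
      stop("unknown entity type(s): ", paste(unique(ents$type[bad]), collapse = ", "))
    if (any(ents$start < 0L | ents$end > n | ents$start >= ents$end))
      stop("entity span out of range in document '", doc$doc_id, "'")
  }
  rels <- doc$relations
  if (nrow(rels)) {
    if (!all(rels$type %in% relation_types()))
      stop("unknown relation type(s)")
    idx <- match(rels$attr_id, ents$id)
    jdx <- match(rels$drug_id, ents$id)
    if (anyNA(idx) || anyNA(jdx))
      stop("relation references a missing entity in document '", doc$doc_id, "'")
    if (any(ents$type[jdx] != "Drug"))
      stop("relation Arg2 must be a Drug entity")
    if (any(rtype_for(ents$type[idx]) != rels$type))
      stop("relation type inconsistent with attribute entity type")
  }
  invisible(doc)
}

#' @export
print.ann_doc <- function(x, ...) {
  cat(sprintf("<ann_doc '%s': %d chars, %d tokens, %d sentences, %d entities, %d relations>\n",
              x$doc_id, nchar(x$text), nrow(x$tokens), nrow(x$sentences),
              nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Read a standoff-annotated document
#'
#' Parses text plus annotation content into an [ann_doc()].  Discontinuous
#' entity records (semicolon-separated fragments) are collapsed to their
#' envelope span and reported in the `load_report` attribute.  A surface
#' string that disagrees with the offsets triggers a warning and the
#' offsets are trusted.
#'
#' @param txt_content Raw document text.
#' @param ann_content Annotation file content ("" for no annotations).
#' @param doc_id Document id.
#' @return An `ann_doc`; `attr(, "load_report")` lists collapsed
#'   discontinuous spans and surface mismatches.
#' @export
read_standoff <- function(txt_content, ann_content, doc_id = "doc") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list()
  report <- list(discontinuous = character(), surface_mismatch = character())
  for (line in lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    rid <- fields[1L]
    if (startsWith(rid, "T")) {
      if (length(fields) < 2L) stop("malformed entity record: ", line)
      spec <- fields[2L]
      surface <- if (length(fields) >= 3L) fields[3L] else NA_character_
      sp <- strsplit(spec, " ", fixed = TRUE)[[1L]]
      ty <- sp[1L]
      if (!ty %in% entity_types()) stop("unknown entity type in record: ", line)
      frag_spec <- paste(sp[-1L], collapse = " ")
      frags <- strsplit(frag_spec, ";", fixed = TRUE)[[1L]]
      nums <- lapply(strsplit(trimws(frags), " +"), as.integer)
      if (any(vapply(nums, function(x) length(x) != 2L || anyNA(x), TRUE)))
        stop("malformed offsets in record: ", line)
      starts <- vapply(nums, `[`, integer(1L), 1L)
      ends <- vapply(nums, `[`, integer(1L), 2L)
      start <- min(starts); end <- max(ends)
      if (length(frags) > 1L) report$discontinuous <- c(report$discontinuous, rid)
      if (start < 0L || end > nchar(txt_content) || start >= end)
        stop("offset out of range in record: ", line)
      actual <- substr0(txt_content, start, end)
      if (!is.na(surface) && length(frags) == 1L && !identical(surface, actual)) {
        warning("surface mismatch for ", rid, " ('", surface, "' vs '",
                actual, "'); trusting offsets", call. = FALSE)
        report$surface_mismatch <- c(report$surface_mismatch, rid)
      }
      ents[[length(ents) + 1L]] <- data.frame(
        id = rid, type = ty, start = start, end = end, surface = actual,
        stringsAsFactors = FALSE)
    } else if (startsWith(rid, "R")) {
      if (length(fields) < 2L) stop("malformed relation record: ", line)
      sp <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      ty <- sp[1L]
      if (!ty %in% relation_types()) stop("unknown relation type in record: ", line)
      args <- sp[-1L]
      a1 <- sub("^Arg1:", "", args[grepl("^Arg1:", args)][1L])
      a2 <- sub("^Arg2:", "", args[grepl("^Arg2:", args)][1L])
      if (is.na(a1) || is.na(a2)) stop("malformed relation args in record: ", line)
      rels[[length(rels) + 1L]] <- data.frame(
        id = rid, type = ty, attr_id = a1, drug_id = a2,
        stringsAsFactors = FALSE)
    } else {
      stop("unrecognized standoff record: ", line)
    }
  }
  ents <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  rels <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  doc <- ann_doc(doc_id, txt_content, ents, rels)
  attr(doc, "load_report") <- report
  doc
}

#' Write a document to standoff format
#'
#' Inverse of [read_standoff()]: the round trip preserves entity
#' `(type, start, end)` triples and relation pairs exactly (ids are
#' renumbered in document order).  Newlines inside entity surfaces are
#' written as spaces, as the flat record format requires.
#'
#' @param doc An `ann_doc`.
#' @return A list with elements `txt_content` and `ann_content`.
#' @export
write_standoff <- function(doc) {
  ents <- doc$entities
  rels <- doc$relations
  tlines <- character(0L)
  id_map <- character(0L)
  if (nrow(ents)) {
    new_ids <- paste0("T", seq_len(nrow(ents)))
    id_map <- setNames(new_ids, ents$id)
    tlines <- sprintf("%s\t%s %d %d\t%s", new_ids, ents$type, ents$start,
                      ents$end, gsub("[\n\t]", " ", ents$surface))
  }
  rlines <- character(0L)
  if (nrow(rels)) {
    rlines <- sprintf("R%d\t%s Arg1:%s Arg2:%s", seq_len(nrow(rels)),
                      rels$type, id_map[rels$attr_id], id_map[rels$drug_id])
  }
  ann <- paste(c(tlines, rlines), collapse = "\n")
  if (nzchar(ann)) ann <- paste0(ann, "\n")
  list(txt_content = doc$text, ann_content = ann)
}

#' Read a standoff corpus directory
#'
#' Expects parallel `<id>.txt` / `<id>.ann` files; a missing `.ann` file is
#' treated as an unannotated document.
#'
#' @param dir Directory path.
#' @return A named list of `ann_doc` objects, sorted by document id.
#' @export
read_corpus_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(tf) {
    id <- sub("\\.txt$", "", basename(tf))
    af <- file.path(dir, paste0(id, ".ann"))
    txt <- readChar(tf, file.size(tf), useBytes = FALSE)
    ann <- if (file.exists(af)) readChar(af, file.size(af)) else ""
    read_standoff(txt, ann, doc_id = id)
  })
  names(docs) <- vapply(docs, `[[`, character(1L), "doc_id")
  docs
}

#' Write a corpus of documents to a standoff directory
#'
#' @param docs List of `ann_doc` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_corpus_dir <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    out <- write_standoff(doc)
    writeLines(out$txt_content, file.path(dir, paste0(doc$doc_id, ".txt")),
               sep = "")
    writeLines(out$ann_content, file.path(dir, paste0(doc$doc_id, ".ann")),
               sep = "")
  }
  invisible(dir)
}
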