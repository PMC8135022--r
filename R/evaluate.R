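# Entity and relation scoring.
#
# Strict matching requires identical (type, start, end); lenient matching
# requires the same type and overlapping character spans.  Either way,
# matching is one-to-one: tp is the size of a maximum bipartite matching
# between gold and predicted spans, so tp <= min(|gold|, |pred|) and the
# counts behave like a contingency table.  Micro scores pool counts over
# all documents; macro scores average per-document micro metrics.

spans_match <- function(g_type, g_start, g_end, p_type, p_start, p_end, mode) {
  if (g_type != p_type) return(FALSE)
  if (mode == "strict") return(g_start == p_start && g_end == p_end)
  max(g_start, p_start) < min(g_end, p_end)
}

span_overlap <- function(g_start, g_end, p_start, p_end) {
  max(0L, min(g_end, p_end) - max(g_start, p_start))
}

# Maximum bipartite matching by Kuhn's augmenting paths.  `adj` is a list:
# adj[[i]] = predicted indices compatible with gold i, in preference order
# (larger overlap first, then earlier).  Golds are processed in order, so
# among maximum matchings the earlier gold / larger overlap pairing is
# preferred.
max_bipartite_matching <- function(adj, n_pred) {
  match_pred <- rep(NA_integer_, n_pred)  # pred -> gold
  for (g0 in seq_along(adj)) {
    visited <- rep(FALSE, n_pred)
    dfs <- function(g) {
      for (p in adj[[g]]) {
        if (visited[p]) next
        visited[p] <<- TRUE
        if (is.na(match_pred[p]) || dfs(match_pred[p])) {
          match_pred[p] <<- g
          return(TRUE)
        }
      }
      FALSE
    }
    dfs(g0)
  }
  match_pred
}

#' Match gold and predicted entities one-to-one
#'
#' @param gold,pred Entity data.frames (`type`, `start`, `end`).
#' @param mode `"lenient"` (same type, overlapping spans) or `"strict"`
#'   (identical spans).
#' @return List with `tp`, `fp`, `fn` and `matched_pairs` (data.frame of
#'   `gold_idx`, `pred_idx` row indices).
#' @export
match_entities <- function(gold, pred, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  if (ng == 0L || np == 0L) {
    return(list(tp = 0L, fp = np, fn = ng,
                matched_pairs = data.frame(gold_idx = integer(),
                                           pred_idx = integer())))
  }
  adj <- lapply(seq_len(ng), function(g) {
    cand <- which(vapply(seq_len(np), function(p) {
      spans_match(gold$type[g], gold$start[g], gold$end[g],
                  pred$type[p], pred$start[p], pred$end[p], mode)
    }, TRUE))
    if (length(cand) > 1L) {
      ov <- vapply(cand, function(p) {
        span_overlap(gold$start[g], gold$end[g], pred$start[p], pred$end[p])
      }, numeric(1L))
      cand <- cand[order(-ov, cand)]
    }
    cand
  })
  match_pred <- max_bipartite_matching(adj, np)
  pairs <- data.frame(gold_idx = match_pred[!is.na(match_pred)],
                      pred_idx = which(!is.na(match_pred)))
  pairs <- pairs[order(pairs$gold_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  tp <- nrow(pairs)
  list(tp = tp, fp = np - tp, fn = ng - tp, matched_pairs = pairs)
}

count_by_type <- function(gold, pred, mode, types) {
  out <- matrix(0L, nrow = length(types), ncol = 3L,
                dimnames = list(types, c("tp", "fp", "fn")))
  for (ty in types) {
    m <- match_entities(gold[gold$type == ty, , drop = FALSE],
                        pred[pred$type == ty, , drop = FALSE], mode)
    out[ty, ] <- c(m$tp, m$fp, m$fn)
  }
  out
}

# Build an eval report from per-document count matrices (list of
# types x (tp, fp, fn)).
build_report <- function(doc_counts, mode, types) {
  pooled <- Reduce(`+`, doc_counts)
  per_type <- data.frame(type = types, tp = pooled[, "tp"],
                         fp = pooled[, "fp"], fn = pooled[, "fn"],
                         stringsAsFactors = FALSE)
  pm <- t(apply(pooled, 1L, function(x) prf(x["tp"], x["fp"], x["fn"])))
  per_type$precision <- pm[, "precision"]
  per_type$recall <- pm[, "recall"]
  per_type$f1 <- pm[, "f1"]
  rownames(per_type) <- NULL
  tot <- colSums(pooled)
  micro <- prf(tot["tp"], tot["fp"], tot["fn"])
  # Macro: per-document micro metrics averaged; a document with neither
  # gold nor predicted instances scores (1, 1, 1).
  doc_metrics <- t(vapply(doc_counts, function(cnt) {
    s <- colSums(cnt)
    if (sum(s) == 0L) c(precision = 1, recall = 1, f1 = 1)
    else prf(s["tp"], s["fp"], s["fn"])
  }, c(precision = 0, recall = 0, f1 = 0)))
  macro <- colMeans(doc_metrics)
  structure(list(per_type = per_type, micro = micro, macro = macro,
                 per_document = doc_metrics, mode = mode,
                 n_documents = length(doc_counts)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3L, ...) {
  cat(sprintf("Evaluation report (%s matching, %d documents)\n", x$mode,
              x$n_documents))
  df <- x$per_type
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("micro  P=%.3f R=%.3f F=%.3f\n", x$micro["precision"],
              x$micro["recall"], x$micro["f1"]))
  cat(sprintf("macro  P=%.3f R=%.3f F=%.3f\n", x$macro["precision"],
              x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

check_parallel_docs <- function(gold_docs, pred_docs) {
  if (length(gold_docs) != length(pred_docs))
    stop("gold and predicted corpora differ in length")
  gids <- vapply(gold_docs, `[[`, character(1L), "doc_id")
  pids <- vapply(pred_docs, `[[`, character(1L), "doc_id")
  if (!identical(unname(gids), unname(pids)))
    stop("gold and predicted document ids do not match")
  invisible(TRUE)
}

#' Score entity predictions over a corpus
#'
#' @param gold_docs,pred_docs Parallel lists of `ann_doc` objects (matched
#'   by position; ids must agree).
#' @param mode `"lenient"` or `"strict"`.
#' @return An `eval_report` with per-type, micro (pooled counts) and macro
#'   (per-document average) precision/recall/F1.
#' @export
evaluate_ner <- function(gold_docs, pred_docs, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  check_parallel_docs(gold_docs, pred_docs)
  types <- entity_types()
  counts <- Map(function(g, p) count_by_type(g$entities, p$entities, mode, types),
                gold_docs, pred_docs)
  build_report(counts, mode, types)
}

# Relation-level counts for one document.  A predicted relation matches a
# gold relation iff same relation type and both endpoint entities match
# under `mode`; matching across relations is one-to-one (maximum matching).
relation_counts <- function(gold_doc, pred_doc, mode) {
  types <- relation_types()
  gents <- gold_doc$entities; pents <- pred_doc$entities
  grels <- gold_doc$relations; prels <- pred_doc$relations
  if (nrow(grels) && anyNA(match(c(grels$attr_id, grels$drug_id), gents$id)))
    stop("gold relations reference missing entities")
  if (nrow(prels) && anyNA(match(c(prels$attr_id, prels$drug_id), pents$id)))
    stop("predicted relations reference missing entities")
  out <- matrix(0L, nrow = length(types), ncol = 3L,
                dimnames = list(types, c("tp", "fp", "fn")))
  ent_row <- function(ents, id) ents[match(id, ents$id), , drop = FALSE]
  for (ty in types) {
    gr <- grels[grels$type == ty, , drop = FALSE]
    pr <- prels[prels$type == ty, , drop = FALSE]
    ng <- nrow(gr); np <- nrow(pr)
    if (ng == 0L || np == 0L) {
      out[ty, ] <- c(0L, np, ng)
      next
    }
    adj <- lapply(seq_len(ng), function(g) {
      ga <- ent_row(gents, gr$attr_id[g]); gd <- ent_row(gents, gr$drug_id[g])
      which(vapply(seq_len(np), function(p) {
        pa <- ent_row(pents, pr$attr_id[p]); pd <- ent_row(pents, pr$drug_id[p])
        spans_match(ga$type, ga$start, ga$end, pa$type, pa$start, pa$end, mode) &&
          spans_match(gd$type, gd$start, gd$end, pd$type, pd$start, pd$end, mode)
      }, TRUE))
    })
    m <- max_bipartite_matching(adj, np)
    tp <- sum(!is.na(m))
    out[ty, ] <- c(tp, np - tp, ng - tp)
  }
  out
}

#' Score relation predictions over a corpus
#'
#' @inheritParams evaluate_ner
#' @return An `eval_report` over the seven relation types.
#' @export
evaluate_relations <- function(gold_docs, pred_docs,
                               mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  check_parallel_docs(gold_docs, pred_docs)
  counts <- Map(function(g, p) relation_counts(g, p, mode),
                gold_docs, pred_docs)
  build_report(counts, mode, relation_types())
}

#' Score an end-to-end system (relations over predicted entities)
#'
#' Identical contract to [evaluate_relations()], reported separately so
#' that the compounding of entity-recognition errors into relation scores
#' stays visible: an entity the recognizer misses takes all of its
#' relations down with it.
#'
#' @inheritParams evaluate_ner
#' @return An `eval_report`.
#' @export
evaluate_end_to_end <- function(gold_docs, pred_docs,
                                mode = c("lenient", "strict")) {
  evaluate_relations(gold_docs, pred_docs, mode = mode)
}

#' Token-level confusion matrix
#'
#' Collapses BIOES labels to entity types (plus `O`) on both sides and
#' tabulates gold (rows) against predicted (columns) per token.
#'
#' @inheritParams evaluate_ner
#' @return A 9x9 integer matrix with attribute `total_errors` (sum of
#'   off-diagonal cells).
#' @export
token_confusion_matrix <- function(gold_docs, pred_docs) {
  check_parallel_docs(gold_docs, pred_docs)
  cats <- c(entity_types(), "O")
  cm <- matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))
  for (k in seq_along(gold_docs)) {
    g <- gold_docs[[k]]; p <- pred_docs[[k]]
    if (nrow(g$tokens) != nrow(p$tokens))
      stop("token count mismatch in document '", g$doc_id, "'")
    gl <- label_type(encode_bioes(g)); gl[is.na(gl)] <- "O"
    pl <- label_type(encode_bioes(p)); pl[is.na(pl)] <- "O"
    for (i in seq_along(gl)) cm[gl[i], pl[i]] <- cm[gl[i], pl[i]] + 1L
  }
  structure(cm, total_errors = sum(cm) - sum(diag(cm)))
}

#' Two-tailed paired t test over per-document metrics
#'
#' @param metric_a,metric_b Equal-length numeric vectors (one value per
#'   document), length >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff` and `degenerate` (`TRUE`
#'   when the differences have zero variance, in which case `t` and `p`
#'   are `NA` rather than an error).
#' @export
paired_ttest <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L)
  d <- metric_a - metric_b
  if (sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    mode = report$mode,
    n_documents = report$n_documents,
    per_type = report$per_type,
    micro = as.list(report$micro),
    macro = as.list(report$macro)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
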