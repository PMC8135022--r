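# Pipeline orchestration: the command-level operations behind the CLI
# script (inst/cli/medlinkr).  Each command reads/writes standard
# artifacts (standoff corpora, model checkpoints, JSON reports) and drops
# a YAML run log capturing config and seed, so any run is reproducible.

write_run_log <- function(dir, command, params) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(list(command = command,
                package = as.character(utils::packageVersion("medlinkr")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           params)
  yaml::write_yaml(log, file.path(dir, paste0(command, "-run.yaml")))
}

#' Generate a synthetic corpus directory
#'
#' @param out_dir Output directory for `.txt`/`.ann` files.
#' @param n_docs,seed Generator size and seed.
#' @param config Optional full [generator_config()] (overrides
#'   `n_docs`/`seed`).
#' @return Invisibly, the corpus statistics.
#' @export
cmd_generate <- function(out_dir, n_docs = 300L, seed = 20180101L,
                         config = NULL) {
  if (is.null(config)) config <- generator_config(n_docs = n_docs, seed = seed)
  docs <- generate_corpus(config)
  write_corpus_dir(docs, out_dir)
  st <- corpus_statistics(docs)
  jsonlite::write_json(st, file.path(out_dir, "corpus-statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(out_dir, "generate",
                list(n_docs = config$n_docs, seed = config$seed))
  invisible(st)
}

#' Train an entity recognizer from a corpus directory
#'
#' @param corpus_dir Standoff corpus with gold annotations.
#' @param model_path Where to save the checkpoint (.rds).
#' @param mode Representation mode (see [repr_config()]).
#' @param seed Training seed.
#' @param embeddings Pretrained vector file path (PWE modes).
#' @param dev_doc_count Development split size.
#' @param max_epochs,patience Optional overrides of the defaults.
#' @return Invisibly, the trained model.
#' @export
cmd_train_ner <- function(corpus_dir, model_path, mode = "RIWE", seed = 42L,
                          embeddings = NULL, dev_doc_count = 30L,
                          max_epochs = NULL, patience = NULL) {
  docs <- read_corpus_dir(corpus_dir)
  config <- repr_config(mode)
  if (!is.null(max_epochs)) config$max_epochs <- as.integer(max_epochs)
  if (!is.null(patience)) config$patience <- as.integer(patience)
  model <- train_ner(docs, config = config, seed = seed,
                     dev_doc_count = dev_doc_count, embeddings = embeddings)
  save_model(model, model_path)
  write_run_log(dirname(model_path), "train-ner",
                list(corpus = corpus_dir, mode = mode, seed = seed,
                     best_epoch = model$best_epoch,
                     dev_micro_f = model$dev_micro_f))
  invisible(model)
}

#' Predict entities over a corpus directory
#'
#' @param model_path Checkpoint from [cmd_train_ner()].
#' @param corpus_dir Input documents (`.txt`; annotations ignored).
#' @param out_dir Output standoff directory.
#' @return Invisibly, the predicted documents.
#' @export
cmd_predict_ner <- function(model_path, corpus_dir, out_dir) {
  model <- load_model(model_path)
  docs <- read_corpus_dir(corpus_dir)
  pred <- predict_corpus(model, docs)
  write_corpus_dir(pred, out_dir)
  write_run_log(out_dir, "predict-ner",
                list(model = model_path, corpus = corpus_dir))
  invisible(pred)
}

#' Train the LSTM relation model from a corpus directory
#'
#' @inheritParams cmd_train_ner
#' @param dev_doc_count Documents held out for early stopping.
#' @param window Candidate scope window.
#' @return Invisibly, the trained model.
#' @export
cmd_train_re <- function(corpus_dir, model_path, seed = 42L,
                         dev_doc_count = 10L, window = 2L,
                         max_epochs = NULL, patience = NULL) {
  docs <- read_corpus_dir(corpus_dir)
  if (length(docs) <= dev_doc_count)
    stop("corpus too small to carve out ", dev_doc_count, " dev documents")
  config <- repr_config("RIWE")
  if (!is.null(max_epochs)) config$max_epochs <- as.integer(max_epochs)
  if (!is.null(patience)) config$patience <- as.integer(patience)
  pick <- with_rng_seed(seed, sample.int(length(docs), dev_doc_count))
  model <- train_re(docs[-pick], docs[pick], config = config, seed = seed,
                    window = window)
  save_model(model, model_path)
  write_run_log(dirname(model_path), "train-re",
                list(corpus = corpus_dir, seed = seed,
                     best_epoch = model$best_epoch,
                     dev_micro_f = model$dev_micro_f))
  invisible(model)
}

#' Link attributes to drugs with the rule-based method
#'
#' @param corpus_dir Standoff corpus carrying entities (gold or
#'   predicted).
#' @param out_dir Output standoff directory (entities plus linked
#'   relations).
#' @param window Lookback window in sentences.
#' @return Invisibly, the linked documents.
#' @export
cmd_link_rules <- function(corpus_dir, out_dir, window = 2L) {
  docs <- read_corpus_dir(corpus_dir)
  linked <- lapply(docs, function(d) {
    out <- ann_doc(d$doc_id, d$text, d$entities)
    out$relations <- extract_relations_rules(d, window = window)
    validate_ann_doc(out)
  })
  write_corpus_dir(linked, out_dir)
  write_run_log(out_dir, "link-rules",
                list(corpus = corpus_dir, window = window))
  invisible(linked)
}

#' Evaluate predictions against a gold corpus
#'
#' @param gold_dir,pred_dir Parallel standoff directories.
#' @param out_path JSON report path.
#' @param what `"entities"` or `"relations"`.
#' @param mode `"lenient"` or `"strict"`.
#' @return Invisibly, the `eval_report`.
#' @export
cmd_evaluate <- function(gold_dir, pred_dir, out_path,
                         what = c("entities", "relations"),
                         mode = c("lenient", "strict")) {
  what <- match.arg(what)
  mode <- match.arg(mode)
  gold <- read_corpus_dir(gold_dir)
  pred <- read_corpus_dir(pred_dir)
  report <- if (what == "entities") evaluate_ner(gold, pred, mode)
            else evaluate_relations(gold, pred, mode)
  write_report_json(report, out_path)
  invisible(report)
}

#' Run the full pipeline: predict entities, link, evaluate
#'
#' Chains entity prediction, relation extraction (rules or a trained LSTM
#' model) and evaluation over a gold test corpus, writing the three JSON
#' reports (`ner`, `re-gold`, `end-to-end`) that summarize the system.
#'
#' @param ner_model A trained `ner_model` (or checkpoint path).
#' @param test_docs Gold-annotated test documents (list or corpus dir).
#' @param out_dir Report/prediction output directory.
#' @param re_method `"rules"` or a trained `re_model` (or checkpoint
#'   path).
#' @param window Rule lookback / candidate window.
#' @return List with `ner`, `re_gold` and `end_to_end` eval reports.
#' @export
cmd_end_to_end <- function(ner_model, test_docs, out_dir,
                           re_method = "rules", window = 2L) {
  if (is.character(ner_model)) ner_model <- load_model(ner_model)
  if (is.character(test_docs)) test_docs <- read_corpus_dir(test_docs)
  if (is.character(re_method) && file.exists(re_method))
    re_method <- load_model(re_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  link <- function(doc, entities) {
    carrier <- ann_doc(doc$doc_id, doc$text, entities)
    rels <- if (inherits(re_method, "re_model")) {
      predict_relations(re_method, carrier)
    } else {
      extract_relations_rules(carrier, window = window)
    }
    carrier$relations <- rels
    validate_ann_doc(carrier)
  }
  # NER predictions and end-to-end relations on them
  pred_entity_docs <- predict_corpus(ner_model, test_docs)
  e2e_docs <- lapply(pred_entity_docs, function(d) link(d, d$entities))
  # RE on gold entities
  re_gold_docs <- lapply(test_docs, function(d) link(d, d$entities))
  reports <- list(
    ner = evaluate_ner(test_docs, pred_entity_docs, "lenient"),
    re_gold = evaluate_relations(test_docs, re_gold_docs, "lenient"),
    end_to_end = evaluate_end_to_end(test_docs, e2e_docs, "lenient"))
  write_corpus_dir(e2e_docs, file.path(out_dir, "predictions"))
  write_report_json(reports$ner, file.path(out_dir, "report-ner.json"))
  write_report_json(reports$re_gold, file.path(out_dir, "report-re-gold.json"))
  write_report_json(reports$end_to_end,
                    file.path(out_dir, "report-end-to-end.json"))
  write_run_log(out_dir, "end-to-end",
                list(re_method = if (inherits(re_method, "re_model")) "lstm"
                                 else "rules",
                     window = window, n_test = length(test_docs)))
  reports
}
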