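# End-to-end demo workflow and structured configuration: simulate a
# repertoire, curate it (QC -> dedup -> split), build the vocabulary, encode,
# pretrain a small encoder jointly on MLM + contrastive objectives, evaluate
# embeddings and a fine-tuned subtype classifier, and run integrated
# gradients on test records. Every stage writes its artifacts under one run
# directory with a manifest, and the resolved configuration is stored next
# to the outputs.

PIPELINE_SCHEMA <- list(
  seed = "integer",
  out_dir = "character",
  data = list(n_records = "positive_integer",
              subtype_labels = "character_vector",
              motif_strength = "unit_interval",
              fraction_heavy = "unit_interval",
              mode = "mode",
              max_len = "positive_integer"),
  model = list(n_layers = "positive_integer", n_heads = "positive_integer",
               hidden_dim = "positive_integer", ffn_dim = "positive_integer",
               dropout = "unit_interval"),
  training = list(w_cl = "unit_interval", tau = "positive",
                  peak_lr = "positive", total_steps = "positive_integer",
                  batch_size = "positive_integer",
                  eval_interval = "positive_integer"),
  eval = list(finetune_epochs = "positive_integer"),
  explain = list(ig_steps = "positive_integer", n_records = "positive_integer")
)

#' Validate a pipeline configuration
#'
#' Schema check only (no side effects): every required key must be present
#' with the right type/range. Errors name the offending key path.
#'
#' @param config A named list, or a path to a YAML file.
#' @return The validated config (invisibly) or an error naming the first
#'   invalid key.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path")
  check <- function(value, rule, path) {
    bad <- function(msg) stop(sprintf("config key '%s': %s", path, msg),
                              call. = FALSE)
    if (is.list(rule)) {
      if (!is.list(value)) bad("must be a section")
      extra <- setdiff(names(value), names(rule))
      if (length(extra) > 0) {
        stop(sprintf("unknown config key '%s'",
                     paste0(path, ".", extra[1])), call. = FALSE)
      }
      for (k in names(rule)) {
        if (is.null(value[[k]])) bad(sprintf("missing required field '%s'", k))
        check(value[[k]], rule[[k]], paste0(path, ".", k))
      }
      return(invisible())
    }
    switch(rule,
      integer = if (!is.numeric(value) || value != round(value))
        bad("must be an integer"),
      positive_integer = if (!is.numeric(value) || length(value) != 1 ||
                             value != round(value) || value <= 0)
        bad("must be a positive integer"),
      positive = if (!is.numeric(value) || length(value) != 1 || value <= 0)
        bad("must be positive"),
      unit_interval = if (!is.numeric(value) || length(value) != 1 ||
                          value < 0 || value > 1)
        bad("must lie in [0, 1]"),
      character = if (!is.character(value) || length(value) != 1)
        bad("must be a string"),
      character_vector = if (!is.character(value) || length(value) < 2)
        bad("must be a character vector of length >= 2"),
      mode = if (!value %in% c("full_length", "hcdr3"))
        bad("must be 'full_length' or 'hcdr3'")
    )
    invisible()
  }
  extra <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(extra) > 0) {
    stop(sprintf("unknown config key '%s'", extra[1]), call. = FALSE)
  }
  for (k in names(PIPELINE_SCHEMA)) {
    if (is.null(config[[k]])) {
      stop(sprintf("config key '%s': missing", k), call. = FALSE)
    }
    check(config[[k]], PIPELINE_SCHEMA[[k]], k)
  }
  invisible(config)
}

#' Default demo configuration
#'
#' A small configuration that exercises every pipeline stage in minutes on
#' one CPU: 3 planted-motif subtypes, HCDR3-focused encoding, a 2-layer
#' encoder.
#'
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @return Config list (already valid).
#' @export
demo_config <- function(out_dir = tempfile("bcrlm_run_"), seed = 1L) {
  list(seed = as.integer(seed), out_dir = out_dir,
       data = list(n_records = 600L,
                   subtype_labels = c("naive", "memory", "plasma"),
                   motif_strength = 1.0, fraction_heavy = 1.0,
                   mode = "hcdr3", max_len = 32L),
       model = list(n_layers = 2L, n_heads = 2L, hidden_dim = 32L,
                    ffn_dim = 64L, dropout = 0.1),
       training = list(w_cl = 0.5, tau = 0.07, peak_lr = 1e-3,
                       total_steps = 300L, batch_size = 16L,
                       eval_interval = 50L),
       eval = list(finetune_epochs = 40L),
       explain = list(ig_steps = 50L, n_records = 3L))
}

#' Run the full pipeline
#'
#' simulate -> curate -> tokenize -> pretrain -> evaluate -> explain, all
#' seeded from `config$seed`; artifacts (AIRR TSVs, vocabulary, checkpoint,
#' metrics JSON, attribution TSV, manifest and resolved config) are written
#' under `config$out_dir`.
#'
#' @param config Pipeline config (see [validate_config()]).
#' @return list with the main in-memory artifacts: `curated`, `vocab`,
#'   `trained` (model + history), `metrics`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$out_dir, "config_resolved.yaml"))
  seed <- config$seed

  # simulate
  pools <- build_germline_pools(seed = seed)
  sc <- sim_config(n_records = config$data$n_records,
                   subtype_labels = config$data$subtype_labels,
                   motif_strength = config$data$motif_strength,
                   fraction_heavy = config$data$fraction_heavy,
                   seed = seed)
  rep_df <- simulate_repertoire(sc, pools)
  write_airr(rep_df, file.path(config$out_dir, "repertoire.tsv"))

  # curate
  cur <- curate(rep_df, seed = seed)
  for (part in c("train", "validation", "test")) {
    write_airr(cur$split[[part]], file.path(config$out_dir,
                                            paste0(part, ".tsv")))
  }
  jsonlite::write_json(as.list(cur$qc_report),
                       file.path(config$out_dir, "qc_report.json"),
                       auto_unbox = TRUE)

  # tokenize
  vocab <- build_vocabulary(pool_gene_symbols(pools))
  write_vocabulary(vocab, file.path(config$out_dir, "vocabulary.tsv"))
  mode <- config$data$mode
  max_len <- config$data$max_len
  enc <- function(df) list(batch = encode_batch(df, vocab, mode = mode,
                                                max_len = max_len),
                           labels = df$subtype)
  train_enc <- enc(cur$split$train)
  val_enc <- enc(cur$split$validation)

  # pretrain
  mcfg <- model_config(n_layers = config$model$n_layers,
                       n_heads = config$model$n_heads,
                       hidden_dim = config$model$hidden_dim,
                       ffn_dim = config$model$ffn_dim,
                       vocab_size = vocab$size, max_len = max_len,
                       dropout = config$model$dropout, seed = seed)
  model <- init_model(mcfg)
  tcfg <- training_config(w_cl = config$training$w_cl,
                          tau = config$training$tau,
                          peak_lr = config$training$peak_lr,
                          total_steps = config$training$total_steps,
                          batch_size = config$training$batch_size,
                          eval_interval = config$training$eval_interval,
                          seed = seed)
  trained <- train(model, train_enc, val_enc, tcfg, vocab)
  save_checkpoint(trained$model, file.path(config$out_dir, "checkpoint.rds"),
                  vocab)
  hist_path <- file.path(config$out_dir, "history.jsonl")
  writeLines(vapply(seq_len(nrow(trained$history)), function(i) {
    jsonlite::toJSON(as.list(trained$history[i, ]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1)), hist_path)

  # evaluate
  test_df <- cur$split$test
  test_enc <- enc(test_df)
  emb <- cls_embedding(trained$model, test_enc$batch)
  emb_metrics <- embedding_eval(emb, test_df$subtype, seed = seed)
  clf <- fine_tune_classifier(trained$model, train_enc$batch,
                              cur$split$train$subtype,
                              epochs = config$eval$finetune_epochs,
                              seed = seed)
  pred <- predict(clf, test_enc$batch)
  report <- classification_report(pred$label, test_df$subtype)
  metrics <- list(embedding = emb_metrics,
                  subtype = list(accuracy = report$accuracy,
                                 precision = report$precision,
                                 recall = report$recall, f1 = report$f1,
                                 mcc = report$mcc))
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(as.data.frame(report$confusion),
              file.path(config$out_dir, "confusion.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # explain
  n_ex <- min(config$explain$n_records, nrow(test_df))
  attr_rows <- list()
  for (i in seq_len(n_ex)) {
    encoded <- encode(test_df[i, ], vocab, mode = mode, max_len = max_len)
    prof <- integrated_gradients(trained$model, encoded,
                                 target = list(type = "class",
                                               classifier = clf),
                                 steps = config$explain$ig_steps)
    attr_rows[[i]] <- data.frame(record = test_df$id[i],
                                 position = prof$positions,
                                 score = prof$scores,
                                 method = prof$method)
  }
  write.table(do.call(rbind, attr_rows),
              file.path(config$out_dir, "attributions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(seed = seed, stages = c("simulate", "curate", "tokenize",
                                           "pretrain", "evaluate", "explain"),
                   n_records = nrow(rep_df),
                   n_representatives = cur$n_representatives,
                   vocab_size = vocab$size,
                   files = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  list(curated = cur, vocab = vocab, trained = trained, metrics = metrics,
       out_dir = config$out_dir)
}
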