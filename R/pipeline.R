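#' Pipeline run configuration
#'
#' A validated bag of paths, thresholds and seeds driving the two
#' workflows ([run_train_pipeline()] and [run_classify_pipeline()]).
#' Round-trips losslessly through JSON.
#'
#' @param genomes_dir Directory of nucleotide FASTA files (one genome
#'   per file).
#' @param tblout Path to a HMMER tblout file of all protein hits.
#' @param gvog_list Path to a text file of GVOG ids, one per line.
#' @param labels Path to a TSV with columns `genome_id`, `order`,
#'   `family` (and optionally `group`).
#' @param model_dir Directory holding/receiving the trained models.
#' @param out_dir Output directory.
#' @param reference_db Optional list with `proteins` (FASTA path) and
#'   `taxonomy` (TSV path) for the AAI module.
#' @param evalue,min_prevalence,prevalence_mode,min_members,af_floor,low_confidence
#'   Thresholds; defaults 1e-10, 0.25, `"any"`, 30, 20, 0.5.
#' @param n_features Named vector: final feature-set size per level
#'   (defaults 150 order / 200 family, capped at what screening
#'   retains).
#' @param cv_folds,outer_folds,inner_folds,n_random_draws Search and
#'   CV sizes.
#' @param do_nested_cv Estimate generalization by nested CV during
#'   training (default `TRUE`).
#' @param seed Integer seed for every stochastic stage.
#' @return Object of class `gv_config`.
#' @export
gv_config <- function(genomes_dir = NULL, tblout = NULL, gvog_list = NULL,
                      labels = NULL, model_dir = NULL, out_dir = NULL,
                      reference_db = NULL,
                      evalue = 1e-10, min_prevalence = 0.25,
                      prevalence_mode = "any", min_members = 30,
                      af_floor = 20, low_confidence = 0.5,
                      n_features = c(order = 150, family = 200),
                      cv_folds = 10, outer_folds = 10, inner_folds = 10,
                      n_random_draws = 10, do_nested_cv = TRUE,
                      seed = 42L) {
  stopifnot(evalue > 0, min_prevalence >= 0, min_prevalence <= 1,
            min_members >= 0, af_floor >= 0, af_floor <= 100,
            low_confidence >= 0, low_confidence <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "gv_config")
}

#' @rdname gv_config
#' @param path JSON path.
#' @export
write_gv_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$n_features <- as.list(out$n_features)  # keep names through JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname gv_config
#' @export
read_gv_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$n_features <- unlist(raw$n_features)
  do.call(gv_config, raw)
}

read_labels_tsv <- function(path) {
  lab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("genome_id", "order", "family")
  missing <- setdiff(need, names(lab))
  if (length(missing) > 0) {
    stopf("labels file lacks column(s): %s", paste(missing, collapse = ", "))
  }
  lab
}

validate_train_inputs <- function(cfg) {
  for (f in c("genomes_dir", "tblout", "gvog_list", "labels")) {
    if (is.null(cfg[[f]])) stopf("config field '%s' is required", f)
    if (!file.exists(cfg[[f]])) stopf("config: %s '%s' does not exist",
                                      f, cfg[[f]])
  }
}

#' Train order- and family-level classifiers from raw inputs
#'
#' Runs the full training workflow once per taxonomic level:
#' featurize (tblout filter + GC), rare-family aggregation,
#' order-prevalence screening, randomized + grid hyperparameter
#' search, impurity importance ranking, final feature selection,
#' final fit, and (optionally) nested cross-validation. All
#' intermediates and both model directories are written under
#' `cfg$out_dir` with a manifest.
#'
#' @param cfg A [gv_config()].
#' @return Invisibly, a list with both `gv_classifier` objects and
#'   their CV reports.
#' @export
run_train_pipeline <- function(cfg) {
  validate_train_inputs(cfg)
  out <- cfg$out_dir %||% stop("config field 'out_dir' is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  message("[featurize] reading inputs")
  genomes <- read_genomes(cfg$genomes_dir, grouping = "per_file")
  gvog_ids <- readLines(cfg$gvog_list)
  hits <- parse_hmm_hits(cfg$tblout, evalue_threshold = cfg$evalue)
  mat <- build_feature_matrix(genomes, hits, gvog_ids)
  labels <- read_labels_tsv(cfg$labels)
  labels <- aggregate_rare_families(labels, min_members = cfg$min_members)
  labels <- labels[match(rownames(mat), labels$genome_id), , drop = FALSE]
  if (anyNA(labels$genome_id)) stopf("genomes missing from the label table")
  write_feature_matrix(mat, file.path(out, "features.tsv"),
                       meta = list(evalue_threshold = cfg$evalue))

  message("[screen] order-prevalence screening at ", cfg$min_prevalence)
  kept <- prevalence_screen(mat, labels$order,
                            min_prevalence = cfg$min_prevalence,
                            mode = cfg$prevalence_mode)
  writeLines(setdiff(kept, "gc_content"), file.path(out, "screened_gvogs.txt"))
  smat <- mat[, kept, drop = FALSE]

  models <- list()
  reports <- list()
  for (level in c("order", "family")) {
    y <- if (level == "order") labels$order else labels$family_class
    message(sprintf("[tune] %s level (%d classes)", level, length(unique(y))))
    tuned <- gv_tune(smat, y, grid = small_grid(),
                     n_random_draws = cfg$n_random_draws,
                     cv_folds = cfg$cv_folds, seed = cfg$seed)
    full_fit <- gv_fit(smat, y, hyper = tuned$best_hyper, level = level,
                       seed = child_seed(cfg$seed, 1))
    rank <- impurity_importance(full_fit)
    k <- min(cfg$n_features[[level]], nrow(rank))
    feats <- select_final_features(rank, k)
    utils::write.table(as.data.frame(rank),
                       file.path(out, paste0("importance_", level, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    message(sprintf("[fit] %s level on %d features", level, k))
    model <- gv_fit(smat, y, features = feats, hyper = tuned$best_hyper,
                    level = level, seed = child_seed(cfg$seed, 2),
                    cv_accuracy = tuned$cv_report$mean)
    cvrep <- NULL
    if (isTRUE(cfg$do_nested_cv)) {
      message(sprintf("[nested-cv] %s level", level))
      cvrep <- gv_nested_cv(smat[, feats, drop = FALSE], y,
                            grid = small_grid(),
                            outer_folds = cfg$outer_folds,
                            inner_folds = cfg$inner_folds,
                            n_random_draws = cfg$n_random_draws,
                            seed = child_seed(cfg$seed, 3))
      utils::write.table(
        data.frame(fold = seq_along(cvrep$per_fold),
                   accuracy = cvrep$per_fold),
        file.path(out, paste0("nested_cv_", level, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    mdir <- file.path(cfg$model_dir %||% file.path(out, "models"), level)
    save_gv_classifier(model, mdir)
    models[[level]] <- model
    reports[[level]] <- list(tuned = tuned, nested_cv = cvrep)
  }

  manifest <- list(
    config = unclass(cfg)[!vapply(cfg, is.null, TRUE)],
    n_genomes = nrow(mat),
    n_screened_features = length(kept),
    nested_cv = lapply(reports, function(r) {
      if (is.null(r$nested_cv)) NULL else
        list(mean = r$nested_cv$mean, sd = r$nested_cv$sd)
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(models = models, reports = reports))
}

#' Classify query genomes with trained models
#'
#' Featurizes the queries the same way as in training (the models'
#' frozen GVOG lists define the columns), applies both classifiers,
#' and optionally appends one-way AAI best matches against a
#' reference database.
#'
#' @param cfg A [gv_config()]; `model_dir` must contain `order/` and
#'   `family/` model directories.
#' @param aai Enable the AAI module (requires `cfg$reference_db` and
#'   `query_proteins`).
#' @param query_proteins Optional path to the query protein FASTA
#'   (protein ids follow the `<contig>_<n>` convention).
#' @return Invisibly, the predictions `data.frame` (also written to
#'   `out_dir/predictions.tsv`).
#' @export
run_classify_pipeline <- function(cfg, aai = FALSE, query_proteins = NULL) {
  out <- cfg$out_dir %||% stop("config field 'out_dir' is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  order_model <- load_gv_classifier(file.path(cfg$model_dir, "order"))
  family_model <- load_gv_classifier(file.path(cfg$model_dir, "family"))

  genomes <- read_genomes(cfg$genomes_dir, grouping = "per_file")
  if (length(genomes) == 0) {
    warnf("no query genomes found in '%s'", cfg$genomes_dir)
    empty <- data.frame(genome_id = character(), order = character(),
                        order_prob = numeric(), family = character(),
                        family_prob = numeric(), low_confidence = logical())
    utils::write.table(empty, file.path(out, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(empty))
  }
  hits <- parse_hmm_hits(cfg$tblout, evalue_threshold = cfg$evalue)
  gvogs <- union(setdiff(order_model$features, "gc_content"),
                 setdiff(family_model$features, "gc_content"))
  mat <- build_feature_matrix(genomes, hits, gvogs)

  po <- predict(order_model, mat[, order_model$features, drop = FALSE],
                low_confidence_cutoff = cfg$low_confidence)
  pf <- predict(family_model, mat[, family_model$features, drop = FALSE],
                low_confidence_cutoff = cfg$low_confidence)
  preds <- data.frame(
    genome_id = po$genome_id,
    order = po$predicted_class, order_prob = po$probability,
    family = pf$predicted_class, family_prob = pf$probability,
    low_confidence = po$low_confidence | pf$low_confidence,
    level_disagreement = unname(level_disagreement(po, pf)),
    stringsAsFactors = FALSE)

  if (aai) {
    if (is.null(cfg$reference_db) || is.null(query_proteins)) {
      stopf("AAI requested but reference_db/query_proteins not configured")
    }
    ref <- aai_reference_db(
      cfg$reference_db$proteins,
      utils::read.table(cfg$reference_db$taxonomy, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
    qprot <- Biostrings::readAAStringSet(query_proteins)
    names(qprot) <- sub("\\s.*$", "", names(qprot))
    qgenome <- map_proteins_to_genomes(names(qprot), genomes)
    aai_rows <- do.call(rbind, lapply(preds$genome_id, function(g) {
      qs <- qprot[!is.na(qgenome) & qgenome == g]
      if (length(qs) == 0) {
        return(data.frame(best_match_genome_id = NA_character_, aai = 0,
                          af = 0, order = NA_character_,
                          family = NA_character_, genus = NA_character_))
      }
      as.data.frame(aai_best_match(qs, ref, af_floor = cfg$af_floor))
    }))
    names(aai_rows) <- paste0("aai_", names(aai_rows))
    preds <- cbind(preds, aai_rows)
  }
  utils::write.table(preds, file.path(out, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(preds)
}
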