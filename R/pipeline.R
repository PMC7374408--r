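#' Pipeline configuration
#'
#' Bundles every tunable of the analysis: the variable registry, the number
#' of principal components retained per variable, the split-half ranking
#' target size, the transfer-function constants, seeds and the normality
#' gate. The configuration is hashed ([configHash()]) and the hash is
#' stamped into every artifact the pipeline writes, so artifacts produced
#' under different configurations cannot be silently mixed.
#'
#' @param registry named character vector of variables and units.
#' @param n_components principal components retained per variable.
#' @param target_size minimum retained feature count for split-half ranking.
#' @param gain,A,B transfer constants, see [fitTransferParams()] and
#'   [massAssignment()].
#' @param split_seed seed of the stratified half-split.
#' @param normality_alpha Shapiro-Wilk level gating parametric tests.
#' @param oks_best_high OKS direction convention, see [defaultInstruments()].
#' @param loo_refit `"params"` or `"full"`, see [looValidate()].
#' @return a `gait_pipeline_config` list.
#' @export
pipelineConfig <- function(registry = defaultVariableRegistry(),
                           n_components = 3L, target_size = 18L,
                           gain = 2, A = 0.2, B = 0.9,
                           split_seed = 1L, normality_alpha = 0.05,
                           oks_best_high = FALSE,
                           loo_refit = c("params", "full")) {
  loo_refit <- match.arg(loo_refit)
  stopifnot(n_components >= 1, target_size >= 1, gain > 0,
            A >= 0, A < 1, B > 0, B < 1)
  structure(list(registry = registry,
                 n_components = as.integer(n_components),
                 target_size = as.integer(target_size),
                 gain = gain, A = A, B = B,
                 split_seed = as.integer(split_seed),
                 normality_alpha = normality_alpha,
                 oks_best_high = oks_best_high,
                 loo_refit = loo_refit),
            class = "gait_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its [pipelineConfig()] default.
#'
#' @param path YAML file.
#' @return a `gait_pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipelineConfig()
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config field(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- utils::modifyList(unclass(defaults), raw[intersect(names(raw), known)])
  if (!is.null(raw$registry)) {
    args$registry <- unlist(raw$registry)
  }
  do.call(pipelineConfig, args)
}

#' Train the full gait classification pipeline
#'
#' End-to-end training stage: per-variable PCA on the pooled baseline
#' cohort, PC-score feature matrix, stratified split-half feature ranking,
#' explicit transfer-parameter training of the belief classifier on the
#' retained features, leave-one-out cross-validation, and baseline belief
#' triplets with simplex coordinates. Deterministic given the cohort and
#' configuration.
#'
#' @param cohort a [GaitCohort-class] with a baseline visit.
#' @param config a `gait_pipeline_config`, see [pipelineConfig()].
#' @param out_dir optional directory; when given, writes `pca_models.json`,
#'   `classifier.json`, `ranking.csv`, `beliefs_baseline.csv`,
#'   `loo_report.csv` and `train_summary.json`, all stamped with the config
#'   hash.
#' @return list with elements `models`, `features`, `selection`,
#'   `classifier`, `loo`, `beliefs`, `config`, `hash`.
#' @export
runTrain <- function(cohort, config = pipelineConfig(), out_dir = NULL) {
  stopifnot(is(cohort, "GaitCohort"),
            inherits(config, "gait_pipeline_config"))
  hash <- configHash(config)
  models <- fitAllPCA(cohort, retained = config$n_components)
  features <- buildFeatureMatrix(models, cohort, "baseline")
  labels <- cohortLabels(cohort)[rownames(features)]
  halves <- splitHalves(labels, seed = config$split_seed)
  rank1 <- rankFeatures(features[halves$half1, , drop = FALSE],
                        labels[halves$half1],
                        gain = config$gain, A = config$A, B = config$B)
  rank2 <- rankFeatures(features[halves$half2, , drop = FALSE],
                        labels[halves$half2],
                        gain = config$gain, A = config$A, B = config$B)
  selection <- selectRetained(rank1, rank2, target_size = config$target_size)
  classifier <- trainClassifier(features, labels,
                                retained = selection$retained,
                                gain = config$gain, A = config$A,
                                B = config$B,
                                meta = list(config_hash = hash))
  loo <- looValidate(features, labels, retained = selection$retained,
                     gain = config$gain, A = config$A, B = config$B,
                     refit = config$loo_refit, cohort = cohort,
                     n_components = config$n_components)
  beliefs <- classifyBeliefs(classifier, features)
  beliefs$visit <- "baseline"
  beliefs <- cbind(beliefs, simplexCoordinates(beliefs))
  beliefs$true <- unname(labels)
  beliefs$correct <- beliefs$predicted == beliefs$true
  result <- list(models = models, features = features,
                 selection = selection, classifier = classifier, loo = loo,
                 beliefs = beliefs, config = config, hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writePCAModels(models, file.path(out_dir, "pca_models.json"),
                   meta = list(config_hash = hash))
    writeClassifier(classifier, file.path(out_dir, "classifier.json"))
    write.csv(rankingReport(selection), file.path(out_dir, "ranking.csv"),
              row.names = FALSE)
    write.csv(beliefs, file.path(out_dir, "beliefs_baseline.csv"),
              row.names = FALSE)
    write.csv(loo$per_subject, file.path(out_dir, "loo_report.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, n_features = ncol(features),
           n_retained = length(selection$retained),
           loo = loo$summary[c("n_correct", "n_total", "accuracy")]),
      file.path(out_dir, "train_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Follow-up stage: post-operative beliefs, change summaries, correlations
#'
#' Projects the post-operative visit through the trained pipeline (no
#' refitting), computes the pre-to-post change in `B(OA)`, `B(NP)` and `U`
#' alongside the PROM percent scores, correlates `B(OA)` against each PROM
#' at baseline, post-operatively, and as change scores, and orders subjects
#' by objective recovery for the arrow plot. Refuses to mix artifacts: the
#' classifier's stamped config hash must match the supplied configuration.
#'
#' Correlations that are undefined on the available data (fewer than three
#' pairwise-complete pairs, or a zero-variance margin, as when all changes
#' are exactly zero) are reported as `NA` rows rather than dropped.
#'
#' @param trained result of [runTrain()] (or a list with `models`,
#'   `classifier`, `beliefs`, `hash`).
#' @param cohort a [GaitCohort-class] with baseline and postop visits and
#'   PROM records.
#' @param config the `gait_pipeline_config` used at training.
#' @param out_dir optional directory; writes `beliefs_postop.csv`,
#'   `change_summary.csv`, `correlations.csv` and `arrow_plot.csv`.
#' @return list with elements `postop_beliefs`, `changes`, `ordering`,
#'   `change_table`, `correlation_table`, `hash`.
#' @export
runFollowup <- function(trained, cohort, config = trained$config,
                        out_dir = NULL) {
  stopifnot(is(cohort, "GaitCohort"))
  hash <- configHash(config)
  stamped <- trained$classifier@meta$config_hash
  if (!is.null(stamped) && !identical(stamped, hash)) {
    stop("config hash mismatch: trained artifacts were produced under a ",
         "different configuration", call. = FALSE)
  }
  postop <- applyPostop(trained$classifier, trained$models, cohort)
  postop <- cbind(postop, simplexCoordinates(postop))
  base <- trained$beliefs
  changes <- beliefChange(base[, c("subject_id", "b_OA")],
                          postop[, c("subject_id", "b_OA")])
  ordering <- arrowOrdering(changes)

  # objective change summaries over the post-operative subset
  ids <- changes$subject_id
  bi <- match(ids, base$subject_id)
  pi <- match(ids, postop$subject_id)
  objective <- rbind(
    changeSummary(base$b_OA[bi], postop$b_OA[pi], "B(OA)",
                  alpha = config$normality_alpha),
    changeSummary(base$b_NP[bi], postop$b_NP[pi], "B(NP)",
                  alpha = config$normality_alpha),
    changeSummary(base$u[bi], postop$u[pi], "U",
                  alpha = config$normality_alpha))

  proms <- promRecords(cohort)
  instruments <- unique(proms$instrument)
  subjective <- do.call(rbind, lapply(instruments, function(inst) {
    w <- promWide(proms, inst, ids)
    changeSummary(w$baseline, w$postop, paste0(inst, " (%)"),
                  alpha = config$normality_alpha)
  }))
  change_table <- rbind(objective, subjective)

  correlation_table <- do.call(rbind, lapply(instruments, function(inst) {
    w <- promWide(proms, inst, ids)
    rbind(
      safeCorrelation(base$b_OA[bi], w$baseline,
                      paste0("B(OA)~", inst), "baseline",
                      config$normality_alpha),
      safeCorrelation(postop$b_OA[pi], w$postop,
                      paste0("B(OA)~", inst), "postop",
                      config$normality_alpha),
      safeCorrelation(changes$delta_b_OA, w$postop - w$baseline,
                      paste0("dB(OA)~d", inst), "change",
                      config$normality_alpha))
  }))

  result <- list(postop_beliefs = postop, changes = changes,
                 ordering = ordering, change_table = change_table,
                 correlation_table = correlation_table, hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(postop, file.path(out_dir, "beliefs_postop.csv"),
              row.names = FALSE)
    write.csv(change_table, file.path(out_dir, "change_summary.csv"),
              row.names = FALSE)
    write.csv(correlation_table, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
    write.csv(ordering, file.path(out_dir, "arrow_plot.csv"),
              row.names = FALSE)
  }
  result
}

# PROM percent scores in wide (baseline/postop) form for given subjects.
promWide <- function(proms, instrument, ids) {
  p <- proms[proms$instrument == instrument, , drop = FALSE]
  pick <- function(visit) {
    v <- p[p$visit == visit, , drop = FALSE]
    v$percent_score[match(ids, v$subject_id)]
  }
  data.frame(subject_id = ids, baseline = pick("baseline"),
             postop = pick("postop"), stringsAsFactors = FALSE)
}

# Correlation row that degrades to NA when undefined on the data.
safeCorrelation <- function(x, y, pair, timepoint, alpha) {
  row <- tryCatch(
    correlateOutcome(x, y, alpha = alpha, pair = pair),
    error = function(e) data.frame(pair = pair, method = NA_character_,
                                   r = NA_real_, p = NA_real_,
                                   n = sum(complete.cases(x, y)),
                                   stringsAsFactors = FALSE))
  cbind(timepoint = timepoint, row)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience front-end of the generator: simulates per
#' [generateCohort()] and writes the exchange-format CSVs plus
#' `ground_truth.csv` (subject id and latent recovery fraction).
#'
#' @param spec a [generatorSpec()].
#' @param out_dir output directory.
#' @return invisibly, the [generateCohort()] result.
#' @export
simulateCohort <- function(spec = generatorSpec(), out_dir) {
  sim <- generateCohort(spec)
  writeCohort(sim$cohort, out_dir)
  write.csv(sim$truth$rho, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(sim)
}
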