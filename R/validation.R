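#' Leave-one-out cross-validation of the belief classifier
#'
#' For each subject the transfer (control) parameters are refitted on the
#' remaining n-1 subjects and the held-out subject is classified; this is
#' repeated until every subject has been classified. By default the PCA
#' models and the retained feature set are fitted once on the full training
#' data and held fixed inside the loop — only the classification control
#' parameters are refitted per fold. This mirrors the usual workflow but is
#' a known source of optimistic bias; `refit = "full"` additionally refits
#' the per-variable PCA models within each fold (the retained feature ids
#' are kept) for comparison.
#'
#' @param features subjects x features matrix from the full-data PCA
#'   (ignored per fold when `refit = "full"`).
#' @param labels character `"NP"`/`"OA"` per row.
#' @param retained feature ids to use (default: all columns).
#' @param gain,A,B transfer constants.
#' @param refit `"params"` (default) or `"full"`.
#' @param cohort the [GaitCohort-class]; required when `refit = "full"`.
#' @param n_components PCA components per variable when `refit = "full"`.
#' @return an object of class `gait_loo_report`: list with `per_subject`
#'   (data.frame: subject_id, b_OA, b_NP, u, predicted, true, correct) and
#'   `summary` (n_correct, n_total, accuracy, per-cohort breakdown).
#' @export
looValidate <- function(features, labels, retained = colnames(features),
                        gain = 2, A = 0.2, B = 0.9,
                        refit = c("params", "full"), cohort = NULL,
                        n_components = 3L) {
  refit <- match.arg(refit)
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  if (refit == "full" && is.null(cohort)) {
    stop("refit = 'full' requires the cohort", call. = FALSE)
  }
  n <- nrow(features)
  ids <- rownames(features)
  res <- vector("list", n)
  dropped_any <- FALSE
  for (i in seq_len(n)) {
    lab_train <- labels[-i]
    if (sum(lab_train == "NP") < 1L || sum(lab_train == "OA") < 1L) {
      stop("cohort collapses when holding out subject ", ids[i],
           call. = FALSE)
    }
    if (refit == "params") {
      train <- features[-i, retained, drop = FALSE]
      test <- features[i, retained, drop = FALSE]
    } else {
      sub <- subsetBaseline(cohort, ids[-i])
      models <- fitAllPCA(sub, retained = n_components)
      train_all <- buildFeatureMatrix(models, sub, "baseline")
      test_all <- buildFeatureMatrix(models, subsetBaseline(cohort, ids[i]),
                                     "baseline")
      train <- train_all[, retained, drop = FALSE]
      test <- test_all[, retained, drop = FALSE]
    }
    tab <- fitTransferTable(train, lab_train, gain = gain, A = A, B = B)
    keep <- !is.na(tab$k)
    if (!all(keep)) dropped_any <- TRUE
    if (!any(keep)) {
      stop("all features degenerate in fold for subject ", ids[i],
           call. = FALSE)
    }
    tab <- tab[keep, , drop = FALSE]
    cf <- confidenceFactor(test[1L, tab$feature], tab$k, tab$theta)
    triplet <- combineEvidence(massAssignment(cf, A, B))
    res[[i]] <- data.frame(
      subject_id = ids[i], b_OA = triplet[["m_OA"]],
      b_NP = triplet[["m_NP"]], u = triplet[["m_U"]],
      stringsAsFactors = FALSE)
  }
  if (dropped_any) {
    warning("degenerate feature(s) were excluded in some folds",
            call. = FALSE)
  }
  per <- do.call(rbind, res)
  per$predicted <- ifelse(per$b_OA > per$b_NP, "OA",
                          ifelse(per$b_NP > per$b_OA, "NP", "tie"))
  per$true <- unname(labels)
  per$correct <- per$predicted == per$true
  by_cohort <- do.call(rbind, lapply(c("NP", "OA"), function(g) {
    idx <- per$true == g
    data.frame(cohort = g, n = sum(idx), n_correct = sum(per$correct[idx]),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    per_subject = per,
    summary = list(n_correct = sum(per$correct), n_total = n,
                   accuracy = mean(per$correct), by_cohort = by_cohort)),
    class = "gait_loo_report")
}

#' @export
print.gait_loo_report <- function(x, ...) {
  s <- x$summary
  cat("Leave-one-out cross-validation:", s$n_correct, "/", s$n_total,
      "correct (", sprintf("%.1f%%", 100 * s$accuracy), ")\n")
  for (i in seq_len(nrow(s$by_cohort))) {
    cat("  ", s$by_cohort$cohort[i], ": ", s$by_cohort$n_correct[i], "/",
        s$by_cohort$n[i], "\n", sep = "")
  }
  invisible(x)
}

# Baseline-only cohort restricted to the given subjects (helper for
# full-pipeline LOO refits).
subsetBaseline <- function(cohort, ids) {
  curves <- list(baseline = lapply(cohort@curves$baseline, function(m) {
    m[intersect(rownames(m), ids), , drop = FALSE]
  }))
  subj <- cohort@subjects[cohort@subjects$subject_id %in% ids, , drop = FALSE]
  new("GaitCohort", subjects = subj, curves = curves,
      variables = cohort@variables, units = cohort@units,
      proms = cohort@proms[0, , drop = FALSE])
}

#' Project post-operative visits through the trained pipeline
#'
#' Post-operative waveforms are projected onto the principal components
#' trained at baseline (never refitted) and classified with the fully
#' trained classifier, so no post-operative data leaks into training.
#' Post-operative subjects absent from the training cohort are still
#' classified, with a warning.
#'
#' @param classifier a [TrainedClassifier-class] trained on the full
#'   baseline data.
#' @param models named list of baseline-trained [PCAModel-class] objects.
#' @param cohort a [GaitCohort-class] with a `postop` visit.
#' @return data.frame of belief triplets with a `visit = "postop"` column.
#' @export
applyPostop <- function(classifier, models, cohort) {
  stopifnot(is(cohort, "GaitCohort"))
  if (!"postop" %in% gaitVisits(cohort)) {
    stop("cohort has no post-operative visit", call. = FALSE)
  }
  feats <- buildFeatureMatrix(models, cohort, "postop")
  base_ids <- if ("baseline" %in% gaitVisits(cohort)) {
    rownames(cohort@curves$baseline[[1L]])
  } else character()
  stray <- setdiff(rownames(feats), base_ids)
  if (length(stray)) {
    warning("post-operative subject(s) absent from the training cohort: ",
            paste(stray, collapse = ", "), call. = FALSE)
  }
  out <- classifyBeliefs(classifier, feats)
  out$visit <- "postop"
  out
}
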