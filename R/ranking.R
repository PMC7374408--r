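#' Split a training cohort into two stratified halves
#'
#' Randomly partitions subjects into two halves, stratified by cohort so
#' that the NP/OA proportions are preserved within one subject. The split
#' is deterministic given the seed. With 31 NP + 41 OA subjects the halves
#' are (16 NP, 21 OA) and (15 NP, 20 OA).
#'
#' @param labels named character vector of `"NP"`/`"OA"` labels (names are
#'   subject ids), e.g. from [cohortLabels()].
#' @param seed integer seed.
#' @return list with character vectors `half1`, `half2`.
#' @export
splitHalves <- function(labels, seed = 1L) {
  ids_np <- names(labels)[labels == "NP"]
  ids_oa <- names(labels)[labels == "OA"]
  if (length(ids_np) < 4L || length(ids_oa) < 4L) {
    stop("need at least 4 subjects per cohort to split into halves",
         call. = FALSE)
  }
  set.seed(substreamSeed(seed, "split_halves"))
  half1 <- c()
  for (ids in list(ids_np, ids_oa)) {
    shuffled <- sample(ids)
    half1 <- c(half1, shuffled[seq_len(ceiling(length(ids) / 2))])
  }
  all_ids <- names(labels)
  list(half1 = all_ids[all_ids %in% half1],
       half2 = all_ids[!all_ids %in% half1])
}

#' Rank features by single-feature leave-one-out classification accuracy
#'
#' Each candidate feature is scored on its own: for every subject in the
#' half, the transfer parameters are fitted on the remaining n-1 subjects
#' and the held-out subject is classified from that single feature's body
#' of evidence. Features are sorted by descending LOO accuracy, with ties
#' broken by the mean belief margin `|m_OA - m_NP|` over the held-out
#' predictions, then by column (registry) order. Degenerate features rank
#' last with zero score.
#'
#' @param features subjects x features numeric matrix.
#' @param labels character vector of `"NP"`/`"OA"` per row.
#' @param gain,A,B transfer constants, see [fitTransferParams()].
#' @return data.frame (one row per feature, sorted) with columns `feature`,
#'   `rank`, `score`, `margin`.
#' @export
rankFeatures <- function(features, labels, gain = 2, A = 0.2, B = 0.9) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  n <- nrow(features)
  if (sum(labels == "NP") < 2L || sum(labels == "OA") < 2L) {
    stop("need at least 2 subjects per cohort", call. = FALSE)
  }
  score <- margin <- numeric(ncol(features))
  for (j in seq_len(ncol(features))) {
    x <- features[, j]
    correct <- logical(n)
    marg <- numeric(n)
    for (i in seq_len(n)) {
      if (sum(labels[-i] == "NP") < 1L || sum(labels[-i] == "OA") < 1L) {
        next  # cohort collapses without this subject: unclassifiable
      }
      par <- fitTransferParams(x[-i][labels[-i] == "NP"],
                               x[-i][labels[-i] == "OA"],
                               gain = gain, A = A, B = B)
      if (isTRUE(par$degenerate)) next  # unclassifiable: incorrect, margin 0
      boe <- massAssignment(confidenceFactor(x[i], par$k, par$theta), A, B)
      marg[i] <- abs(boe[1L, "m_OA"] - boe[1L, "m_NP"])
      pred <- if (boe[1L, "m_OA"] > boe[1L, "m_NP"]) "OA"
              else if (boe[1L, "m_NP"] > boe[1L, "m_OA"]) "NP" else "tie"
      correct[i] <- pred == labels[i]
    }
    score[j] <- mean(correct)
    margin[j] <- mean(marg)
  }
  ord <- order(-score, -margin, seq_along(score))
  data.frame(feature = colnames(features)[ord], rank = seq_along(ord),
             score = score[ord], margin = margin[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Retain features highly ranked in both halves
#'
#' Finds the smallest depth `K` such that the top-`K` lists of the two
#' half-rankings share at least `target_size` features; the retained set is
#' that intersection (so it may slightly exceed the target). If no depth
#' suffices, the full-universe intersection is returned with a warning.
#' The retained set is reported in order of increasing summed rank, ties by
#' first-half rank.
#'
#' @param ranking1,ranking2 rankings from [rankFeatures()] over the same
#'   feature universe.
#' @param target_size minimum number of features to retain (default 18).
#' @return list with elements `retained` (character vector), `k_used`,
#'   `ranking1`, `ranking2`.
#' @export
selectRetained <- function(ranking1, ranking2, target_size = 18L) {
  if (!setequal(ranking1$feature, ranking2$feature)) {
    stop("rankings cover different feature universes", call. = FALSE)
  }
  universe <- ranking1$feature
  if (!length(universe)) stop("empty feature universe", call. = FALSE)
  retained <- NULL
  k_used <- NA_integer_
  for (K in seq_along(universe)) {
    inter <- intersect(ranking1$feature[seq_len(K)],
                       ranking2$feature[seq_len(K)])
    if (length(inter) >= target_size) {
      retained <- inter
      k_used <- K
      break
    }
  }
  if (is.null(retained)) {
    warning("top-K intersection never reached the target size; ",
            "retaining the full-universe intersection", call. = FALSE)
    retained <- universe
    k_used <- length(universe)
  }
  r1 <- match(retained, ranking1$feature)
  r2 <- match(retained, ranking2$feature)
  retained <- retained[order(r1 + r2, r1)]
  list(retained = retained, k_used = k_used,
       ranking1 = ranking1, ranking2 = ranking2)
}

#' Tabular report of a split-half ranking
#'
#' @param selection result of [selectRetained()].
#' @return data.frame with columns `feature_id`, `half1_rank`,
#'   `half1_score`, `half2_rank`, `half2_score`, `retained`.
#' @export
rankingReport <- function(selection) {
  r1 <- selection$ranking1
  r2 <- selection$ranking2
  idx2 <- match(r1$feature, r2$feature)
  data.frame(feature_id = r1$feature,
             half1_rank = r1$rank, half1_score = r1$score,
             half2_rank = r2$rank[idx2], half2_score = r2$score[idx2],
             retained = r1$feature %in% selection$retained,
             row.names = NULL, stringsAsFactors = FALSE)
}
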