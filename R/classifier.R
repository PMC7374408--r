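#' Sigmoid confidence factor of a feature value
#'
#' `cf = 1 / (1 + exp(-k * (v - theta)))`, strictly monotone in `v` with the
#' sign of `k`. The result is clamped to `[1e-15, 1 - 1e-15]` before mass
#' assignment to guard against overflow at extreme feature values.
#'
#' @param v numeric vector of feature values.
#' @param k sigmoid slope (signed).
#' @param theta sigmoid midpoint.
#' @return confidence factors in `(0, 1)`.
#' @export
confidenceFactor <- function(v, k, theta) {
  cf <- 1 / (1 + exp(-k * (v - theta)))
  pmin(pmax(cf, 1e-15), 1 - 1e-15)
}

#' Map a confidence factor to a body of evidence
#'
#' CaRBS-style linear map of the confidence factor onto the mass triplet
#' over the frame of discernment \{OA\}, \{NP\}, Theta = \{OA, NP\}:
#' `m_OA = max(0, B/(1-A) * cf - A*B/(1-A))`,
#' `m_NP = max(0, -B/(1-A) * cf + B)`, `m_U = 1 - m_OA - m_NP`.
#' `A` is the ignorance margin (the confidence factor at which evidence
#' toward OA begins) and `B < 1` the maximum assignable belief, so a single
#' feature always leaves residual uncertainty `m_U >= 1 - B`.
#'
#' @param cf confidence factor(s) in `(0, 1)`.
#' @param A ignorance margin in `[0, 1)`.
#' @param B maximum assignable belief in `(0, 1)`.
#' @return a matrix with columns `m_OA`, `m_NP`, `m_U` (one row per `cf`).
#' @export
massAssignment <- function(cf, A = 0.2, B = 0.9) {
  if (A < 0 || A >= 1 || B <= 0 || B >= 1) {
    stop("require 0 <= A < 1 and 0 < B < 1", call. = FALSE)
  }
  m_oa <- pmax(0, (B / (1 - A)) * cf - A * B / (1 - A))
  m_np <- pmax(0, -(B / (1 - A)) * cf + B)
  cbind(m_OA = m_oa, m_NP = m_np, m_U = 1 - m_oa - m_np)
}

#' Combine two bodies of evidence by Dempster's rule
#'
#' Normalised conjunctive combination on the two-hypothesis frame:
#' with conflict `kappa = m1_OA * m2_NP + m1_NP * m2_OA`,
#' `m_OA = (m1_OA*m2_OA + m1_OA*m2_U + m1_U*m2_OA) / (1 - kappa)`, the
#' symmetric form for `m_NP`, and `m_U = m1_U * m2_U / (1 - kappa)`.
#' The vacuous body of evidence `(0, 0, 1)` is the identity; the rule is
#' commutative and associative.
#'
#' @param b1,b2 numeric triplets `(m_OA, m_NP, m_U)` summing to 1.
#' @return a named numeric triplet `(m_OA, m_NP, m_U)`.
#' @examples
#' dempsterCombine(c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2))
#' @export
dempsterCombine <- function(b1, b2) {
  kappa <- b1[[1L]] * b2[[2L]] + b1[[2L]] * b2[[1L]]
  if (kappa >= 1) {
    stop("total conflict between bodies of evidence (kappa = 1)",
         call. = FALSE)
  }
  out <- c(m_OA = b1[[1L]] * b2[[1L]] + b1[[1L]] * b2[[3L]] + b1[[3L]] * b2[[1L]],
           m_NP = b1[[2L]] * b2[[2L]] + b1[[2L]] * b2[[3L]] + b1[[3L]] * b2[[2L]],
           m_U  = b1[[3L]] * b2[[3L]])
  # dividing by the exact mass sum rather than 1 - kappa keeps long folds on
  # the simplex: with near-certain masses the two differ by rounding, and
  # that drift compounds multiplicatively over repeated combination
  out / sum(out)
}

#' Combine a stack of bodies of evidence
#'
#' Left-fold of [dempsterCombine()] over the rows of a mass matrix. By
#' associativity and commutativity of Dempster's rule the order is
#' immaterial.
#'
#' @param boes matrix with columns `(m_OA, m_NP, m_U)`, one row per feature.
#' @return a named numeric triplet.
#' @export
combineEvidence <- function(boes) {
  stopifnot(is.matrix(boes), ncol(boes) == 3L, nrow(boes) >= 1L)
  out <- boes[1L, ]
  for (i in seq_len(nrow(boes))[-1L]) {
    out <- dempsterCombine(out, boes[i, ])
  }
  # renormalise to absorb the floating-point drift of the fold
  setNames(out / sum(out), c("m_OA", "m_NP", "m_U"))
}

#' Fit the transfer parameters of one feature from labelled training values
#'
#' The control parameters are defined explicitly from group statistics, not
#' iteratively optimised: the midpoint sits between the group means,
#' `theta = (mean_NP + mean_OA) / 2`, and the slope scales the pooled spread,
#' `k = sign(mean_OA - mean_NP) * 2 * gain / (sd_NP + sd_OA)`, so that a
#' feature value at either group mean maps to a confidence factor of
#' `1 / (1 + exp(-gain * d))` roughly `gain` logits from the midpoint for a
#' one-pooled-SD separation. Features with zero spread or zero group
#' separation are degenerate and must be excluded by the caller.
#'
#' @param x_np,x_oa numeric feature values of the NP and OA training
#'   subjects (each of length >= 2).
#' @param gain slope gain (default 2).
#' @param A,B mass-assignment constants, see [massAssignment()].
#' @return list with elements `k`, `theta`, `A`, `B`, `degenerate`.
#' @note Inside leave-one-out folds a group can shrink to a single subject;
#'   a singleton group contributes zero spread (its `sd` is taken as 0)
#'   rather than aborting the fold.
#' @export
fitTransferParams <- function(x_np, x_oa, gain = 2, A = 0.2, B = 0.9) {
  stopifnot(length(x_np) >= 1L, length(x_oa) >= 1L)
  sd0 <- function(v) if (length(v) < 2L) 0 else sd(v)
  m_np <- mean(x_np); m_oa <- mean(x_oa)
  spread <- sd0(x_np) + sd0(x_oa)
  sep <- m_oa - m_np
  if (spread == 0 || sep == 0) {
    return(list(k = NA_real_, theta = (m_np + m_oa) / 2, A = A, B = B,
                degenerate = TRUE))
  }
  list(k = sign(sep) * 2 * gain / spread, theta = (m_np + m_oa) / 2,
       A = A, B = B, degenerate = FALSE)
}

# Vectorised transfer-parameter fit over the columns of a feature matrix.
# Returns a data.frame with one row per feature; degenerate features carry
# k = NA.
fitTransferTable <- function(features, labels, gain = 2, A = 0.2, B = 0.9) {
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  np <- features[labels == "NP", , drop = FALSE]
  oa <- features[labels == "OA", , drop = FALSE]
  if (nrow(np) < 1L || nrow(oa) < 1L) {
    stop("cannot fit transfer parameters: a cohort is empty", call. = FALSE)
  }
  m_np <- colMeans(np); m_oa <- colMeans(oa)
  colSd <- function(m) if (nrow(m) < 2L) rep(0, ncol(m)) else apply(m, 2L, sd)
  sd_np <- colSd(np); sd_oa <- colSd(oa)
  sep <- m_oa - m_np
  spread <- sd_np + sd_oa
  k <- ifelse(spread == 0 | sep == 0, NA_real_,
              sign(sep) * 2 * gain / spread)
  data.frame(feature = colnames(features), k = k, theta = (m_np + m_oa) / 2,
             A = A, B = B, row.names = NULL, stringsAsFactors = FALSE)
}

#' Train the belief classifier on a feature matrix
#'
#' Fits explicit transfer parameters for every retained feature from the
#' labelled training rows. Degenerate features (zero spread or zero group
#' separation) are excluded with a warning rather than given an infinite
#' slope.
#'
#' @param features subjects x features numeric matrix (see
#'   [buildFeatureMatrix()]).
#' @param labels character vector of `"NP"`/`"OA"` per row.
#' @param retained character vector of feature ids to use (default: all
#'   columns).
#' @param gain,A,B transfer constants, see [fitTransferParams()].
#' @param meta optional named list stored in the classifier.
#' @return a [TrainedClassifier-class] object.
#' @export
trainClassifier <- function(features, labels, retained = colnames(features),
                            gain = 2, A = 0.2, B = 0.9, meta = list()) {
  missing_feats <- setdiff(retained, colnames(features))
  if (length(missing_feats)) {
    stop("feature(s) absent from the matrix: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  if (sum(labels == "NP") < 2L || sum(labels == "OA") < 2L) {
    stop("need at least 2 subjects per cohort to train", call. = FALSE)
  }
  tab <- fitTransferTable(features[, retained, drop = FALSE], labels,
                          gain = gain, A = A, B = B)
  bad <- is.na(tab$k)
  if (any(bad)) {
    warning("excluding degenerate feature(s): ",
            paste(tab$feature[bad], collapse = ", "), call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stop("all features degenerate; nothing to train",
                       call. = FALSE)
  meta <- c(meta, list(n_np = sum(labels == "NP"), n_oa = sum(labels == "OA"),
                       gain = gain))
  new("TrainedClassifier", features = tab$feature, params = tab, meta = meta)
}

#' Classify feature rows into belief triplets
#'
#' Maps every retained feature value through its sigmoid transfer function
#' and mass assignment, combines the per-feature bodies of evidence by
#' Dempster's rule, and reports the final beliefs `B(OA)`, `B(NP)` and
#' uncertainty `U` (on a two-hypothesis frame the singleton beliefs equal
#' the combined masses). The predicted label is OA iff `B(OA) > B(NP)`, NP
#' iff `B(NP) > B(OA)`; exact ties are flagged `"tie"` and counted as
#' incorrect by downstream accuracy summaries.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param features numeric matrix (subjects x features, with column names)
#'   or a named numeric vector for a single subject.
#' @return data.frame with columns `subject_id`, `b_OA`, `b_NP`, `u`,
#'   `predicted`.
#' @export
classifyBeliefs <- function(classifier, features) {
  stopifnot(is(classifier, "TrainedClassifier"))
  if (!is.matrix(features)) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list("subject", names(features)))
  }
  missing_feats <- setdiff(classifier@features, colnames(features))
  if (length(missing_feats)) {
    stop("missing feature(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  p <- classifier@params
  x <- features[, p$feature, drop = FALSE]
  out <- matrix(NA_real_, nrow = nrow(x), ncol = 3L)
  for (i in seq_len(nrow(x))) {
    cf <- confidenceFactor(x[i, ], p$k, p$theta)
    boes <- massAssignment(cf, p$A[1L], p$B[1L])
    out[i, ] <- combineEvidence(boes)
  }
  predicted <- ifelse(out[, 1L] > out[, 2L], "OA",
                      ifelse(out[, 2L] > out[, 1L], "NP", "tie"))
  data.frame(subject_id = rownames(x), b_OA = out[, 1L], b_NP = out[, 2L],
             u = out[, 3L], predicted = predicted,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Barycentric simplex coordinates of belief triplets
#'
#' Places each triplet in the unit-side triangle with vertices
#' `v_NP = (0, 0)`, `v_OA = (1, 0)` and `v_U = (0.5, sqrt(3)/2)`:
#' `p = b_NP * v_NP + b_OA * v_OA + u * v_U`. The decision boundary
#' `B(OA) = B(NP)` is the vertical line `x = 0.5`.
#'
#' @param triplets data.frame with columns `b_OA`, `b_NP`, `u` (e.g. from
#'   [classifyBeliefs()]), or a numeric triplet `(b_NP, b_OA, u)`.
#' @return matrix with columns `x`, `y`.
#' @export
simplexCoordinates <- function(triplets) {
  if (is.data.frame(triplets)) {
    b_oa <- triplets$b_OA; u <- triplets$u
  } else {
    stopifnot(length(triplets) == 3L)
    b_oa <- triplets[[2L]]; u <- triplets[[3L]]
  }
  cbind(x = b_oa + 0.5 * u, y = u * sqrt(3) / 2)
}

#' Pre-to-post change in the belief of osteoarthritic gait
#'
#' `delta = B(OA, postop) - B(OA, baseline)` per subject; negative values
#' indicate objective biomechanical improvement.
#'
#' @param baseline,postop data.frames with columns `subject_id`, `b_OA`
#'   (and optionally `visit`, which is checked when present).
#' @return data.frame with columns `subject_id`, `baseline_b_OA`,
#'   `postop_b_OA`, `delta_b_OA`, restricted to subjects present at both
#'   visits.
#' @export
beliefChange <- function(baseline, postop) {
  if (!is.null(baseline$visit) && any(baseline$visit != "baseline")) {
    stop("'baseline' triplets carry a non-baseline visit", call. = FALSE)
  }
  if (!is.null(postop$visit) && any(postop$visit != "postop")) {
    stop("'postop' triplets carry a non-postop visit", call. = FALSE)
  }
  common <- intersect(baseline$subject_id, postop$subject_id)
  b <- baseline[match(common, baseline$subject_id), ]
  p <- postop[match(common, postop$subject_id), ]
  data.frame(subject_id = common, baseline_b_OA = b$b_OA,
             postop_b_OA = p$b_OA, delta_b_OA = p$b_OA - b$b_OA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialise a trained classifier to JSON
#'
#' @param classifier a [TrainedClassifier-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeClassifier <- function(classifier, path) {
  payload <- list(features = classifier@features,
                  params = classifier@params,
                  meta = classifier@meta)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trained classifier from JSON
#'
#' @param path JSON file written by [writeClassifier()].
#' @return a [TrainedClassifier-class].
#' @export
readClassifier <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TrainedClassifier", features = as.character(payload$features),
      params = as.data.frame(payload$params),
      meta = as.list(payload$meta))
}
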