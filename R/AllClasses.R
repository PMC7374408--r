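#' GaitCohort: subjects, time-normalised waveforms and PROM records
#'
#' Container for a gait study cohort. Waveforms are stored per visit and per
#' biomechanical variable as numeric matrices with one row per subject and
#' 101 columns spanning 0--100% of the gait cycle. Patient-reported outcome
#' measures (PROMs) are kept in long form alongside.
#'
#' @slot subjects data.frame with columns `subject_id` and `cohort`
#'   (`"NP"` or `"OA"`).
#' @slot curves named list: visit (`"baseline"`, `"postop"`) -> variable name
#'   -> numeric matrix (subjects x 101) with subject ids as row names.
#' @slot variables character vector, the variable registry; every visit holds
#'   exactly this set of variables.
#' @slot units named character vector of measurement units per variable.
#' @slot proms data.frame with columns `subject_id`, `visit`, `instrument`,
#'   `raw_score`, `percent_score` (percent: 100 = healthy; `NA` = missing).
#'
#' @details Invariants enforced by the validity method: exactly 101 finite
#' samples per waveform; every visit present carries the identical variable
#' set; non-pathological (NP) subjects have a baseline visit only; PROM
#' percent scores lie in `[0, 100]` or are `NA` (missing scores are
#' represented, never imputed).
#'
#' @export
setClass("GaitCohort",
  representation(
    subjects  = "data.frame",
    curves    = "list",
    variables = "character",
    units     = "character",
    proms     = "data.frame"
  )
)

setValidity("GaitCohort", function(object) {
  msgs <- character()
  subj <- object@subjects
  if (!all(c("subject_id", "cohort") %in% names(subj))) {
    return("@subjects must have columns subject_id, cohort")
  }
  if (anyDuplicated(subj$subject_id)) {
    msgs <- c(msgs, "duplicated subject ids")
  }
  if (!all(subj$cohort %in% c("NP", "OA"))) {
    msgs <- c(msgs, "cohort labels must be 'NP' or 'OA'")
  }
  bad_visit <- setdiff(names(object@curves), c("baseline", "postop"))
  if (length(bad_visit)) {
    msgs <- c(msgs, paste("unknown visit(s):", paste(bad_visit, collapse = ", ")))
  }
  for (visit in names(object@curves)) {
    vars <- names(object@curves[[visit]])
    if (!setequal(vars, object@variables)) {
      msgs <- c(msgs, sprintf(
        "visit '%s' does not carry the full variable registry", visit))
    }
    for (v in vars) {
      m <- object@curves[[visit]][[v]]
      if (!is.matrix(m) || ncol(m) != GAIT_SAMPLES) {
        msgs <- c(msgs, sprintf(
          "waveforms for %s/%s must be a matrix with %d columns",
          visit, v, GAIT_SAMPLES))
        next
      }
      if (!all(is.finite(m))) {
        msgs <- c(msgs, sprintf("non-finite samples in %s/%s", visit, v))
      }
      if (is.null(rownames(m)) || !all(rownames(m) %in% subj$subject_id)) {
        msgs <- c(msgs, sprintf("unknown subject ids in %s/%s", visit, v))
      }
    }
  }
  if ("postop" %in% names(object@curves) && length(object@curves$postop)) {
    po <- rownames(object@curves$postop[[1L]])
    np <- subj$subject_id[subj$cohort == "NP"]
    if (any(po %in% np)) {
      msgs <- c(msgs, "NP subjects must have a baseline visit only")
    }
  }
  if (nrow(object@proms)) {
    need <- c("subject_id", "visit", "instrument", "raw_score", "percent_score")
    if (!all(need %in% names(object@proms))) {
      msgs <- c(msgs, "@proms must have columns subject_id, visit, instrument, raw_score, percent_score")
    } else {
      pct <- object@proms$percent_score
      if (any(!is.na(pct) & (pct < 0 | pct > 100))) {
        msgs <- c(msgs, "percent_score outside [0, 100]")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PCAModel: principal components of one variable's gait waveforms
#'
#' Trained principal-component model for a single biomechanical variable:
#' the pointwise mean curve over the pooled NP+OA training cohort and the
#' retained orthonormal component curves, ordered by decreasing explained
#' variance. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, removing eigenvector sign
#' ambiguity across platforms.
#'
#' @slot variable variable name.
#' @slot center numeric(101), the training mean curve.
#' @slot rotation 101 x k matrix of orthonormal component curves (columns).
#' @slot variance numeric(k), explained variance per component,
#'   non-increasing.
#' @export
setClass("PCAModel",
  representation(
    variable = "character",
    center   = "numeric",
    rotation = "matrix",
    variance = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  msgs <- character()
  if (length(object@center) != GAIT_SAMPLES) {
    msgs <- c(msgs, sprintf("center must have %d samples", GAIT_SAMPLES))
  }
  if (nrow(object@rotation) != GAIT_SAMPLES) {
    msgs <- c(msgs, "rotation must have 101 rows")
  }
  k <- ncol(object@rotation)
  if (length(object@variance) != k) {
    msgs <- c(msgs, "one variance per component required")
  }
  if (k > 0) {
    gram <- crossprod(object@rotation)
    if (max(abs(gram - diag(k))) > 1e-8) {
      msgs <- c(msgs, "components must be orthonormal to 1e-8")
    }
    if (is.unsorted(rev(object@variance), strictly = FALSE)) {
      msgs <- c(msgs, "explained variance must be non-increasing")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TrainedClassifier: per-feature transfer parameters of the belief classifier
#'
#' A trained Dempster-Shafer gait classifier: the retained feature list and,
#' for each feature, the sigmoid transfer parameters (slope `k`, midpoint
#' `theta`) and the mass-assignment constants (`A`, ignorance margin; `B`,
#' maximum assignable belief).
#'
#' @slot features character vector of retained feature ids
#'   (`"<variable>.PC<k>"`), duplicate-free.
#' @slot params data.frame with one row per feature and columns
#'   `feature`, `k`, `theta`, `A`, `B`.
#' @slot meta list of training metadata (cohort sizes, config hash).
#' @export
setClass("TrainedClassifier",
  representation(
    features = "character",
    params   = "data.frame",
    meta     = "list"
  )
)

setValidity("TrainedClassifier", function(object) {
  msgs <- character()
  if (!length(object@features)) msgs <- c(msgs, "empty feature list")
  if (anyDuplicated(object@features)) msgs <- c(msgs, "duplicate features")
  need <- c("feature", "k", "theta", "A", "B")
  if (!all(need %in% names(object@params))) {
    msgs <- c(msgs, "params must have columns feature, k, theta, A, B")
  } else {
    if (!setequal(object@params$feature, object@features)) {
      msgs <- c(msgs, "params rows must match the feature list")
    }
    if (any(object@params$B >= 1 | object@params$B <= 0)) {
      msgs <- c(msgs, "B must lie in (0, 1)")
    }
    if (any(object@params$A < 0 | object@params$A >= 1)) {
      msgs <- c(msgs, "A must lie in [0, 1)")
    }
    if (any(!is.finite(object@params$k) | object@params$k == 0)) {
      msgs <- c(msgs, "k must be finite and nonzero")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GaitCohort", function(object) {
  tab <- table(factor(object@subjects$cohort, c("NP", "OA")))
  n_post <- if ("postop" %in% names(object@curves) && length(object@curves$postop)) {
    nrow(object@curves$postop[[1L]])
  } else 0L
  cat("GaitCohort:", nrow(object@subjects), "subjects (",
      tab[["NP"]], "NP /", tab[["OA"]], "OA ),",
      n_post, "with a post-operative visit\n")
  cat("  variables:", length(object@variables), "x", GAIT_SAMPLES,
      "samples per gait cycle\n")
  cat("  PROM records:", nrow(object@proms), "\n")
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel for", object@variable, "-", ncol(object@rotation),
      "components\n  explained variance:",
      paste(signif(object@variance, 4), collapse = ", "), "\n")
})

setMethod("show", "TrainedClassifier", function(object) {
  cat("TrainedClassifier:", length(object@features), "features\n")
  cat("  A =", object@params$A[1L], " B =", object@params$B[1L], "\n")
  if (!is.null(object@meta$n_np)) {
    cat("  trained on", object@meta$n_np, "NP +", object@meta$n_oa,
        "OA subjects\n")
  }
})

#' Accessors for GaitCohort objects
#'
#' @param object a [GaitCohort-class] object.
#' @return `subjectIds()`: character vector of subject ids;
#'   `cohortLabels()`: named character vector of `"NP"`/`"OA"` labels;
#'   `variableRegistry()`: character vector of variable names;
#'   `promRecords()`: the long-form PROM data.frame;
#'   `gaitVisits()`: visits present in the cohort;
#'   `waveformMatrix()`: subjects x 101 matrix for one visit and variable.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
subjectIds <- function(object) object@subjects$subject_id

#' @rdname cohort-accessors
#' @export
cohortLabels <- function(object) {
  setNames(object@subjects$cohort, object@subjects$subject_id)
}

#' @rdname cohort-accessors
#' @export
variableRegistry <- function(object) object@variables

#' @rdname cohort-accessors
#' @export
promRecords <- function(object) object@proms

#' @rdname cohort-accessors
#' @export
gaitVisits <- function(object) names(object@curves)

#' @rdname cohort-accessors
#' @param visit `"baseline"` or `"postop"`.
#' @param variable a registered variable name.
#' @export
waveformMatrix <- function(object, visit, variable) {
  if (!visit %in% names(object@curves)) {
    stop("visit '", visit, "' not present in cohort", call. = FALSE)
  }
  if (!variable %in% object@variables) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  object@curves[[visit]][[variable]]
}
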