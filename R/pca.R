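#' Fit a principal-component model for one variable's waveforms
#'
#' PCA of the pooled NP+OA training curves of a single biomechanical
#' variable. Curves are mean-centred pointwise (not variance-standardised:
#' per-variable PCA cannot mix scales across variables, and feature
#' standardisation happens inside the classifier's transfer function).
#' Components are the eigenvectors of the 101 x 101 sample covariance,
#' computed via the singular value decomposition of the centred data matrix
#' and ordered by decreasing eigenvalue. Each component's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param curves numeric matrix, subjects x 101, training waveforms.
#' @param retained number of components to retain (default 3).
#' @param variable variable name recorded in the model.
#' @return a [PCAModel-class] object.
#' @export
fitPCA <- function(curves, retained = 3L, variable = "variable") {
  stopifnot(is.matrix(curves), ncol(curves) == GAIT_SAMPLES)
  if (nrow(curves) < retained + 1L) {
    stop(sprintf(
      "need at least %d training subjects to retain %d components, got %d",
      retained + 1L, retained, nrow(curves)), call. = FALSE)
  }
  pc <- prcomp(curves, center = TRUE, scale. = FALSE)
  k <- min(retained, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) rot[, j] <- -rot[, j]
  }
  new("PCAModel", variable = variable, center = unname(pc$center),
      rotation = unname(rot), variance = unname(pc$sdev[seq_len(k)]^2))
}

#' Project a waveform onto a trained principal-component model
#'
#' `score_k = <waveform - center, component_k>`. Projection always uses the
#' trained mean and basis; post-operative curves are never refit.
#'
#' @param model a [PCAModel-class].
#' @param waveform numeric vector of 101 samples, or a subjects x 101
#'   matrix.
#' @return a score vector (or subjects x k matrix) in component order.
#' @export
pcScores <- function(model, waveform) {
  stopifnot(is(model, "PCAModel"))
  if (is.matrix(waveform)) {
    if (ncol(waveform) != GAIT_SAMPLES) {
      stop("waveform matrix must have 101 columns", call. = FALSE)
    }
    sweep(waveform, 2L, model@center) %*% model@rotation
  } else {
    if (length(waveform) != GAIT_SAMPLES) {
      stop("waveform must have 101 samples", call. = FALSE)
    }
    drop(crossprod(model@rotation, waveform - model@center))
  }
}

#' Fit PCA models for every registered variable of a cohort
#'
#' @param cohort a [GaitCohort-class]; the baseline visit of the pooled
#'   NP+OA cohort is the training set.
#' @param retained components retained per variable.
#' @return named list of [PCAModel-class] objects in registry order.
#' @export
fitAllPCA <- function(cohort, retained = 3L) {
  stopifnot(is(cohort, "GaitCohort"))
  vars <- variableRegistry(cohort)
  models <- lapply(vars, function(v) {
    fitPCA(waveformMatrix(cohort, "baseline", v), retained, variable = v)
  })
  setNames(models, vars)
}

#' Build the subjects x features PC-score matrix
#'
#' One column per (variable, component) pair, named `"<variable>.PC<k>"`,
#' in registry order then component order; one row per subject at the
#' requested visit. Every included subject must carry every registered
#' variable.
#'
#' @param models named list of [PCAModel-class] objects (one per variable).
#' @param cohort a [GaitCohort-class].
#' @param visit `"baseline"` or `"postop"`.
#' @return numeric matrix with subject ids as row names.
#' @export
buildFeatureMatrix <- function(models, cohort, visit = "baseline") {
  stopifnot(is(cohort, "GaitCohort"))
  vars <- variableRegistry(cohort)
  missing_models <- setdiff(vars, names(models))
  if (length(missing_models)) {
    stop("no PCA model for variable(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(vars, function(v) {
    m <- waveformMatrix(cohort, visit, v)
    if (anyNA(m)) {
      stop("missing waveform for variable '", v, "' at visit '", visit, "'",
           call. = FALSE)
    }
    sc <- pcScores(models[[v]], m)
    colnames(sc) <- paste0(v, ".PC", seq_len(ncol(sc)))
    sc
  })
  do.call(cbind, blocks)
}

#' Serialise trained PCA models to JSON
#'
#' Writes mean curves, component loadings and explained variances with full
#' double precision so that reloading and re-projecting is reproducible
#' bit-for-bit.
#'
#' @param models named list of [PCAModel-class] objects.
#' @param path output JSON file.
#' @param meta optional named list stored alongside (e.g. a config hash).
#' @return invisibly, `path`.
#' @export
writePCAModels <- function(models, path, meta = list()) {
  payload <- list(
    meta = meta,
    models = lapply(models, function(m) list(
      variable = m@variable,
      center = m@center,
      rotation = m@rotation,
      variance = m@variance)))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read trained PCA models from JSON
#'
#' @param path JSON file written by [writePCAModels()].
#' @return list with elements `models` (named list of [PCAModel-class]) and
#'   `meta`.
#' @export
readPCAModels <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(payload$models, function(m) {
    new("PCAModel", variable = m$variable, center = as.numeric(m$center),
        rotation = matrix(as.numeric(m$rotation), nrow = GAIT_SAMPLES),
        variance = as.numeric(m$variance))
  })
  list(models = models, meta = payload$meta)
}
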