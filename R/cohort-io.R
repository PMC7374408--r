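#' Default biomechanical variable registry
#'
#' Twenty-four time-normalised gait variables: hip, knee and ankle angles and
#' external moments in the sagittal, frontal and transverse planes (18), the
#' three ground-reaction-force components, and the three pelvic orientation
#' angles. The registry is configuration-driven; any variable set can be
#' declared via [pipelineConfig()].
#'
#' @return named character vector: names are variable ids, values are units
#'   (`deg`, `N.m/kg`, `N/kg`).
#' @export
defaultVariableRegistry <- function() {
  joints <- c("hip", "knee", "ankle")
  planes <- c("sagittal", "frontal", "transverse")
  angles <- outer(joints, planes, function(j, p) paste(j, p, "angle", sep = "_"))
  moments <- outer(joints, planes, function(j, p) paste(j, p, "moment", sep = "_"))
  grf <- c("grf_vertical", "grf_anteroposterior", "grf_mediolateral")
  pelvis <- paste("pelvis", planes, "angle", sep = "_")
  vars <- c(t(angles), t(moments), grf, pelvis)
  units <- c(rep("deg", 9L), rep("N.m/kg", 9L), rep("N/kg", 3L), rep("deg", 3L))
  setNames(units, vars)
}

#' Default PROM instrument definitions
#'
#' Native scoring ranges for the three patient-reported outcome measures.
#' The Oxford Knee Score (OKS) is taken on its original 0--48 scale where 0
#' is a perfect (healthy) score; set `oks_best_high = TRUE` for the modern
#' convention where 48 is best. The Knee Outcome Survey activities-of-daily-
#' living scale (KOS) runs 0--70 with 70 best; the Pain Audit Collection
#' System (PACS) runs 0--110 with 0 (no pain) best.
#'
#' Only the percent score (100 = healthy) is used by downstream analysis,
#' so the direction convention affects nothing but the raw-to-percent map.
#'
#' @param oks_best_high logical; if `TRUE`, OKS 48 is the healthy endpoint.
#' @return a list keyed by instrument with elements `min`, `max`, `best`.
#' @export
defaultInstruments <- function(oks_best_high = FALSE) {
  list(
    OKS  = list(min = 0, max = 48,  best = if (oks_best_high) 48 else 0),
    KOS  = list(min = 0, max = 70,  best = 70),
    PACS = list(min = 0, max = 110, best = 0)
  )
}

#' Convert a raw PROM score to a percent score (100 = healthy)
#'
#' Affine map from an instrument's native range onto `[0, 100]` with 100 at
#' the healthy endpoint and 0 at the worst. Missing raw scores propagate as
#' `NA`; they are never imputed.
#'
#' @param instrument instrument id (`"OKS"`, `"KOS"`, `"PACS"`, or any id
#'   declared in `instruments`).
#' @param raw_score numeric vector of raw scores on the native scale.
#' @param instruments instrument definitions, see [defaultInstruments()].
#' @return numeric vector of percent scores in `[0, 100]`.
#' @examples
#' percentScore("OKS", c(0, 24, 48))   # 100, 50, 0
#' @export
percentScore <- function(instrument, raw_score,
                         instruments = defaultInstruments()) {
  if (!instrument %in% names(instruments)) {
    stop("unknown instrument '", instrument, "'", call. = FALSE)
  }
  def <- instruments[[instrument]]
  worst <- if (def$best == def$max) def$min else def$max
  out_of_range <- !is.na(raw_score) &
    (raw_score < def$min | raw_score > def$max)
  if (any(out_of_range)) {
    stop(sprintf("raw %s score outside native range [%g, %g]",
                 instrument, def$min, def$max), call. = FALSE)
  }
  100 * (raw_score - worst) / (def$best - worst)
}

#' Construct a GaitCohort from long-form tables
#'
#' @param subjects data.frame with columns `subject_id`, `cohort`.
#' @param waveforms long data.frame with columns `subject_id`, `visit`,
#'   `variable_name`, `cycle_percent` (integer 0--100), `value`.
#' @param proms optional data.frame with columns `subject_id`, `visit`,
#'   `instrument`, `raw_score` (blank/NA = missing).
#' @param registry named character vector of variables and units; defaults
#'   to the variables present in `waveforms` (with unknown units).
#' @param instruments instrument definitions for percent scoring.
#' @return a validated [GaitCohort-class] object.
#' @export
gaitCohort <- function(subjects, waveforms, proms = NULL, registry = NULL,
                       instruments = defaultInstruments()) {
  subjects <- data.frame(subject_id = as.character(subjects$subject_id),
                         cohort = as.character(subjects$cohort),
                         stringsAsFactors = FALSE)
  if (is.null(registry)) {
    registry <- setNames(rep("unknown", length(unique(waveforms$variable_name))),
                         sort(unique(as.character(waveforms$variable_name))))
  }
  vars <- names(registry)
  extra <- setdiff(unique(as.character(waveforms$variable_name)), vars)
  if (length(extra)) {
    stop("variable(s) not in the registry: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  curves <- list()
  for (visit in intersect(c("baseline", "postop"),
                          unique(as.character(waveforms$visit)))) {
    wv <- waveforms[waveforms$visit == visit, , drop = FALSE]
    subj_here <- unique(as.character(wv$subject_id))
    # reject subjects that do not carry the complete variable set
    have <- table(factor(as.character(wv$subject_id), subj_here),
                  factor(as.character(wv$variable_name), vars))
    complete <- rownames(have)[apply(have > 0, 1L, all)]
    dropped <- setdiff(subj_here, complete)
    if (length(dropped)) {
      warning(sprintf(
        "visit '%s': dropping %d subject(s) with incomplete variable sets: %s",
        visit, length(dropped), paste(dropped, collapse = ", ")),
        call. = FALSE)
      wv <- wv[wv$subject_id %in% complete, , drop = FALSE]
      subj_here <- complete
    }
    subj_here <- subj_here[order(match(subj_here, subjects$subject_id))]
    per_var <- list()
    for (v in vars) {
      wvv <- wv[wv$variable_name == v, , drop = FALSE]
      m <- matrix(NA_real_, nrow = length(subj_here), ncol = GAIT_SAMPLES,
                  dimnames = list(subj_here, NULL))
      for (s in subj_here) {
        rows <- wvv[wvv$subject_id == s, , drop = FALSE]
        if (nrow(rows) != GAIT_SAMPLES ||
            !setequal(rows$cycle_percent, 0:100)) {
          stop(sprintf(
            "subject '%s', variable '%s', visit '%s': expected %d samples at 0..100%%, got %d",
            s, v, visit, GAIT_SAMPLES, nrow(rows)), call. = FALSE)
        }
        m[s, ] <- rows$value[order(rows$cycle_percent)]
      }
      per_var[[v]] <- m
    }
    curves[[visit]] <- per_var
  }
  prom_df <- promFrame(proms, instruments)
  new("GaitCohort", subjects = subjects, curves = curves,
      variables = vars, units = registry, proms = prom_df)
}

# Normalises a raw PROM table into the internal long form with percent
# scores attached; blank cells become NA and stay NA.
promFrame <- function(proms, instruments = defaultInstruments()) {
  if (is.null(proms) || !nrow(proms)) {
    return(data.frame(subject_id = character(), visit = character(),
                      instrument = character(), raw_score = numeric(),
                      percent_score = numeric(), stringsAsFactors = FALSE))
  }
  raw <- proms$raw_score
  if (is.character(raw)) raw[!nzchar(trimws(raw))] <- NA
  raw <- as.numeric(raw)
  inst <- as.character(proms$instrument)
  unknown <- setdiff(unique(inst), names(instruments))
  if (length(unknown)) {
    stop("unknown instrument(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pct <- rep(NA_real_, length(raw))
  for (i in names(instruments)) {
    idx <- inst == i
    pct[idx] <- percentScore(i, raw[idx], instruments)
  }
  data.frame(subject_id = as.character(proms$subject_id),
             visit = as.character(proms$visit),
             instrument = inst, raw_score = raw, percent_score = pct,
             stringsAsFactors = FALSE)
}

#' Read a cohort from CSV files
#'
#' Reads the package's exchange format: a long-form waveform CSV with
#' columns `subject_id`, `cohort`, `visit`, `variable_name`, `cycle_percent`
#' (integer 0--100) and `value` (one row per gait-cycle sample), and an
#' optional PROM CSV with columns `subject_id`, `visit`, `instrument`,
#' `raw_score`. Inputs sampled at other than 101 points per cycle are
#' rejected, not resampled, since resampling would silently change the PCA.
#' Unrecognised columns are ignored with a warning.
#'
#' @param waveform_path path to the waveform CSV.
#' @param prom_path optional path to the PROM CSV.
#' @param registry variable registry (named units vector); `NULL` infers it
#'   from the file.
#' @param instruments instrument definitions for percent scoring.
#' @return a validated [GaitCohort-class] object.
#' @seealso [writeCohort()] for the inverse; the two round-trip bit-exactly.
#' @export
readCohort <- function(waveform_path, prom_path = NULL, registry = NULL,
                       instruments = defaultInstruments()) {
  if (!file.exists(waveform_path)) {
    stop("waveform file not found: ", waveform_path, call. = FALSE)
  }
  wf <- read.csv(waveform_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort", "visit", "variable_name",
            "cycle_percent", "value")
  missing_cols <- setdiff(need, names(wf))
  if (length(missing_cols)) {
    stop("waveform file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(wf), need)
  if (length(extra)) {
    warning("ignoring unrecognised column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(wf$value) | is.na(wf$cycle_percent))
  if (length(bad)) {
    stop("malformed waveform row at line ", bad[1L] + 1L, call. = FALSE)
  }
  subjects <- unique(wf[, c("subject_id", "cohort")])
  proms <- NULL
  if (!is.null(prom_path)) {
    if (!file.exists(prom_path)) {
      stop("PROM file not found: ", prom_path, call. = FALSE)
    }
    proms <- read.csv(prom_path, stringsAsFactors = FALSE,
                      colClasses = c(raw_score = "character"))
  }
  gaitCohort(subjects, wf, proms, registry = registry,
             instruments = instruments)
}

#' Write a cohort to CSV files
#'
#' Writes `waveforms.csv` (long form, one row per gait-cycle sample) and,
#' when PROM records exist, `proms.csv` into `dir`. Numeric values are
#' serialised with 17 significant digits so that
#' `readCohort(writeCohort(x))` reproduces every numeric field bit-exactly.
#' Rows are emitted only for visits actually present per subject.
#'
#' @param cohort a [GaitCohort-class] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (named `waveforms`, `proms`).
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "GaitCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  rows <- list()
  labels <- cohortLabels(cohort)
  for (visit in gaitVisits(cohort)) {
    for (v in variableRegistry(cohort)) {
      m <- cohort@curves[[visit]][[v]]
      if (!nrow(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rep(rownames(m), each = GAIT_SAMPLES),
        cohort = rep(unname(labels[rownames(m)]), each = GAIT_SAMPLES),
        visit = visit,
        variable_name = v,
        cycle_percent = rep(0:100, times = nrow(m)),
        value = sprintf("%.17g", as.vector(t(m))),
        stringsAsFactors = FALSE)
    }
  }
  wf <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(subject_id = character(), cohort = character(),
               visit = character(), variable_name = character(),
               cycle_percent = integer(), value = character())
  }
  wf_path <- file.path(dir, "waveforms.csv")
  write.csv(wf, wf_path, row.names = FALSE, quote = FALSE)
  prom_path <- file.path(dir, "proms.csv")
  pr <- promRecords(cohort)
  pr_out <- data.frame(subject_id = pr$subject_id, visit = pr$visit,
                       instrument = pr$instrument,
                       raw_score = ifelse(is.na(pr$raw_score), "",
                                          sprintf("%.17g", pr$raw_score)),
                       stringsAsFactors = FALSE)
  write.csv(pr_out, prom_path, row.names = FALSE, quote = FALSE)
  invisible(c(waveforms = wf_path, proms = prom_path))
}
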