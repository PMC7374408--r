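#' Pre/post change summary with effect size
#'
#' Paired summary of a measure at baseline and post-operative visits on
#' complete cases: per-visit mean and SD, difference of means
#' (post minus pre), a paired test p-value, and the effect size
#' `(mean_post - mean_pre) / sqrt((sd_pre^2 + sd_post^2) / 2)` — the mean
#' difference divided by the pooled (two-visit variance average) standard
#' deviation. The paired test is Student's t when the paired differences
#' pass a Shapiro-Wilk normality check at `alpha`, otherwise the Wilcoxon
#' signed-rank test; either can be forced via `test`.
#'
#' @param baseline,postop numeric vectors, paired by position; incomplete
#'   pairs (`NA` at either visit) are dropped and reflected in `n`.
#' @param measure label for the summary row.
#' @param test `"auto"` (default), `"t"` or `"wilcoxon"`.
#' @param alpha significance level of the normality gate.
#' @return one-row data.frame: `measure`, `n`, `baseline_mean`,
#'   `baseline_sd`, `postop_mean`, `postop_sd`, `diff`, `p_value`,
#'   `effect_size`, `test_used`.
#' @export
changeSummary <- function(baseline, postop, measure = "measure",
                          test = c("auto", "t", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(baseline) == length(postop))
  ok <- complete.cases(baseline, postop)
  x <- baseline[ok]; y <- postop[ok]
  if (length(x) < 2L) {
    stop("need at least 2 complete pairs, got ", length(x), call. = FALSE)
  }
  d <- y - x
  if (test == "auto") {
    # Shapiro-Wilk is defined for 3..5000 observations; outside that range
    # (or with constant differences) default to the t test
    test <- if (sd(d) == 0 || length(d) < 3L || length(d) > 5000L ||
                shapiro.test(d)$p.value >= alpha) "t" else "wilcoxon"
  }
  p <- if (all(d == 0)) {
    1
  } else if (test == "t") {
    # essentially-constant nonzero differences have no defined t p-value
    tryCatch(t.test(y, x, paired = TRUE)$p.value,
             error = function(e) NA_real_)
  } else {
    suppressWarnings(wilcox.test(y, x, paired = TRUE, exact = FALSE))$p.value
  }
  pooled <- sqrt((sd(x)^2 + sd(y)^2) / 2)
  es <- if (pooled == 0) 0 else (mean(y) - mean(x)) / pooled
  data.frame(measure = measure, n = length(x),
             baseline_mean = mean(x), baseline_sd = sd(x),
             postop_mean = mean(y), postop_sd = sd(y),
             diff = mean(y) - mean(x), p_value = p, effect_size = es,
             test_used = test, row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between an objective and a subjective outcome
#'
#' Pearson's correlation for parametric data or Spearman's rank correlation
#' for nonparametric data, on pairwise-complete cases. Under
#' `method = "auto"` each margin is tested with Shapiro-Wilk at `alpha`;
#' Pearson is used only when both margins pass.
#'
#' @param x,y numeric vectors, paired by position.
#' @param method `"auto"` (default), `"pearson"` or `"spearman"`.
#' @param alpha significance level of the normality gate.
#' @param pair optional label of the variable pair.
#' @return one-row data.frame: `pair`, `method`, `r`, `p`, `n`.
#' @export
correlateOutcome <- function(x, y, method = c("auto", "pearson", "spearman"),
                             alpha = 0.05, pair = "x~y") {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 pairwise-complete pairs, got ", length(x),
         call. = FALSE)
  }
  # a margin whose spread is at rounding level is constant for all
  # statistical purposes (e.g. belief changes of identical waveforms)
  nearConstant <- function(v) sd(v) <= 1e-13 * max(1, abs(v))
  if (nearConstant(x) || nearConstant(y)) {
    stop("correlation undefined: zero variance in a margin", call. = FALSE)
  }
  if (method == "auto") {
    normal <- shapiro.test(x)$p.value >= alpha &&
      shapiro.test(y)$p.value >= alpha
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  data.frame(pair = pair, method = method, r = unname(ct$estimate),
             p = ct$p.value, n = length(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Order subjects by objective functional recovery
#'
#' Sorts subjects by `delta_b_OA` ascending, so rank 1 is the greatest
#' reduction in the belief of OA gait (greatest objective recovery) and
#' subjects whose function worsened (`delta_b_OA > 0`) sit at the tail,
#' flagged `worsened`. Ties are broken by subject id for a stable order.
#'
#' @param changes data.frame from [beliefChange()] (columns `subject_id`,
#'   `delta_b_OA`, optionally `baseline_b_OA`).
#' @return `changes` reordered, with `rank` and `worsened` columns added.
#' @export
arrowOrdering <- function(changes) {
  stopifnot(all(c("subject_id", "delta_b_OA") %in% names(changes)))
  out <- changes[order(changes$delta_b_OA, changes$subject_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$worsened <- out$delta_b_OA > 0
  rownames(out) <- NULL
  out
}
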