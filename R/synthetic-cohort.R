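#' Specification for the synthetic gait cohort generator
#'
#' Defines the statistical structure of a simulated study: a non-pathological
#' (NP) and an osteoarthritic (OA) cohort whose time-normalised waveforms
#' differ by group shifts along smooth latent variation modes, a
#' post-operative visit for a subset of OA subjects with partial,
#' heterogeneous recovery toward the NP mean, and patient-reported outcome
#' scores correlated with the latent recovery at a tunable strength.
#'
#' Each variable's curves are built as
#' `template(t) + sum_m score[s, m] * mode_m(t) + noise`, with the mode
#' shapes an orthonormalised low-order cosine basis ([modeBasis()]). OA
#' subjects' scores on the discriminatory (variable, mode) pairs are shifted
#' by `effect_size_d * score_sd`. A post-operative subject with recovery
#' fraction `rho` moves fraction `rho` of the way from its baseline score
#' toward the NP mean on every mode; `rho` is drawn from a normal truncated
#' to `recovery_bounds` (the lower bound sits below 0 so that a small
#' worsening of function is possible). PROM percent changes are
#' `slope * rho + noise`, with the noise standard deviation set analytically
#' from the bivariate-normal identity
#' `sd(noise) = slope * sd(rho) * sqrt(1 / prom_r^2 - 1)`
#' so that `cor(change, rho)` approaches `prom_r` in expectation.
#'
#' @param n_np,n_oa NP and OA cohort sizes.
#' @param n_postop number of OA subjects with a post-operative visit.
#' @param n_variables number of waveform variables.
#' @param n_modes latent variation modes per variable.
#' @param discriminatory data.frame with columns `variable`, `mode` listing
#'   the (variable, mode) pairs carrying the group effect; default: mode 1
#'   of the first six registry variables.
#' @param effect_size_d standardised mean difference on each discriminatory
#'   mode score.
#' @param score_sd per-mode score standard deviation.
#' @param noise_sd within-curve residual noise standard deviation.
#' @param recovery_mean,recovery_sd,recovery_bounds truncated-normal
#'   distribution of the per-subject recovery fraction.
#' @param prom_r target correlation between PROM percent change and latent
#'   recovery; must be nonzero with `|prom_r| <= 1`.
#' @param prom_slope PROM percent-change per unit recovery fraction.
#' @param prom_baseline_mean,prom_baseline_sd baseline PROM percent score
#'   distribution (truncated to `[5, 95]`).
#' @param prom_missing logical; if `TRUE`, plant the study-like missingness
#'   pattern (PACS collected only for a late-recruited subset at baseline,
#'   sporadic missing post-operative scores).
#' @param seed master integer seed; every stochastic component draws from a
#'   sub-stream derived from it.
#' @return a `gait_generator_spec` list.
#' @export
generatorSpec <- function(n_np = 31L, n_oa = 41L, n_postop = 22L,
                          n_variables = 24L, n_modes = 3L,
                          discriminatory = NULL,
                          effect_size_d = 2.0, score_sd = 1.0,
                          noise_sd = 0.03,
                          recovery_mean = 0.5, recovery_sd = 0.35,
                          recovery_bounds = c(-0.1, 1.1),
                          prom_r = 0.8, prom_slope = 55,
                          prom_baseline_mean = 40, prom_baseline_sd = 12,
                          prom_missing = TRUE, seed = 1L) {
  stopifnot(n_np > 0, n_oa > 0, n_postop >= 0, n_postop <= n_oa,
            n_variables > 0, n_modes > 0, score_sd > 0, noise_sd >= 0,
            length(recovery_bounds) == 2L,
            recovery_bounds[1L] < recovery_bounds[2L])
  if (abs(prom_r) > 1 || prom_r == 0 || prom_slope <= 0) {
    stop("prom_r must be nonzero in [-1, 1] with positive prom_slope; ",
         "the PROM noise calibration is otherwise infeasible", call. = FALSE)
  }
  defaults <- defaultVariableRegistry()
  if (n_variables <= length(defaults)) {
    registry <- defaults[seq_len(n_variables)]
  } else {
    extra <- paste0("extra_variable_", seq_len(n_variables - length(defaults)))
    registry <- c(defaults, setNames(rep("unknown", length(extra)), extra))
  }
  if (is.null(discriminatory)) {
    discriminatory <- data.frame(
      variable = names(registry)[seq_len(min(6L, n_variables))],
      mode = 1L, stringsAsFactors = FALSE)
  }
  stopifnot(all(discriminatory$variable %in% names(registry)),
            all(discriminatory$mode >= 1 & discriminatory$mode <= n_modes))
  structure(list(
    n_np = as.integer(n_np), n_oa = as.integer(n_oa),
    n_postop = as.integer(n_postop),
    n_variables = as.integer(n_variables), n_modes = as.integer(n_modes),
    registry = registry, discriminatory = discriminatory,
    effect_size_d = effect_size_d, score_sd = score_sd, noise_sd = noise_sd,
    recovery_mean = recovery_mean, recovery_sd = recovery_sd,
    recovery_bounds = recovery_bounds,
    prom_r = prom_r, prom_slope = prom_slope,
    prom_baseline_mean = prom_baseline_mean,
    prom_baseline_sd = prom_baseline_sd,
    prom_missing = prom_missing, seed = as.integer(seed)),
    class = "gait_generator_spec")
}

#' Generate a synthetic gait cohort with known ground truth
#'
#' Simulates a full study per a [generatorSpec()]: baseline waveforms for
#' both cohorts, post-operative waveforms for the first `n_postop` OA
#' subjects, PROM records for the post-operative subset at both visits, and
#' the latent ground truth (mode scores, recovery fractions, discriminatory
#' set) that the analysis pipeline is expected to recover.
#'
#' @param spec a `gait_generator_spec`, see [generatorSpec()].
#' @return a list with elements `cohort` (a [GaitCohort-class]) and `truth`
#'   (list: `rho`, `scores`, `postop_scores`, `discriminatory`, `spec`).
#' @examples
#' sim <- generateCohort(generatorSpec(n_np = 5, n_oa = 6, n_postop = 3,
#'                                     n_variables = 2, seed = 7))
#' sim$cohort
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "gait_generator_spec"))
  vars <- names(spec$registry)
  basis <- modeBasis(spec$n_modes)
  ids_np <- sprintf("NP%02d", seq_len(spec$n_np))
  ids_oa <- sprintf("OA%02d", seq_len(spec$n_oa))
  ids <- c(ids_np, ids_oa)
  is_oa <- c(rep(FALSE, spec$n_np), rep(TRUE, spec$n_oa))
  ids_post <- ids_oa[seq_len(spec$n_postop)]

  # latent recovery fractions
  set.seed(substreamSeed(spec$seed, "recovery"))
  rho <- rtruncnorm(spec$n_postop, spec$recovery_mean, spec$recovery_sd,
                    spec$recovery_bounds[1L], spec$recovery_bounds[2L])
  names(rho) <- ids_post

  curves_base <- list()
  curves_post <- list()
  scores_base <- list()
  scores_post <- list()
  for (v in vars) {
    set.seed(substreamSeed(spec$seed, paste0("template_", v)))
    t <- seq(0, 100, length.out = GAIT_SAMPLES)
    coef <- rnorm(6, 0, 10 / rep(1:3, 2))
    template <- coef[1] * cos(pi * t / 100) + coef[2] * cos(2 * pi * t / 100) +
      coef[3] * cos(3 * pi * t / 100) + coef[4] * sin(pi * t / 100) +
      coef[5] * sin(2 * pi * t / 100) + coef[6] * sin(3 * pi * t / 100)

    disc_modes <- spec$discriminatory$mode[spec$discriminatory$variable == v]
    set.seed(substreamSeed(spec$seed, paste0("scores_", v)))
    sc <- matrix(rnorm(length(ids) * spec$n_modes, 0, spec$score_sd),
                 nrow = length(ids),
                 dimnames = list(ids, paste0("mode", seq_len(spec$n_modes))))
    if (length(disc_modes)) {
      sc[is_oa, disc_modes] <- sc[is_oa, disc_modes] +
        spec$effect_size_d * spec$score_sd
    }
    scores_base[[v]] <- sc

    set.seed(substreamSeed(spec$seed, paste0("noise_", v)))
    noise <- matrix(rnorm(length(ids) * GAIT_SAMPLES, 0, spec$noise_sd),
                    nrow = length(ids))
    m <- matrix(rep(template, each = length(ids)), nrow = length(ids)) +
      sc %*% t(basis) + noise
    rownames(m) <- ids
    curves_base[[v]] <- m

    if (spec$n_postop > 0) {
      # move fraction rho of the way from baseline toward the NP mean (0)
      sc_post <- sc[ids_post, , drop = FALSE] * (1 - rho[ids_post])
      scores_post[[v]] <- sc_post
      set.seed(substreamSeed(spec$seed, paste0("postnoise_", v)))
      noise_p <- matrix(rnorm(spec$n_postop * GAIT_SAMPLES, 0, spec$noise_sd),
                        nrow = spec$n_postop)
      mp <- matrix(rep(template, each = spec$n_postop), nrow = spec$n_postop) +
        sc_post %*% t(basis) + noise_p
      rownames(mp) <- ids_post
      curves_post[[v]] <- mp
    }
  }

  proms <- generateProms(spec, rho, ids_post)
  curves <- list(baseline = curves_base)
  if (spec$n_postop > 0) curves$postop <- curves_post
  cohort <- new("GaitCohort",
                subjects = data.frame(subject_id = ids,
                                      cohort = ifelse(is_oa, "OA", "NP"),
                                      stringsAsFactors = FALSE),
                curves = curves, variables = vars, units = spec$registry,
                proms = promFrame(proms))
  truth <- list(
    rho = data.frame(subject_id = ids_post, rho = unname(rho),
                     stringsAsFactors = FALSE),
    scores = scores_base, postop_scores = scores_post,
    discriminatory = spec$discriminatory, spec = spec)
  list(cohort = cohort, truth = truth)
}

# PROM records for the post-operative subset: baseline and post-op raw
# scores for OKS, KOS and PACS, with percent change tied to the latent
# recovery fraction and optional study-like missingness.
generateProms <- function(spec, rho, ids_post) {
  if (spec$n_postop == 0) return(NULL)
  instruments <- defaultInstruments()
  sd_rho <- if (spec$recovery_sd <= 0) 0 else {
    sqrt(truncnormVar(spec$recovery_mean, spec$recovery_sd,
                      spec$recovery_bounds[1L], spec$recovery_bounds[2L]))
  }
  slope <- spec$prom_slope * sign(spec$prom_r)
  noise_sd <- spec$prom_slope * sd_rho * sqrt(1 / spec$prom_r^2 - 1)
  out <- list()
  for (inst in names(instruments)) {
    set.seed(substreamSeed(spec$seed, paste0("prom_", inst)))
    base_pct <- rtruncnorm(spec$n_postop, spec$prom_baseline_mean,
                           spec$prom_baseline_sd, 5, 95)
    change <- slope * rho + rnorm(spec$n_postop, 0, noise_sd)
    post_pct <- pmin(pmax(base_pct + change, 0), 100)
    def <- instruments[[inst]]
    worst <- if (def$best == def$max) def$min else def$max
    to_raw <- function(p) worst + p / 100 * (def$best - worst)
    out[[inst]] <- data.frame(
      subject_id = rep(ids_post, 2L),
      visit = rep(c("baseline", "postop"), each = spec$n_postop),
      instrument = inst,
      raw_score = c(to_raw(base_pct), to_raw(post_pct)),
      stringsAsFactors = FALSE)
  }
  proms <- do.call(rbind, out)
  rownames(proms) <- NULL
  if (spec$prom_missing && spec$n_postop >= 2) {
    set.seed(substreamSeed(spec$seed, "prom_missing"))
    # PACS joined the study late: baseline scores exist only for the most
    # recently recruited fraction (16/22 in the emulated study)
    n_pacs_base <- round(16 / 22 * spec$n_postop)
    pacs_base_ids <- ids_post[seq.int(spec$n_postop - n_pacs_base + 1,
                                      spec$n_postop)]
    drop_base <- proms$instrument == "PACS" & proms$visit == "baseline" &
      !(proms$subject_id %in% pacs_base_ids)
    proms$raw_score[drop_base] <- NA
    # one post-operative KOS score missing
    kos_miss <- sample(ids_post, 1L)
    proms$raw_score[proms$instrument == "KOS" & proms$visit == "postop" &
                      proms$subject_id == kos_miss] <- NA
    # post-operative PACS missing for ~2/22, one of them among the
    # baseline-complete subset so the paired n shrinks too
    n_pacs_post_miss <- max(1L, round(2 / 22 * spec$n_postop))
    cand <- c(sample(pacs_base_ids, 1L),
              sample(setdiff(ids_post, pacs_base_ids),
                     min(n_pacs_post_miss - 1L,
                         spec$n_postop - n_pacs_base)))
    proms$raw_score[proms$instrument == "PACS" & proms$visit == "postop" &
                      proms$subject_id %in% cand] <- NA
  }
  proms
}

#' Latent recovery fractions of a generated cohort
#'
#' @param truth the `truth` element returned by [generateCohort()].
#' @return data.frame with columns `subject_id`, `rho` for every subject
#'   with a post-operative visit.
#' @export
groundTruthRecovery <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth$rho))
  truth$rho
}

#' @export
print.gait_generator_spec <- function(x, ...) {
  cat("Synthetic gait cohort spec:", x$n_np, "NP +", x$n_oa, "OA subjects,",
      x$n_postop, "post-operative\n")
  cat("  ", x$n_variables, "variables x", x$n_modes, "modes;",
      nrow(x$discriminatory), "discriminatory mode(s), d =",
      x$effect_size_d, "\n")
  cat("  recovery ~ truncN(", x$recovery_mean, ",", x$recovery_sd,
      "); target PROM correlation r =", x$prom_r, "\n")
  invisible(x)
}
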