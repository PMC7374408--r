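# Shared fixtures: tiny cohorts, random bodies of evidence, and the
# brute-force Dempster combination oracle used to check the fold.

# Long-form waveform rows for one subject-visit: value = f(cycle_percent).
longWaveform <- function(subject_id, cohort, visit, variable, f) {
  t <- 0:100
  data.frame(subject_id = subject_id, cohort = cohort, visit = visit,
             variable_name = variable, cycle_percent = t, value = f(t),
             stringsAsFactors = FALSE)
}

# A small deterministic two-variable cohort: n_np + n_oa subjects at
# baseline, OA curves offset so the groups separate cleanly.
tinyCohort <- function(n_np = 4, n_oa = 5, variables = c("varA", "varB"),
                       offset = 5) {
  ids <- c(sprintf("NP%02d", seq_len(n_np)), sprintf("OA%02d", seq_len(n_oa)))
  cohorts <- rep(c("NP", "OA"), c(n_np, n_oa))
  rows <- list()
  for (i in seq_along(ids)) {
    shift <- if (cohorts[i] == "OA") offset else 0
    for (v in variables) {
      amp <- i %% 3 + 1
      rows[[length(rows) + 1L]] <- longWaveform(
        ids[i], cohorts[i], "baseline", v,
        function(t) shift + amp * sin(2 * pi * t / 100) + 0.01 * i)
    }
  }
  gaitCohort(data.frame(subject_id = ids, cohort = cohorts),
             do.call(rbind, rows),
             registry = stats::setNames(rep("deg", length(variables)),
                                        variables))
}

# Random valid bodies of evidence (rows sum to one).
randomBOEs <- function(n) {
  m <- matrix(stats::runif(3 * n), ncol = 3)
  m <- m / rowSums(m)
  colnames(m) <- c("m_OA", "m_NP", "m_U")
  m
}

# Independent oracle for Dempster's rule: enumerate all 3^n combinations of
# focal elements ({OA}, {NP}, Theta), accumulate product masses on the
# intersections, discard conflict and renormalise.
bruteCombine <- function(boes) {
  n <- nrow(boes)
  choices <- expand.grid(rep(list(1:3), n))
  mass <- c(OA = 0, NP = 0, U = 0, conflict = 0)
  for (r in seq_len(nrow(choices))) {
    idx <- as.integer(choices[r, ])
    w <- prod(boes[cbind(seq_len(n), idx)])
    has_oa <- any(idx == 1L)
    has_np <- any(idx == 2L)
    target <- if (has_oa && has_np) "conflict"
              else if (has_oa) "OA"
              else if (has_np) "NP"
              else "U"
    mass[target] <- mass[target] + w
  }
  out <- mass[c("OA", "NP", "U")] / (1 - mass[["conflict"]])
  stats::setNames(out, c("m_OA", "m_NP", "m_U"))
}

# Feature matrix with one planted discriminatory column among noise.
plantedFeatures <- function(n_np, n_oa, n_features, d = 5, seed = 1,
                            planted = 1L) {
  set.seed(seed)
  n <- n_np + n_oa
  x <- matrix(stats::rnorm(n * n_features), nrow = n,
              dimnames = list(c(sprintf("NP%02d", seq_len(n_np)),
                                sprintf("OA%02d", seq_len(n_oa))),
                              sprintf("f%02d", seq_len(n_features))))
  labels <- rep(c("NP", "OA"), c(n_np, n_oa))
  x[labels == "OA", planted] <- x[labels == "OA", planted] + d
  list(features = x, labels = labels)
}
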