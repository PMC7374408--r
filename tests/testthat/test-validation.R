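test_that("a trivially separated minimal cohort validates perfectly", {
  x <- matrix(c(0, 0.1, 10, 10.1, 0.2, 0, 10.2, 10),
              ncol = 2, dimnames = list(c("n1", "n2", "o1", "o2"),
                                        c("f1", "f2")))
  labels <- setNames(c("NP", "NP", "OA", "OA"), rownames(x))
  rep <- looValidate(x, labels)
  expect_identical(rep$summary$n_correct, 4L)
  expect_identical(rep$summary$n_total, 4L)
})

test_that("a strongly separated synthetic cohort validates at 100%", {
  sim <- generateCohort(generatorSpec(n_np = 10, n_oa = 12, n_postop = 0,
                                      n_variables = 6, effect_size_d = 3,
                                      seed = 7))
  models <- fitAllPCA(sim$cohort, 3)
  fm <- buildFeatureMatrix(models, sim$cohort, "baseline")
  labels <- cohortLabels(sim$cohort)[rownames(fm)]
  planted <- paste0(sim$truth$discriminatory$variable, ".PC",
                    sim$truth$discriminatory$mode)
  rep <- looValidate(fm, labels, retained = planted)
  expect_identical(rep$summary$n_correct, rep$summary$n_total)
  # per-cohort breakdown adds up
  expect_identical(sum(rep$summary$by_cohort$n), rep$summary$n_total)
  expect_identical(sum(rep$summary$by_cohort$n_correct),
                   rep$summary$n_correct)
})

test_that("held-out subjects never leak into the fold fit", {
  pf <- plantedFeatures(6, 6, n_features = 4, d = 3, seed = 8)
  rep1 <- looValidate(pf$features, pf$labels)
  # poison subject 1's features: every other subject's fold now differs,
  # but subject 1's own fold must be fitted without it
  poisoned <- pf$features
  poisoned[1, ] <- poisoned[1, ] + 1e3
  rep2 <- looValidate(poisoned, pf$labels)
  tab <- gaitbelief:::fitTransferTable(pf$features[-1, ], pf$labels[-1])
  cf <- confidenceFactor(poisoned[1, tab$feature], tab$k, tab$theta)
  expected <- combineEvidence(massAssignment(cf, 0.2, 0.9))
  expect_equal(rep2$per_subject$b_OA[1], expected[["m_OA"]],
               tolerance = 1e-12)
  expect_equal(rep2$per_subject$u[1], expected[["m_U"]], tolerance = 1e-12)
})

test_that("accuracy is invariant to subject ordering", {
  pf <- plantedFeatures(7, 8, n_features = 5, d = 2, seed = 10)
  rep1 <- looValidate(pf$features, pf$labels)
  idx <- sample(seq_len(nrow(pf$features)))
  rep2 <- looValidate(pf$features[idx, ], pf$labels[idx])
  expect_identical(rep1$summary$n_correct, rep2$summary$n_correct)
  m <- merge(rep1$per_subject, rep2$per_subject, by = "subject_id")
  expect_equal(m$b_OA.x, m$b_OA.y, tolerance = 1e-12)
})

test_that("full-pipeline refit also refits the principal components", {
  sim <- generateCohort(generatorSpec(n_np = 6, n_oa = 7, n_postop = 0,
                                      n_variables = 2, effect_size_d = 3,
                                      seed = 12,
                                      discriminatory = data.frame(
                                        variable = "hip_sagittal_angle",
                                        mode = 1)))
  models <- fitAllPCA(sim$cohort, 3)
  fm <- buildFeatureMatrix(models, sim$cohort, "baseline")
  labels <- cohortLabels(sim$cohort)[rownames(fm)]
  fixed <- looValidate(fm, labels, refit = "params")
  full <- looValidate(fm, labels, refit = "full", cohort = sim$cohort)
  expect_identical(full$summary$n_total, fixed$summary$n_total)
  # the two modes agree on this easy cohort but are distinct computations
  expect_false(identical(full$per_subject$b_OA, fixed$per_subject$b_OA))
  expect_error(looValidate(fm, labels, refit = "full"), "requires the cohort")
})

test_that("post-operative projection reuses the trained pipeline verbatim", {
  sim <- generateCohort(generatorSpec(n_np = 8, n_oa = 10, n_postop = 5,
                                      n_variables = 3, effect_size_d = 3,
                                      seed = 14))
  models <- fitAllPCA(sim$cohort, 3)
  fm <- buildFeatureMatrix(models, sim$cohort, "baseline")
  labels <- cohortLabels(sim$cohort)[rownames(fm)]
  clf <- trainClassifier(fm, labels)
  post <- applyPostop(clf, models, sim$cohort)
  expect_identical(nrow(post), 5L)
  expect_true(all(post$visit == "postop"))

  # postop waveforms identical to baseline give identical triplets
  clone <- sim$cohort
  clone@curves$postop <- lapply(sim$cohort@curves$baseline, function(m) {
    m[rownames(sim$cohort@curves$postop[[1]]), , drop = FALSE]
  })
  post_same <- applyPostop(clf, models, clone)
  base_beliefs <- classifyBeliefs(clf, fm)
  m <- match(post_same$subject_id, base_beliefs$subject_id)
  expect_equal(post_same$b_OA, base_beliefs$b_OA[m], tolerance = 1e-12)

  # postop curves at the NP training mean classify as NP
  np_ids <- names(labels)[labels == "NP"]
  at_np_mean <- sim$cohort
  at_np_mean@curves$postop <- lapply(sim$cohort@curves$baseline, function(m) {
    mu <- colMeans(m[np_ids, , drop = FALSE])
    out <- matrix(rep(mu, each = 5), nrow = 5)
    rownames(out) <- rownames(sim$cohort@curves$postop[[1]])
    out
  })
  post_np <- applyPostop(clf, models, at_np_mean)
  expect_true(all(post_np$b_NP > post_np$b_OA))

  # applying a reloaded model equals the in-memory application bit-for-bit
  dir <- withr::local_tempdir()
  writePCAModels(models, file.path(dir, "m.json"))
  writeClassifier(clf, file.path(dir, "c.json"))
  models2 <- readPCAModels(file.path(dir, "m.json"))$models
  clf2 <- readClassifier(file.path(dir, "c.json"))
  expect_identical(applyPostop(clf2, models2, sim$cohort), post)
})

test_that("recovery shows as a negative mean belief change at defaults", {
  sim <- generateCohort(generatorSpec(seed = 20))
  models <- fitAllPCA(sim$cohort, 3)
  fm <- buildFeatureMatrix(models, sim$cohort, "baseline")
  labels <- cohortLabels(sim$cohort)[rownames(fm)]
  clf <- trainClassifier(fm, labels)
  base <- classifyBeliefs(clf, fm)
  post <- applyPostop(clf, models, sim$cohort)
  ch <- beliefChange(base[, c("subject_id", "b_OA")],
                     post[, c("subject_id", "b_OA")])
  expect_lt(mean(ch$delta_b_OA), 0)
})
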