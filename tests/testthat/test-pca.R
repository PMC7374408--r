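test_that("identical training curves give zero variance and zero scores", {
  curves <- matrix(rep(sin(2 * pi * (0:100) / 100), 6), nrow = 6,
                   byrow = TRUE, dimnames = list(paste0("S", 1:6), NULL))
  model <- fitPCA(curves, retained = 3, variable = "flat")
  expect_equal(model@variance, rep(0, 3), tolerance = 1e-24)
  expect_equal(unname(pcScores(model, curves)),
               matrix(0, 6, 3), tolerance = 1e-12)
})

test_that("a single planted mode is recovered up to sign", {
  mode <- modeBasis(1)[, 1]
  template <- cos(4 * pi * (0:100) / 100)
  curves <- rbind(template - mode, template, template + mode)
  rownames(curves) <- paste0("S", 1:3)
  model <- fitPCA(curves, retained = 2, variable = "onemode")
  cosine <- sum(model@rotation[, 1] * mode)
  expect_gt(abs(cosine), 0.999)
  expect_gt(model@variance[1], 0.5)
  expect_lt(model@variance[2], 1e-20)
})

test_that("the retained subspace matches the generating modes", {
  sim <- generateCohort(generatorSpec(n_variables = 6, seed = 21))
  basis <- modeBasis(3)
  for (v in sim$truth$discriminatory$variable) {
    model <- fitPCA(waveformMatrix(sim$cohort, "baseline", v), 3, v)
    # principal angles between the fitted and generating 3-dim subspaces
    sv <- svd(crossprod(basis, model@rotation))$d
    angles <- acos(pmin(sv, 1)) * 180 / pi
    expect_true(all(angles < 5),
                label = sprintf("%s: max angle %.2f deg", v, max(angles)))
  }
})

test_that("projection identities hold", {
  sim <- generateCohort(generatorSpec(n_np = 6, n_oa = 7, n_postop = 0,
                                      n_variables = 1, seed = 4))
  v <- variableRegistry(sim$cohort)[1]
  curves <- waveformMatrix(sim$cohort, "baseline", v)
  model <- fitPCA(curves, 3, v)
  # centring identity
  expect_equal(pcScores(model, model@center), c(0, 0, 0), tolerance = 1e-12)
  # orthonormal projection of a constructed displacement
  probe <- model@center + 2 * model@rotation[, 1]
  expect_equal(pcScores(model, probe), c(2, 0, 0), tolerance = 1e-10)
  # training-set scores are reproduced by projection
  pc <- prcomp(curves, center = TRUE)
  fitted_scores <- pc$x[, 1:3]
  flip <- sign(colSums(pc$rotation[, 1:3] * model@rotation))
  expect_equal(unname(pcScores(model, curves)),
               unname(sweep(fitted_scores, 2, flip, `*`)), tolerance = 1e-10)
  # linearity: shifting every curve shifts scores by the projected shift
  shift <- 1.5 * model@rotation[, 2]
  shifted <- sweep(curves, 2, -shift)
  expect_equal(unname(pcScores(model, shifted)),
               unname(sweep(pcScores(model, curves), 2, c(0, 1.5, 0), `+`)),
               tolerance = 1e-10)
})

test_that("orthonormality and variance ordering hold on random cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    curves <- matrix(rnorm(12 * 101), nrow = 12,
                     dimnames = list(paste0("S", 1:12), NULL))
    model <- fitPCA(curves, 4, "random")
    expect_equal(crossprod(model@rotation), diag(4), tolerance = 1e-10)
    expect_true(all(diff(model@variance) <= 1e-12))
    # sign convention: peak loading positive
    for (j in 1:4) {
      expect_gte(model@rotation[which.max(abs(model@rotation[, j])), j], 0)
    }
  }
})

test_that("reconstruction error is monotone non-increasing in rank", {
  set.seed(8)
  curves <- matrix(rnorm(10 * 101), nrow = 10,
                   dimnames = list(paste0("S", 1:10), NULL))
  target <- curves[3, ]
  errs <- vapply(1:9, function(k) {
    model <- fitPCA(curves, k, "recon")
    recon <- model@center + drop(model@rotation %*% pcScores(model, target))
    sqrt(sum((recon - target)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("the feature matrix has one column per variable and component", {
  sim <- generateCohort(generatorSpec(seed = 6))
  models <- fitAllPCA(sim$cohort, retained = 3)
  fm <- buildFeatureMatrix(models, sim$cohort, "baseline")
  expect_identical(dim(fm), c(72L, 72L))  # 24 variables x 3 components
  expect_identical(colnames(fm)[1:3],
                   paste0(variableRegistry(sim$cohort)[1], ".PC", 1:3))
  # post-operative matrix: 22 rows, identical columns, trained projection
  fm_post <- buildFeatureMatrix(models, sim$cohort, "postop")
  expect_identical(dim(fm_post), c(22L, 72L))
  expect_identical(colnames(fm_post), colnames(fm))

  one <- generateCohort(generatorSpec(n_np = 5, n_oa = 5, n_postop = 0,
                                      n_variables = 1, seed = 6))
  fm1 <- buildFeatureMatrix(fitAllPCA(one$cohort, 3), one$cohort)
  expect_identical(ncol(fm1), 3L)
})

test_that("too few training subjects is a fit error", {
  curves <- matrix(rnorm(3 * 101), nrow = 3,
                   dimnames = list(paste0("S", 1:3), NULL))
  expect_error(fitPCA(curves, retained = 3), "at least 4")
})

test_that("PCA models round-trip through JSON bit-for-bit", {
  sim <- generateCohort(generatorSpec(n_np = 5, n_oa = 6, n_postop = 2,
                                      n_variables = 2, seed = 10))
  models <- fitAllPCA(sim$cohort, 3)
  path <- withr::local_tempfile(fileext = ".json")
  writePCAModels(models, path, meta = list(config_hash = "abc"))
  back <- readPCAModels(path)
  expect_identical(back$meta$config_hash, "abc")
  probe <- waveformMatrix(sim$cohort, "baseline",
                          variableRegistry(sim$cohort)[1])
  expect_identical(pcScores(back$models[[1]], probe),
                   pcScores(models[[1]], probe))
})
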