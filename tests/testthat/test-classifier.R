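test_that("the sigmoid confidence factor has the stated geometry", {
  expect_equal(confidenceFactor(1.3, k = 2, theta = 1.3), 0.5)
  expect_equal(confidenceFactor(log(3), k = 1, theta = 0), 0.75)
  v <- seq(-4, 4, by = 0.5)
  expect_equal(confidenceFactor(v, -1.7, 0.2),
               1 - confidenceFactor(v, 1.7, 0.2), tolerance = 1e-12)
  # monotone with the sign of k; clamped at the extremes
  expect_true(all(diff(confidenceFactor(v, 3, 0)) > 0))
  expect_true(all(diff(confidenceFactor(v, -3, 0)) < 0))
  expect_equal(confidenceFactor(1e6, 10, 0), 1 - 1e-15)
})

test_that("mass assignment matches the linear evidence map", {
  expect_equal(unname(massAssignment(1, A = 0.2, B = 0.9)[1, ]),
               c(0.9, 0, 0.1), tolerance = 1e-12)
  expect_equal(unname(massAssignment(0.5, A = 0.2, B = 0.9)[1, ]),
               c(0.3375, 0.3375, 0.325), tolerance = 1e-12)
  # cf = A is the onset of evidence toward OA
  for (B in c(0.5, 0.9, 0.99)) {
    expect_equal(unname(massAssignment(0.2, A = 0.2, B = B)[1, "m_OA"]), 0,
                 tolerance = 1e-15)
  }
  # conservation and the residual-uncertainty floor, across the range
  cf <- seq(1e-6, 1 - 1e-6, length.out = 101)
  m <- massAssignment(cf, A = 0.2, B = 0.9)
  expect_true(all(m >= 0))
  expect_equal(rowSums(m), rep(1, 101), tolerance = 1e-15)
  expect_true(all(m[, "m_U"] >= 1 - 0.9 - 1e-12))
  expect_error(massAssignment(0.5, A = 1.2, B = 0.9), "require")
})

test_that("Dempster's rule matches the hand-worked example and identities", {
  got <- dempsterCombine(c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2))
  expect_equal(unname(got), c(0.52, 0.16, 0.04) / 0.72, tolerance = 1e-12)
  # vacuous body of evidence is the identity
  x <- c(0.37, 0.41, 0.22)
  expect_equal(unname(dempsterCombine(x, c(0, 0, 1))), x, tolerance = 1e-15)
  # commutativity and associativity on random masses
  set.seed(42)
  for (i in 1:25) {
    b <- randomBOEs(3)
    expect_equal(dempsterCombine(b[1, ], b[2, ]),
                 dempsterCombine(b[2, ], b[1, ]), tolerance = 1e-13)
    left <- dempsterCombine(dempsterCombine(b[1, ], b[2, ]), b[3, ])
    right <- dempsterCombine(b[1, ], dempsterCombine(b[2, ], b[3, ]))
    expect_equal(left, right, tolerance = 1e-12)
  }
  expect_error(dempsterCombine(c(1, 0, 0), c(0, 1, 0)), "total conflict")
})

test_that("folded combination equals brute-force focal enumeration", {
  set.seed(7)
  for (n in 2:6) {
    b <- randomBOEs(n)
    expect_equal(combineEvidence(b), bruteCombine(b), tolerance = 1e-10)
  }
})

test_that("explicit transfer parameters follow the group statistics", {
  par <- fitTransferParams(x_np = c(-1, 0, 1), x_oa = c(1, 2, 3), gain = 2)
  expect_equal(par$theta, 1)
  expect_equal(par$k, 2)
  expect_false(par$degenerate)
  # orientation: mean_OA > mean_NP gives k > 0, so larger v favours OA
  lo <- massAssignment(confidenceFactor(0, par$k, par$theta))
  hi <- massAssignment(confidenceFactor(3, par$k, par$theta))
  expect_gt(hi[1, "m_OA"], lo[1, "m_OA"])
  # zero separation is degenerate
  expect_true(fitTransferParams(c(0, 1), c(0.5, 0.5))$degenerate ||
                fitTransferParams(c(0, 1), c(1, 0))$degenerate)
  expect_true(fitTransferParams(c(1, 1), c(1, 1))$degenerate)
})

test_that("classification folds features into a belief triplet", {
  pf <- plantedFeatures(6, 6, n_features = 5, d = 4, seed = 2)
  clf <- trainClassifier(pf$features, pf$labels)
  out <- classifyBeliefs(clf, pf$features)
  expect_equal(out$b_OA + out$b_NP + out$u, rep(1, 12), tolerance = 1e-12)
  # single-feature classifier: triplet equals that feature's own evidence
  clf1 <- trainClassifier(pf$features, pf$labels, retained = "f01")
  p <- clf1@params
  cf <- confidenceFactor(pf$features[1, "f01"], p$k, p$theta)
  out1 <- classifyBeliefs(clf1, pf$features[1, , drop = FALSE])
  expect_equal(c(out1$b_OA, out1$b_NP, out1$u),
               unname(as.vector(massAssignment(cf, p$A, p$B))),
               tolerance = 1e-12)
  # combination order is immaterial
  set.seed(5)
  row <- pf$features[3, , drop = FALSE]
  base <- classifyBeliefs(clf, row)
  for (i in 1:10) {
    perm <- sample(clf@features)
    clf_perm <- new("TrainedClassifier", features = perm,
                    params = clf@params[match(perm, clf@params$feature), ],
                    meta = clf@meta)
    got <- classifyBeliefs(clf_perm, row)
    expect_equal(got[, c("b_OA", "b_NP", "u")],
                 base[, c("b_OA", "b_NP", "u")], tolerance = 1e-10)
  }
})

test_that("a subject at every midpoint sits on the decision boundary", {
  pf <- plantedFeatures(5, 5, n_features = 4, d = 3, seed = 3)
  clf <- trainClassifier(pf$features, pf$labels, gain = 2, A = 0, B = 0.9)
  row <- setNames(clf@params$theta, clf@params$feature)
  out <- classifyBeliefs(clf, row)
  expect_equal(out$b_OA, out$b_NP, tolerance = 1e-12)
  expect_identical(out$predicted, "tie")
  # uncertainty never vanishes when every feature leaves residual ignorance
  expect_gt(out$u, 0)
  far <- setNames(clf@params$theta + 50 * sign(clf@params$k),
                  clf@params$feature)
  expect_gt(classifyBeliefs(clf, far)$u, 0)
})

test_that("beliefs respond monotonically to an OA-oriented feature", {
  pf <- plantedFeatures(6, 6, n_features = 3, d = 2, seed = 4)
  clf <- trainClassifier(pf$features, pf$labels)
  p <- clf@params[clf@params$feature == "f01", ]
  stopifnot(p$k > 0)
  row <- pf$features[2, ]
  # probe values keeping the confidence factor inside the unclamped band
  vals <- p$theta + seq(-0.4, 0.4, length.out = 9) / abs(p$k)
  b_oa <- vapply(vals, function(v) {
    row["f01"] <- v
    classifyBeliefs(clf, row)$b_OA
  }, numeric(1))
  expect_true(all(diff(b_oa) >= -1e-12))
})

test_that("simplex coordinates place beliefs in the unit triangle", {
  expect_equal(unname(simplexCoordinates(c(1, 0, 0))[1, ]), c(0, 0))
  expect_equal(unname(simplexCoordinates(c(0, 1, 0))[1, ]), c(1, 0))
  expect_equal(unname(simplexCoordinates(c(0, 0, 1))[1, ]),
               c(0.5, sqrt(3) / 2))
  expect_equal(unname(simplexCoordinates(c(1, 1, 1) / 3)[1, ]),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  # the decision boundary B(OA) = B(NP) is the line x = 0.5
  set.seed(11)
  for (i in 1:10) {
    u <- runif(1)
    b <- (1 - u) / 2
    xy <- simplexCoordinates(data.frame(b_OA = b, b_NP = b, u = u))
    expect_equal(unname(xy[1, "x"]), 0.5, tolerance = 1e-12)
  }
})

test_that("belief change is the post-minus-pre belief of OA", {
  base <- data.frame(subject_id = c("a", "b"), visit = "baseline",
                     b_OA = c(0.662, 0.3))
  post <- data.frame(subject_id = c("a", "b"), visit = "postop",
                     b_OA = c(0.511, 0.4))
  ch <- beliefChange(base, post)
  expect_equal(ch$delta_b_OA, c(-0.151, 0.1), tolerance = 1e-12)
  expect_equal(beliefChange(base, transform(base, visit = NULL))$delta_b_OA,
               c(0, 0))
  expect_error(beliefChange(post, base), "visit")
})

test_that("classifiers round-trip through JSON", {
  pf <- plantedFeatures(5, 5, n_features = 4, d = 3, seed = 6)
  clf <- trainClassifier(pf$features, pf$labels,
                         meta = list(config_hash = "xyz"))
  path <- withr::local_tempfile(fileext = ".json")
  writeClassifier(clf, path)
  back <- readClassifier(path)
  expect_identical(back@features, clf@features)
  expect_identical(back@params$k, clf@params$k)
  expect_identical(back@meta$config_hash, "xyz")
  expect_identical(classifyBeliefs(back, pf$features),
                   classifyBeliefs(clf, pf$features))
})
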