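test_that("edge-behavior correlations match the brute-force oracle", {
  withr::with_seed(14, {
    edges <- randomEdgeMatrix(5, 2)
    trait <- rnorm(5)
  })
  st <- edgeBehaviorCorr(edges, trait)
  for (k in 1:2) {
    r0 <- oraclePearson(edges[, k], trait)
    expect_equal(st$r[k], r0, tolerance = 1e-12)
    expect_equal(st$p[k], oraclePearsonP(r0, 5), tolerance = 1e-12)
  }

  # 1,000 random instances against the oracle
  withr::with_seed(15, {
    for (b in 1:50) {
      n <- sample(5:12, 1)
      e <- randomEdgeMatrix(n, 20)
      y <- rnorm(n)
      st <- edgeBehaviorCorr(e, y)
      ks <- sample(20, 20)
      for (k in ks) {
        expect_equal(st$r[k], oraclePearson(e[, k], y), tolerance = 1e-10)
      }
    }
  })
})

test_that("perfect predictor edge gets r = 1 with a floored positive p", {
  y <- c(1, 3, 2, 5, 4, 6)
  edges <- cbind(y, rnorm(6))
  st <- edgeBehaviorCorr(edges, y)
  expect_equal(st$r[1], 1)
  expect_gt(st$p[1], 0)
  expect_lt(st$p[1], 1e-20)
})

test_that("edgeBehaviorCorr handles missing traits and degenerate input", {
  withr::with_seed(16, edges <- randomEdgeMatrix(8, 3))
  trait <- c(rnorm(6), NA, NA)
  st <- edgeBehaviorCorr(edges, trait)
  expect_equal(attr(st, "nDropped"), 2)
  expect_equal(attr(st, "n"), 6)
  expect_error(edgeBehaviorCorr(edges, rep(1, 8)), "constant")
  expect_error(edgeBehaviorCorr(edges[1:3, ], rnorm(3)), "at least 4")
})

test_that("null edges show calibrated type-I error at p < 0.05", {
  withr::with_seed(17, {
    edges <- randomEdgeMatrix(40, 1000)
    trait <- rnorm(40)
  })
  st <- edgeBehaviorCorr(edges, trait)
  expect_gt(mean(st$p < 0.05), 0.03)
  expect_lt(mean(st$p < 0.05), 0.07)
})

test_that("edge selection filters by sign and threshold", {
  st <- data.frame(edge = 1:3, r = c(0.5, 0.4, -0.6), p = c(0.005, 0.02, 0.5))
  sel <- selectEdges(st, 0.01)
  expect_equal(sel$positive, 1L)
  expect_length(sel$negative, 0)

  # near-1 threshold: all edges selected, split purely by sign
  sel2 <- selectEdges(st, 1 - 1e-12)
  expect_setequal(c(sel2$positive, sel2$negative), 1:3)
  expect_equal(sel2$negative, 3L)
  expect_length(intersect(sel2$positive, sel2$negative), 0)

  # null edges: selected count within a Poisson band around m * threshold
  withr::with_seed(18, {
    edges <- randomEdgeMatrix(60, 1000)
    trait <- rnorm(60)
  })
  stN <- edgeBehaviorCorr(edges, trait)
  selN <- selectEdges(stN, 0.01)
  nSel <- length(selN$positive) + length(selN$negative)
  expect_lt(abs(nSel - 10), 4 * sqrt(10) + 1)
})

test_that("selection sets partition the sub-threshold edges", {
  withr::with_seed(19, {
    edges <- randomEdgeMatrix(30, 200)
    trait <- rnorm(30)
  })
  st <- edgeBehaviorCorr(edges, trait)
  sel <- selectEdges(st, 0.1)
  expect_setequal(c(sel$positive, sel$negative), st$edge[st$p < 0.1])
  expect_length(intersect(sel$positive, sel$negative), 0)
})

test_that("network strength is a plain sum with an empty-set flag", {
  v <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(networkStrength(v, 2L), 0.2)
  expect_equal(networkStrength(v, 1:3), 0.6)
  expect_equal(networkStrength(v, seq_along(v)), sum(v))
  s0 <- networkStrength(v, integer())
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "empty"))
  expect_error(networkStrength(v, 9L), "out of range")
})

test_that("LOOCV predictions equal a slow per-fold reference implementation", {
  withr::with_seed(28, {
    for (b in 1:8) {
      n <- sample(12:25, 1)
      x <- randomEdgeMatrix(n, 12)
      y <- x[, 1] - 0.5 * x[, 5] + rnorm(n, 0, 0.8)
      for (sg in c("positive", "negative")) {
        fit <- loocvPredict(x, y, pThreshold = 0.1, sign = sg, warnSmall = 0L)
        ref <- oracleLoocv(x, y, pThreshold = 0.1, sign = sg)
        expect_equal(cpmPredictions(fit), ref, tolerance = 1e-8, ignore_attr = TRUE)
      }
    }
  })
})

test_that("noiseless affine trait is recovered exactly by LOOCV", {
  withr::with_seed(20, driver <- rnorm(20))
  edges <- cbind(driver, matrix(1, 20, 5)) # constant decoys select nothing
  trait <- 3 * driver - 2
  fit <- loocvPredict(edges, trait, pThreshold = 0.05, sign = "positive",
                      warnSmall = 0L)
  expect_equal(rPred(fit), 1, tolerance = 1e-8)
  expect_equal(cpmPredictions(fit), trait, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit@nEdgesMean, 1)
})

test_that("LOOCV r_pred is invariant to affine rescaling of the trait", {
  withr::with_seed(22, {
    edges <- randomEdgeMatrix(40, 30)
    trait <- edges[, 3] + edges[, 7] + rnorm(40, 0, 0.5)
  })
  f1 <- loocvPredict(edges, trait, 0.05, "positive", warnSmall = 0L)
  f2 <- loocvPredict(edges, 5 * trait - 100, 0.05, "positive", warnSmall = 0L)
  expect_equal(rPred(f1), rPred(f2), tolerance = 1e-10)
})

test_that("LOOCV flags empty folds, no-model cases and constant-trait folds", {
  withr::with_seed(23, edges <- randomEdgeMatrix(12, 5))
  # independent trait at a tiny threshold: every fold empty -> no model
  fit <- loocvPredict(edges, rnorm(12), pThreshold = 1e-8, sign = "positive",
                      warnSmall = 0L)
  expect_true(fit@noModel)
  expect_true(is.na(rPred(fit)))
  expect_length(fit@emptyFolds, 12)

  trait <- c(0, rep(1, 11)) # constant once subject 1 is the only variation
  expect_error(loocvPredict(edges, trait, 0.05, "positive", warnSmall = 0L),
               "constant in training fold 1")

  expect_warning(loocvPredict(randomEdgeMatrix(6, 4), rnorm(6), 0.5, "positive"),
                 "unstable")
})

test_that("BH-FDR matches the hand-applied step-up rule and the brute-force oracle", {
  res <- fdrCorrect(c(0.01, 0.02, 0.03, 0.04, 0.2), q = 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  expect_equal(fdrCorrect(rep(1, 6), 0.05)$rejected, rep(FALSE, 6))
  expect_true(fdrCorrect(0.04, 0.05)$rejected) # m = 1 reduces to the raw test
  expect_error(fdrCorrect(c(0.5, 0), 0.05), "0, 1")

  withr::with_seed(24, {
    for (b in 1:200) {
      m <- sample(1:30, 1)
      p <- runif(m)
      q <- runif(1, 0.01, 0.2)
      got <- fdrCorrect(p, q)
      want <- oracleBH(p, q)
      expect_identical(got$rejected, want$reject)
      expect_equal(got$pAdjusted, want$adjusted, tolerance = 1e-12)
    }
  })
})

test_that("adjusted p-values are monotone nondecreasing in raw p", {
  withr::with_seed(25, p <- runif(50))
  adj <- fdrCorrect(p, 0.05)$pAdjusted
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("the model matrix reduces to a single LOOCV call and counts trait rows", {
  withr::with_seed(26, {
    edges <- randomEdgeMatrix(25, 15)
    trait <- edges[, 2] + rnorm(25, 0, 0.5)
  })
  traits <- data.frame(subject_id = paste0("s", 1:25), t1 = trait)
  res <- runMatrixOfModels(list(FCz = edges), traits,
                           pThreshold = 0.05, signs = "positive",
                           pMethod = "tapprox")
  expect_equal(nrow(res), 1)
  direct <- loocvPredict(edges, trait, 0.05, "positive", warnSmall = 0L)
  expect_equal(res$r_pred, rPred(direct))
  expect_equal(res$p_pred, pPred(direct))
  expect_equal(res$p_param, pPred(direct))

  # the permutation route reports the same r_pred and a matching
  # permutation p as a direct cpmPermutationP call
  resP <- runMatrixOfModels(list(FCz = edges), traits,
                            pThreshold = 0.05, signs = "positive",
                            pMethod = "permutation", nPerm = 50, seed = 4)
  directP <- cpmPermutationP(edges, trait, 0.05, "positive", nPerm = 50, seed = 4)
  expect_equal(resP$r_pred, rPred(directP$observed))
  expect_equal(resP$p_pred, directP$p)

  # 29-trait battery: one row per trait x group x sign x weight kind
  withr::with_seed(27, {
    battery <- as.data.frame(matrix(rnorm(25 * 29), 25, 29))
  })
  names(battery) <- paste0("m", 1:29)
  battery <- cbind(data.frame(subject_id = paste0("s", 1:25)), battery)
  res29 <- runMatrixOfModels(list(FCz = edges), battery,
                             pThreshold = 0.05, signs = c("positive", "negative"),
                             pMethod = "tapprox")
  expect_equal(nrow(res29), 29 * 2)
  expect_setequal(unique(res29$trait), paste0("m", 1:29))
})

test_that("a planted within-subnetwork effect lights up only that subnetwork", {
  # parcels 1-4 form group A; plant the effect on within-A edges
  nP <- 8
  labs <- paste0("P", 1:nP)
  scheme <- groupingScheme(labs, rep(c("A", "B"), each = 4))
  withinA <- connfp:::groupEdgeIndices(scheme, labs, "A")
  hits <- 0L
  falseHits <- 0L
  nRep <- 20
  for (b in seq_len(nRep)) {
    cfg <- cohortConfig(nSubjects = 120, nParcels = nP,
                        effectEdgesPos = withinA, beta = 1,
                        sigmaTrait = 0.2, seed = 500 + b)
    coh <- generateFcCohort(cfg)
    edges <- cohortEdgeMatrix(coh)
    res <- runMatrixOfModels(list(FCz = edges), coh@traits, scheme = scheme,
                             parcels = labs, pThreshold = 0.01, q = 0.05,
                             signs = "positive")
    aRow <- res[res$group == "A", ]
    bRow <- res[res$group == "B", ]
    if (isTRUE(aRow$significant)) hits <- hits + 1L
    if (isTRUE(bRow$significant)) falseHits <- falseHits + 1L
  }
  expect_gte(hits / nRep, 0.9)
  expect_lte(falseHits / nRep, 0.2)
})
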