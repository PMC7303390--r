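test_that("fcMatrix matches a brute-force Pearson/Fisher-z oracle", {
  withr::with_seed(7, {
    ts <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  })
  cm <- fcMatrix(ts)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(connWeights(cm)[i, j], atanh(oraclePearson(ts[, i], ts[, j])),
                   tolerance = 1e-12)
    }
  }
  expect_equal(diag(connWeights(cm)), c(A = 0, B = 0, C = 0))
})

test_that("perfectly (anti)correlated parcels give clipped finite z", {
  x <- c(1, 3, 2, 5, 4)
  ts <- cbind(a = x, b = 2 * x + 1, c = -x)
  cm <- fcMatrix(ts)
  zmax <- atanh(1 - 1e-7)
  expect_equal(connWeights(cm)["a", "b"], zmax)
  expect_equal(connWeights(cm)["a", "c"], -zmax)
  expect_true(all(is.finite(connWeights(cm))))
})

test_that("fcMatrix errors name the offending parcel and enforce preconditions", {
  ts <- cbind(a = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  expect_error(fcMatrix(ts), "flat")
  expect_error(fcMatrix(matrix(rnorm(4), 2, 2)), "timepoints")
})

test_that("fcMatrix is invariant to affine rescaling of columns", {
  withr::with_seed(21, {
    ts <- matrix(rnorm(30 * 4), 30, 4)
  })
  z1 <- connWeights(fcMatrix(ts))
  ts2 <- ts
  ts2[, 2] <- 3.7 * ts2[, 2] - 11
  ts2[, 4] <- 0.02 * ts2[, 4] + 5
  z2 <- connWeights(fcMatrix(ts2))
  expect_equal(z1, z2, tolerance = 1e-10)
})

# --- structural connectivity ---

# hard one-hot parcel field over a tiny grid with parcels at known voxels
hardField <- function(nParcels) {
  labels <- array(0L, dim = c(nParcels, 1, 1))
  for (p in seq_len(nParcels)) labels[p, 1, 1] <- p
  parcelVolumeFromLabels(labels)
}

# straight 2-point streamline between voxel centers of two parcels
lineBetween <- function(i, j, extraLen = 0) {
  a <- c(i - 0.5, 0.5, 0.5)
  b <- c(j - 0.5, 0.5, 0.5)
  if (extraLen > 0) {
    mid <- (a + b) / 2 + c(0, extraLen / 2, 0)
    rbind(a, mid, b)
  } else {
    rbind(a, b)
  }
}

test_that("SC aggregation reproduces the hand-computed 3-streamline fixture", {
  # endpoints in parcels (1,2),(1,2),(1,3) with lengths 10,20,30, QA 0.5
  field <- hardField(31)
  pts <- list(
    lineBetween(1, 11), # length 10
    lineBetween(1, 21), # length 20
    lineBetween(1, 31) # length 30
  )
  # relabel so endpoint parcels are (1,2),(1,2),(1,3): custom label volume
  labels <- array(0L, dim = c(31, 1, 1))
  labels[1, 1, 1] <- 1L
  labels[11, 1, 1] <- 2L
  labels[21, 1, 1] <- 2L
  labels[31, 1, 1] <- 3L
  field <- parcelVolumeFromLabels(labels)
  qa <- list(rep(0.5, 2), rep(0.5, 2), rep(0.5, 2))
  streams <- streamlineSet(pts, qa = qa)
  expect_equal(streamlineLengths(streams), c(10, 20, 30))
  sc <- scMatrices(streams, field)
  expect_equal(connWeights(sc$NS)[1, 2], 2)
  expect_equal(connWeights(sc$NS)[1, 3], 1)
  expect_equal(connWeights(sc$ML)[1, 2], 15) # (10 + 20) / 2
  expect_equal(connWeights(sc$ML)[1, 3], 30)
  expect_equal(connWeights(sc$QA)[1, 2], 0.5)
  # normalized variants: NS / n_streamlines, ML / mean length
  scn <- scMatrices(streams, field, normalized = TRUE)
  expect_equal(connWeights(scn$NS)[1, 2], 2 / 3)
  expect_equal(connWeights(scn$ML)[1, 2], 15 / 20)
})

test_that("empty and self-loop streamline sets give zero matrices", {
  field <- hardField(3)
  empty <- streamlineSet(list())
  sc <- scMatrices(empty, field)
  expect_true(all(connWeights(sc$NS) == 0))
  expect_true(all(connWeights(sc$ML) == 0))
  expect_true(all(connWeights(sc$QA) == 0))

  selfLoop <- streamlineSet(list(rbind(c(0.2, 0.5, 0.5), c(0.8, 0.5, 0.5))),
                            qa = list(c(0.4, 0.4)))
  sc2 <- scMatrices(selfLoop, field)
  expect_true(all(connWeights(sc2$NS) == 0))
})

test_that("QA requested without a QA channel errors; requireQa=FALSE drops it", {
  field <- hardField(3)
  streams <- streamlineSet(list(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5))))
  expect_error(scMatrices(streams, field), "QA channel")
  sc <- scMatrices(streams, field, requireQa = FALSE)
  expect_null(sc$QA)
  expect_equal(connWeights(sc$NS)[1, 3], 1)
})

test_that("hard-label SC equals a brute-force endpoint tally on random streamlines", {
  nP <- 6
  withr::with_seed(33, {
    ep <- cbind(sample.int(nP, 200, replace = TRUE), sample.int(nP, 200, replace = TRUE))
    qa <- runif(200)
    extra <- runif(200, 0, 10)
  })
  pts <- lapply(seq_len(200), function(s) lineBetween(ep[s, 1], ep[s, 2], extra[s]))
  streams <- streamlineSet(pts, qa = lapply(seq_len(200), function(s) rep(qa[s], nrow(pts[[s]]))))
  field <- hardField(nP)
  sc <- scMatrices(streams, field)
  oracle <- oracleHardSc(ep[, 1], ep[, 2], streamlineLengths(streams), qa, nP)
  expect_equal(connWeights(sc$NS), oracle$NS, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(connWeights(sc$ML), oracle$ML, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(connWeights(sc$QA), oracle$QA, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("soft endpoint weights split streamline mass between parcels", {
  # voxel 1 belongs 60/40 to parcels 1/2; voxel 3 fully to parcel 3
  w <- array(0, dim = c(3, 1, 1, 3))
  w[1, 1, 1, 1] <- 0.6
  w[1, 1, 1, 2] <- 0.4
  w[3, 1, 1, 3] <- 1
  field <- parcelVolume(w)
  streams <- streamlineSet(list(rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5))),
                           qa = list(c(0.7, 0.7)))
  sc <- scMatrices(streams, field)
  expect_equal(connWeights(sc$NS)[1, 3], 0.6)
  expect_equal(connWeights(sc$NS)[2, 3], 0.4)
  expect_equal(connWeights(sc$NS)[1, 2], 0)
  expect_equal(connWeights(sc$ML)[1, 3], 2) # weighted mean length of a single line
  expect_equal(connWeights(sc$QA)[1, 3], 0.7)
})

test_that("ML of identical-length streamlines equals that length regardless of weights", {
  nP <- 4
  field <- hardField(nP)
  withr::with_seed(9, {
    ep <- cbind(sample.int(nP, 30, replace = TRUE), sample.int(nP, 30, replace = TRUE))
  })
  pts <- lapply(seq_len(30), function(s) lineBetween(ep[s, 1], ep[s, 2], 0))
  # force all lengths equal by padding each to a 3-point detour of length 5
  pts <- lapply(seq_len(30), function(s) {
    a <- pts[[s]][1, ]; b <- pts[[s]][nrow(pts[[s]]), ]
    d <- sqrt(sum((b - a)^2))
    h <- sqrt(max((5 / 2)^2 - (d / 2)^2, 0))
    rbind(a, (a + b) / 2 + c(0, h, 0), b)
  })
  streams <- streamlineSet(pts, qa = lapply(1:30, function(s) rep(0.5, 3)))
  expect_equal(streamlineLengths(streams), rep(5, 30), tolerance = 1e-9)
  sc <- scMatrices(streams, field)
  ns <- connWeights(sc$NS)
  ml <- connWeights(sc$ML)
  expect_true(all(abs(ml[ns > 0] - 5) < 1e-9))
})

# --- bundle assignment ---

test_that("bundle membership follows the point-fraction rule", {
  # bundles A and B along x in a 10-voxel row; B overlaps A at voxels 5-6
  w <- array(0, dim = c(10, 1, 1, 2))
  w[1:6, 1, 1, 1] <- 1 # A: voxels 1-6
  w[5:10, 1, 1, 2] <- 1 # B: voxels 5-10
  bundles <- parcelVolume(w, parcelLabels = c("A", "B"), exclusive = FALSE)

  inside <- cbind(seq(0.5, 5.5, by = 1), 0.5, 0.5) # 6 points in A, 2 in B
  streams <- streamlineSet(list(inside))
  expect_equal(bundleAssign(streams, bundles, tau = 0.5)[[1]], "A")

  # 10 points: 6 in A (60%), 5 in B (50%), tau = 0.5 -> both
  pts <- cbind(seq(0.5, 9.5, by = 1), 0.5, 0.5)
  streams2 <- streamlineSet(list(pts))
  expect_setequal(bundleAssign(streams2, bundles, tau = 0.5)[[1]], c("A", "B"))

  # tau = 1 with one point outside every mask -> empty membership
  ptsOut <- rbind(pts, c(20.5, 0.5, 0.5))
  streams3 <- streamlineSet(list(ptsOut))
  expect_length(bundleAssign(streams3, bundles, tau = 1)[[1]], 0)

  expect_error(bundleAssign(streams, bundles, tau = 0), "tau")
})

test_that("bundle-pair counts include streamlines intersecting both bundles", {
  w <- array(0, dim = c(10, 1, 1, 2))
  w[1:6, 1, 1, 1] <- 1
  w[5:10, 1, 1, 2] <- 1
  bundles <- parcelVolume(w, parcelLabels = c("A", "B"), exclusive = FALSE)
  both <- cbind(seq(0.5, 9.5, by = 1), 0.5, 0.5)
  onlyA <- cbind(seq(0.5, 3.5, by = 1), 0.5, 0.5)
  streams <- streamlineSet(list(both, both, onlyA))
  mem <- bundleAssign(streams, bundles, tau = 0.5)
  counts <- bundlePairCounts(mem, c("A", "B"))
  expect_equal(connWeights(counts)["A", "B"], 2)
})

# --- group reduction ---

test_that("groupReduce matches combinatorial block counts and conserves mass", {
  labs <- paste0("P", 1:4)
  w <- matrix(1, 4, 4)
  diag(w) <- 0
  cm <- connMatrix(w, "NS", parcelLabels = labs)
  scheme <- groupingScheme(labs, c("g1", "g1", "g2", "g2"))
  red <- groupReduce(cm, scheme, stat = "sum")
  expect_equal(red["g1", "g2"], 4) # 2 x 2 between-block edges
  expect_equal(red["g1", "g1"], 1) # single within-block edge
  expect_equal(red["g2", "g2"], 1)

  # identity grouping with sum returns the original matrix
  m <- randomSymMatrix(5)
  cm2 <- connMatrix(m, "FCz")
  ident <- groupingScheme(parcelLabels(cm2), parcelLabels(cm2))
  expect_equal(groupReduce(cm2, ident, "sum"), connWeights(cm2), ignore_attr = TRUE)

  # sum-reduction conserves total edge mass (within-block edges counted once)
  scheme2 <- groupingScheme(parcelLabels(cm2), c("a", "a", "b", "b", "b"))
  red2 <- groupReduce(cm2, scheme2, "sum")
  mass <- sum(red2[upper.tri(red2)]) + sum(diag(red2))
  expect_equal(mass, sum(vectorizeEdges(m)), tolerance = 1e-10)

  # zero matrix reduces to zero blocks
  zero <- connMatrix(matrix(0, 4, 4), "NS", parcelLabels = labs)
  expect_true(all(groupReduce(zero, scheme, "mean") == 0))

  # missing parcel is named in the error
  schemeBad <- groupingScheme(labs[1:3], c("g1", "g1", "g2"))
  expect_error(groupReduce(cm, schemeBad, "sum"), "P4")
})
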