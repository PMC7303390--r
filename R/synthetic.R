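#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-session cohort generator. Each subject
#' \code{i} receives a persistent edge-wise fingerprint \code{f_i} drawn
#' i.i.d. \code{N(0, sigmaFingerprint^2)}; the session-\code{s} edge vector
#' is \code{mu + f_i + eps_{i,s}} with session noise
#' \code{eps ~ N(0, sigmaSession^2)} and a baseline \code{mu} drawn once per
#' cohort from \code{N(muMean, muSd^2)} per edge. Behavioral traits are a
#' linear function of the session-averaged weights over planted
#' positive/negative effect edges plus Gaussian noise
#' (\code{\link{generateTraits}}).
#'
#' The defaults mirror a two-session resting-state cohort of 144 subjects
#' on a 268-parcel functional atlas; scale \code{nSubjects}/\code{nParcels}
#' down for fast simulations.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nParcels number of parcels (>= 3).
#' @param nSessions number of sessions (default 2).
#' @param sigmaFingerprint std-dev of the persistent subject-specific edge
#'   component (Fisher-z units).
#' @param sigmaSession std-dev of the per-session edge noise.
#' @param muMean,muSd mean and std-dev of the cohort baseline edge weights.
#' @param effectEdgesPos,effectEdgesNeg canonical edge indices (see
#'   \code{\link{edgeIndexMap}}) whose summed weights drive the trait
#'   positively / negatively.
#' @param beta trait units per unit summed edge weight.
#' @param sigmaTrait trait noise std-dev.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   reproduce cohorts bit-for-bit.
#' @return a validated \code{CohortConfig} object.
#' @export
cohortConfig <- function(nSubjects = 144L, nParcels = 268L, nSessions = 2L,
                         sigmaFingerprint = 0.1, sigmaSession = 0.1,
                         muMean = 0.25, muSd = 0.25,
                         effectEdgesPos = integer(), effectEdgesNeg = integer(),
                         beta = 0, sigmaTrait = 0, seed = 1L) {
  cfg <- structure(
    list(
      nSubjects = as.integer(nSubjects), nParcels = as.integer(nParcels),
      nSessions = as.integer(nSessions),
      sigmaFingerprint = sigmaFingerprint, sigmaSession = sigmaSession,
      muMean = muMean, muSd = muSd,
      effectEdgesPos = as.integer(effectEdgesPos),
      effectEdgesNeg = as.integer(effectEdgesNeg),
      beta = beta, sigmaTrait = sigmaTrait, seed = as.integer(seed)
    ),
    class = "CohortConfig"
  )
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid cohort configuration: %s %s", field, why), call. = FALSE)
  }
  if (!isCount(cfg$nSubjects, 2L)) bad("nSubjects", "must be an integer >= 2")
  if (!isCount(cfg$nParcels, 3L)) bad("nParcels", "must be an integer >= 3")
  if (!isCount(cfg$nSessions, 1L)) bad("nSessions", "must be an integer >= 1")
  for (f in c("sigmaFingerprint", "sigmaSession", "sigmaTrait", "muSd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) bad(f, "must be >= 0")
  }
  nEdges <- cfg$nParcels * (cfg$nParcels - 1L) / 2L
  for (f in c("effectEdgesPos", "effectEdgesNeg")) {
    e <- cfg[[f]]
    if (length(e) && (any(e < 1L) || any(e > nEdges))) {
      bad(f, sprintf("indices must lie in 1..%d", nEdges))
    }
  }
  if (cfg$beta != 0 && !length(cfg$effectEdgesPos) && !length(cfg$effectEdgesNeg)) {
    bad("effectEdgesPos/effectEdgesNeg", "must be non-empty when beta != 0")
  }
  invisible(cfg)
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(
    "CohortConfig: %d subjects x %d sessions, %d parcels (seed %d)\n",
    x$nSubjects, x$nSessions, x$nParcels, x$seed
  ))
  cat(sprintf(
    "  sigma fingerprint %.3g, session %.3g; baseline N(%.3g, %.3g^2)\n",
    x$sigmaFingerprint, x$sigmaSession, x$muMean, x$muSd
  ))
  if (x$beta != 0) {
    cat(sprintf(
      "  trait: beta %.3g over %d pos / %d neg edges, sigma %.3g\n",
      x$beta, length(x$effectEdgesPos), length(x$effectEdgesNeg), x$sigmaTrait
    ))
  }
  invisible(x)
}

#' Generate a synthetic two-session FC cohort with planted fingerprints
#'
#' Draws a cohort under the additive model of \code{\link{cohortConfig}}:
#' per-edge baseline \code{mu}, persistent per-subject fingerprints
#' \code{f_i}, and independent per-session noise. Edge vectors are placed
#' into symmetric zero-diagonal Fisher-z connectivity matrices. When
#' \code{beta != 0}, a behavioral trait driven by the planted effect edges
#' is attached via \code{\link{generateTraits}}. All randomness flows from
#' \code{config$seed} through a local generator; the caller's RNG state is
#' untouched and identical configs reproduce identical cohorts.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{SyntheticCohort} whose \code{truth} records
#'   \code{mu} and the fingerprint matrix.
#' @export
generateFcCohort <- function(config) {
  validateCohortConfig(config)
  P <- config$nParcels
  E <- P * (P - 1L) / 2L
  labs <- paste0("P", seq_len(P))
  drawn <- withLocalSeed(config$seed, {
    mu <- rnorm(E, config$muMean, config$muSd)
    f <- matrix(rnorm(config$nSubjects * E, 0, config$sigmaFingerprint),
                nrow = config$nSubjects)
    eps <- array(rnorm(config$nSubjects * config$nSessions * E, 0, config$sigmaSession),
                 dim = c(config$nSubjects, config$nSessions, E))
    list(mu = mu, f = f, eps = eps)
  })
  fc <- vector("list", config$nSubjects)
  for (i in seq_len(config$nSubjects)) {
    fc[[i]] <- vector("list", config$nSessions)
    for (s in seq_len(config$nSessions)) {
      v <- drawn$mu + drawn$f[i, ] + drawn$eps[i, s, ]
      fc[[i]][[s]] <- connMatrix(devectorizeEdges(v, P, labs), "FCz",
                                 parcelLabels = labs,
                                 subjectId = sprintf("sub%03d", i),
                                 sessionId = sprintf("ses%d", s))
    }
  }
  names(fc) <- sprintf("sub%03d", seq_len(config$nSubjects))
  cohort <- new("SyntheticCohort",
    fcMatrices = fc, streamlines = list(),
    traits = data.frame(subject_id = names(fc), stringsAsFactors = FALSE),
    truth = list(mu = drawn$mu, fingerprints = drawn$f,
                 effectEdgesPos = config$effectEdgesPos,
                 effectEdgesNeg = config$effectEdgesNeg),
    config = config
  )
  if (config$beta != 0 || config$sigmaTrait > 0) {
    cohort@traits <- generateTraits(cohort, config)
  }
  cohort
}

#' Session-averaged edge matrix of a cohort
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @return subjects x edges matrix of session-averaged canonical edge
#'   vectors.
#' @export
cohortEdgeMatrix <- function(cohort) {
  mats <- lapply(cohort@fcMatrices, function(sess) {
    vs <- vapply(sess, function(cm) vectorizeEdges(connWeights(cm)),
                 numeric(nrow(connWeights(sess[[1L]])) * (nrow(connWeights(sess[[1L]])) - 1L) / 2L))
    rowMeans(as.matrix(vs))
  })
  t(vapply(mats, identity, numeric(length(mats[[1L]]))))
}

#' Per-session edge matrix of a cohort
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param session session index.
#' @return subjects x edges matrix for one session.
#' @export
sessionEdgeMatrix <- function(cohort, session) {
  t(vapply(cohort@fcMatrices, function(sess) {
    vectorizeEdges(connWeights(sess[[session]]))
  }, numeric(nrow(connWeights(cohort@fcMatrices[[1L]][[1L]])) *
               (nrow(connWeights(cohort@fcMatrices[[1L]][[1L]])) - 1L) / 2L)))
}

#' Generate behavioral traits driven by planted effect edges
#'
#' The trait of subject \code{i} is
#' \code{beta * (sum of session-averaged weights over the positive effect
#' edges - sum over the negative effect edges) + N(0, sigmaTrait^2)}.
#' Trait noise is drawn from its own local stream seeded with
#' \code{config$seed + 1}, so cohort generation and trait generation are
#' independently reproducible.
#'
#' @param cohort a \linkS4class{SyntheticCohort} with FC matrices.
#' @param config a \code{\link{cohortConfig}} (effect edges, beta,
#'   sigmaTrait, seed).
#' @param traitName trait column name.
#' @return data.frame with columns \code{subject_id} and the trait.
#' @export
generateTraits <- function(cohort, config, traitName = "trait1") {
  validateCohortConfig(config)
  if (config$beta != 0 &&
      !length(config$effectEdgesPos) && !length(config$effectEdgesNeg)) {
    stop("effect-edge lists are empty but beta != 0", call. = FALSE)
  }
  edges <- cohortEdgeMatrix(cohort)
  nS <- nrow(edges)
  signal <- rep(0, nS)
  if (length(config$effectEdgesPos)) {
    signal <- signal + rowSums(edges[, config$effectEdgesPos, drop = FALSE])
  }
  if (length(config$effectEdgesNeg)) {
    signal <- signal - rowSums(edges[, config$effectEdgesNeg, drop = FALSE])
  }
  noise <- withLocalSeed(config$seed + 1L, rnorm(nS, 0, config$sigmaTrait))
  out <- data.frame(
    subject_id = names(cohort@fcMatrices),
    trait = config$beta * signal + noise,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  names(out) <- c("subject_id", traitName)
  out
}

#' Trait noise level giving a target signal-to-noise ratio
#'
#' Under the generative model the across-subject variance of the summed
#' effect-edge signal is \code{k * (sigmaFingerprint^2 + sigmaSession^2 /
#' nSessions)} for \code{k} planted edges (the baseline \code{mu} is common
#' to all subjects). This helper returns the \code{sigmaTrait} for which
#' \code{beta^2 * Var(signal) / sigmaTrait^2 = snr}; at \code{snr = 1} the
#' population correlation between the trait and its noiseless signal is
#' \code{sqrt(1/2) ~ 0.707}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param snr target signal-to-noise variance ratio (> 0).
#' @return the matching \code{sigmaTrait}.
#' @export
snrTraitSigma <- function(config, snr = 1) {
  stopIfNot(is.numeric(snr) && snr > 0, "snr must be > 0")
  k <- length(config$effectEdgesPos) + length(config$effectEdgesNeg)
  stopIfNot(k > 0, "config has no effect edges")
  varSignal <- k * (config$sigmaFingerprint^2 + config$sigmaSession^2 / config$nSessions)
  sqrt(config$beta^2 * varSignal / snr)
}

#' Generate a synthetic label volume and streamline set
#'
#' Places \code{nParcels} compact cubic parcels on a grid inside a 3-D
#' label volume and draws polylines whose endpoints sit at parcel voxel
#' centers. Each streamline detours sinusoidally between its endpoints so
#' that its physical length falls inside \code{lengthRange} (defaults 20 to
#' 500 length units, the usual deterministic-tracking bounds). The QA
#' channel holds a known per-streamline constant.
#'
#' @param nParcels number of parcels (>= 2).
#' @param nStreamlines number of streamlines (0 allowed).
#' @param labelVolumeShape 3-D voxel dimensions of the label volume.
#' @param seed integer RNG seed.
#' @param lengthRange admissible streamline lengths (length-units).
#' @param voxelSize physical voxel size.
#' @param endpointParcels optional 2-column matrix of parcel indices forcing
#'   the endpoint parcels of each streamline (row per streamline); sampled
#'   uniformly when NULL.
#' @param qaValues optional per-streamline QA constants; sampled from
#'   U(0.1, 0.9) when NULL.
#' @return list with \code{streamlines} (a \linkS4class{StreamlineSet}),
#'   \code{labels} (3-D integer label array), and \code{parcels} (the
#'   corresponding hard \linkS4class{ParcelVolume}).
#' @export
generateStreamlines <- function(nParcels, nStreamlines,
                                labelVolumeShape = c(24L, 24L, 24L),
                                seed = 1L, lengthRange = c(20, 500),
                                voxelSize = c(1, 1, 1),
                                endpointParcels = NULL, qaValues = NULL) {
  stopIfNot(isCount(nParcels, 2L), "nParcels must be an integer >= 2")
  stopIfNot(isCount(nStreamlines, 0L), "nStreamlines must be an integer >= 0")
  shape <- as.integer(labelVolumeShape)
  stopIfNot(length(shape) == 3L && all(shape >= 1L), "labelVolumeShape must be 3 positive integers")

  side <- 2L # parcel cube side in voxels
  gap <- 2L
  pitch <- side + gap
  perAxis <- pmax(0L, shape %/% pitch)
  if (prod(perAxis) < nParcels) {
    stop(sprintf(
      "label volume %s too small to place %d parcels (capacity %d)",
      paste(shape, collapse = "x"), nParcels, prod(perAxis)
    ), call. = FALSE)
  }
  labels <- array(0L, dim = shape)
  centers <- matrix(0, nParcels, 3L)
  p <- 0L
  for (iz in seq_len(perAxis[3L])) {
    for (iy in seq_len(perAxis[2L])) {
      for (ix in seq_len(perAxis[1L])) {
        if (p >= nParcels) break
        p <- p + 1L
        o <- (c(ix, iy, iz) - 1L) * pitch
        labels[o[1L] + seq_len(side), o[2L] + seq_len(side), o[3L] + seq_len(side)] <- p
        centers[p, ] <- (o + (side + 1) / 2 - 0.5) * voxelSize # physical center
      }
    }
  }
  field <- parcelVolumeFromLabels(labels, voxelSize = voxelSize)

  if (nStreamlines == 0L) {
    return(list(
      streamlines = streamlineSet(list(), qa = list()),
      labels = labels, parcels = field
    ))
  }

  drawn <- withLocalSeed(seed, {
    ep <- endpointParcels
    if (is.null(ep)) {
      ep <- cbind(
        sample.int(nParcels, nStreamlines, replace = TRUE),
        sample.int(nParcels, nStreamlines, replace = TRUE)
      )
    }
    qa <- qaValues
    if (is.null(qa)) qa <- runif(nStreamlines, 0.1, 0.9)
    targets <- runif(nStreamlines, lengthRange[1L], min(lengthRange[2L], 2 * lengthRange[1L]))
    list(ep = ep, qa = qa, targets = targets)
  })
  ep <- drawn$ep
  stopIfNot(nrow(ep) == nStreamlines && ncol(ep) == 2L,
            "endpointParcels must be an nStreamlines x 2 matrix")
  stopIfNot(all(ep >= 1L & ep <= nParcels), "endpointParcels indices out of range")

  mkPolyline <- function(a, b, targetLen) {
    npts <- 50L
    t0 <- seq(0, 1, length.out = npts)
    base <- outer(1 - t0, a) + outer(t0, b)
    straight <- sqrt(sum((b - a)^2))
    # orthogonal sinusoidal detour; amplitude solved numerically so the arc
    # length hits targetLen
    ref <- if (abs(a[1L] - b[1L]) < abs(a[3L] - b[3L])) c(1, 0, 0) else c(0, 0, 1)
    dir <- (b - a)
    dn <- sqrt(sum(dir^2))
    if (dn < 1e-9) dir <- c(1, 0, 0) else dir <- dir / dn
    orth <- ref - sum(ref * dir) * dir
    if (sqrt(sum(orth^2)) < 1e-9) orth <- c(0, 1, 0)
    orth <- orth / sqrt(sum(orth^2))
    lenWith <- function(amp) {
      pts <- base + outer(sin(pi * t0 * 6), amp * orth)
      polylineLength(pts)
    }
    lo <- 0
    hi <- max(1, targetLen)
    while (lenWith(hi) < targetLen && hi < 1e4) hi <- hi * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (lenWith(mid) < targetLen) lo <- mid else hi <- mid
    }
    amp <- (lo + hi) / 2
    if (lenWith(amp) < max(straight, 1e-6)) amp <- 0
    base + outer(sin(pi * t0 * 6), amp * orth)
  }

  pts <- vector("list", nStreamlines)
  qaCh <- vector("list", nStreamlines)
  for (s in seq_len(nStreamlines)) {
    a <- centers[ep[s, 1L], ]
    b <- centers[ep[s, 2L], ]
    tl <- max(drawn$targets[s], lengthRange[1L])
    pts[[s]] <- mkPolyline(a, b, tl)
    qaCh[[s]] <- rep(drawn$qa[s], nrow(pts[[s]]))
  }
  streams <- streamlineSet(pts, qa = qaCh)
  list(streamlines = streams, labels = labels, parcels = field,
       endpointParcels = ep, qaValues = drawn$qa)
}
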