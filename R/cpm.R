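# Connectome-based predictive modeling (CPM): edge selection by thresholded
# edge-trait correlation, network-strength summation, linear prediction
# under leave-one-out cross-validation, BH-FDR over the model family.

#' Edge-behavior correlations
#'
#' Pearson correlation of every edge with a behavioral trait, with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' Subjects with a missing trait value are dropped (pairwise per trait) and
#' the number dropped is recorded in the result's attributes. Zero-variance
#' edges get r = 0, p = 1.
#'
#' @param edges subjects x edges numeric matrix.
#' @param trait numeric trait vector (one value per subject; NAs dropped).
#' @return data.frame with columns \code{edge}, \code{r}, \code{p} and
#'   attribute \code{nDropped}.
#' @export
edgeBehaviorCorr <- function(edges, trait) {
  stopIfNot(is.matrix(edges) && is.numeric(edges), "edges must be a numeric matrix")
  stopIfNot(length(trait) == nrow(edges), "trait must have one value per subject")
  keep <- !is.na(trait)
  nDropped <- sum(!keep)
  x <- edges[keep, , drop = FALSE]
  y <- trait[keep]
  n <- length(y)
  stopIfNot(n >= 4L, sprintf("need at least 4 subjects after missing-value removal (have %d)", n))
  stopIfNot(sd(y) > 0, "trait is constant")
  yc <- y - mean(y)
  xc <- sweep(x, 2L, colMeans(x))
  ssx <- colSums(xc^2)
  r <- rep(0, ncol(x))
  ok <- ssx > 0
  r[ok] <- as.vector(crossprod(xc[, ok, drop = FALSE], yc)) /
    sqrt(ssx[ok] * sum(yc^2))
  r <- pmin(pmax(r, -1), 1)
  p <- rep(1, ncol(x))
  df <- n - 2L
  rr <- r[ok]
  tt <- abs(rr) * sqrt(df / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- pmax(2 * pt(tt, df, lower.tail = FALSE), .Machine$double.xmin)
  out <- data.frame(edge = seq_len(ncol(x)), r = r, p = p)
  attr(out, "nDropped") <- nDropped
  attr(out, "n") <- n
  out
}

#' Select edges by signed thresholded correlation
#'
#' @param stats data.frame from \code{\link{edgeBehaviorCorr}}.
#' @param pThreshold selection threshold in (0, 1); edges with
#'   \code{p < pThreshold} enter the positive set when \code{r > 0} and the
#'   negative set when \code{r < 0}. The sets are disjoint and may be empty.
#' @return list with integer vectors \code{positive} and \code{negative}.
#' @export
selectEdges <- function(stats, pThreshold = 0.01) {
  stopIfNot(isProb(pThreshold), "pThreshold must lie in (0, 1)")
  sig <- stats$p < pThreshold
  list(
    positive = stats$edge[sig & stats$r > 0],
    negative = stats$edge[sig & stats$r < 0]
  )
}

#' Network strength of a subject over an edge set
#'
#' Unweighted sum of the subject's edge weights over the selected edge set
#' (the standard CPM summary). An empty set yields 0 with attribute
#' \code{empty = TRUE}.
#'
#' @param edgeVector a subject's canonical edge vector.
#' @param edgeSet integer indices into the edge vector.
#' @return scalar strength.
#' @export
networkStrength <- function(edgeVector, edgeSet) {
  if (length(edgeSet) == 0L) {
    return(structure(0, empty = TRUE))
  }
  stopIfNot(all(edgeSet >= 1L & edgeSet <= length(edgeVector)),
            "edge set index out of range")
  sum(edgeVector[edgeSet])
}

pearsonP <- function(r, n, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.finite(r) || n < 3L) return(NA_real_)
  df <- n - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- if (alternative == "greater") {
    pt(tt, df, lower.tail = FALSE)
  } else {
    2 * pt(abs(tt), df, lower.tail = FALSE)
  }
  pmax(p, .Machine$double.xmin)
}

#' CPM prediction under leave-one-out cross-validation
#'
#' For every left-out subject: recompute the edge-trait correlations on the
#' remaining subjects, select the requested-sign edges at
#' \code{pThreshold}, fit ordinary least squares
#' \code{trait ~ network strength} on the training subjects, and predict
#' the left-out subject from their strength. Folds whose edge set is empty
#' (or whose training strengths are constant) predict the training-trait
#' mean and are flagged. The summary statistic is the Pearson correlation
#' \code{rPred} between predictions and observations. Its p-value is
#' one-sided (upper tail of the t approximation): a model carries
#' predictive information only when its predictions correlate positively
#' with the observations, and the LOOCV null distribution of \code{rPred}
#' is left-skewed, so a two-sided test would be anti-conservative. A
#' subject-level permutation alternative free of the t-approximation
#' caveat is available via \code{\link{cpmPermutationP}}.
#'
#' @param edges subjects x edges matrix.
#' @param trait trait vector (NAs dropped with the matching rows).
#' @param pThreshold edge-selection threshold in (0, 1).
#' @param sign \code{"positive"} or \code{"negative"} edge network.
#' @param trait.name,group,weightKind labels carried into the result.
#' @param warnSmall warn when fewer than this many subjects (default 10).
#' @return a \linkS4class{CpmResult}.
#' @export
loocvPredict <- function(edges, trait, pThreshold = 0.01,
                         sign = c("positive", "negative"),
                         trait.name = "trait", group = "whole_brain",
                         weightKind = NA_character_, warnSmall = 10L) {
  sign <- match.arg(sign)
  stopIfNot(isProb(pThreshold), "pThreshold must lie in (0, 1)")
  keep <- !is.na(trait)
  x <- edges[keep, , drop = FALSE]
  y <- trait[keep]
  n <- length(y)
  stopIfNot(n >= 4L, "need at least 4 subjects")
  if (n < warnSmall) {
    warning(sprintf("LOOCV with only %d subjects; estimates will be unstable", n),
            call. = FALSE)
  }
  preds <- numeric(n)
  emptyFolds <- integer()
  selCount <- numeric(ncol(x))
  nSel <- numeric(n)
  # leave-one-out edge-trait correlations via downdated sufficient
  # statistics: O(E) per fold instead of re-scanning the training block
  Sx <- colSums(x)
  Sxx <- colSums(x^2)
  Sxy <- as.vector(crossprod(x, y))
  Sy <- sum(y)
  Syy <- sum(y^2)
  m <- n - 1L
  df <- m - 2L
  for (i in seq_len(n)) {
    xi <- x[i, ]
    yi <- y[i]
    sx <- Sx - xi
    sy <- Sy - yi
    varY <- (Syy - yi^2) - sy^2 / m
    if (varY <= 0) {
      stop(sprintf("trait is constant in training fold %d", i), call. = FALSE)
    }
    varX <- (Sxx - xi^2) - sx^2 / m
    covXY <- (Sxy - xi * yi) - sx * sy / m
    r <- numeric(length(sx))
    ok <- varX > 0
    r[ok] <- covXY[ok] / sqrt(varX[ok] * varY)
    r <- pmin(pmax(r, -1), 1)
    p <- rep(1, length(r))
    tt <- abs(r[ok]) * sqrt(df / pmax(1 - r[ok]^2, .Machine$double.eps))
    p[ok] <- pmax(2 * pt(tt, df, lower.tail = FALSE), .Machine$double.xmin)
    sel <- if (sign == "positive") which(p < pThreshold & r > 0) else which(p < pThreshold & r < 0)
    nSel[i] <- length(sel)
    meanYtr <- sy / m
    if (length(sel) == 0L) {
      preds[i] <- meanYtr
      emptyFolds <- c(emptyFolds, i)
      next
    }
    selCount[sel] <- selCount[sel] + 1
    strengths <- rowSums(x[, sel, drop = FALSE])
    sTrain <- strengths[-i]
    sTest <- strengths[i]
    vS <- var(sTrain)
    if (vS == 0) {
      preds[i] <- meanYtr
      emptyFolds <- c(emptyFolds, i)
      next
    }
    slope <- cov(sTrain, y[-i]) / vS
    preds[i] <- meanYtr + slope * (sTest - mean(sTrain))
  }
  noModel <- length(emptyFolds) == n
  rP <- if (noModel || sd(preds) == 0) NA_real_ else cor(preds, y)
  new("CpmResult",
    trait = trait.name, group = group, weightKind = weightKind, sign = sign,
    predictions = preds, observed = y,
    rPred = if (noModel) NA_real_ else if (is.na(rP)) 0 else rP,
    pPred = if (noModel || is.na(rP)) NA_real_ else pearsonP(rP, n, "greater"),
    selectionFreq = selCount / n, emptyFolds = emptyFolds,
    nEdgesMean = mean(nSel), nSubjects = as.integer(n),
    noModel = noModel
  )
}

#' Subject-level permutation p-value for a CPM model
#'
#' Shuffles the trait across subjects and reruns the full LOOCV pipeline
#' (including per-fold edge selection), yielding a permutation null for
#' \code{rPred} that is free of the LOOCV dependence caveat attached to the
#' t approximation. Add-one estimator, one-sided on \code{rPred >=
#' observed}.
#'
#' @param edges subjects x edges matrix.
#' @param trait trait vector.
#' @param nPerm number of permutations (>= 100 recommended).
#' @param seed RNG seed.
#' @inheritParams loocvPredict
#' @return list with \code{observed} (the \linkS4class{CpmResult}) and
#'   \code{p} (permutation p-value).
#' @export
cpmPermutationP <- function(edges, trait, pThreshold = 0.01,
                            sign = c("positive", "negative"),
                            nPerm = 100L, seed = 1L) {
  sign <- match.arg(sign)
  obs <- loocvPredict(edges, trait, pThreshold, sign, warnSmall = 0L)
  if (obs@noModel) {
    return(list(observed = obs, p = 1))
  }
  keep <- !is.na(trait)
  y <- trait[keep]
  x <- edges[keep, , drop = FALSE]
  perms <- withLocalSeed(seed, {
    t(vapply(seq_len(nPerm), function(b) sample.int(length(y)), integer(length(y))))
  })
  nullR <- vapply(seq_len(nPerm), function(b) {
    fit <- loocvPredict(x, y[perms[b, ]], pThreshold, sign, warnSmall = 0L)
    if (fit@noModel) -Inf else fit@rPred
  }, numeric(1))
  list(observed = obs, p = (1 + sum(nullR >= obs@rPred)) / (nPerm + 1))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH over a family of p-values: adjusted p-values are monotone
#' nondecreasing in the raw p-values and hypotheses with adjusted p at most
#' \code{q} are rejected.
#'
#' @param p vector of p-values in (0, 1] (NAs allowed; they are neither
#'   adjusted nor rejected).
#' @param q target false discovery rate in (0, 1).
#' @return data.frame with columns \code{p}, \code{pAdjusted},
#'   \code{rejected}.
#' @export
fdrCorrect <- function(p, q = 0.05) {
  stopIfNot(isProb(q), "q must lie in (0, 1)")
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  adj <- rep(NA_real_, length(p))
  adj[ok] <- p.adjust(p[ok], method = "BH")
  data.frame(p = p, pAdjusted = adj,
             rejected = !is.na(adj) & adj <= q)
}

#' Run the full matrix of CPM models
#'
#' One model per combination of behavioral trait, subnetwork-restricted
#' edge set (plus a whole-brain row), correlation sign and edge-weight
#' kind, with a single BH-FDR correction over the whole family — the
#' tabular equivalent of a signed r heat map of traits against
#' subnetworks.
#'
#' By default the p-values entering the FDR step come from the
#' subject-level permutation null (\code{pMethod = "permutation"}): the
#' trait is shuffled and the entire LOOCV pipeline — including per-fold
#' edge selection — is rerun, which keeps the family-wise behavior
#' calibrated in the presence of selection leakage (an edge that is
#' significant by chance in the full sample is re-selected in nearly every
#' fold, so cross-validation alone does not attenuate its chance
#' correlation). The one-sided t-approximation p is always reported
#' alongside as \code{p_param}; \code{pMethod = "tapprox"} uses it for the
#' FDR step instead, which is faster but optimistic under the null.
#'
#' @param connSets named list (by weight kind, e.g. \code{"FCz"},
#'   \code{"QA"}) of per-subject \linkS4class{ConnMatrix} lists, or of
#'   subjects x edges matrices (then \code{parcels} must give the parcel
#'   labels).
#' @param traits data.frame with \code{subject_id} and one column per
#'   trait.
#' @param scheme optional \linkS4class{GroupingScheme}; when NULL only the
#'   whole-brain model is run.
#' @param parcels parcel labels (needed when \code{connSets} holds plain
#'   matrices and \code{scheme} is given).
#' @param pThreshold edge-selection threshold.
#' @param q FDR level.
#' @param signs model signs to run.
#' @param groupMode \code{"within"} (both endpoints in the group) or
#'   \code{"incident"} (at least one endpoint).
#' @param pMethod p-value entering the FDR step: \code{"permutation"}
#'   (default, calibrated) or \code{"tapprox"} (one-sided t, fast).
#' @param nPerm permutations per model when \code{pMethod = "permutation"}.
#' @param seed RNG seed for the permutation draws.
#' @return data.frame with one row per model: \code{trait}, \code{group},
#'   \code{weight_kind}, \code{sign}, \code{n}, \code{n_edges_mean},
#'   \code{r_pred}, \code{p_param} (one-sided t approximation),
#'   \code{p_pred} (the \code{pMethod} p used for FDR), \code{p_fdr},
#'   \code{significant}.
#' @export
runMatrixOfModels <- function(connSets, traits, scheme = NULL, parcels = NULL,
                              pThreshold = 0.01, q = 0.05,
                              signs = c("positive", "negative"),
                              groupMode = c("within", "incident"),
                              pMethod = c("permutation", "tapprox"),
                              nPerm = 100L, seed = 1L) {
  groupMode <- match.arg(groupMode)
  pMethod <- match.arg(pMethod)
  stopIfNot(is.list(connSets) && !is.null(names(connSets)), "connSets must be a named list")
  stopIfNot("subject_id" %in% names(traits), "traits must have a subject_id column")
  traitNames <- setdiff(names(traits), "subject_id")
  stopIfNot(length(traitNames) >= 1L, "traits must contain at least one trait column")

  edgeSets <- lapply(connSets, function(x) {
    if (is.matrix(x)) x else edgeMatrixFromConn(x)
  })
  if (is.null(parcels)) {
    first <- connSets[[1L]]
    if (is.list(first) && is(first[[1L]], "ConnMatrix")) parcels <- parcelLabels(first[[1L]])
  }
  groups <- "whole_brain"
  if (!is.null(scheme)) {
    stopIfNot(!is.null(parcels), "parcels labels required to restrict edges by group")
    groups <- c("whole_brain", groupLevels(scheme))
  }

  rows <- list()
  for (kind in names(edgeSets)) {
    em <- edgeSets[[kind]]
    stopIfNot(nrow(em) == nrow(traits), "subject count mismatch between connSets and traits")
    for (grp in groups) {
      idx <- if (grp == "whole_brain") seq_len(ncol(em)) else {
        groupEdgeIndices(scheme, parcels, grp, mode = groupMode)
      }
      if (length(idx) == 0L) next
      sub <- em[, idx, drop = FALSE]
      for (tn in traitNames) {
        for (sg in signs) {
          if (pMethod == "permutation") {
            pr <- cpmPermutationP(sub, traits[[tn]], pThreshold, sg,
                                  nPerm = nPerm, seed = seed)
            fit <- pr$observed
            pUse <- pr$p
          } else {
            fit <- loocvPredict(sub, traits[[tn]], pThreshold, sg,
                                warnSmall = 0L)
            pUse <- fit@pPred
          }
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tn, group = grp, weight_kind = kind, sign = sg,
            n = fit@nSubjects, n_edges_mean = fit@nEdgesMean,
            r_pred = fit@rPred, p_param = fit@pPred, p_pred = pUse,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  fdr <- fdrCorrect(res$p_pred, q)
  res$p_fdr <- fdr$pAdjusted
  res$significant <- fdr$rejected
  res
}
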