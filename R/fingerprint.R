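# Cross-session connectome fingerprinting: similarity of vectorized edge
# profiles between a reference and a target session, argmax identification
# in both directions, and a permutation null for the accuracy.

asEdgeMatrix <- function(x, what) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && length(x) && is(x[[1L]], "ConnMatrix")) {
    return(edgeMatrixFromConn(x))
  }
  stop(sprintf("%s must be a subjects x edges matrix or a list of ConnMatrix", what),
       call. = FALSE)
}

#' Similarity scores between reference and target connectome fingerprints
#'
#' Entry (i, k) is the Pearson correlation between the vectorized edge
#' profile of reference-session subject i and target-session subject k.
#'
#' @param reference,target lists of \linkS4class{ConnMatrix} (one per
#'   subject, equal parcel sets) or subjects x edges matrices in the
#'   canonical edge order.
#' @return N x N similarity matrix (rows: reference, columns: target).
#' @export
similarityScores <- function(reference, target) {
  refE <- asEdgeMatrix(reference, "reference")
  tgtE <- asEdgeMatrix(target, "target")
  stopIfNot(nrow(refE) >= 2L, "need at least 2 subjects")
  stopIfNot(nrow(refE) == nrow(tgtE), "reference and target must have equal subject counts")
  stopIfNot(ncol(refE) == ncol(tgtE), "reference and target must share the edge set")
  if (is.list(reference) && is.list(target) &&
      !identical(parcelLabels(reference[[1L]]), parcelLabels(target[[1L]]))) {
    stop("parcel labels of reference and target do not match", call. = FALSE)
  }
  sdRef <- apply(refE, 1L, sd)
  sdTgt <- apply(tgtE, 1L, sd)
  if (any(sdRef == 0)) {
    stop(sprintf("reference subject %d has a zero-variance edge vector", which(sdRef == 0)[1L]),
         call. = FALSE)
  }
  if (any(sdTgt == 0)) {
    stop(sprintf("target subject %d has a zero-variance edge vector", which(sdTgt == 0)[1L]),
         call. = FALSE)
  }
  s <- cor(t(refE), t(tgtE))
  dimnames(s) <- list(rownames(refE), rownames(tgtE))
  s
}

argmaxWithTieWarning <- function(row, label) {
  m <- max(row)
  hits <- which(row == m)
  if (length(hits) > 1L) {
    warning(sprintf("similarity tie for %s; choosing the lowest index", label), call. = FALSE)
  }
  hits[1L]
}

directionAccuracy <- function(scores, trueIds) {
  pred <- vapply(seq_len(nrow(scores)), function(i) {
    argmaxWithTieWarning(scores[i, ], sprintf("reference subject %d", i))
  }, integer(1))
  list(pred = pred, acc = mean(pred == trueIds))
}

#' Identify subjects across sessions from similarity scores
#'
#' Each reference subject is identified as the target subject with the
#' highest similarity score (ties broken toward the lowest index with a
#' warning). Both directions are evaluated — reference as rows and, using
#' the transposed score matrix, target as rows — and the pooled accuracy is
#' their mean.
#'
#' @param scores square similarity matrix from
#'   \code{\link{similarityScores}}.
#' @param trueIds integer vector mapping reference subject i to its true
#'   target column (default \code{1:N}: row i corresponds to column i).
#' @return an \linkS4class{IdentificationResult} (permutation p not yet
#'   attached).
#' @export
identifySubjects <- function(scores, trueIds = seq_len(nrow(scores))) {
  stopIfNot(is.matrix(scores) && nrow(scores) == ncol(scores),
            "scores must be a square matrix")
  stopIfNot(length(trueIds) == nrow(scores), "trueIds must have one entry per subject")
  fwd <- directionAccuracy(scores, trueIds)
  inv <- integer(length(trueIds))
  inv[trueIds] <- seq_along(trueIds) # column k's true row
  bwd <- directionAccuracy(t(scores), inv)
  new("IdentificationResult",
    similarity = scores,
    predictedRefToTarget = fwd$pred,
    predictedTargetToRef = bwd$pred,
    accuracyRefToTarget = fwd$acc,
    accuracyTargetToRef = bwd$acc,
    accuracyPooled = (fwd$acc + bwd$acc) / 2
  )
}

pooledAccuracyUnder <- function(scores, predFwd, predBwd, trueIds) {
  inv <- integer(length(trueIds))
  inv[trueIds] <- seq_along(trueIds)
  (mean(predFwd == trueIds) + mean(predBwd == inv)) / 2
}

#' Permutation test for identification accuracy
#'
#' Builds a null distribution of the pooled identification accuracy by
#' randomly relabeling the target identities (shuffling which target column
#' is "correct" for each reference subject) and recomputing the accuracy of
#' the fixed argmax predictions. The p-value uses the add-one estimator
#' \code{(1 + #\{null >= observed\}) / (nPerm + 1)}, so it is never zero.
#'
#' @param scores square similarity matrix.
#' @param trueIds true reference-to-target correspondence (default
#'   \code{1:N}).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @param permutations optional explicit permutation matrix (one permutation
#'   per row) replacing random sampling, e.g. the full permutation group for
#'   small N.
#' @return the \linkS4class{IdentificationResult} of
#'   \code{\link{identifySubjects}} with \code{permutationP} and
#'   \code{nPermutations} filled in.
#' @export
permutationTestIdentification <- function(scores, trueIds = seq_len(nrow(scores)),
                                          nPerm = 1000L, seed = 1L,
                                          permutations = NULL) {
  res <- identifySubjects(scores, trueIds)
  n <- nrow(scores)
  if (is.null(permutations)) {
    stopIfNot(isCount(nPerm, 1L), "nPerm must be a positive integer")
    permutations <- withLocalSeed(seed, {
      t(vapply(seq_len(nPerm), function(b) sample.int(n), integer(n)))
    })
  } else {
    permutations <- as.matrix(permutations)
    stopIfNot(ncol(permutations) == n, "permutations must have N columns")
  }
  nullAcc <- vapply(seq_len(nrow(permutations)), function(b) {
    relabeled <- permutations[b, ][trueIds]
    pooledAccuracyUnder(scores, res@predictedRefToTarget,
                        res@predictedTargetToRef, relabeled)
  }, numeric(1))
  obs <- res@accuracyPooled
  res@permutationP <- (1 + sum(nullAcc >= obs)) / (nrow(permutations) + 1)
  res@nPermutations <- nrow(permutations)
  res
}
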