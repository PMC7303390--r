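#' Connectivity matrix
#'
#' A symmetric parcel-by-parcel edge-weight matrix with a weight-kind tag.
#' The four recognised kinds are \code{"FCz"} (Fisher z-transformed Pearson
#' functional connectivity), \code{"NS"} (streamline count, optionally
#' normalized by the total streamline count), \code{"ML"} (mean connecting
#' streamline length, optionally normalized by the whole-set mean length)
#' and \code{"QA"} (mean quantitative anisotropy along connecting
#' streamlines).
#'
#' @slot weights numeric matrix, symmetric with zero diagonal.
#' @slot parcelLabels character vector of parcel names (row/col order).
#' @slot weightKind one of \code{"FCz"}, \code{"NS"}, \code{"ML"}, \code{"QA"}.
#' @slot subjectId,sessionId optional identifiers (may be \code{NA}).
#' @slot meta free-form list of provenance metadata (e.g. normalization flags).
#'
#' @export
setClass("ConnMatrix",
  representation(
    weights = "matrix",
    parcelLabels = "character",
    weightKind = "character",
    subjectId = "character",
    sessionId = "character",
    meta = "list"
  ),
  prototype(
    subjectId = NA_character_,
    sessionId = NA_character_,
    meta = list()
  )
)

connKinds <- c("FCz", "NS", "ML", "QA")

setValidity("ConnMatrix", function(object) {
  w <- object@weights
  msgs <- character()
  if (nrow(w) != ncol(w)) msgs <- c(msgs, "weights must be square")
  if (length(object@parcelLabels) != nrow(w)) {
    msgs <- c(msgs, "parcelLabels length must equal matrix dimension")
  }
  if (anyDuplicated(object@parcelLabels)) {
    msgs <- c(msgs, "parcelLabels must be unique")
  }
  if (!all(is.finite(w))) msgs <- c(msgs, "weights must be finite")
  if (nrow(w) == ncol(w) && maxAsymmetry(w) > 1e-12) {
    msgs <- c(msgs, "weights must be symmetric (tolerance 1e-12)")
  }
  if (nrow(w) == ncol(w) && any(diag(w) != 0)) {
    msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(object@weightKind) != 1L || !object@weightKind %in% connKinds) {
    msgs <- c(msgs, sprintf(
      "weightKind must be one of %s", paste(connKinds, collapse = ", ")
    ))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConnMatrix
#'
#' @param weights square symmetric numeric matrix; the diagonal is forced to
#'   zero and small (below \code{1e-12}) asymmetries are symmetrized away.
#' @param weightKind edge-weight kind tag; see \linkS4class{ConnMatrix}.
#' @param parcelLabels parcel names; defaults to existing dimnames or
#'   \code{"P1"..."Pn"}.
#' @param subjectId,sessionId optional identifiers.
#' @param meta optional metadata list.
#' @return a \linkS4class{ConnMatrix}.
#' @examples
#' m <- matrix(c(0, .3, .1, .3, 0, .2, .1, .2, 0), 3)
#' connMatrix(m, "FCz")
#' @export
connMatrix <- function(weights, weightKind, parcelLabels = NULL,
                       subjectId = NA_character_, sessionId = NA_character_,
                       meta = list()) {
  stopIfNot(is.matrix(weights) && is.numeric(weights), "weights must be a numeric matrix")
  stopIfNot(nrow(weights) == ncol(weights), "weights must be square")
  asym <- maxAsymmetry(weights)
  stopIfNot(asym <= 1e-12, sprintf("weights asymmetric (max |w - t(w)| = %g)", asym))
  if (is.null(parcelLabels)) {
    parcelLabels <- if (!is.null(rownames(weights))) rownames(weights) else paste0("P", seq_len(nrow(weights)))
  }
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  dimnames(w) <- list(parcelLabels, parcelLabels)
  new("ConnMatrix",
    weights = w, parcelLabels = as.character(parcelLabels),
    weightKind = weightKind, subjectId = as.character(subjectId),
    sessionId = as.character(sessionId), meta = meta
  )
}

#' @describeIn connMatrix extract the weight matrix.
#' @param x a \code{ConnMatrix}.
#' @export
connWeights <- function(x) x@weights

#' @describeIn connMatrix parcel labels.
#' @export
parcelLabels <- function(x) x@parcelLabels

#' @describeIn connMatrix weight-kind tag.
#' @export
weightKind <- function(x) x@weightKind

#' @describeIn connMatrix number of parcels.
#' @export
nParcels <- function(x) nrow(x@weights)

setMethod("show", "ConnMatrix", function(object) {
  cat(sprintf(
    "ConnMatrix [%s] %d x %d parcels", object@weightKind,
    nrow(object@weights), ncol(object@weights)
  ))
  if (!is.na(object@subjectId)) cat(sprintf(" | subject %s", object@subjectId))
  if (!is.na(object@sessionId)) cat(sprintf(" session %s", object@sessionId))
  cat(sprintf(
    "\n  edge weights: range [%.4g, %.4g]\n",
    min(object@weights), max(object@weights)
  ))
  invisible(object)
})

#' Streamline set
#'
#' A collection of 3-D polylines in physical coordinates (length units of the
#' voxel grid, conventionally mm), with an optional per-point scalar channel
#' carrying quantitative anisotropy (QA), and cached per-streamline lengths.
#'
#' @slot points list of numeric matrices, one per streamline, each
#'   \code{n_points x 3}.
#' @slot qa list of per-point scalar vectors (parallel to \code{points});
#'   empty list when no QA channel is attached.
#' @slot lengths cached streamline lengths (sum of segment Euclidean norms).
#'
#' @export
setClass("StreamlineSet",
  representation(points = "list", qa = "list", lengths = "numeric")
)

setValidity("StreamlineSet", function(object) {
  msgs <- character()
  npts <- vapply(object@points, function(p) {
    if (!is.matrix(p) || ncol(p) != 3L) return(-1L)
    nrow(p)
  }, integer(1))
  if (any(npts < 0L)) msgs <- c(msgs, "each streamline must be an n x 3 matrix")
  bad <- which(npts >= 0L & npts < 2L)
  if (length(bad)) {
    msgs <- c(msgs, sprintf("streamline %d has fewer than 2 points", bad[1L]))
  }
  if (length(object@lengths) != length(object@points)) {
    msgs <- c(msgs, "lengths must parallel points")
  }
  if (length(object@points) && any(object@lengths <= 0)) {
    msgs <- c(msgs, "streamline lengths must be positive")
  }
  if (length(object@qa) && length(object@qa) != length(object@points)) {
    msgs <- c(msgs, "qa channel must parallel points (or be empty)")
  }
  if (length(object@qa)) {
    nqa <- vapply(object@qa, length, integer(1))
    if (any(nqa != npts)) msgs <- c(msgs, "qa vectors must have one value per point")
  }
  if (length(msgs)) msgs else TRUE
})

polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Construct a StreamlineSet
#'
#' @param points list of \code{n x 3} coordinate matrices (n >= 2).
#' @param qa optional list of per-point scalar vectors (QA channel).
#' @return a \linkS4class{StreamlineSet}; lengths are computed on
#'   construction.
#' @export
streamlineSet <- function(points, qa = list()) {
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  })
  lengths <- vapply(points, polylineLength, numeric(1))
  new("StreamlineSet", points = points, qa = qa, lengths = lengths)
}

#' @describeIn streamlineSet number of streamlines.
#' @param x a \code{StreamlineSet}.
#' @export
nStreamlines <- function(x) length(x@points)

#' @describeIn streamlineSet cached physical lengths.
#' @export
streamlineLengths <- function(x) x@lengths

#' @describeIn streamlineSet list of coordinate matrices.
#' @export
streamlinePoints <- function(x) x@points

#' @describeIn streamlineSet TRUE when a QA channel is attached.
#' @export
hasQa <- function(x) length(x@qa) > 0L

#' @describeIn streamlineSet per-streamline mean QA (requires a QA channel).
#' @export
meanQa <- function(x) {
  stopIfNot(hasQa(x), "StreamlineSet has no QA channel")
  vapply(x@qa, mean, numeric(1))
}

setMethod("show", "StreamlineSet", function(object) {
  n <- length(object@points)
  cat(sprintf("StreamlineSet: %d streamlines", n))
  if (n) {
    cat(sprintf(
      ", lengths [%.3g, %.3g]", min(object@lengths), max(object@lengths)
    ))
  }
  cat(if (length(object@qa)) ", QA channel attached\n" else ", no QA channel\n")
  invisible(object)
})

#' Parcel weight field
#'
#' Soft (or hard) parcel membership over a voxel grid: for every voxel and
#' every parcel a membership weight in [0, 1], with per-voxel sums at most 1.
#' Hard label volumes are the special case of one-hot weights. The same
#' container holds white-matter bundle template masks for bundle assignment.
#'
#' @slot weights 4-D numeric array (x, y, z, parcel) of memberships in [0,1].
#' @slot voxelSize physical size of a voxel along each axis.
#' @slot parcelLabels names of the parcels (4th-dimension order).
#' @slot exclusive when TRUE (parcel memberships) per-voxel weight sums may
#'   not exceed 1; bundle template masks overlap by nature and use FALSE.
#'
#' @export
setClass("ParcelVolume",
  representation(
    weights = "array", voxelSize = "numeric",
    parcelLabels = "character", exclusive = "logical"
  ),
  prototype(exclusive = TRUE)
)

setValidity("ParcelVolume", function(object) {
  msgs <- character()
  d <- dim(object@weights)
  if (length(d) != 4L) msgs <- c(msgs, "weights must be a 4-D array (x, y, z, parcel)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0)) {
    msgs <- c(msgs, "voxelSize must be 3 positive numbers")
  }
  if (length(d) == 4L && length(object@parcelLabels) != d[4L]) {
    msgs <- c(msgs, "parcelLabels must match 4th dimension")
  }
  w <- object@weights
  if (any(w < 0) || any(w > 1)) msgs <- c(msgs, "weights must lie in [0, 1]")
  if (length(d) == 4L && isTRUE(object@exclusive)) {
    sums <- apply(w, c(1L, 2L, 3L), sum)
    if (any(sums > 1 + 1e-6)) msgs <- c(msgs, "per-voxel weight sums must not exceed 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ParcelVolume
#'
#' @param weights 4-D array (x, y, z, parcel) of membership weights in [0,1].
#' @param voxelSize physical voxel size (length 3; default 1 unit isotropic).
#' @param parcelLabels parcel names; default \code{"P1"..."Pk"}.
#' @param exclusive enforce per-voxel weight sums at most 1 (TRUE for parcel
#'   memberships; use FALSE for overlapping bundle template masks).
#' @return a \linkS4class{ParcelVolume}.
#' @export
parcelVolume <- function(weights, voxelSize = c(1, 1, 1), parcelLabels = NULL,
                         exclusive = TRUE) {
  if (is.null(parcelLabels)) parcelLabels <- paste0("P", seq_len(dim(weights)[4L]))
  new("ParcelVolume",
    weights = weights, voxelSize = as.numeric(voxelSize),
    parcelLabels = as.character(parcelLabels), exclusive = exclusive
  )
}

#' Build a hard-membership ParcelVolume from an integer label image
#'
#' Voxels labelled \code{1..k} become one-hot parcel memberships; label 0 is
#' background.
#'
#' @param labels 3-D integer array of parcel labels (0 = background).
#' @param voxelSize physical voxel size (length 3).
#' @param parcelLabels optional parcel names for labels \code{1..max}.
#' @return a \linkS4class{ParcelVolume} with one-hot weights.
#' @export
parcelVolumeFromLabels <- function(labels, voxelSize = c(1, 1, 1), parcelLabels = NULL) {
  stopIfNot(length(dim(labels)) == 3L, "labels must be a 3-D array")
  k <- max(labels)
  stopIfNot(k >= 1, "label image contains no parcels")
  d <- dim(labels)
  w <- array(0, dim = c(d, k))
  for (p in seq_len(k)) {
    idx <- which(labels == p)
    if (length(idx)) {
      w[idx + (p - 1L) * prod(d)] <- 1
    }
  }
  parcelVolume(w, voxelSize = voxelSize, parcelLabels = parcelLabels)
}

setMethod("show", "ParcelVolume", function(object) {
  d <- dim(object@weights)
  cat(sprintf(
    "ParcelVolume: %d x %d x %d voxels, %d parcels, voxel size (%s)\n",
    d[1], d[2], d[3], d[4], paste(object@voxelSize, collapse = ", ")
  ))
  invisible(object)
})

#' Grouping scheme
#'
#' A mapping from parcels to subnetworks or bundle groups, defining the
#' submatrix blocks used for group-level reduction and for
#' subnetwork-restricted predictive models (e.g. the eight resting-state
#' networks of a functional atlas, seven homologous bundle sets, or eight
#' language subnetworks).
#'
#' @slot name scheme name.
#' @slot parcels parcel labels.
#' @slot groups group assignment, parallel to \code{parcels}.
#' @slot groupLevels ordered unique group labels.
#'
#' @export
setClass("GroupingScheme",
  representation(
    name = "character", parcels = "character",
    groups = "character", groupLevels = "character"
  )
)

setValidity("GroupingScheme", function(object) {
  msgs <- character()
  if (length(object@parcels) != length(object@groups)) {
    msgs <- c(msgs, "parcels and groups must be parallel")
  }
  if (anyDuplicated(object@parcels)) msgs <- c(msgs, "parcels must be unique")
  if (!all(object@groups %in% object@groupLevels)) {
    msgs <- c(msgs, "groups must be drawn from groupLevels")
  }
  if (!all(object@groupLevels %in% object@groups)) {
    msgs <- c(msgs, "every group level must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GroupingScheme
#'
#' @param parcels parcel labels (unique).
#' @param groups group label per parcel.
#' @param name scheme name.
#' @param groupLevels optional explicit group ordering; defaults to order of
#'   first appearance.
#' @return a \linkS4class{GroupingScheme}.
#' @export
groupingScheme <- function(parcels, groups, name = "grouping", groupLevels = NULL) {
  if (is.null(groupLevels)) groupLevels <- unique(as.character(groups))
  new("GroupingScheme",
    name = name, parcels = as.character(parcels),
    groups = as.character(groups), groupLevels = as.character(groupLevels)
  )
}

#' @describeIn groupingScheme group labels in scheme order.
#' @param x a \code{GroupingScheme}.
#' @export
groupLevels <- function(x) x@groupLevels

#' @describeIn groupingScheme named vector parcel -> group.
#' @export
parcelGroups <- function(x) setNames(x@groups, x@parcels)

setMethod("show", "GroupingScheme", function(object) {
  cat(sprintf(
    "GroupingScheme '%s': %d parcels in %d groups (%s)\n",
    object@name, length(object@parcels), length(object@groupLevels),
    paste(head(object@groupLevels, 8L), collapse = ", ")
  ))
  invisible(object)
})

#' Cross-session identification result
#'
#' Similarity scores between reference- and target-session connectome
#' fingerprints, argmax-based identity predictions in both directions,
#' per-direction and pooled accuracies, and (once attached) a permutation
#' p-value.
#'
#' @slot similarity N x N matrix of Pearson similarity scores
#'   (rows: reference subjects, columns: target subjects).
#' @slot predictedRefToTarget,predictedTargetToRef argmax predictions.
#' @slot accuracyRefToTarget,accuracyTargetToRef,accuracyPooled accuracies
#'   in [0, 1].
#' @slot permutationP permutation p-value in (0, 1]; \code{NA} until
#'   \code{\link{permutationTestIdentification}} is run.
#' @slot nPermutations number of permutations behind \code{permutationP}.
#'
#' @export
setClass("IdentificationResult",
  representation(
    similarity = "matrix",
    predictedRefToTarget = "integer",
    predictedTargetToRef = "integer",
    accuracyRefToTarget = "numeric",
    accuracyTargetToRef = "numeric",
    accuracyPooled = "numeric",
    permutationP = "numeric",
    nPermutations = "integer"
  ),
  prototype(permutationP = NA_real_, nPermutations = 0L)
)

setValidity("IdentificationResult", function(object) {
  msgs <- character()
  s <- object@similarity
  if (nrow(s) != ncol(s)) msgs <- c(msgs, "similarity must be square")
  if (any(abs(s) > 1 + 1e-9)) msgs <- c(msgs, "similarity entries must lie in [-1, 1]")
  for (a in c(object@accuracyRefToTarget, object@accuracyTargetToRef, object@accuracyPooled)) {
    if (!is.na(a) && (a < 0 || a > 1)) msgs <- c(msgs, "accuracies must lie in [0, 1]")
  }
  if (!is.na(object@permutationP) &&
    (object@permutationP <= 0 || object@permutationP > 1)) {
    msgs <- c(msgs, "permutationP must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn identifySubjects pooled identification accuracy.
#' @export
accuracy <- function(x) x@accuracyPooled

#' @describeIn identifySubjects similarity score matrix.
#' @export
similarityMatrix <- function(x) x@similarity

setMethod("show", "IdentificationResult", function(object) {
  cat(sprintf(
    "IdentificationResult: %d subjects\n  accuracy ref->target %.3f, target->ref %.3f, pooled %.3f\n",
    nrow(object@similarity), object@accuracyRefToTarget,
    object@accuracyTargetToRef, object@accuracyPooled
  ))
  if (!is.na(object@permutationP)) {
    cat(sprintf(
      "  permutation p = %.4g (%d permutations)\n",
      object@permutationP, object@nPermutations
    ))
  }
  invisible(object)
})

#' CPM leave-one-out cross-validation fit
#'
#' Result of a single connectome-based predictive model: per-subject LOOCV
#' predictions, the predicted-vs-observed Pearson correlation and its
#' p-value, and the per-edge selection frequency across folds.
#'
#' @slot trait,group,weightKind,sign model labels.
#' @slot predictions per-subject LOOCV predictions.
#' @slot observed observed trait values (same order).
#' @slot rPred predicted-vs-observed Pearson r (\code{NA} when no fold
#'   selected any edge).
#' @slot pPred p-value for \code{rPred} (t approximation, n - 2 df).
#' @slot selectionFreq per-edge selection frequency across folds (named by
#'   edge index into the supplied edge matrix).
#' @slot emptyFolds indices of folds whose edge set was empty (those folds
#'   predict the training-trait mean).
#' @slot nEdgesMean mean number of selected edges per fold.
#' @slot nSubjects number of subjects after missing-trait removal.
#' @slot noModel TRUE when every fold had an empty edge set.
#'
#' @export
setClass("CpmResult",
  representation(
    trait = "character", group = "character",
    weightKind = "character", sign = "character",
    predictions = "numeric", observed = "numeric",
    rPred = "numeric", pPred = "numeric",
    selectionFreq = "numeric", emptyFolds = "integer",
    nEdgesMean = "numeric", nSubjects = "integer",
    noModel = "logical"
  ),
  prototype(
    trait = NA_character_, group = "whole_brain",
    weightKind = NA_character_, noModel = FALSE
  )
)

setValidity("CpmResult", function(object) {
  msgs <- character()
  if (length(object@predictions) != length(object@observed)) {
    msgs <- c(msgs, "predictions and observed must be parallel")
  }
  if (!object@noModel && !is.finite(object@rPred)) {
    msgs <- c(msgs, "rPred must be finite unless no model could be fit")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn loocvPredict predicted-vs-observed correlation.
#' @export
rPred <- function(x) x@rPred

#' @describeIn loocvPredict p-value of the predicted-vs-observed correlation.
#' @export
pPred <- function(x) x@pPred

#' @describeIn loocvPredict per-subject LOOCV predictions.
#' @export
cpmPredictions <- function(x) x@predictions

setMethod("show", "CpmResult", function(object) {
  cat(sprintf(
    "CpmResult [%s | %s | %s | %s]: n = %d\n",
    object@trait, object@group, object@weightKind, object@sign, object@nSubjects
  ))
  if (object@noModel) {
    cat("  no model: every LOOCV fold had an empty edge set\n")
  } else {
    cat(sprintf(
      "  r_pred = %.3f (p = %.3g), mean %.1f edges/fold, %d empty folds\n",
      object@rPred, object@pPred, object@nEdgesMean, length(object@emptyFolds)
    ))
  }
  invisible(object)
})

#' Synthetic cohort
#'
#' A simulated two-session cohort with known ground truth: per-subject,
#' per-session functional connectivity matrices built from a planted
#' subject-specific fingerprint plus session noise, optional streamline
#' sets, a behavioral trait table, and a \code{truth} record of everything
#' that was planted.
#'
#' @slot fcMatrices list (one per subject) of lists (one per session) of
#'   \linkS4class{ConnMatrix} objects.
#' @slot streamlines list of \linkS4class{StreamlineSet} (possibly empty).
#' @slot traits data.frame with one row per subject (column
#'   \code{subject_id} plus trait columns).
#' @slot truth list: \code{mu} (baseline edge vector), \code{fingerprints}
#'   (subjects x edges), planted effect-edge indices, trait noise draws.
#' @slot config the \linkS4class{CohortConfig} that produced the cohort.
#'
#' @export
setClass("SyntheticCohort",
  representation(
    fcMatrices = "list", streamlines = "list",
    traits = "data.frame", truth = "list", config = "ANY"
  )
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (nrow(object@traits) && nrow(object@traits) != length(object@fcMatrices)) {
    msgs <- c(msgs, "traits must have one row per subject")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  nS <- length(object@fcMatrices)
  nSess <- if (nS) length(object@fcMatrices[[1L]]) else 0L
  nP <- if (nS) nrow(connWeights(object@fcMatrices[[1L]][[1L]])) else 0L
  cat(sprintf(
    "SyntheticCohort: %d subjects x %d sessions, %d parcels; %d trait column(s)\n",
    nS, nSess, nP, max(0L, ncol(object@traits) - 1L)
  ))
  invisible(object)
})
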