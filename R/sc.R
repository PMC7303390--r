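# Structural connectivity from streamlines: endpoint soft weights against a
# parcel field give each streamline a mass contribution
#   c_ij = w_i(start) * w_j(end) + w_j(start) * w_i(end),  i != j,
# aggregated into NS (count mass), ML (mass-weighted mean connecting
# length) and QA (mass-weighted mean per-streamline QA).

# Map physical points to voxel indices (1-based); points outside the grid
# return 0 weight for every parcel.
pointParcelWeights <- function(points, field) {
  d <- dim(field@weights)
  vox <- sweep(points, 2L, field@voxelSize, "/")
  ijk <- floor(vox) + 1L
  n <- nrow(points)
  w <- matrix(0, n, d[4L])
  inside <- ijk[, 1L] >= 1L & ijk[, 1L] <= d[1L] &
    ijk[, 2L] >= 1L & ijk[, 2L] <= d[2L] &
    ijk[, 3L] >= 1L & ijk[, 3L] <= d[3L]
  if (any(inside)) {
    base <- (ijk[inside, 1L] - 1L) +
      (ijk[inside, 2L] - 1L) * d[1L] +
      (ijk[inside, 3L] - 1L) * d[1L] * d[2L]
    for (p in seq_len(d[4L])) {
      w[inside, p] <- field@weights[base + (p - 1L) * prod(d[1:3]) + 1L]
    }
  }
  w
}

# Endpoint weight matrices (start and end) for every streamline.
endpointWeights <- function(streams, field) {
  pts <- streamlinePoints(streams)
  n <- length(pts)
  k <- dim(field@weights)[4L]
  starts <- matrix(0, n, k)
  ends <- matrix(0, n, k)
  if (n) {
    startPts <- do.call(rbind, lapply(pts, function(p) p[1L, , drop = FALSE]))
    endPts <- do.call(rbind, lapply(pts, function(p) p[nrow(p), , drop = FALSE]))
    starts <- pointParcelWeights(startPts, field)
    ends <- pointParcelWeights(endPts, field)
  }
  list(start = starts, end = ends)
}

#' Structural connectivity matrices (NS, ML, QA) from streamlines
#'
#' Aggregates a streamline set into the three structural edge-weight
#' matrices: the (optionally normalized) number of connecting streamlines
#' (NS), the (optionally normalized) mean length of the connecting
#' streamlines (ML), and the mean quantitative anisotropy along the
#' connecting streamlines (QA). Parcel membership at the two streamline
#' endpoints may be soft; each streamline contributes mass
#' \code{w_i(start) w_j(end) + w_j(start) w_i(end)} to edge (i, j).
#' Self-connections (both endpoints in the same parcel) are excluded.
#' Edges receiving no mass are zero in all three matrices.
#'
#' With \code{normalized = TRUE}, NS is divided by the total number of
#' streamlines in the set and ML by the mean length over all streamlines
#' (both recorded in the output metadata).
#'
#' @param streams a \linkS4class{StreamlineSet}.
#' @param parcels a \linkS4class{ParcelVolume} covering the endpoints.
#' @param normalized apply the NS/ML normalizations described above.
#' @param subjectId optional identifier carried into the results.
#' @return named list of three \linkS4class{ConnMatrix} objects
#'   (\code{NS}, \code{ML}, \code{QA}); \code{QA} is omitted (NULL) when the
#'   set has no QA channel and \code{requireQa = FALSE}.
#' @param requireQa error when the QA channel is missing (default TRUE).
#' @export
scMatrices <- function(streams, parcels, normalized = FALSE,
                       requireQa = TRUE, subjectId = NA_character_) {
  stopIfNot(is(streams, "StreamlineSet"), "streams must be a StreamlineSet")
  stopIfNot(is(parcels, "ParcelVolume"), "parcels must be a ParcelVolume")
  if (requireQa && nStreamlines(streams) > 0L && !hasQa(streams)) {
    stop("QA matrix requested but the StreamlineSet has no QA channel", call. = FALSE)
  }
  labs <- parcels@parcelLabels
  k <- length(labs)
  zero <- matrix(0, k, k)
  meta <- list(normalized = normalized)
  mk <- function(w, kind) {
    connMatrix(w, kind, parcelLabels = labs, subjectId = subjectId, meta = meta)
  }
  n <- nStreamlines(streams)
  if (n == 0L) {
    return(list(NS = mk(zero, "NS"), ML = mk(zero, "ML"), QA = mk(zero, "QA")))
  }
  ew <- endpointWeights(streams, parcels)
  S <- ew$start
  E <- ew$end
  lens <- streamlineLengths(streams)
  qa <- if (hasQa(streams)) meanQa(streams) else rep(NA_real_, n)

  mass <- crossprod(S, E) # mass[i,j] = sum_s S[s,i] E[s,j]
  cMat <- mass + t(mass) # c_ij = sum_s (S_i E_j + S_j E_i)
  wsum <- function(x) {
    m <- crossprod(S * x, E)
    m + t(m)
  }
  lenNum <- wsum(lens)
  qaNum <- if (hasQa(streams)) wsum(qa) else zero

  diag(cMat) <- 0
  diag(lenNum) <- 0
  diag(qaNum) <- 0

  pos <- cMat > 0
  ml <- zero
  ml[pos] <- lenNum[pos] / cMat[pos]
  qaM <- zero
  qaM[pos] <- qaNum[pos] / cMat[pos]
  ns <- cMat
  if (normalized) {
    ns <- ns / n
    ml <- ml / mean(lens)
    meta$meanLength <- mean(lens)
    meta$nStreamlines <- n
  }
  list(NS = mk(ns, "NS"), ML = mk(ml, "ML"),
       QA = if (hasQa(streams)) mk(qaM, "QA") else NULL)
}

#' Assign streamlines to bundle templates
#'
#' A streamline belongs to bundle \code{b} when the fraction of its points
#' whose membership weight in \code{b} exceeds 0.5 is at least \code{tau}.
#' Membership is a set: a streamline intersecting several bundle masks (and
#' so providing a physical path between them) belongs to all of them, which
#' is what lets intersecting bundles be included in bundle-pair counts.
#'
#' @param streams a \linkS4class{StreamlineSet}.
#' @param bundles a \linkS4class{ParcelVolume} of bundle template masks.
#' @param tau membership fraction threshold in (0, 1].
#' @return list (one element per streamline) of character vectors of bundle
#'   labels.
#' @export
bundleAssign <- function(streams, bundles, tau = 0.5) {
  stopIfNot(is.numeric(tau) && length(tau) == 1L && tau > 0 && tau <= 1,
            "tau must lie in (0, 1]")
  labs <- bundles@parcelLabels
  lapply(streamlinePoints(streams), function(p) {
    w <- pointParcelWeights(p, bundles)
    frac <- colMeans(w > 0.5)
    labs[frac >= tau]
  })
}

#' Bundle-pair connectivity from bundle memberships
#'
#' Counts, for every unordered pair of bundles, the streamlines whose
#' membership set (see \code{\link{bundleAssign}}) contains both bundles.
#'
#' @param memberships list of bundle-label vectors from
#'   \code{\link{bundleAssign}}.
#' @param bundleLabels the full ordered set of bundle labels.
#' @return a \linkS4class{ConnMatrix} of kind \code{"NS"} over bundles.
#' @export
bundlePairCounts <- function(memberships, bundleLabels) {
  k <- length(bundleLabels)
  m <- matrix(0, k, k, dimnames = list(bundleLabels, bundleLabels))
  for (mem in memberships) {
    idx <- match(mem, bundleLabels)
    idx <- idx[!is.na(idx)]
    if (length(idx) >= 2L) {
      prs <- utils::combn(sort(idx), 2L)
      for (c0 in seq_len(ncol(prs))) {
        m[prs[1L, c0], prs[2L, c0]] <- m[prs[1L, c0], prs[2L, c0]] + 1
      }
    }
  }
  m <- m + t(m)
  connMatrix(m, "NS", parcelLabels = bundleLabels,
             meta = list(unit = "streamline pair count"))
}

#' Reduce a parcel-level matrix to group-level blocks
#'
#' Block (A, B) aggregates (mean or sum) the edges with one endpoint in
#' group A and the other in group B; within-group blocks aggregate the
#' unordered within-group edges with the diagonal excluded. The result is
#' symmetric with a zero diagonal convention replaced by the within-group
#' aggregate on the diagonal.
#'
#' @param m a \linkS4class{ConnMatrix}.
#' @param scheme a \linkS4class{GroupingScheme} covering all parcels of
#'   \code{m}.
#' @param stat \code{"mean"} or \code{"sum"}.
#' @return group x group numeric matrix (groups in scheme order on both
#'   dimensions).
#' @export
groupReduce <- function(m, scheme, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopIfNot(is(m, "ConnMatrix"), "m must be a ConnMatrix")
  parcels <- parcelLabels(m)
  map <- parcelGroups(scheme)
  missing <- setdiff(parcels, names(map))
  if (length(missing)) {
    stop(sprintf("parcel '%s' missing from grouping scheme '%s'", missing[1L], scheme@name),
         call. = FALSE)
  }
  g <- factor(map[parcels], levels = groupLevels(scheme))
  w <- connWeights(m)
  k <- nlevels(g)
  out <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  fn <- if (stat == "mean") mean else sum
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(as.integer(g) == a)
      ib <- which(as.integer(g) == b)
      if (a == b) {
        if (length(ia) < 2L) {
          val <- 0
        } else {
          sub <- w[ia, ia, drop = FALSE]
          val <- fn(sub[upper.tri(sub)])
        }
      } else {
        val <- fn(w[ia, ib, drop = FALSE])
      }
      out[a, b] <- val
      out[b, a] <- val
    }
  }
  out
}
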