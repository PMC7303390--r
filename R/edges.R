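# Canonical edge indexing: upper triangle (i < j), row-major, i.e.
# (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
# This single convention orders every edge vector in the package.

#' Canonical edge index map
#'
#' Upper-triangle (i < j), row-major edge ordering used throughout the
#' package for edge vectors: \code{(1,2), (1,3), ..., (1,n), (2,3), ...}.
#'
#' @param n number of parcels (>= 2).
#' @return data.frame with integer columns \code{i}, \code{j} (1-based) of
#'   length \code{n(n-1)/2}.
#' @examples
#' edgeIndexMap(3) # rows (1,2), (1,3), (2,3)
#' @export
edgeIndexMap <- function(n) {
  stopIfNot(isCount(n, min = 2L), "n must be an integer >= 2")
  n <- as.integer(n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  data.frame(i = i, j = j)
}

#' Count connections of an n-parcel network
#'
#' Two conventions are exposed: \code{"unordered"}, the standard
#' \code{n(n-1)/2} count of unordered off-diagonal pairs, and
#' \code{"ordered-halved"}, the \code{n^2/2} count (ordered pairs halved,
#' diagonal included) that some reports use when quoting a network's total
#' number of connections. For a 52-parcel language network these give 1,326
#' and 1,352 respectively.
#'
#' @param n number of parcels.
#' @param convention counting convention.
#' @return the connection count.
#' @export
edgeCount <- function(n, convention = c("unordered", "ordered-halved")) {
  convention <- match.arg(convention)
  stopIfNot(isCount(n, min = 1L), "n must be a positive integer")
  switch(convention,
    "unordered" = n * (n - 1) / 2,
    "ordered-halved" = n * n / 2
  )
}

#' Vectorize a symmetric matrix into the canonical edge order
#'
#' @param m a \linkS4class{ConnMatrix} or symmetric numeric matrix.
#' @param tol symmetry tolerance for plain matrices.
#' @return numeric edge vector of length \code{n(n-1)/2} with attribute
#'   \code{"indexMap"} (the \code{\link{edgeIndexMap}} data.frame).
#' @export
vectorizeEdges <- function(m, tol = 1e-9) {
  if (is(m, "ConnMatrix")) m <- connWeights(m)
  stopIfNot(is.matrix(m) && nrow(m) == ncol(m), "m must be a square matrix")
  asym <- maxAsymmetry(m)
  stopIfNot(asym <= tol, sprintf("matrix asymmetric beyond tolerance (max %g)", asym))
  # lower.tri in column-major order enumerates exactly the (i<j) pairs in
  # row-major upper-triangle order for a symmetric matrix
  v <- m[lower.tri(m)]
  attr(v, "indexMap") <- edgeIndexMap(nrow(m))
  v
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of \code{\link{vectorizeEdges}}; the diagonal is zero.
#'
#' @param v edge vector of length \code{n(n-1)/2}.
#' @param n number of parcels.
#' @param labels optional parcel labels for the dimnames.
#' @return symmetric \code{n x n} numeric matrix with zero diagonal.
#' @export
devectorizeEdges <- function(v, n, labels = NULL) {
  stopIfNot(isCount(n, min = 2L), "n must be an integer >= 2")
  n <- as.integer(n)
  stopIfNot(length(v) == n * (n - 1L) / 2L,
            sprintf("edge vector must have length n(n-1)/2 = %d", n * (n - 1L) / 2L))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Stack the edge vectors of a list of ConnMatrix objects into a
# subjects x edges matrix, validating parcel-label agreement.
edgeMatrixFromConn <- function(conns) {
  stopIfNot(length(conns) >= 1L, "need at least one connectivity matrix")
  labs <- parcelLabels(conns[[1L]])
  for (k in seq_along(conns)) {
    if (!identical(parcelLabels(conns[[k]]), labs)) {
      stop(sprintf("parcel labels of matrix %d do not match matrix 1", k), call. = FALSE)
    }
  }
  t(vapply(conns, function(cm) vectorizeEdges(connWeights(cm)),
           numeric(length(labs) * (length(labs) - 1L) / 2L)))
}

# Edge indices (into the canonical ordering for `parcels`) restricted to a
# grouping-scheme group: mode "within" keeps edges with both endpoints in
# the group, "incident" keeps edges with at least one endpoint in it.
groupEdgeIndices <- function(scheme, parcels, group, mode = c("within", "incident")) {
  mode <- match.arg(mode)
  map <- parcelGroups(scheme)
  missing <- setdiff(parcels, names(map))
  if (length(missing)) {
    stop(sprintf("parcel '%s' missing from grouping scheme '%s'", missing[1L], scheme@name),
         call. = FALSE)
  }
  g <- map[parcels]
  idx <- edgeIndexMap(length(parcels))
  inA <- g[idx$i] == group
  inB <- g[idx$j] == group
  which(if (mode == "within") inA & inB else inA | inB)
}
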