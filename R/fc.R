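#' Functional connectivity matrix (Fisher z of Pearson r)
#'
#' Computes the parcel-by-parcel Pearson correlation matrix of a BOLD
#' time-series matrix and applies the Fisher z-transform
#' \code{atanh(r)} to every off-diagonal entry. Correlations are clipped to
#' \code{±(1 - 1e-7)} before the transform so that perfectly (anti)correlated
#' parcels map to large finite z rather than infinity. The diagonal is zero.
#' No thresholding or binarization is applied.
#'
#' @param ts numeric matrix, timepoints x parcels (>= 3 timepoints); column
#'   names are used as parcel labels when present.
#' @param parcelLabels optional parcel labels overriding column names.
#' @param subjectId,sessionId optional identifiers carried into the result.
#' @return a \linkS4class{ConnMatrix} with \code{weightKind = "FCz"}.
#' @examples
#' ts <- matrix(rnorm(60), nrow = 20, ncol = 3,
#'              dimnames = list(NULL, c("A", "B", "C")))
#' fcMatrix(ts)
#' @export
fcMatrix <- function(ts, parcelLabels = NULL,
                     subjectId = NA_character_, sessionId = NA_character_) {
  stopIfNot(is.matrix(ts) && is.numeric(ts), "ts must be a numeric matrix")
  stopIfNot(nrow(ts) >= 3L, "need at least 3 timepoints")
  stopIfNot(ncol(ts) >= 2L, "need at least 2 parcels")
  if (is.null(parcelLabels)) {
    parcelLabels <- if (!is.null(colnames(ts))) colnames(ts) else paste0("P", seq_len(ncol(ts)))
  }
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    stop(sprintf("parcel '%s' has a constant time series", parcelLabels[which(sds == 0)[1L]]),
         call. = FALSE)
  }
  r <- cor(ts)
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2 # guard against last-bit asymmetry
  connMatrix(z, "FCz", parcelLabels = parcelLabels,
             subjectId = subjectId, sessionId = sessionId)
}
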