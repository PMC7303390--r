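# Readers and writers. CSV is the canonical matrix format (labeled, full
# double precision); streamlines go to TRK or a plain-text TSV dialect
# (one point per line: streamline_id x y z qa); label volumes to NIfTI.

#' Write / read a labeled connectivity-matrix CSV
#'
#' The file starts with a comment line \code{# weight_kind=<kind>}, then a
#' header row of parcel labels and one labeled row per parcel. Values are
#' printed at 17 significant digits so that a write/read round trip is
#' bit-identical.
#'
#' @param m a \linkS4class{ConnMatrix}.
#' @param path output file.
#' @return \code{writeConnCsv}: the path, invisibly. \code{readConnCsv}:
#'   a \linkS4class{ConnMatrix}.
#' @export
writeConnCsv <- function(m, path) {
  stopIfNot(is(m, "ConnMatrix"), "m must be a ConnMatrix")
  w <- connWeights(m)
  labs <- parcelLabels(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weight_kind=%s", weightKind(m)), con)
  writeLines(paste(c("parcel", labs), collapse = ","), con)
  for (i in seq_len(nrow(w))) {
    writeLines(paste(c(labs[i], fmtNum(w[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname writeConnCsv
#' @param weightKind kind tag to use when the file has no
#'   \code{# weight_kind} comment.
#' @export
readConnCsv <- function(path, weightKind = NULL) {
  lines <- readLines(path)
  stopIfNot(length(lines) >= 2L, "connectivity CSV is empty")
  kind <- weightKind
  if (startsWith(lines[1L], "#")) {
    m0 <- regmatches(lines[1L], regexec("weight_kind=([A-Za-z]+)", lines[1L]))[[1L]]
    if (length(m0) == 2L) kind <- m0[2L]
    lines <- lines[-1L]
  }
  stopIfNot(!is.null(kind), "weight kind not recorded in file and not supplied")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  labs <- header[-1L]
  if (anyDuplicated(labs)) stop("duplicated parcel labels in header", call. = FALSE)
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  stopIfNot(length(body) == length(labs), "row count does not match header")
  rowLabs <- vapply(body, `[[`, character(1), 1L)
  if (!identical(rowLabs, labs)) {
    stop("row labels do not match column labels", call. = FALSE)
  }
  w <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(length(labs))))
  stopIfNot(all(is.finite(w)), "non-numeric or non-finite matrix entries")
  asym <- maxAsymmetry(w)
  if (asym > 1e-9) {
    stop(sprintf("matrix asymmetric beyond tolerance on read (max %g)", asym), call. = FALSE)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  connMatrix(w, kind, parcelLabels = labs)
}

#' Write / read streamlines in the plain-text TSV dialect
#'
#' One point per line: \code{streamline_id x y z qa} (tab-separated,
#' \code{qa} is \code{NA} when no QA channel is attached). Coordinates are
#' printed with enough digits for round trips within 1e-6.
#'
#' @param streams a \linkS4class{StreamlineSet}.
#' @param path file path.
#' @return \code{writeStreamlinesTsv}: the path, invisibly.
#'   \code{readStreamlinesTsv}: a \linkS4class{StreamlineSet}.
#' @export
writeStreamlinesTsv <- function(streams, path) {
  stopIfNot(is(streams, "StreamlineSet"), "streams must be a StreamlineSet")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("streamline_id\tx\ty\tz\tqa", con)
  pts <- streamlinePoints(streams)
  withQa <- hasQa(streams)
  for (s in seq_along(pts)) {
    p <- pts[[s]]
    qa <- if (withQa) streams@qa[[s]] else rep(NA_real_, nrow(p))
    writeLines(sprintf("%d\t%.9g\t%.9g\t%.9g\t%s",
                       s, p[, 1L], p[, 2L], p[, 3L],
                       ifelse(is.na(qa), "NA", sprintf("%.9g", qa))), con)
  }
  invisible(path)
}

#' @rdname writeStreamlinesTsv
#' @export
readStreamlinesTsv <- function(path) {
  d <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("streamline_id", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("streamline TSV must have columns streamline_id, x, y, z[, qa]", call. = FALSE)
  }
  ids <- unique(d$streamline_id)
  pts <- vector("list", length(ids))
  qa <- vector("list", length(ids))
  withQa <- "qa" %in% names(d) && !all(is.na(d$qa))
  for (k in seq_along(ids)) {
    rows <- d[d$streamline_id == ids[k], , drop = FALSE]
    if (nrow(rows) < 2L) {
      stop(sprintf("streamline %s has fewer than 2 points", ids[k]), call. = FALSE)
    }
    if (any(!is.finite(rows$x) | !is.finite(rows$y) | !is.finite(rows$z))) {
      stop(sprintf("malformed coordinates in streamline %s", ids[k]), call. = FALSE)
    }
    pts[[k]] <- cbind(rows$x, rows$y, rows$z)
    if (withQa) qa[[k]] <- rows$qa
  }
  streamlineSet(pts, qa = if (withQa) qa else list())
}

#' Write / read streamlines in TRK format
#'
#' Minimal TRK (TrackVis) v2 support: a 1000-byte little-endian header and
#' one record per streamline. Coordinates are stored as given (physical
#' units, identity orientation); the QA channel, when attached, is written
#' as a single per-point scalar named \code{"qa"}.
#'
#' @param streams a \linkS4class{StreamlineSet}.
#' @param path file path.
#' @param dim,voxelSize header fields (voxel grid dimensions and size).
#' @return \code{writeTrk}: the path, invisibly. \code{readTrk}: a
#'   \linkS4class{StreamlineSet}.
#' @export
writeTrk <- function(streams, path, dim = c(1L, 1L, 1L), voxelSize = c(1, 1, 1)) {
  stopIfNot(is(streams, "StreamlineSet"), "streams must be a StreamlineSet")
  withQa <- hasQa(streams)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(as.raw(0L), con) # terminator of id_string[6]
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxelSize), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little") # origin
  writeBin(as.integer(if (withQa) 1L else 0L), con, size = 2L, endian = "little")
  scalarNames <- raw(200L)
  if (withQa) scalarNames[1:2] <- charToRaw("qa")
  writeBin(scalarNames, con)
  writeBin(0L, con, size = 2L, endian = "little") # n_properties
  writeBin(raw(200L), con) # property names
  vox2ras <- diag(c(voxelSize, 1))
  writeBin(as.numeric(t(vox2ras)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con) # reserved
  writeChar("RAS", con, nchars = 3L, eos = NULL)
  writeBin(as.raw(0L), con)
  writeBin(raw(4L), con) # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2L), con) # pad1
  writeBin(raw(6L), con) # invert/swap flags
  writeBin(as.integer(nStreamlines(streams)), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little") # version
  writeBin(1000L, con, size = 4L, endian = "little") # hdr_size
  pts <- streamlinePoints(streams)
  for (s in seq_along(pts)) {
    p <- pts[[s]]
    writeBin(nrow(p), con, size = 4L, endian = "little")
    rec <- if (withQa) cbind(p, streams@qa[[s]]) else p
    writeBin(as.numeric(t(rec)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname writeTrk
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readChar(con, 5L, useBytes = TRUE)
  stopIfNot(identical(id, "TRACK"), "not a TRK file (bad id string)")
  invisible(readBin(con, "raw", 1L))
  invisible(readBin(con, "integer", 3L, size = 2L, endian = "little"))
  invisible(readBin(con, "numeric", 3L, size = 4L, endian = "little"))
  invisible(readBin(con, "numeric", 3L, size = 4L, endian = "little"))
  nScalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  nProps <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))
  invisible(readBin(con, "numeric", 16L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", 444L + 4L + 4L)) # reserved, voxel_order, pad2
  invisible(readBin(con, "numeric", 6L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", 2L + 6L))
  nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  stopIfNot(hdrSize == 1000L, "unexpected TRK header size")
  stopIfNot(version %in% c(1L, 2L), "unsupported TRK version")
  pts <- list()
  qa <- list()
  s <- 0L
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    s <- s + 1L
    if (npts < 2L) {
      stop(sprintf("streamline %d has fewer than 2 points", s), call. = FALSE)
    }
    rec <- readBin(con, "numeric", npts * (3L + nScalars), size = 4L, endian = "little")
    if (length(rec) != npts * (3L + nScalars)) {
      stop(sprintf("truncated record for streamline %d", s), call. = FALSE)
    }
    rec <- matrix(rec, ncol = 3L + nScalars, byrow = TRUE)
    pts[[s]] <- rec[, 1:3, drop = FALSE]
    if (nScalars >= 1L) qa[[s]] <- rec[, 4L]
    if (nProps > 0L) invisible(readBin(con, "numeric", nProps, size = 4L, endian = "little"))
  }
  if (nCount > 0L && s != nCount) {
    stop(sprintf("TRK header announces %d streamlines, found %d", nCount, s), call. = FALSE)
  }
  streamlineSet(pts, qa = if (length(qa)) qa else list())
}

#' Read / write a grouping scheme as two-column CSV
#'
#' Columns \code{parcel,group}, one row per parcel.
#'
#' @param path file path.
#' @param name scheme name (defaults to the file name).
#' @return \code{readGroupingCsv}: a \linkS4class{GroupingScheme}.
#' @export
readGroupingCsv <- function(path, name = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parcel", "group") %in% names(d))) {
    stop("grouping CSV must have columns parcel,group", call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  groupingScheme(d$parcel, d$group, name = name)
}

#' @rdname readGroupingCsv
#' @param scheme a \linkS4class{GroupingScheme}.
#' @export
writeGroupingCsv <- function(scheme, path) {
  write.csv(data.frame(parcel = scheme@parcels, group = scheme@groups),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a behavioral trait table
#'
#' CSV with a \code{subject_id} column and one column per trait; missing
#' values stay \code{NA}.
#'
#' @param path file path.
#' @return \code{readTraitsCsv}: data.frame.
#' @export
readTraitsCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopIfNot("subject_id" %in% names(d), "trait table must have a subject_id column")
  stopIfNot(!anyDuplicated(d$subject_id), "duplicated subject ids in trait table")
  d
}

#' @rdname readTraitsCsv
#' @param traits trait data.frame.
#' @export
writeTraitsCsv <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a parcel label volume as NIfTI
#'
#' @param labels 3-D integer label array (0 = background).
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize physical voxel size.
#' @return \code{readLabelVolumeNifti}: list with \code{labels} and
#'   \code{voxelSize}.
#' @export
writeLabelVolumeNifti <- function(labels, path, voxelSize = c(1, 1, 1)) {
  img <- RNifti::asNifti(labels, reference = NULL)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeLabelVolumeNifti
#' @export
readLabelVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(labels = array(as.integer(round(img)), dim = dim(img)),
       voxelSize = RNifti::pixdim(img)[1:3])
}
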