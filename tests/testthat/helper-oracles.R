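# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written from first principles (loops, textbook formulas),
# not by calling the code paths they validate.

# Textbook two-pass Pearson correlation of two vectors.
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Two-sided p for Pearson r via the t distribution, n - 2 df.
oraclePearsonP <- function(r, n) {
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(tt, n - 2, lower.tail = FALSE)
}

# Brute-force Benjamini-Hochberg step-up: rejection set and adjusted p.
oracleBH <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- (seq_len(m) / m) * q
  kmax <- suppressWarnings(max(which(ps <= thresh)))
  reject <- logical(m)
  if (is.finite(kmax)) reject[o[seq_len(kmax)]] <- TRUE
  adj <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, ps[k] * m / k)
    adj[k] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  list(reject = reject, adjusted = out)
}

# Brute-force per-streamline endpoint tally for hard parcel labels.
oracleHardSc <- function(startParcel, endParcel, lengths, qa, nParcels) {
  ns <- matrix(0, nParcels, nParcels)
  lenSum <- matrix(0, nParcels, nParcels)
  qaSum <- matrix(0, nParcels, nParcels)
  for (s in seq_along(startParcel)) {
    i <- startParcel[s]; j <- endParcel[s]
    if (i == j) next
    a <- min(i, j); b <- max(i, j)
    ns[a, b] <- ns[a, b] + 1
    lenSum[a, b] <- lenSum[a, b] + lengths[s]
    qaSum[a, b] <- qaSum[a, b] + qa[s]
  }
  ml <- matrix(0, nParcels, nParcels)
  qm <- matrix(0, nParcels, nParcels)
  pos <- ns > 0
  ml[pos] <- lenSum[pos] / ns[pos]
  qm[pos] <- qaSum[pos] / ns[pos]
  sym <- function(m) m + t(m)
  list(NS = sym(ns), ML = sym(ml), QA = sym(qm))
}

# Make a small random symmetric zero-diagonal matrix.
randomSymMatrix <- function(n) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Build a tiny cohort-like edge matrix (subjects x edges) directly.
randomEdgeMatrix <- function(nSubjects, nEdges) {
  matrix(stats::rnorm(nSubjects * nEdges), nSubjects, nEdges)
}

# Slow reference LOOCV-CPM: per-fold two-pass correlations, explicit OLS.
oracleLoocv <- function(x, y, pThreshold, sign) {
  n <- length(y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    rs <- apply(x[tr, , drop = FALSE], 2, function(col) {
      if (stats::sd(col) == 0) return(0)
      oraclePearson(col, y[tr])
    })
    ps <- vapply(rs, function(r) {
      if (r == 0) return(1)
      min(max(oraclePearsonP(min(max(r, -1), 1), n - 1), .Machine$double.xmin), 1)
    }, numeric(1))
    sel <- if (sign == "positive") which(ps < pThreshold & rs > 0) else which(ps < pThreshold & rs < 0)
    if (length(sel) == 0L) {
      preds[i] <- mean(y[tr])
      next
    }
    s <- rowSums(x[, sel, drop = FALSE])
    fit <- stats::lm(y[tr] ~ s[tr])
    preds[i] <- sum(stats::coef(fit) * c(1, s[i]))
  }
  preds
}

# All permutations of 1..n (for exhaustive permutation-null enumeration).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
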