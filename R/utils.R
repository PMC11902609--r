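# Shared internal helpers: classed errors, input checks, index reflection,
# circular interpolation and 8-connected labeling.

.busErr <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "bussegError")))
}

# A frame is a plain numeric matrix of 8-bit intensities, rows = y (depth,
# row 1 is the transducer side), cols = x.
.checkFrame <- function(frame, minSize = 3L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    .busErr("bussegInvalidInput", "'frame' must be a numeric matrix")
  if (nrow(frame) < minSize || ncol(frame) < minSize)
    .busErr("bussegInvalidInput",
            sprintf("'frame' must be at least %d x %d", minSize, minSize))
  if (anyNA(frame) || any(frame < 0 | frame > 255))
    .busErr("bussegInvalidInput", "frame intensities must lie in [0, 255]")
  invisible(frame)
}

.checkSigmas <- function(sigmas) {
  if (length(sigmas) < 1L || !is.numeric(sigmas))
    .busErr("bussegInvalidParameter", "scale schedule must be non-empty numeric")
  if (any(sigmas <= 0) || any(sigmas > 128))
    .busErr("bussegInvalidParameter", "sigmas must lie in (0, 128]")
  if (is.unsorted(sigmas, strictly = TRUE))
    .busErr("bussegInvalidParameter", "sigmas must be strictly increasing")
  invisible(sigmas)
}

# Half-sample symmetric reflection of 1-based indices into [1, n]
# (... c b a | a b c ... c b a | a b c ...), applied with period 2n so
# kernels wider than the image fold correctly.
.reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Population standard deviation (divide by N).
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Fill values at 'bad' positions by linear interpolation in 'angle'
# between the circularly nearest good neighbours. Runs of bad points are
# spanned as a whole. Requires at least one good point.
.circularFill <- function(values, bad, angle) {
  n <- length(values)
  good <- which(!bad)
  if (length(good) == 0L)
    .busErr("bussegInternal", "no surviving points to interpolate from")
  if (length(good) == n || length(good) == 1L) {
    if (length(good) == 1L) values[bad] <- values[good]
    return(values)
  }
  out <- values
  for (i in which(bad)) {
    prev <- good[good < i]
    nxt <- good[good > i]
    p <- if (length(prev)) max(prev) else max(good)   # wrap backwards
    q <- if (length(nxt)) min(nxt) else min(good)     # wrap forwards
    ap <- angle[p]; aq <- angle[q]; ai <- angle[i]
    if (p > i) ap <- ap - 360           # neighbour from the previous turn
    if (q < i) aq <- aq + 360           # neighbour from the next turn
    t <- if (aq == ap) 0 else (ai - ap) / (aq - ap)
    out[i] <- values[p] + t * (values[q] - values[p])
  }
  out
}

# 8-connected component labeling of a logical matrix by iterative label
# propagation (each foreground pixel takes the max label among itself and
# its 8 neighbours until a fixed point). Returns an integer matrix with
# components relabeled 1..K in order of first (column-major) occurrence.
.label8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  lab[idx] <- idx
  shifts <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  repeat {
    best <- lab
    for (s in shifts) {
      dr <- s[1]; dc <- s[2]
      sh <- matrix(0L, n, m)
      rs <- max(1L, 1L + dr):min(n, n + dr)   # destination rows
      cs <- max(1L, 1L + dc):min(m, m + dc)
      sh[rs, cs] <- lab[rs - dr, cs - dc]
      best <- pmax(best, sh)
    }
    best[!mask] <- 0L
    if (identical(best, lab)) break
    lab <- best
  }
  # relabel 1..K in column-major order of first occurrence ('idx' ascending)
  lab[idx] <- match(lab[idx], unique(lab[idx]))
  lab
}
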