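# Independent oracles. These deliberately do not share code with the
# package: the filter oracle is a literal double loop, the survival
# estimator is the closed-form geometric MLE, and the matching oracle
# enumerates assignments exhaustively.

# Mirror an out-of-range index back into 1..n (edge pixel duplicated).
reflectIndex <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Literal double-loop discoidal average filter: mean over the inner disc
# (Euclidean pixel-centre distance <= rIn, centre included) minus mean over
# the annulus rIn < d <= rOut, reflective borders.
oracleDiscoidal <- function(img, rIn = 1, rOut = 3) {
  n <- nrow(img); m <- ncol(img)
  r <- ceiling(rOut)
  out <- matrix(0, n, m)
  for (y in 1:n) for (x in 1:m) {
    sIn <- 0; nIn <- 0; sAnn <- 0; nAnn <- 0
    for (dy in -r:r) for (dx in -r:r) {
      d <- sqrt(dy^2 + dx^2)
      if (d > rOut) next
      v <- img[reflectIndex(y + dy, n), reflectIndex(x + dx, m)]
      if (d <= rIn) { sIn <- sIn + v; nIn <- nIn + 1 }
      else { sAnn <- sAnn + v; nAnn <- nAnn + 1 }
    }
    out[y, x] <- sIn / nIn - sAnn / nAnn
  }
  out
}

# Maximum-likelihood per-frame survival probability from observed frame
# counts of a (conditional, support >= 1) geometric distribution.
geometricSurvivalMLE <- function(nFrames) {
  (sum(nFrames) - length(nFrames)) / sum(nFrames)
}

# Exhaustive minimum-total-distance assignment between two point sets under
# a distance gate: among all gated matchings of maximum cardinality, the
# one with the smallest total distance. Returns an integer vector over b
# (index into a, NA = unmatched).
bruteForceMatch <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2))
  best <- list(card = -1L, cost = Inf, match = rep(NA_integer_, nb))
  recurse <- function(j, usedA, match, card, cost) {
    if (j > nb) {
      if (card > best$card ||
          (card == best$card && cost < best$cost))
        best <<- list(card = card, cost = cost, match = match)
      return(invisible())
    }
    recurse(j + 1L, usedA, match, card, cost)     # leave b_j unmatched
    for (i in seq_len(na)) {
      if (usedA[i] || d[i, j] > radius) next
      usedA[i] <- TRUE; match[j] <- i
      recurse(j + 1L, usedA, match, card + 1L, cost + d[i, j])
      usedA[i] <- FALSE; match[j] <- NA_integer_
    }
  }
  recurse(1L, rep(FALSE, na), rep(NA_integer_, nb), 0L, 0)
  best
}

# Closed-form relative survival of the kept-event frame-count distribution
# under the whole-frame observation model (mixture-aware).
oracleSurvival <- function(m, tauInt, tauTl, kb, koff, amplitudes = 1) {
  p <- exp(-(kb * tauInt + koff * tauTl))
  drop(outer(m, p, function(mm, pp) pp^mm) %*% amplitudes) /
    drop(sum(p * amplitudes))
}
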