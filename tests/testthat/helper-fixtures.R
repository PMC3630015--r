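## Shared fixtures and independent oracles used across the test files.

## small random paired data set with full-rank blocks
randomPaired <- function(n, p, q, seed = 1, standardize = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(p))))
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("m", seq_len(q))))
  pairedOmics(X, Y, standardize = standardize)
}

## brute-force network edges: double loop over all entries
bruteEdges <- function(m, threshold) {
  out <- NULL
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      if (abs(m[i, j]) >= threshold)
        out <- rbind(out, data.frame(x = rownames(m)[i],
                                     y = colnames(m)[j],
                                     weight = m[i, j],
                                     stringsAsFactors = FALSE))
  out
}

## naive agglomerative clustering oracle: rescans the full distance matrix
## at every step with the Lance-Williams update for the requested linkage.
## Returns merge matrix (hclust convention) and heights.
naiveAgglom <- function(D, linkage = "ward") {
  D <- as.matrix(D)
  n <- nrow(D)
  active <- seq_len(n)
  sizes <- rep(1, n)
  labels <- -seq_len(n)          # hclust codes: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    ## find the closest active pair (ties: smallest indices)
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active))
      for (b in seq_along(active))
        if (a < b) {
          dd <- D[active[a], active[b]]
          if (dd < bd - 1e-12) { bd <- dd; best <- c(a, b) }
        }
    i <- best[1]; j <- best[2]
    ci <- active[i]; cj <- active[j]
    m1 <- labels[ci]; m2 <- labels[cj]
    merge[step, ] <- sort(c(m1, m2))
    height[step] <- bd
    ## Lance-Williams update against every other active cluster
    for (b in seq_along(active)) {
      ck <- active[b]
      if (ck == ci || ck == cj) next
      dik <- D[ci, ck]; djk <- D[cj, ck]; dij <- bd
      ni <- sizes[ci]; nj <- sizes[cj]; nk <- sizes[ck]
      dnew <- switch(linkage,
        ward = ((ni + nk) * dik + (nj + nk) * djk - nk * dij) /
               (ni + nj + nk),
        single = min(dik, djk),
        complete = max(dik, djk),
        average = (ni * dik + nj * djk) / (ni + nj))
      D[ci, ck] <- D[ck, ci] <- dnew
    }
    sizes[ci] <- sizes[ci] + sizes[cj]
    labels[ci] <- step
    active <- active[-j]
  }
  list(merge = merge, height = height)
}

## normalize an hclust-style merge matrix so each row is sorted and rows are
## comparable across implementations with identical merge heights
normalizeMerge <- function(merge) t(apply(merge, 1, sort))

## block labels of the default simulation design ids
idGroup <- function(ids) ifelse(isNoiseId(ids), "noise", substr(ids, 2, 2))
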