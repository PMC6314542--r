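# Independent reference implementations used as oracles.

# Brute-force marker-controlled watershed: at every step, among all
# unlabeled masked pixels 8-adjacent to a labeled pixel, label the one
# with the smallest (value, row-major index), giving it the label of its
# labeled 8-neighbor with the smallest (value, label id) -- the neighbor
# the flood arrives through. O(n^2) - fixtures only.
brute_watershed <- function(values, seed_matrix, mask) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- ifelse(mask, seed_matrix, 0L)
  nbrs <- function(i, j) {
    out <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        out <- rbind(out, c(ii, jj))
    }
    out
  }
  repeat {
    best <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nb <- nbrs(i, j)
      labs <- lab[nb]
      if (!any(labs > 0L)) next
      sel <- labs > 0L
      nv <- values[nb][sel]
      nl <- labs[sel]
      src <- order(nv, nl)[1]
      key <- c(values[i, j], (i - 1) * nc + (j - 1))
      if (is.null(best) || key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2]))
        best <- list(key = key, i = i, j = j, lab = nl[src])
    }
    if (is.null(best)) break
    lab[best$i, best$j] <- best$lab
  }
  lab
}

# paraboloid pit image: value = base - depth * max(0, 1 - r^2/R^2)
paraboloid_pit <- function(n, center, R, base = 100, depth = 60) {
  v <- matrix(base, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- (i - center[1])^2 + (j - center[2])^2
    v[i, j] <- base - depth * max(0, 1 - r2 / R^2)
  }
  v
}

# small synthetic image with Gaussian pits at given (row, col, depth)
pit_image <- function(n, pits, base = 100, sigma = 1.5) {
  v <- matrix(base, n, n)
  for (k in seq_len(nrow(pits))) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r2 <- (i - pits[k, 1])^2 + (j - pits[k, 2])^2
      v[i, j] <- v[i, j] - pits[k, 3] * exp(-r2 / (2 * sigma^2))
    }
  }
  v
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_true(max(abs(a - b)) <= tol)
}
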