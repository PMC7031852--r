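# Brute-force oracles, deliberately independent of the package's compiled
# kernels: plain R loops over definitions.

# mirror-reflect an out-of-range index into [1, n]
reflect1 <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  w / sum(w)
}

# direct (non-separable) 3D convolution with the outer-product Gaussian
# kernel, mirror boundaries
bruteGaussSmooth <- function(vol, sigmaVox) {
  d <- dim(vol)
  ks <- lapply(sigmaVox, gaussKernel1d)
  rs <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, 1L)
  out <- array(0, d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    acc <- 0
    for (kx in seq_along(ks[[3]])) for (ky in seq_along(ks[[2]]))
      for (kz in seq_along(ks[[1]])) {
        zz <- reflect1(z + kz - rs[1] - 1L, d[1])
        yy <- reflect1(y + ky - rs[2] - 1L, d[2])
        xx <- reflect1(x + kx - rs[3] - 1L, d[3])
        acc <- acc + ks[[1]][kz] * ks[[2]][ky] * ks[[3]][kx] * vol[zz, yy, xx]
      }
    out[z, y, x] <- acc
  }
  out
}

# sliding-window local mean, window clipped at the boundary
bruteLocalMean <- function(vol, half) {
  d <- dim(vol)
  out <- array(0, d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    zs <- max(1, z - half[1]):min(d[1], z + half[1])
    ys <- max(1, y - half[2]):min(d[2], y + half[2])
    xs <- max(1, x - half[3]):min(d[3], x + half[3])
    out[z, y, x] <- mean(vol[zs, ys, xs])
  }
  out
}

# 26-connected flood fill labelling (BFS), arbitrary label order
bruteFloodFill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextLab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      i0 <- cur - 1L
      z <- i0 %% d[1]
      y <- (i0 %/% d[1]) %% d[2]
      x <- i0 %/% (d[1] * d[2])
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        zz <- z + dz; yy <- y + dy; xx <- x + dx
        if (zz < 0 || zz >= d[1] || yy < 0 || yy >= d[2] ||
            xx < 0 || xx >= d[3]) next
        j <- zz + d[1] * (yy + d[2] * xx) + 1L
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nextLab
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# two labelings identical up to renaming?
sameUpToRelabel <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- which(a > 0L)
  if (!length(fg)) return(TRUE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# hypergeometric upper tail by direct enumeration of the support
bruteHyperUpper <- function(a, K, n, N) {
  ks <- max(0, K + n - N):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

# small, fast synthetic fixture (a few nuclei in a small field)
tinyParams <- function(nNuclei = 3L, seed = 1L, ...) {
  synthParams(nNuclei = as.integer(nNuclei),
              gridShape = c(24L, 140L, 140L), seed = as.integer(seed), ...)
}
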