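# Shared fixture builders. Everything is generated in code; no files.

# Constant tensor field: the same axially symmetric tensor at every voxel
# (axis `dir`), whole-grid validity mask.
const_tensor_field <- function(shape = c(9, 21, 9), dir = c(0, 1, 0),
                               lambda = c(1.7e-3, 3e-4, 3e-4), res = 1,
                               origin = c(0, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  D <- outer(dir, dir) * (lambda[1] - lambda[2]) + diag(lambda[2], 3)
  d6 <- c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  arr <- array(rep(d6, each = prod(shape)), c(shape, 6))
  tensor_field(arr, grid_affine(res, origin),
               mask = array(TRUE, shape))
}

# Random multichannel map on a small grid (plain array form).
random_map <- function(shape = c(4, 4, 3), K = 3) {
  array(runif(prod(shape) * K), c(shape, K))
}

# Scalar trilinear interpolation oracle: direct 8-corner loop, written
# independently of the vectorized implementation.
trilinear_oracle <- function(data3d, affine, point) {
  v <- solve(affine) %*% c(point, 1)
  v <- v[1:3]
  d <- dim(data3d)
  if (any(v < 0) || any(v > d - 1)) return(0)
  x0 <- pmin(floor(v), d - 2); x0 <- pmax(x0, 0)
  f <- v - x0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * data3d[min(x0[1] + dx, d[1] - 1) + 1,
                            min(x0[2] + dy, d[2] - 1) + 1,
                            min(x0[3] + dz, d[3] - 1) + 1]
  }
  acc
}

# Brute-force aggregation oracle: explicit loops over streamlines,
# points and channels using the scalar trilinear oracle.
aggregate_oracle <- function(bundle, cv) {
  K <- dim(cv$data)[4]
  out <- numeric(K)
  for (s in bundle$streamlines) {
    pts <- unclass(s)
    for (i in seq_len(nrow(pts))) for (k in seq_len(K))
      out[k] <- out[k] + trilinear_oracle(cv$data[, , , k], cv$affine,
                                          pts[i, ])
  }
  out
}

# Brute-force squared-distance oracle: scalar loops over voxels/channels.
distance_oracle <- function(a, b, mask) {
  d <- dim(a)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    for (c in seq_len(d[4])) acc <- acc + (a[i, j, k, c] - b[i, j, k, c])^2
  }
  acc
}

# Naive icd oracle built on the distance oracle.
icd_oracle <- function(maps1, maps2, mask) {
  N <- length(maps1)
  intra <- sum(vapply(seq_len(N), function(n)
    distance_oracle(maps1[[n]], maps2[[n]], mask), 0))
  inter <- 0
  for (j in seq_len(N)) for (n in seq_len(N))
    inter <- inter + distance_oracle(maps1[[j]], maps2[[n]], mask)
  100 * (1 - N * intra / inter)
}
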