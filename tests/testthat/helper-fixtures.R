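# Shared fixtures: everything is generated in code at test time.

# small deterministic volume with non-trivial geometry
tiny_volume <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume(array(rnorm(prod(dim)), dim), spacing = spacing, id = "tiny")
}

# brute-force 26-connected dilation, the independent oracle for
# binarize_and_dilate: per-voxel neighbourhood max, repeated
dilate_oracle <- function(mask, iters) {
  d <- dim(mask)
  cur <- mask != 0
  for (it in seq_len(iters)) {
    nxt <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      ii <- max(1, i - 1):min(d[1], i + 1)
      jj <- max(1, j - 1):min(d[2], j + 1)
      kk <- max(1, k - 1):min(d[3], k + 1)
      nxt[i, j, k] <- any(cur[ii, jj, kk])
    }
    cur <- nxt
  }
  cur
}

# exhaustive rank-permutation enumeration of the two-sided rank-sum
# p-value (no ties assumed): the oracle for compare_methods
ranksum_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(ix) sum(seq_len(n + m)[ix]))
  mu <- n * (n + m + 1) / 2
  p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  min(1, p)
}

# small phantom spec used across tests (fast to render)
test_spec <- function(shape = 64, noise_sd = 6, ...) {
  phantom_spec(shape = rep(shape, 3), noise_sd = noise_sd, ...)
}

# tiny net config for fast training tests
tiny_net <- function() net_config(2L, c(4L, 6L), dropout_rate = 0)
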