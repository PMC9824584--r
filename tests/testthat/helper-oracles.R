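# Shared oracles and tiny builders used across test files.

# brute-force O(N^2) force oracle, independent of the cell-list path
brute_forces <- function(pos, params) {
  N <- nrow(pos)
  f <- matrix(0, N, 3)
  rc <- 2^(1 / 6) * params$sigma
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      d <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(d^2))
      if (r < rc) {
        sr6 <- (params$sigma / r)^6
        fr <- 24 * params$epsilon * (2 * sr6^2 - sr6) / r^2
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
      }
    }
  }
  for (i in seq_len(N - 1)) {
    d <- pos[i + 1, ] - pos[i, ]
    b <- sqrt(sum(d^2))
    fb <- -params$k_spring * (b - params$b0) / b
    f[i + 1, ] <- f[i + 1, ] + fb * d
    f[i, ] <- f[i, ] - fb * d
  }
  f
}

# central-difference derivative oracle
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# random loose chain (no tight overlaps) for force comparisons: a grown
# self-avoiding chain, jittered so some pairs sit inside the WCA cutoff
random_chain <- function(N, seed = 1, spread = 1.2) {
  pos <- initialize_free(N, model_params(), seed = seed,
                         min_sep = 0.85)$positions
  set.seed(seed)
  pos + matrix(rnorm(3 * N, sd = 0.03), N, 3)
}
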