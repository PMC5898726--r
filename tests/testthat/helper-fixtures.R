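# Shared fixtures: random fingerprints and small planted-structure sets,
# all generated in code under fixed seeds.

rand_bits <- function(n, m, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(as.numeric(runif(n * m) < p), n, m)
}

# enumerate every quad (a, b, c, d) with a+b+c+d = m
all_quads <- function(m) {
  g <- expand.grid(a = 0:m, b = 0:m, c = 0:m)
  g <- g[g$a + g$b + g$c <= m, ]
  g$d <- m - g$a - g$b - g$c
  as.matrix(g)
}

# two well-separated fingerprint "blobs": bit-flip noise around two
# disjoint seed patterns occupying different halves of the bit space
planted_blobs <- function(n_per = 10, m = 64, flip = 0.03, seed = 1) {
  set.seed(seed)
  half <- m / 2
  s1 <- c(rep(1, half), rep(0, half))
  s2 <- c(rep(0, half), rep(1, half))
  flipmat <- function(s, n) {
    fl <- matrix(runif(n * m) < flip, n, m)
    abs(matrix(s, n, m, byrow = TRUE) - fl)
  }
  list(bits = rbind(flipmat(s1, n_per), flipmat(s2, n_per)),
       membership = rep(1:2, each = n_per))
}

# separable screening problem: coherent actives vs random decoys
separable_set <- function(n_active = 10, n_inactive = 150, m = 128,
                          seed = 1) {
  generate_synthetic(n_active = n_active, n_inactive = n_inactive, m = m,
                     n_scaffolds = 1, seed_density = 0.25, flip_prob = 0.01,
                     inactive_density = 0.25, seed = seed)
}
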