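# Internal RNG helpers.
#
# Per-woman deterministic substreams are derived from a master seed with a
# multiplicative-congruential mix so results do not depend on cohort order
# and stay within the 32-bit integer range R's set.seed() accepts.

.derive_seed <- function(master, i) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(i) * 10007 + 1) %% m
  as.integer(s)
}

# Evaluate expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (for positive cycle lengths: half up).
.round_half_up <- function(x) floor(x + 0.5)

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy envelope rejection.
# mu in radians, kappa >= 0; returns angles in [0, 2*pi).
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- runif(1); u2 <- runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        u3 <- runif(1)
        out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

# Uniform row-wise permutations: returns an n_perm x n integer matrix, each
# row an independent uniform permutation of 1..n. Single radix sort over
# random keys, much faster than n_perm calls to sample().
.perm_matrix <- function(n_perm, n) {
  u <- runif(n_perm * n)
  row_id <- rep.int(seq_len(n_perm), rep.int(n, n_perm))
  ord <- order(row_id, u, method = "radix")
  matrix(((ord - 1L) %% n) + 1L, nrow = n_perm, byrow = TRUE)
}
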