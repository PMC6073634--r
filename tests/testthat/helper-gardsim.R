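# shared fixture builders for the suite (all generated in code)

# small default parameter set for fast dynamic tests
tiny_params <- function(n_types = 10L, n_max = 20L, seed = 1L, ...) {
  gard_params(sample_beta(n_types, -4, 4, seed = seed), n_max = n_max, ...)
}

# a beta matrix of given values without sampling
beta_from <- function(m) gard_params(m, n_max = 2L)$beta

# matrix with a strong mutually catalytic clique on `clique` and negligible
# catalysis elsewhere: produces a single dominant composome
clique_beta <- function(n_types, clique, strong = 50, weak = 1e-6) {
  m <- matrix(weak, n_types, n_types)
  m[clique, clique] <- strong
  m
}

# count the compositions of size N over ng types by explicit recursion
# (independent oracle for the multiset coefficient)
enumerate_compositions <- function(N, ng) {
  if (ng == 1L) return(1L)
  total <- 0L
  for (k in 0:N) total <- total + enumerate_compositions(N - k, ng - 1L)
  total
}

# Monte-Carlo oracle for the distinct-type count of a random assembly
mc_repertoire <- function(N, ng, n_draws = 1e5, chunk = 1e4) {
  out <- numeric(0)
  remaining <- n_draws
  while (remaining > 0) {
    k <- min(chunk, remaining)
    m <- stats::rmultinom(k, N, rep(1 / ng, ng))
    out <- c(out, colSums(m > 0))
    remaining <- remaining - k
  }
  out
}
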