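test_that("propensities implement the catalysed rate law", {
  # all beta zeroed, k = rho = 1, N = 2: basal forward rate is 2 per type
  b <- apply_cutoff(sample_beta(3, seed = 1), 1e12)
  p <- gard_params(b, n_max = 4, k_f = 1, k_b = 1, rho = 1)
  pr <- propensities(assembly(c(1, 1, 0)), p)
  expect_equal(pr$forward, rep(2, 3))

  # hand substitution: n = (1,1), beta = [[0,1],[1,0]] gives
  # C_1 = 1 + (0*1 + 1*1)/2 and forward_1 = 1*1*2*1.5 = 3
  p2 <- gard_params(matrix(c(0, 1, 1, 0), 2, 2), n_max = 4,
                    k_f = 1, k_b = 1, rho = 1)
  pr2 <- propensities(assembly(c(1, 1)), p2)
  expect_equal(pr2$forward[1], 3)
  expect_equal(pr2$forward[2], 3)

  # nothing to leave: n_i = 0 means backward_i = 0
  expect_equal(pr$backward[3], 0)

  # catalysis scales both directions equally (K_i preserved)
  bu <- matrix(10, 2, 2)
  pu <- gard_params(bu, n_max = 4, k_f = 1, k_b = 1, rho = 1)
  pru <- propensities(assembly(c(1, 1)), pu)
  pr0 <- propensities(assembly(c(1, 1)),
                      gard_params(matrix(1e-300, 2, 2), n_max = 4,
                                  k_f = 1, k_b = 1, rho = 1))
  expect_equal(pru$forward / pru$backward, pr0$forward / pr0$backward)

  expect_error(propensities(structure(c(0L, 0L), class = "assembly"), p2),
               "empty")
})

test_that("step_ssa picks channels with the direct-method law", {
  # every step moves exactly one molecule
  p <- tiny_params(seed = 2)
  a <- seed_assembly(10, 10, seed = 3)
  set.seed(4)
  for (i in 1:50) {
    s <- step_ssa(a, p)
    expect_equal(abs(assembly_size(s$assembly) - assembly_size(a)), 1)
    expect_gt(s$dt, 0)
    a <- s$assembly
  }

  # two-channel system with propensity ratio 3:1: selection frequency is
  # binomial around 0.75 (backward rates negligible)
  b0 <- apply_cutoff(sample_beta(2, seed = 1), 1e12)
  p2 <- gard_params(b0, n_max = 4, k_f = c(3, 1), k_b = 1e-12, rho = 1)
  a2 <- assembly(c(1, 1))
  set.seed(11)
  hits <- replicate(1e4, step_ssa(a2, p2)$event == 1L)
  expect_lt(abs(mean(hits) - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))

  # same seed and state: identical event sequence
  run_events <- function(seed) {
    set.seed(seed)
    x <- a
    vapply(1:20, function(i) {
      s <- step_ssa(x, p); x <<- s$assembly; s$event
    }, integer(1))
  }
  expect_identical(run_events(42), run_events(42))
})

test_that("grow_to_size reaches N_MAX and catalysis accelerates growth", {
  p <- tiny_params(seed = 5)
  a <- seed_assembly(10, 10, seed = 6)

  # already at target: nothing happens
  afull <- seed_assembly(10, 20, seed = 7)
  g0 <- grow_to_size(afull, p)
  expect_identical(g0$steps, 0L)
  expect_identical(g0$time, 0)

  set.seed(8)
  g <- grow_to_size(a, p)
  expect_identical(assembly_size(g$assembly), 20L)

  # repeated step_ssa under the same seed reproduces grow_to_size exactly
  set.seed(9); gref <- grow_to_size(a, p)
  set.seed(9)
  x <- a; tt <- 0
  while (assembly_size(x) < 20) {
    s <- step_ssa(x, p); x <- s$assembly; tt <- tt + s$dt
  }
  expect_identical(unclass(gref$assembly), unclass(x))
  expect_equal(gref$time, tt)

  # strong uniform catalysis shortens the mean inter-split time vs no
  # catalysis with the same seed stream (paired over 100 cycles)
  p_cat <- gard_params(matrix(100, 10, 10), n_max = 20, k_f = 1e-2,
                       k_b = 1e-5, rho = 1e-2)
  p_non <- gard_params(apply_cutoff(sample_beta(10, seed = 1), 1e12),
                       n_max = 20, k_f = 1e-2, k_b = 1e-5, rho = 1e-2)
  times <- vapply(1:100, function(k) {
    a0 <- seed_assembly(10, 10, seed = 100 + k)
    set.seed(200 + k); t_cat <- grow_to_size(a0, p_cat)$time
    set.seed(200 + k); t_non <- grow_to_size(a0, p_non)$time
    c(t_cat, t_non)
  }, numeric(2))
  expect_lt(mean(times[1, ]), mean(times[2, ]))

  # stall guard raises an explicit error
  p_stall <- tiny_params(seed = 5, max_steps = 2)
  set.seed(1)
  expect_error(grow_to_size(a, p_stall), "stalled")
})

test_that("split is an exact multivariate hypergeometric halving", {
  # conservation holds for arbitrary parents
  set.seed(12)
  parent <- assembly(c(5, 0, 9, 2, 4))
  s <- split_assembly(parent)
  expect_identical(unclass(s$first) + unclass(s$second), unclass(parent))
  expect_identical(assembly_size(s$first), 10L)

  # parent (2,2): type-1 count in progeny 1 follows hypergeometric(4,2,2)
  set.seed(13)
  counts <- replicate(1e4, unclass(split_assembly(assembly(c(2, 2))))[[1]][1])
  emp <- tabulate(counts + 1L, 3L) / 1e4
  ref <- stats::dhyper(0:2, 2, 2, 2)
  for (k in 1:3) {
    expect_lt(abs(emp[k] - ref[k]), 3 * sqrt(ref[k] * (1 - ref[k]) / 1e4))
  }

  # expected progeny composition is half the parent
  set.seed(14)
  reps <- replicate(2000, unclass(split_assembly(parent)$first))
  expect_equal(rowMeans(reps), unclass(parent) / 2, tolerance = 0.05)

  expect_error(split_assembly(assembly(c(1, 2))), "even")
})

test_that("run_trace records N_MAX compositions deterministically", {
  p <- tiny_params(n_types = 20, n_max = 20, seed = 15)
  tr <- run_trace(p, 40, seed = 16)
  expect_identical(nrow(tr$composition), 40L)
  expect_true(all(rowSums(tr$composition) == 20))
  expect_false(is.unsorted(tr$time, strictly = TRUE))

  tr2 <- run_trace(p, 40, seed = 16)
  expect_identical(tr$composition, tr2$composition)
  expect_identical(tr$time, tr2$time)

  # tidy layout
  td <- tidy(tr)
  expect_identical(nrow(td), 40L * 20L)
  expect_identical(sum(td$count), 40L * 20L)
})

test_that("mutate_composition edits one coordinate with bounds", {
  a <- assembly(c(3, 0, 1))
  expect_identical(unclass(mutate_composition(a, 2, 0)), unclass(a))
  expect_identical(
    unclass(mutate_composition(mutate_composition(a, 1, 1), 1, -1)),
    unclass(a))
  expect_identical(unclass(mutate_composition(a, 2, 3))[2], 3L)
  expect_error(mutate_composition(a, 2, -1), "negative")
})

test_that("finite-supply relaxation equalizes equal-K molar fractions", {
  b <- sample_beta(20, -4, 4, seed = 3)
  p <- gard_params(b, n_max = 1000, n_min = 20, supply = "finite",
                   budget = 100, fission = FALSE)
  ts <- run_to_equilibrium(p, n_steps = 3e5, record_every = 500, seed = 9)

  nfin <- nrow(ts$composition)
  N <- sum(ts$composition[nfin, ])
  fr <- ts$composition[nfin, ] / N
  tol <- 3 * sqrt((1 / 20) * (1 - 1 / 20) / N)
  expect_lt(max(abs(fr - 1 / 20)), tol)

  # the transient is composome-like: unequal beyond sampling noise midway
  mid <- which(ts$size >= 0.5 * max(ts$size))[1]
  frm <- ts$composition[mid, ] / sum(ts$composition[mid, ])
  tolm <- 3 * sqrt((1 / 20) * (1 - 1 / 20) / ts$size[mid])
  expect_gt(max(abs(frm - 1 / 20)), tolm)

  # size rises to a plateau (monotone up to stochastic jitter)
  expect_gte(ts$size[nfin], 0.99 * max(ts$size))
  expect_gt(ts$size[nfin], ts$size[1])

  expect_error(gard_params(b, supply = "finite", fission = FALSE),
               "budget")
  expect_error(run_to_equilibrium(tiny_params(), n_steps = 10), "finite")
})

test_that("uniform catalysis equilibrium matches the detailed-balance oracle", {
  # all-equal beta, unequal K_i: stationary fractions follow K_i rho_i
  # because the catalytic factor multiplies both directions and cancels
  kf <- c(4, 2, 1, 1) * 1e-2
  p <- gard_params(matrix(5, 4, 4), n_max = 1e6, n_min = 8,
                   supply = "finite", budget = 500, fission = FALSE,
                   k_f = kf, k_b = 2e-2, rho = 1e-2)
  ts <- run_to_equilibrium(p, n_steps = 2e5, record_every = 1000, seed = 31)
  nfin <- nrow(ts$composition)
  n_i <- ts$composition[nfin, ]
  # brute-force balance per species: kf_i rho_i(final) N = kb n_i
  rho_fin <- ts$budget * 1e-2
  pred <- kf * rho_fin * sum(n_i) / 2e-2
  expect_equal(n_i, pred, tolerance = 0.15)
})

test_that("keq_sweep is reproducible and bounded", {
  p <- tiny_params(n_types = 20, n_max = 20, seed = 18)
  sw <- keq_sweep(p, c(1, 1, 0.5), n_generations = 60, seed = 19,
                  n_reps = 2)
  expect_true(all(sw$persistence >= 0 & sw$persistence <= 1))
  # identical scale entries share replicate streams: scale 1 reproduces
  # the unscaled statistics exactly
  expect_identical(sw$persistence[1], sw$persistence[2])
  expect_error(keq_sweep(p, numeric(0), 10), "empty")
  expect_error(keq_sweep(p, -1, 10), "scales")
})
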