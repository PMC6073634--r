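test_that("similarity_H is the normalized dot product", {
  expect_equal(similarity_H(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(similarity_H(c(1, 0, 2), c(0, 5, 0)), 0)
  expect_equal(similarity_H(c(1, 1, 0), c(1, 0, 1)), 0.5)
  # scale invariance and symmetry
  expect_equal(similarity_H(c(1, 2, 3), 10 * c(3, 1, 2)),
               similarity_H(c(3, 1, 2), c(1, 2, 3)))
  expect_error(similarity_H(c(0, 0), c(1, 1)), "zero")
  expect_error(similarity_H(c(1, 1), c(1, 1, 1)), "mismatch")
})

test_that("carpet is a symmetric unit-diagonal correlation matrix", {
  tr <- make_fixture("trace", seed = 2, n_types = 15, n_max = 16,
                     n_generations = 30)
  h <- carpet(tr)
  expect_equal(diag(h), rep(1, 30))
  expect_equal(h, t(h))
  expect_true(all(h >= 0 & h <= 1))

  # alternating orthogonal compositions give a checkerboard
  comp <- matrix(0, 6, 4)
  comp[c(1, 3, 5), 1] <- 10
  comp[c(2, 4, 6), 3] <- 10
  hc <- carpet(comp)
  expect_equal(hc, outer(1:6, 1:6,
                         function(i, j) as.numeric((i - j) %% 2 == 0)))
  expect_error(carpet(comp[1, , drop = FALSE]), "two generations")
})

test_that("detect_composomes finds exactly the mutually similar runs", {
  # constant trace: one episode spanning everything
  const <- matrix(rep(c(5, 3, 2, 0), each = 12), 12, 4)
  ep <- detect_composomes(const, threshold = 0.9, min_len = 5)
  expect_identical(nrow(ep), 1L)
  expect_identical(c(ep$start, ep$end), c(1L, 12L))
  expect_equal(ep$min_H, 1)

  # sparse random compositions (N_G >> N) are near orthogonal: no episodes,
  # confirmed against the pairwise similarities themselves
  set.seed(5)
  rnd <- t(stats::rmultinom(40, 15, rep(1 / 200, 200)))
  h <- carpet(rnd)
  expect_lt(max(h[upper.tri(h)]), 0.9) # simulation oracle for the fixture
  expect_identical(nrow(detect_composomes(rnd, 0.9, 5)), 0L)

  # planted block inside noise is recovered exactly
  fx <- make_fixture("planted-composome", seed = 8, n_generations = 40,
                     block_start = 16, block_len = 10)
  ep2 <- detect_composomes(fx$composition, threshold = 0.9, min_len = 5)
  expect_identical(nrow(ep2), 1L)
  expect_identical(c(ep2$start, ep2$end),
                   c(fx$planted$start, fx$planted$end))

  expect_error(detect_composomes(const, threshold = 0), "threshold")
})

test_that("cluster_compotypes groups episodes first-fit by centroid", {
  mk_ep <- function(centroids) {
    tibble::tibble(
      start = seq_along(centroids) * 10L,
      end = seq_along(centroids) * 10L + 4L,
      length = 5L,
      min_H = 1,
      n_mol = vapply(centroids, function(x) sum(x > 0), numeric(1)),
      entropy = 0,
      centroid = centroids)
  }
  a <- c(1, 0, 0, 0) / 1; b <- c(0, 0, 1, 0)
  ep1 <- mk_ep(list(a, a, a))
  ct1 <- cluster_compotypes(ep1, 0.9, n_generations = 50)
  expect_identical(nrow(ct1), 1L)
  expect_equal(ct1$frequency, 15 / 50)

  ep2 <- mk_ep(list(a, b, a, b))
  ct2 <- cluster_compotypes(ep2, 0.9, n_generations = 50)
  expect_identical(nrow(ct2), 2L)

  # appending an episode identical to an existing centroid leaves the
  # clustering (number and centroids) unchanged
  ep3 <- mk_ep(list(a, b, a, b, a))
  ct3 <- cluster_compotypes(ep3, 0.9, n_generations = 50)
  expect_identical(nrow(ct3), 2L)
  expect_equal(ct3$centroid, ct2$centroid)

  expect_error(cluster_compotypes(ep1[0, ]), "no episodes")
})

test_that("repertoire size counts present types", {
  expect_identical(repertoire_size(rep(1, 7)), 7L)
  expect_identical(repertoire_size(c(0, 0, 5)), 1L)
  expect_identical(repertoire_size(c(3, 0, 1, 0)), 2L)
  expect_error(repertoire_size(c(-1, 1)), "negative")
})

test_that("expected_repertoire gives the analytic occupancy moments", {
  # the published yardstick: 100 molecules over 100 types
  er <- expected_repertoire(100, 100)
  expect_equal(round(er$mean, 1), 63.4)
  expect_equal(round(er$sd, 1), 3.1)

  er1 <- expected_repertoire(1, 50)
  expect_equal(er1$mean, 1)
  expect_lt(er1$sd, 1e-6)

  # exhaustive enumeration for N = 2, N_G = 2: four equally likely draws
  # give 1, 2, 2, 1 distinct types
  er2 <- expected_repertoire(2, 2)
  expect_equal(er2$mean, 1.5)
  expect_equal(er2$sd, 0.5)

  # Monte-Carlo oracle within 3 standard errors
  set.seed(33)
  for (case in list(c(10, 10), c(100, 100), c(50, 200))) {
    draws <- mc_repertoire(case[1], case[2], n_draws = 1e5)
    era <- expected_repertoire(case[1], case[2])
    se_mean <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - era$mean), 3 * se_mean)
    se_sd <- sd(draws) / sqrt(2 * (length(draws) - 1))
    expect_lt(abs(sd(draws) - era$sd), 3 * se_sd)
  }
})

test_that("assembly_entropy is the Shannon entropy of molar fractions", {
  expect_equal(assembly_entropy(c(2, 2, 2, 0)), log(3))
  expect_equal(assembly_entropy(c(0, 9, 0)), 0)
  expect_equal(assembly_entropy(c(3, 1)), 0.5623, tolerance = 1e-4)
  expect_equal(assembly_entropy(c(1, 1), base = 2), 1)
  expect_error(assembly_entropy(c(0, 0)), "empty")
})

test_that("n_compositions is the exact multiset coefficient", {
  # brute-force enumeration agrees everywhere in the small grid
  for (N in 0:6) for (ng in 1:6) {
    expect_identical(n_compositions(N, ng)$value,
                     as.numeric(enumerate_compositions(N, ng)),
                     label = sprintf("N=%d ng=%d", N, ng))
  }
  expect_identical(n_compositions(1, 42)$value, 42)

  # printed magnitudes at 2 significant figures
  expect_identical(format(n_compositions(100, 100), digits = 2), "4.5e58")
  expect_identical(format(n_compositions(36, 100), digits = 2), "7.7e32")

  # exact decimal expansion matches R's double where it is representable
  expect_identical(n_compositions(10, 10)$string,
                   format(choose(19, 10), scientific = FALSE))
  expect_error(n_compositions(-1, 5), "N")
})

test_that("compositional information is bounded by sequential information", {
  expect_equal(information_bits(100, 2, "sequential"), 100)
  grid <- expand.grid(N = c(1, 5, 20, 100), ng = c(2, 4, 64, 1024))
  for (r in seq_len(nrow(grid))) {
    expect_lte(information_bits(grid$N[r], grid$ng[r], "compositional"),
               information_bits(grid$N[r], grid$ng[r], "sequential") + 1e-9)
  }
  # the ratio approaches 1 as the repertoire grows at fixed N = 50
  ratio <- vapply(4^(1:6), function(ng) {
    information_bits(50, ng) / information_bits(50, ng, "sequential")
  }, numeric(1))
  expect_false(is.unsorted(ratio))
  expect_gt(tail(ratio, 1), 0.6)
  expect_gt(tail(ratio, 1) - ratio[1], 0.2)
})

test_that("canonical_composome is the Perron eigenvector", {
  # rank-one u v^T has leading eigenvector u
  m <- outer(c(1, 2), c(1, 1))
  expect_equal(canonical_composome(m), c(1, 2) / 3)

  b <- sample_beta(30, -4, 4, seed = 44)
  v <- canonical_composome(b)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1)

  # permutation equivariance
  perm <- c(3, 1, 2, 5, 4, 6, 7:30)
  pm <- diag(30)[perm, ]
  v2 <- canonical_composome(pm %*% unclass(b) %*% t(pm))
  expect_equal(v2, v[perm], tolerance = 1e-10)

  expect_warning(canonical_composome(rbind(c(0, 0), c(1, 1))), "zero rows")
})

test_that("antipode similarity and enantiomeric excess read chirality", {
  cp <- chiral_params(2) # D1 D2 L1 L2
  expect_equal(antipode_similarity(c(3, 1, 3, 1), cp), 1) # racemic
  expect_equal(antipode_similarity(c(3, 1, 0, 0), cp), 0) # homochiral
  cp1 <- chiral_params(1)
  expect_equal(antipode_similarity(c(3, 1), cp1), 0.6)

  expect_equal(enantiomeric_excess(c(3, 1, 3, 1), cp), 0)
  expect_equal(enantiomeric_excess(c(3, 1, 0, 0), cp), 1)
  expect_equal(enantiomeric_excess(c(2, 1, 1, 0), cp), 0.5)
  expect_error(enantiomeric_excess(c(1, 2, 3), cp), "mismatch")
  # the chiral map attached by build_chiral_beta works directly
  bc <- build_chiral_beta(2, seed = 1)
  expect_equal(enantiomeric_excess(c(1, 0, 0, 1), bc), 0)
})

test_that("composomes are lower-entropy, restricted-repertoire states", {
  b <- sample_beta(100, -4, 4, seed = 11)
  p <- gard_params(b, n_max = 100)
  tr <- run_trace(p, 500, seed = 42)
  ep <- detect_composomes(tr, 0.9, 5)
  expect_gt(nrow(ep), 0)

  # entropy of composome compositions below random same-size assemblies
  set.seed(43)
  rand <- t(stats::rmultinom(1e4, 100, rep(0.01, 100)))
  rand_entropy <- mean(apply(rand, 1, assembly_entropy))
  ep_rows <- unlist(purrr::map2(ep$start, ep$end, seq))
  ep_entropy <- mean(apply(tr$composition[ep_rows, ], 1, assembly_entropy))
  expect_lt(ep_entropy, rand_entropy)

  # repertoire restriction well below the random-assembly 63.4
  expect_lt(weighted.mean(ep$n_mol, ep$length), 40)
})
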