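test_that("the reactor conserves population size and is reproducible", {
  b <- sample_beta(30, -4, 4, seed = 21)
  p <- gard_params(b, n_max = 30)
  ref <- reference_compotypes(p, 300, seed = 22)
  rh <- run_reactor(p, pop_size = 20, n_splits = 100, seed = 23, ref = ref,
                    record_every = 10)
  expect_identical(length(rh$population), 20L)
  # frequencies at every record sum to 1 over drift + compotypes
  sums <- rh$frequencies |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(s = sum(.data$frequency))
  expect_equal(sums$s, rep(1, nrow(sums)))

  rh2 <- run_reactor(p, pop_size = 20, n_splits = 100, seed = 23, ref = ref,
                     record_every = 10)
  expect_identical(rh$frequencies, rh2$frequencies)
})

test_that("a strong composome outgrows drift in the reactor", {
  # matrix with a strong mutually catalytic clique: the pre-run composome
  # covers most generations, and under selection the matching compotype
  # dominates the population over drift
  m <- clique_beta(20, clique = 1:4, strong = 50)
  p <- gard_params(m, n_max = 20)
  ref <- reference_compotypes(p, 300, seed = 52)
  expect_gte(nrow(ref), 1L)
  rh <- run_reactor(p, pop_size = 20, n_splits = 200, seed = 53, ref = ref,
                    record_every = 10)
  late <- dplyr::filter(rh$frequencies, .data$split > 100)
  # the composome class as a whole, and its dominant member, beat drift
  f_drift <- mean(late$frequency[late$compotype == 0])
  per_ct <- tapply(late$frequency[late$compotype > 0],
                   late$compotype[late$compotype > 0], mean)
  expect_gt(sum(per_ct), f_drift)
  expect_gt(max(per_ct), f_drift)
})

test_that("detect_takeover flags sustained dominance changes only", {
  t <- 1:100
  rise <- 0.6 / (1 + 60 * exp(-0.15 * t))    # B rises through constant A
  const <- rep(0.3, 100)
  ev <- detect_takeover(cbind(A = const, B = rise), window = 10)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$winner, 2L)
  expect_identical(ev$loser, 1L)
  expect_identical(ev$crossing, which(rise > 0.3)[1])

  # monotone non-crossing series: no events
  expect_identical(nrow(detect_takeover(cbind(const, const + 0.2), 10)), 0L)
  # a series and its copy: ties are not takeovers
  expect_identical(nrow(detect_takeover(cbind(rise, rise), 10)), 0L)
  expect_error(detect_takeover(cbind(const), 10), "two")
})

test_that("fit_logistic recovers known parameters", {
  t <- seq(0, 300, by = 2)
  f <- 0.6 / (1 + 59 * exp(-0.05 * t))
  fit <- fit_logistic(t, f)
  expect_equal(fit$K, 0.6, tolerance = 1e-6)
  expect_equal(fit$r, 0.05, tolerance = 1e-6)
  expect_equal(fit$K / (1 + fit$A), 0.01, tolerance = 1e-5)
  expect_lt(glance(fit)$residual_norm, 1e-8)

  # constant series degenerates to r = 0
  fit0 <- fit_logistic(1:20, rep(0.25, 20))
  expect_identical(fit0$r, 0)
  expect_equal(fit0$K, 0.25)

  # noisy recovery: K within 10%
  fx <- make_fixture("logistic-series", seed = 5)
  fitn <- fit_logistic(fx$t, fx$f)
  expect_lt(abs(fitn$K - 0.6) / 0.6, 0.10)

  td <- tidy(fitn)
  expect_identical(td$term, c("K", "A", "r", "f0"))
  expect_error(fit_logistic(1:3, c(0.1, 0.2, 0.3)), "5")
  expect_error(fit_logistic(1:6, c(0.1, 0.2, 0.3, 0.4, 0.5, 1.2)), "0, 1")
})

test_that("shift_environment blends and conserves total concentration", {
  rho0 <- rep(2, 5)
  target <- c(6, 0, 2, 0, 0)
  expect_identical(shift_environment(rho0, target, 0), rho0)

  s1 <- shift_environment(rho0, target, 1)
  expect_equal(s1, target / sum(target) * sum(rho0))

  # the printed blend: each coordinate moves by w * (target_i - rho_i)
  s01 <- shift_environment(rho0, target, 0.1)
  scaled <- target / sum(target) * sum(rho0)
  expect_equal(s01, rho0 + 0.1 * (scaled - rho0))
  expect_equal(sum(s01), sum(rho0))

  expect_error(shift_environment(rho0, target, 1.2), "weight")
  expect_error(shift_environment(rho0, target[1:3], 0.1), "mismatch")
})

test_that("a weight-zero environment shift reproduces the control exactly", {
  b <- sample_beta(20, -4, 4, seed = 61)
  p <- gard_params(b, n_max = 20)
  ref <- reference_compotypes(p, 300, seed = 62)
  skip_if(nrow(ref) < 1, "matrix yields no composomes in the pre-run")
  sh <- run_shift_experiment(p, weight = 0, switch_at = 50, n_splits = 100,
                             pop_size = 15, seed = 63, ref = ref,
                             record_every = 10)
  expect_identical(sh$post_shifted, sh$post_control)
  expect_equal(sh$rho_shifted, p$rho)
})

test_that("depletion of a catalytically irrelevant compound is neutral", {
  # compound 10 is outside the dominant clique and essentially uncatalysed:
  # removing it leaves the growth rate almost unchanged
  m <- clique_beta(10, clique = 1:3, strong = 50, weak = 1e-8)
  p <- gard_params(m, n_max = 10)
  tr_before <- run_trace(p, 150, seed = 71)
  p_dep <- update_params(p, beta = deplete_compound(beta_from(m), 10))
  tr_after <- run_trace(p_dep, 150, seed = 71)
  ratio <- growth_rate(tr_after) / growth_rate(tr_before)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("the depletion screen reports non-negative ratios per compound", {
  p <- gard_params(sample_beta(10, -4, 4, seed = 81), n_max = 10)
  sc <- depletion_screen(p, n_matrices = 2, n_generations = 80, seed = 82)
  expect_identical(nrow(sc), 2L * 10L)
  expect_true(all(sc$ratio >= 0))
  expect_true(all(sc$compound %in% 1:10))
  expect_true(all(!sc$stalled))
  expect_true(all(is.na(sc$best_H) | (sc$best_H >= 0 & sc$best_H <= 1)))
})
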