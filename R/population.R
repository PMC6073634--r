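#' Reference compotypes for frequency tracking
#'
#' Builds a self-consistent compotype labelling for a given \eqn{\beta}
#' matrix from a long trace-mode pre-run: composome episodes are detected
#' and clustered, and the resulting centroids serve as the fixed reference
#' classes against which reactor populations are scored.
#'
#' @param params A [gard_params()] set.
#' @param n_generations Length of the pre-run trace.
#' @param seed Optional seed for the pre-run.
#' @param threshold,min_len Composome detection settings.
#' @return A [cluster_compotypes()] tibble (possibly zero rows if the matrix
#'   yields no composomes in the pre-run).
#' @export
reference_compotypes <- function(params, n_generations = 500, seed = NULL,
                                 threshold = 0.9, min_len = 5L) {
  tr <- run_trace(params, n_generations, seed = seed)
  ep <- detect_composomes(tr, threshold = threshold, min_len = min_len)
  if (nrow(ep) == 0) {
    return(tibble::tibble(compotype = integer(), n_episodes = integer(),
                          generations = double(), frequency = double(),
                          n_mol = integer(), episodes = list(),
                          centroid = list()))
  }
  cluster_compotypes(ep, threshold = threshold,
                     n_generations = n_generations)
}

# classify a matrix of compositions (rows) against reference centroids:
# best-matching compotype if best H >= threshold, else 0 (drift)
classify_compositions <- function(comp, centroids, threshold) {
  if (length(centroids) == 0) return(rep(0L, nrow(comp)))
  cen <- do.call(cbind, lapply(centroids, function(v) v / sqrt(sum(v^2))))
  norm <- comp / sqrt(rowSums(comp^2))
  sims <- norm %*% cen
  best <- max.col(sims, ties.method = "first")
  best_h <- sims[cbind(seq_len(nrow(sims)), best)]
  ifelse(best_h >= threshold, best, 0L)
}

# mutable reactor state in an environment; all randomness from the current
# R RNG stream so continuations are exact
reactor_init <- function(params, pop_size) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$P <- pop_size
  st$grown <- vector("list", pop_size)
  st$completion <- numeric(pop_size)
  st$t <- 0
  st$splits <- 0L
  for (a in seq_len(pop_size)) {
    counts <- cpp_seed_assembly(params$n_types, params$n_min)
    g <- cpp_grow(counts, unclass(params$beta), params$k_f, params$k_b,
                  params$rho, params$n_max, params$max_steps)
    st$grown[[a]] <- g$counts
    st$completion[a] <- g$time
  }
  st
}

reactor_step <- function(st, params) {
  i <- which.min(st$completion)
  t <- st$completion[i]
  prog <- cpp_split(st$grown[[i]])
  others <- seq_len(st$P)[-i]
  victim <- others[floor(runif(1) * (st$P - 1)) + 1L]
  for (slot_counts in list(list(i, prog$first), list(victim, prog$second))) {
    g <- cpp_grow(slot_counts[[2]], unclass(params$beta), params$k_f,
                  params$k_b, params$rho, params$n_max, params$max_steps)
    st$grown[[slot_counts[[1]]]] <- g$counts
    st$completion[slot_counts[[1]]] <- t + g$time
  }
  st$t <- t
  st$splits <- st$splits + 1L
  invisible(st)
}

reactor_record <- function(st, centroids, threshold) {
  comp <- do.call(rbind, st$grown)
  storage.mode(comp) <- "double"
  cls <- classify_compositions(comp, centroids, threshold)
  k <- length(centroids)
  counts <- tabulate(cls + 1L, nbins = k + 1L) # slot 1 = drift
  tibble::tibble(split = st$splits, time = st$t,
                 compotype = c(0L, seq_len(k)),
                 frequency = counts / st$P)
}

#' Constant-population reactor simulation
#'
#' Simulates a population of `pop_size` assemblies competing in a chemostat:
#' each assembly grows independently to \eqn{N_{MAX}}; the first to arrive
#' (by simulated time) splits, both progeny are kept, and one uniformly
#' random other assembly is removed, holding the population exactly
#' constant. Faster-growing composomes therefore accumulate at the expense
#' of drift and slower compotypes — selection acting directly on the
#' compositional phenotype. Time is counted in split events.
#'
#' @param params A [gard_params()] set.
#' @param pop_size Population size (>= 2).
#' @param n_splits Number of split events to simulate.
#' @param seed Optional seed.
#' @param ref Reference compotypes ([reference_compotypes()] tibble); built
#'   automatically from a pre-run of the same matrix if `NULL`.
#' @param record_every Record compotype frequencies every this many splits.
#' @param threshold Similarity threshold for assigning an assembly to a
#'   compotype (below it the assembly counts as drift, compotype 0).
#' @return A `reactor_history`: tibble of frequencies in `$frequencies`
#'   (split, time, compotype — 0 is drift — and frequency), reference
#'   compotypes in `$ref`, final population in `$population`.
#' @export
run_reactor <- function(params, pop_size, n_splits, seed = NULL, ref = NULL,
                        record_every = 10L, threshold = 0.9) {
  stop_if_not_scalar_count(pop_size, "pop_size", min = 2L)
  stop_if_not_scalar_count(n_splits, "n_splits")
  with_seed(seed, {
    if (is.null(ref)) {
      ref <- reference_compotypes(params, n_generations = 500,
                                  threshold = threshold)
    }
    centroids <- ref$centroid
    st <- reactor_init(params, pop_size)
    recs <- list(reactor_record(st, centroids, threshold))
    for (e in seq_len(n_splits)) {
      reactor_step(st, params)
      if (e %% record_every == 0L || e == n_splits) {
        recs[[length(recs) + 1L]] <- reactor_record(st, centroids, threshold)
      }
    }
    new_reactor_history(dplyr::bind_rows(recs), ref, st, params)
  })
}

new_reactor_history <- function(frequencies, ref, st, params) {
  structure(list(frequencies = frequencies, ref = ref,
                 population = st$grown, params = params,
                 n_splits = st$splits),
            class = "reactor_history")
}

#' @export
print.reactor_history <- function(x, ...) {
  k <- nrow(x$ref)
  last <- dplyr::filter(x$frequencies, .data$split == max(.data$split))
  cat(sprintf("<reactor_history> %d splits, %d assemblies, %d compotype(s)\n",
              x$n_splits, length(x$population), k))
  for (r in seq_len(nrow(last))) {
    lab <- if (last$compotype[r] == 0) "drift" else
      sprintf("C%d", last$compotype[r])
    cat(sprintf("  final %s: %.2f\n", lab, last$frequency[r]))
  }
  invisible(x)
}

#' @export
tidy.reactor_history <- function(x, ...) x$frequencies

#' Detect compotype takeover events
#'
#' A takeover is a sustained change of dominance: series `i` strictly above
#' series `j` throughout a window before the crossing, and strictly below
#' throughout a window after it. Ties are not dominance, so a series never
#' takes over from its own copy.
#'
#' @param freq A numeric matrix (rows = time points, columns = series) or a
#'   `reactor_history` (compotype frequency series, drift excluded).
#' @param window Number of consecutive points of strict dominance required
#'   on each side of the crossing.
#' @return A tibble of events: `winner`, `loser` (column indices), and
#'   `crossing` (row index of the first point where the winner leads).
#' @export
detect_takeover <- function(freq, window = 10L) {
  if (inherits(freq, "reactor_history")) {
    wide <- tidyr::pivot_wider(
      dplyr::filter(freq$frequencies, .data$compotype > 0),
      id_cols = "split", names_from = "compotype",
      values_from = "frequency")
    freq <- as.matrix(wide[, -1, drop = FALSE])
  }
  if (!is.matrix(freq) || ncol(freq) < 2L) {
    stop("need at least two frequency series", call. = FALSE)
  }
  n <- nrow(freq)
  events <- list()
  for (i in seq_len(ncol(freq))) {
    for (j in seq_len(ncol(freq))) {
      if (i == j) next
      d <- freq[, i] - freq[, j] # positive where i dominates
      for (t in seq_len(n - 1L)) {
        if (d[t] > 0 && d[t + 1L] < 0) {
          lo <- t - window + 1L
          hi <- t + window
          if (lo < 1L || hi > n) next
          if (all(d[lo:t] > 0) && all(d[(t + 1L):hi] < 0)) {
            events[[length(events) + 1L]] <-
              tibble::tibble(winner = j, loser = i, crossing = t + 1L)
          }
        }
      }
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(winner = integer(), loser = integer(),
                          crossing = integer()))
  }
  dplyr::bind_rows(events)
}

#' Fit an ecological logistic curve to a frequency series
#'
#' Least-squares fit of \eqn{f(t) = K / (1 + A e^{-r t})} via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]), the standard description of
#' a compotype rising to carrying capacity after a takeover. Start values
#' come from a logit-linear regression; an exactly constant series is the
#' degenerate solution \eqn{r = 0}, \eqn{K = \bar f}, returned directly.
#' Non-convergence is an error, never a silent result.
#'
#' @param t Time points (split counts).
#' @param f Frequencies in `[0, 1]`, at least 5 points.
#' @return A `logistic_fit` with [tidy()] (parameters `K`, `A`, `r`,
#'   `f0 = K/(1+A)`) and [glance()] (residual norm, convergence) methods.
#' @export
fit_logistic <- function(t, f) {
  if (length(t) != length(f) || length(f) < 5L) {
    stop("need >= 5 matched points", call. = FALSE)
  }
  if (any(f < 0) || any(f > 1)) stop("frequencies must be in [0, 1]",
                                     call. = FALSE)
  if (diff(range(f)) < 1e-12) {
    return(new_logistic_fit(K = mean(f), A = 0, r = 0, t = t, f = f,
                            fitted = rep(mean(f), length(f)),
                            converged = TRUE, degenerate = TRUE))
  }
  K0 <- max(f) * 1.05 + 1e-9
  y <- log(pmax(K0 / pmax(f, 1e-9) - 1, 1e-9))
  lin <- stats::lm(y ~ t)
  r0 <- max(-coef(lin)[2], 1e-6)
  A0 <- max(exp(coef(lin)[1]), 1e-6)
  dat <- data.frame(t = t, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ K / (1 + A * exp(-r * t)), data = dat,
                      start = list(K = K0, A = A0, r = r0),
                      lower = c(K = 0, A = 0, r = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("logistic fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- coef(fit)
  new_logistic_fit(K = unname(co["K"]), A = unname(co["A"]),
                   r = unname(co["r"]), t = t, f = f,
                   fitted = stats::fitted(fit), converged = TRUE,
                   degenerate = FALSE)
}

new_logistic_fit <- function(K, A, r, t, f, fitted, converged, degenerate) {
  structure(list(K = K, A = A, r = r, t = t, f = f, fitted = fitted,
                 converged = converged, degenerate = degenerate),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> K = %.4g, r = %.4g, f0 = %.4g%s\n",
              x$K, x$r, x$K / (1 + x$A),
              if (x$degenerate) " (constant series)" else ""))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("K", "A", "r", "f0"),
                 estimate = c(x$K, x$A, x$r, x$K / (1 + x$A)))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(residual_norm = sqrt(sum((x$f - x$fitted)^2)),
                 n = length(x$f), converged = x$converged,
                 degenerate = x$degenerate)
}

#' Blend the external environment towards a target composition
#'
#' Implements the environment-shift recipe
#' \eqn{\rho_i' = (1 - w)\,\rho_i(0) + w\,\tilde n_i}, where the target
#' composition is first rescaled so its total equals the total of
#' \eqn{\rho(0)} — concentrations and counts then share one unit and the
#' total external concentration is conserved.
#'
#' @param rho0 Baseline concentration vector.
#' @param target Target composition (e.g. a compotype centroid).
#' @param weight Blend weight `w` in `[0, 1]`.
#' @return The shifted concentration vector.
#' @export
shift_environment <- function(rho0, target, weight) {
  if (length(rho0) != length(target)) stop("length mismatch", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 ||
      weight > 1) {
    stop("`weight` must be in [0, 1]", call. = FALSE)
  }
  if (any(target < 0) || sum(target) <= 0) {
    stop("`target` must be non-negative with positive sum", call. = FALSE)
  }
  scaled <- as.double(target) / sum(target) * sum(rho0)
  (1 - weight) * as.double(rho0) + weight * scaled
}

#' Environment-shift reactor experiment
#'
#' Runs a constant-population reactor to a steady state, then replaces the
#' external concentrations by a blend biased towards the centroid of a
#' chosen (by default, the minority) compotype, and continues. A paired
#' control continues from the identical population and RNG state without the
#' shift, so any post-switch difference is caused by the environment alone.
#'
#' @inheritParams run_reactor
#' @param weight Blend weight passed to [shift_environment()].
#' @param switch_at Split count at which the environment changes.
#' @param n_splits Total splits (pre + post).
#' @param target_compotype Compotype id to favour; `NULL` picks the minority
#'   (lowest mean frequency over the pre-phase among reference compotypes).
#' @return A `shift_experiment`: `$pre`, `$post_shifted`, `$post_control`
#'   frequency tibbles, `$target` compotype id, `$rho_shifted`.
#' @export
run_shift_experiment <- function(params, weight, switch_at, n_splits,
                                 pop_size, seed = NULL, ref = NULL,
                                 target_compotype = NULL,
                                 record_every = 10L, threshold = 0.9) {
  if (switch_at >= n_splits) stop("`switch_at` must be < `n_splits`",
                                  call. = FALSE)
  with_seed(seed, {
    if (is.null(ref)) {
      ref <- reference_compotypes(params, n_generations = 500,
                                  threshold = threshold)
    }
    if (nrow(ref) < 1L) stop("no reference compotypes for this matrix",
                             call. = FALSE)
    centroids <- ref$centroid
    st <- reactor_init(params, pop_size)
    pre <- list(reactor_record(st, centroids, threshold))
    for (e in seq_len(switch_at)) {
      reactor_step(st, params)
      if (e %% record_every == 0L || e == switch_at) {
        pre[[length(pre) + 1L]] <- reactor_record(st, centroids, threshold)
      }
    }
    pre <- dplyr::bind_rows(pre)

    if (is.null(target_compotype)) {
      means <- pre |>
        dplyr::filter(.data$compotype > 0) |>
        dplyr::group_by(.data$compotype) |>
        dplyr::summarise(f = mean(.data$frequency), .groups = "drop")
      target_compotype <- means$compotype[which.min(means$f)]
    }
    rho_shifted <- shift_environment(params$rho,
                                     centroids[[target_compotype]], weight)

    run_arm <- function(arm_params) {
      arm <- as_reactor_snapshot(st)
      recs <- list()
      for (e in (switch_at + 1L):n_splits) {
        reactor_step(arm, arm_params)
        if (e %% record_every == 0L || e == n_splits) {
          recs[[length(recs) + 1L]] <-
            reactor_record(arm, centroids, threshold)
        }
      }
      dplyr::bind_rows(recs)
    }
    rng <- get(".Random.seed", envir = globalenv())
    post_control <- run_arm(params)
    assign(".Random.seed", rng, envir = globalenv())
    post_shifted <- run_arm(update_params(params, rho = rho_shifted))

    structure(list(pre = pre, post_control = post_control,
                   post_shifted = post_shifted, target = target_compotype,
                   rho_shifted = rho_shifted, ref = ref, weight = weight,
                   switch_at = switch_at),
              class = "shift_experiment")
  })
}

as_reactor_snapshot <- function(st) {
  cp <- new.env(parent = emptyenv())
  cp$params <- st$params
  cp$P <- st$P
  cp$grown <- st$grown
  cp$completion <- st$completion
  cp$t <- st$t
  cp$splits <- st$splits
  cp
}

#' @export
print.shift_experiment <- function(x, ...) {
  summ <- function(tb) {
    tb |> dplyr::filter(.data$compotype == x$target) |>
      dplyr::summarise(f = mean(.data$frequency)) |> dplyr::pull("f")
  }
  cat(sprintf("<shift_experiment> target C%d, weight %.2f\n", x$target,
              x$weight))
  cat(sprintf("  target frequency: pre %.3f, control %.3f, shifted %.3f\n",
              summ(x$pre), summ(x$post_control), summ(x$post_shifted)))
  invisible(x)
}

#' @export
tidy.shift_experiment <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pre, phase = "pre"),
    dplyr::mutate(x$post_control, phase = "post_control"),
    dplyr::mutate(x$post_shifted, phase = "post_shifted")
  )
}

#' Single-compound depletion screen
#'
#' For each of `n_matrices` random \eqn{\beta} matrices, simulates a
#' baseline trace and then, for every compound in the repertoire, a trace
#' with that compound depleted ([deplete_compound()]). Reports the
#' normalized growth rate (splits per unit simulated time after depletion,
#' divided by before) and, where both traces contain composomes, the best
#' compositional match between pre- and post-depletion composomes. Most
#' depletions are near neutral (ratio about 1); a minority appreciably
#' diminish growth and a small tail enhances it — composomes that are
#' fitter in the modified environment.
#'
#' @param params Template [gard_params()]; the repertoire size and the
#'   distribution metadata of its `beta` are used to draw screen matrices.
#' @param n_matrices Number of random matrices to screen.
#' @param n_generations Trace length for each run.
#' @param seed Root seed (matrices and traces use derived streams).
#' @param threshold,min_len Composome detection settings.
#' @return A `depletion_screen` tibble: `matrix`, `compound`, `ratio`
#'   (after/before growth rate; 0 when the depleted run stalled),
#'   `best_H` (NA when either side shows no composome), `stalled`.
#' @export
depletion_screen <- function(params, n_matrices, n_generations = 200,
                             seed = NULL, threshold = 0.9, min_len = 5L) {
  stop_if_not_scalar_count(n_matrices, "n_matrices")
  ng <- params$n_types
  mu <- attr(params$beta, "mu"); sigma <- attr(params$beta, "sigma")
  if (is.na(mu) || is.na(sigma)) { mu <- -4; sigma <- 4 }
  rows <- purrr::map_dfr(seq_len(n_matrices), function(m) {
    beta_m <- sample_beta(ng, mu = mu, sigma = sigma,
                          seed = derive_seed(seed, "screen-beta", m))
    p0 <- update_params(params, beta = beta_m)
    tr0 <- run_trace(p0, n_generations,
                     seed = derive_seed(seed, "screen-trace", m))
    rate0 <- growth_rate(tr0)
    ep0 <- detect_composomes(tr0, threshold = threshold, min_len = min_len)
    cen0 <- if (nrow(ep0)) cluster_compotypes(ep0, threshold)$centroid
            else list()
    purrr::map_dfr(seq_len(ng), function(cmp) {
      pd <- update_params(p0, beta = deplete_compound(beta_m, cmp))
      res <- tryCatch({
        trd <- run_trace(pd, n_generations,
                         seed = derive_seed(seed, "screen-trace",
                                            m * 10000L + cmp))
        epd <- detect_composomes(trd, threshold = threshold,
                                 min_len = min_len)
        cend <- if (nrow(epd)) cluster_compotypes(epd, threshold)$centroid
                else list()
        best_h <- if (length(cen0) && length(cend)) {
          max(vapply(cen0, function(a)
            max(vapply(cend, function(b) similarity_H(a, b), numeric(1))),
            numeric(1)))
        } else NA_real_
        list(ratio = growth_rate(trd) / rate0, best_H = best_h,
             stalled = FALSE)
      }, error = function(e) list(ratio = 0, best_H = NA_real_,
                                  stalled = TRUE))
      tibble::tibble(matrix = m, compound = cmp, ratio = res$ratio,
                     best_H = res$best_H, stalled = res$stalled)
    })
  })
  class(rows) <- c("depletion_screen", class(rows))
  rows
}
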