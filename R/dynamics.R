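#' Entry and exit propensities of the GARD rate law
#'
#' The compositional dependence of the kinetics enters through the catalytic
#' factor
#' \deqn{C_i = 1 + \frac{1}{N} \sum_j \beta_{ij} n_j,}
#' which multiplies both directions of the exchange reaction:
#' forward (entry) \eqn{k_i \rho_i N C_i} and backward (exit)
#' \eqn{k_{-i} n_i C_i}. Because the same factor scales both, catalysis
#' accelerates the approach to — but never shifts — the equilibrium
#' \eqn{K_i = k_i / k_{-i}}.
#'
#' Exits are disabled when \eqn{N = 1} so the assembly never empties.
#'
#' @param x An [assembly()].
#' @param params A [gard_params()] set.
#' @return A list with numeric vectors `forward` and `backward`.
#' @examples
#' p <- gard_params(sample_beta(3, seed = 1), n_max = 4)
#' propensities(assembly(c(1, 1, 0)), p)
#' @export
propensities <- function(x, params) {
  counts <- as.double(unclass(x))
  N <- sum(counts)
  if (N < 1) stop("empty assembly", call. = FALSE)
  C <- 1 + as.vector(unclass(params$beta) %*% counts) / N
  forward <- params$k_f * params$rho * N * C
  backward <- if (N > 1) params$k_b * counts * C else numeric(params$n_types)
  list(forward = forward, backward = backward)
}

#' Execute one stochastic reaction event
#'
#' One step of the Gillespie direct method over the \eqn{2 N_G} entry/exit
#' channels: the waiting time is exponential with rate equal to the total
#' propensity, and the channel is chosen with probability proportional to its
#' propensity. Exactly one molecule enters or leaves.
#'
#' @inheritParams propensities
#' @return A list: `assembly` (new state), `dt` (elapsed time), `event`
#'   (channel id: `1..N_G` entry of that type, `N_G+1..2*N_G` exit).
#' @export
step_ssa <- function(x, params) {
  res <- cpp_step(as.integer(unclass(x)), unclass(params$beta), params$k_f,
                  params$k_b, effective_rho(params))
  list(assembly = structure(res$counts, class = "assembly"),
       dt = res$dt, event = res$event)
}

effective_rho <- function(params) params$rho

#' Grow an assembly to its fission size
#'
#' Repeats SSA steps until the total count reaches `params$n_max`. The
#' elapsed simulated time is the inter-split interval, the natural
#' growth-rate clock of the model.
#'
#' @inheritParams propensities
#' @return A list: `assembly` (at \eqn{N_{MAX}}), `time` (elapsed), `steps`.
#' @export
grow_to_size <- function(x, params) {
  counts <- as.integer(unclass(x))
  if (sum(counts) > params$n_max) stop("assembly larger than n_max",
                                       call. = FALSE)
  if (sum(counts) == params$n_max) {
    return(list(assembly = structure(counts, class = "assembly"),
                time = 0, steps = 0L))
  }
  res <- cpp_grow(counts, unclass(params$beta), params$k_f, params$k_b,
                  effective_rho(params), params$n_max, params$max_steps)
  list(assembly = structure(res$counts, class = "assembly"),
       time = res$time, steps = as.integer(res$steps))
}

#' Random fission into two equal halves
#'
#' Partitions the \eqn{N} molecules (N even) at random without replacement
#' into two progeny of exactly \eqn{N/2} each; per-type counts follow the
#' multivariate hypergeometric law, so the expected progeny composition is
#' half the parent composition and counts are conserved exactly.
#'
#' @param x An [assembly()] with even total count.
#' @return A list of two assemblies, `first` and `second`.
#' @export
split_assembly <- function(x) {
  counts <- as.integer(unclass(x))
  if (sum(counts) %% 2 != 0) stop("split requires an even total count",
                                  call. = FALSE)
  res <- cpp_split(counts)
  list(first = structure(res$first, class = "assembly"),
       second = structure(res$second, class = "assembly"))
}

#' Simulate a growth-fission trace
#'
#' The trace mode follows a single assembly lineage: a randomly seeded
#' assembly of size \eqn{N_{MIN}} grows to \eqn{N_{MAX}}, splits into two
#' random halves, one progeny is kept at random and the other discarded, for
#' `n_generations` cycles. The composition and cumulative simulated time at
#' every fission are recorded. Composomes appear as runs of generations with
#' high mutual compositional similarity (see [detect_composomes()]).
#'
#' @param params A [gard_params()] set (`n_max` even).
#' @param n_generations Number of growth-fission cycles.
#' @param seed Optional seed; same seed gives an identical trace.
#' @param init Optional starting composition (defaults to a random seed
#'   assembly of size `n_min`).
#' @return A `gard_trace`: list with `composition` (generations x
#'   \eqn{N_G} integer matrix of at-fission compositions), `time` (cumulative
#'   fission times), and the parameter snapshot.
#' @examples
#' p <- gard_params(sample_beta(20, seed = 1), n_max = 20)
#' tr <- run_trace(p, 50, seed = 2)
#' tr
#' @export
run_trace <- function(params, n_generations, seed = NULL, init = NULL) {
  stop_if_not_scalar_count(n_generations, "n_generations")
  if (params$n_max %% 2 != 0) stop("`n_max` must be even for fission",
                                   call. = FALSE)
  init_counts <- if (is.null(init)) integer(0) else as.integer(unclass(init))
  res <- with_seed(seed, cpp_run_trace(
    unclass(params$beta), params$k_f, params$k_b, effective_rho(params),
    params$n_max, params$n_min, n_generations, params$max_steps, init_counts))
  new_gard_trace(res$composition, res$time, params, seed)
}

new_gard_trace <- function(composition, time, params, seed = NULL) {
  structure(list(composition = composition, time = as.double(time),
                 params = params, seed = seed),
            class = "gard_trace")
}

#' @export
print.gard_trace <- function(x, ...) {
  ng <- ncol(x$composition)
  cat(sprintf("<gard_trace> %d generations, N_G = %d, N_MAX = %d\n",
              nrow(x$composition), ng, x$params$n_max))
  cat(sprintf("  total simulated time: %.4g, growth rate: %.4g splits/time\n",
              max(x$time), growth_rate(x)))
  invisible(x)
}

#' @export
tidy.gard_trace <- function(x, ...) {
  comp <- x$composition
  tibble::tibble(
    generation = rep(seq_len(nrow(comp)), times = ncol(comp)),
    time = rep(x$time, times = ncol(comp)),
    compound = rep(seq_len(ncol(comp)), each = nrow(comp)),
    count = as.vector(comp)
  ) |> dplyr::arrange(.data$generation, .data$compound)
}

#' Reproductive growth rate of a trace
#'
#' Splits per unit simulated time over the whole trace.
#'
#' @param trace A [run_trace()] result.
#' @return A single number.
#' @export
growth_rate <- function(trace) {
  nrow(trace$composition) / max(trace$time)
}

#' Relax a finite-supply assembly to equilibrium
#'
#' Runs the entry/exit dynamics without fission against a finite external
#' budget: \eqn{\rho_i(t)} is proportional to the remaining external count of
#' type \eqn{i}, decremented on entry and restored on exit. The assembly
#' grows, transiently displays composome-like unequal molar fractions (for a
#' structured \eqn{\beta}), and finally plateaus. Because the catalytic
#' factor multiplies both directions, it cancels at detailed balance: with
#' equal \eqn{K_i} and equal initial \eqn{\rho_i} all molar fractions
#' equalize at the plateau, demonstrating that composomes are
#' out-of-equilibrium (kinetically selected) states.
#'
#' @param params A [gard_params()] with `supply = "finite"` and a `budget`.
#' @param n_steps Total SSA steps to simulate.
#' @param record_every Record the composition every this many steps.
#' @param seed Optional seed.
#' @param init Optional initial composition (default: one molecule of type
#'   1..`n_min` drawn at random).
#' @return A `gard_timeseries`: `time`, `size`, `composition` matrix (one row
#'   per record), final remaining `budget`, and the parameter snapshot.
#' @export
run_to_equilibrium <- function(params, n_steps = 2e5, record_every = 100,
                               seed = NULL, init = NULL) {
  if (params$supply != "finite") {
    stop("`run_to_equilibrium()` requires finite supply (see gard_params)",
         call. = FALSE)
  }
  if (params$fission) {
    stop("equilibrium runs require `fission = FALSE`", call. = FALSE)
  }
  res <- with_seed(seed, {
    init_counts <- if (is.null(init)) {
      cpp_seed_assembly(params$n_types, params$n_min)
    } else as.integer(unclass(init))
    cpp_run_equilibrium(unclass(params$beta), params$k_f, params$k_b,
                        params$budget, params$rho[1], init_counts,
                        n_steps, as.integer(record_every))
  })
  structure(list(time = res$time, size = res$size,
                 composition = res$composition, budget = res$budget,
                 params = params, seed = seed),
            class = "gard_timeseries")
}

#' @export
print.gard_timeseries <- function(x, ...) {
  cat(sprintf("<gard_timeseries> %d records, final N = %d of budget %g\n",
              length(x$time), as.integer(tail(x$size, 1)),
              sum(x$params$budget) + sum(x$composition[1, ])))
  invisible(x)
}

#' @export
tidy.gard_timeseries <- function(x, ...) {
  comp <- x$composition
  tibble::tibble(
    time = rep(x$time, times = ncol(comp)),
    compound = rep(seq_len(ncol(comp)), each = nrow(comp)),
    count = as.vector(comp),
    fraction = as.vector(comp / rowSums(comp))
  )
}

#' Sweep the equilibrium constant and measure composome persistence
#'
#' Emulates an increasing compositional mutation rate thermodynamically:
#' scaling all forward constants \eqn{k_i} down (with \eqn{k_{-i}} fixed)
#' lowers \eqn{K_{eq}}, raises the propensity of highly mutated
#' compositions, and ultimately dissolves composomes — the compositional
#' analogue of the quasispecies error catastrophe.
#'
#' @param params Baseline [gard_params()].
#' @param scales Positive multipliers applied to `k_f` (e.g. a decreasing
#'   grid spanning a factor of 10).
#' @param n_generations Trace length per grid point.
#' @param seed Root seed; each grid point and replicate uses a derived
#'   stream so points are independent but reproducible.
#' @param n_reps Replicate traces averaged per grid point.
#' @param threshold,min_len Composome detection settings (see
#'   [detect_composomes()]).
#' @return A tibble with `scale`, `keq_scale` (same value; the ratio
#'   \eqn{K_{eq}/K_{eq}^0}), and `persistence` (mean fraction of generations
#'   inside composome episodes, in `[0, 1]`).
#' @export
keq_sweep <- function(params, scales, n_generations, seed = NULL,
                      n_reps = 1L, threshold = 0.9, min_len = 5L) {
  if (length(scales) < 1L) stop("`scales` must be non-empty", call. = FALSE)
  stop_if_not_positive(scales, "scales")
  purrr::map_dfr(seq_along(scales), function(si) {
    sc <- scales[si]
    p <- update_params(params, k_f = params$k_f * sc)
    # replicate r shares its seed across grid points (paired comparison)
    pers <- vapply(seq_len(n_reps), function(r) {
      tr <- run_trace(p, n_generations, seed = derive_seed(seed, "keq", r))
      ep <- detect_composomes(tr, threshold = threshold, min_len = min_len)
      if (nrow(ep) == 0) 0 else sum(ep$end - ep$start + 1) / n_generations
    }, numeric(1))
    tibble::tibble(scale = sc, keq_scale = sc, persistence = mean(pers))
  })
}
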