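#' Generate deterministic test fixtures
#'
#' Everything the test suite (or a user exploring the analysis functions)
#' needs, generated in code with no external data:
#' \describe{
#'   \item{`"beta"`}{a lognormal rate-enhancement matrix.}
#'   \item{`"trace"`}{a simulated growth-fission trace.}
#'   \item{`"planted-composome"`}{a synthetic composition matrix of noisy
#'     random assemblies with one contiguous block repeating a fixed
#'     composition — [detect_composomes()] must recover exactly the planted
#'     block.}
#'   \item{`"logistic-series"`}{a noisy logistic frequency series with known
#'     parameters, for [fit_logistic()] recovery checks.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param seed Seed; the same seed always yields the identical fixture.
#' @param path Optional file path; if given, the fixture is also written as
#'   delimited text (beta matrices via [write_beta()], others as CSV).
#' @param ... Kind-specific settings: `n_types`, `mu`, `sigma` (beta);
#'   `n_generations`, `n_max` (trace); `n_generations`, `n_types`, `n_max`,
#'   `block_start`, `block_len` (planted-composome); `K`, `A`, `r`, `n`,
#'   `noise_sd` (logistic-series).
#' @return The fixture object: a `beta_matrix`, a `gard_trace`, a list with
#'   `composition` and `planted` (start/end), or a tibble `t`, `f`,
#'   `f_true`.
#' @export
make_fixture <- function(kind = c("beta", "trace", "planted-composome",
                                  "logistic-series"),
                         seed = 1L, path = NULL, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  get_opt <- function(name, default) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  fx <- switch(kind,
    "beta" = sample_beta(get_opt("n_types", 20L), get_opt("mu", -4),
                         get_opt("sigma", 4), seed = seed),
    "trace" = {
      b <- sample_beta(get_opt("n_types", 20L), get_opt("mu", -4),
                       get_opt("sigma", 4),
                       seed = derive_seed(seed, "fixture-beta"))
      p <- gard_params(b, n_max = get_opt("n_max", 20L))
      run_trace(p, get_opt("n_generations", 100L), seed = seed)
    },
    "planted-composome" = {
      ng <- get_opt("n_types", 50L)
      n_max <- get_opt("n_max", 50L)
      ngen <- get_opt("n_generations", 40L)
      start <- get_opt("block_start", 16L)
      len <- get_opt("block_len", 10L)
      with_seed(seed, {
        comp <- t(rmultinom(ngen, n_max, rep(1 / ng, ng)))
        # planted block: one fixed composition concentrated on few types
        planted <- rep(0L, ng)
        picked <- sample.int(ng, 5L)
        planted[picked] <- as.vector(rmultinom(1, n_max, rep(0.2, 5)))
        comp[start:(start + len - 1L), ] <-
          matrix(planted, nrow = len, ncol = ng, byrow = TRUE)
        list(composition = comp,
             planted = list(start = as.integer(start),
                            end = as.integer(start + len - 1)))
      })
    },
    "logistic-series" = {
      K <- get_opt("K", 0.6); A <- get_opt("A", 59); r <- get_opt("r", 0.05)
      n <- get_opt("n", 200L); noise_sd <- get_opt("noise_sd", 0.02)
      with_seed(seed, {
        t <- seq_len(n)
        f_true <- K / (1 + A * exp(-r * t))
        f <- pmin(pmax(f_true + stats::rnorm(n, 0, noise_sd), 0), 1)
        tibble::tibble(t = t, f = f, f_true = f_true)
      })
    }
  )
  if (!is.null(path)) {
    if (kind == "beta") {
      write_beta(fx, path)
    } else if (kind == "trace") {
      write_trace(fx, path)
    } else if (kind == "planted-composome") {
      utils::write.csv(fx$composition, path, row.names = FALSE)
    } else {
      utils::write.csv(fx, path, row.names = FALSE)
    }
  }
  fx
}
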