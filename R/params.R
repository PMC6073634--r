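#' Kinetic parameter set for a GARD simulation
#'
#' Bundles the full kinetic specification of the entry/exit dynamics:
#' per-type basal forward rate constants \eqn{k_i} (1/(concentration time)),
#' basal backward rate constants \eqn{k_{-i}} (1/time), external
#' concentrations \eqn{\rho_i} (concentration), the rate-enhancement matrix
#' \eqn{\beta}, and the fission sizes. The forward/backward ratio defines the
#' per-type equilibrium constant \eqn{K_i = k_i / k_{-i}}; catalysis
#' multiplies both directions identically and therefore never changes
#' \eqn{K_i}.
#'
#' Defaults \eqn{k_f = 10^{-2}}, \eqn{k_b = 10^{-5}}, \eqn{\rho = 10^{-2}}
#' are the historical GARD micelle values (time and concentration units are
#' arbitrary; only products such as \eqn{k_f \rho} and ratios matter).
#'
#' @param beta A [sample_beta()] matrix; defines the repertoire size
#'   \eqn{N_G}.
#' @param n_max Assembly size that triggers fission (must be even unless
#'   `fission = FALSE`).
#' @param n_min Post-fission size; defaults to `n_max / 2`.
#' @param k_f,k_b,rho Scalars or length-\eqn{N_G} vectors of positive rates
#'   and concentrations.
#' @param supply `"infinite"` (default; \eqn{\rho} held constant) or
#'   `"finite"` (a shared external budget depletes as molecules join; see
#'   [run_to_equilibrium()]).
#' @param budget Total external molecule budget per type (finite supply
#'   only); scalar or length-\eqn{N_G}.
#' @param fission Logical; growth-fission cycling on (default) or off.
#' @param zero_rho If `TRUE`, compounds whose beta row and column have been
#'   zeroed by [deplete_compound()] also get \eqn{\rho_i = 0} (the fully
#'   equivalent environmental description). Off by default.
#' @param max_steps Stall guard: maximum SSA steps per growth phase.
#' @return A `gard_params` object.
#' @examples
#' p <- gard_params(sample_beta(10, seed = 1), n_max = 10)
#' p
#' @export
gard_params <- function(beta, n_max = nrow(beta), n_min = n_max / 2,
                        k_f = 1e-2, k_b = 1e-5, rho = 1e-2,
                        supply = c("infinite", "finite"), budget = NULL,
                        fission = TRUE, zero_rho = FALSE, max_steps = 1e7) {
  if (!inherits(beta, "beta_matrix")) {
    if (is.matrix(beta) && nrow(beta) == ncol(beta)) {
      beta <- new_beta_matrix(beta)
    } else stop("`beta` must be a square matrix", call. = FALSE)
  }
  ng <- nrow(beta)
  supply <- match.arg(supply)
  stop_if_not_scalar_count(n_max, "n_max", min = 2L)
  stop_if_not_scalar_count(n_min, "n_min")
  if (n_min > n_max) stop("`n_min` must not exceed `n_max`", call. = FALSE)
  expand <- function(x, name) {
    stop_if_not_positive(x, name)
    if (length(x) == 1L) rep(as.double(x), ng)
    else if (length(x) == ng) as.double(x)
    else stop(sprintf("`%s` must have length 1 or %d", name, ng),
              call. = FALSE)
  }
  k_f <- expand(k_f, "k_f"); k_b <- expand(k_b, "k_b")
  rho <- expand(rho, "rho")
  if (zero_rho) {
    gone <- which(rowSums(unclass(beta)) == 0 & colSums(unclass(beta)) == 0)
    rho[gone] <- 0
    if (all(rho == 0)) stop("all external concentrations are zero",
                            call. = FALSE)
  }
  if (supply == "finite") {
    if (is.null(budget)) stop("finite supply requires `budget`", call. = FALSE)
    stop_if_not_positive(budget, "budget")
    budget <- if (length(budget) == 1L) rep(as.double(budget), ng)
              else as.double(budget)
    if (length(budget) != ng) stop("`budget` must have length 1 or N_G",
                                   call. = FALSE)
  }
  structure(list(n_types = ng, beta = beta, n_max = as.integer(n_max),
                 n_min = as.integer(n_min), k_f = k_f, k_b = k_b, rho = rho,
                 supply = supply, budget = budget, fission = isTRUE(fission),
                 max_steps = as.double(max_steps)),
            class = "gard_params")
}

#' @export
print.gard_params <- function(x, ...) {
  cat(sprintf(
    "<gard_params> N_G = %d, N_MAX = %d, N_MIN = %d, supply = %s, fission = %s\n",
    x$n_types, x$n_max, x$n_min, x$supply, x$fission))
  cat(sprintf("  k_f in [%.3g, %.3g], k_b in [%.3g, %.3g], rho in [%.3g, %.3g]\n",
              min(x$k_f), max(x$k_f), min(x$k_b), max(x$k_b), min(x$rho),
              max(x$rho)))
  invisible(x)
}

# replace selected fields, revalidating
update_params <- function(params, ...) {
  dots <- list(...)
  args <- list(beta = params$beta, n_max = params$n_max, n_min = params$n_min,
               k_f = params$k_f, k_b = params$k_b, rho = params$rho,
               supply = params$supply, budget = params$budget,
               fission = params$fission, max_steps = params$max_steps)
  do.call(gard_params, modifyList(args, dots))
}
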