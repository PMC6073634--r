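# Exact big-integer arithmetic (base 1e9 little-endian digit vectors).
# Only multiply/divide by machine-size integers are needed for the exact
# binomial recurrence; division is always exact there.

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  d <- c()
  while (x > 0) { d <- c(d, x %% 1e9); x <- x %/% 1e9 }
  d
}

big_mul_small <- function(d, m) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] * m + carry
    d[i] <- v %% 1e9
    carry <- v %/% 1e9
  }
  while (carry > 0) { d <- c(d, carry %% 1e9); carry <- carry %/% 1e9 }
  d
}

big_div_small <- function(d, m) { # exact division
  rem <- 0
  for (i in rev(seq_along(d))) {
    v <- rem * 1e9 + d[i]
    d[i] <- v %/% m
    rem <- v %% m
  }
  stopifnot(rem == 0)
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_to_string <- function(d) {
  paste0(format(d[length(d)], scientific = FALSE),
         paste(rev(sprintf("%09d", utils::head(d, -1))), collapse = ""))
}

big_to_double <- function(d) sum(d * 1e9^(seq_along(d) - 1))

# exact C(n, k) via the integer-preserving recurrence prod (n-k+i)/i
big_choose <- function(n, k) {
  k <- min(k, n - k)
  if (k < 0) return(big_from_int(0))
  d <- big_from_int(1)
  if (k == 0) return(d)
  for (i in seq_len(k)) {
    d <- big_mul_small(d, n - k + i)
    d <- big_div_small(d, i)
  }
  d
}

#' Count the distinct compositions of an assembly
#'
#' The number of multisets of size `N` over a repertoire of `n_types`
#' molecule types is the multiset coefficient
#' \deqn{\binom{N + N_G - 1}{N},}
#' computed exactly in arbitrary precision. Its logarithm is the
#' compositional information capacity of an assembly. For \eqn{N = N_G =
#' 100} there are about \eqn{4.5 \times 10^{58}} compositions; for a small
#' micelle of \eqn{N = 36} over \eqn{N_G = 100}, about
#' \eqn{7.7 \times 10^{32}}.
#'
#' @param N Assembly size (total molecule count), `N >= 0`.
#' @param n_types Repertoire size \eqn{N_G >= 1}.
#' @return A `bigint`: list with `string` (exact decimal), `value` (double
#'   approximation, `Inf` if above double range) and `log10`.
#' @examples
#' n_compositions(100, 100)
#' @export
n_compositions <- function(N, n_types) {
  stop_if_not_scalar_count(N, "N", min = 0L)
  stop_if_not_scalar_count(n_types, "n_types")
  d <- big_choose(N + n_types - 1, N)
  s <- big_to_string(d)
  lg <- if (N == 0 || n_types == 1L) 0 else lchoose(N + n_types - 1, N) / log(10)
  structure(list(string = s, value = big_to_double(d), log10 = lg),
            class = "bigint")
}

#' @export
print.bigint <- function(x, ...) {
  if (nchar(x$string) > 12) {
    lead <- as.numeric(substr(x$string, 1, 10)) / 1e9
    cat(sprintf("<bigint> %.4g x 10^%d (%d digits)\n", lead,
                nchar(x$string) - 1L, nchar(x$string)))
  } else {
    cat(sprintf("<bigint> %s\n", x$string))
  }
  invisible(x)
}

#' @export
format.bigint <- function(x, digits = 2, ...) {
  lead <- as.numeric(substr(paste0(x$string, "000000000000000"), 1, 15)) / 1e14
  exp10 <- nchar(x$string) - 1L
  lead <- signif(lead, digits)
  if (lead >= 10) { lead <- lead / 10; exp10 <- exp10 + 1L }
  sprintf("%se%d", format(lead), exp10)
}

#' Information content of sequences and compositions
#'
#' Compositional information is the log2 count of distinct compositions,
#' \eqn{\log_2 \binom{N + N_G - 1}{N}} bits; sequential information for the
#' same \eqn{N} and alphabet, with equal monomer frequencies, is the Shannon
#' capacity \eqn{N \log_2 N_G} bits. Compositions are unordered sequences,
#' so compositional information is never larger; at large \eqn{N_G} relative
#' to \eqn{N} the two become asymptotically equal.
#'
#' @param N Polymer length / assembly size.
#' @param n_types Alphabet / repertoire size.
#' @param kind `"compositional"` or `"sequential"`.
#' @return Information in bits.
#' @export
information_bits <- function(N, n_types, kind = c("compositional",
                                                  "sequential")) {
  kind <- match.arg(kind)
  stop_if_not_scalar_count(N, "N", min = 0L)
  stop_if_not_scalar_count(n_types, "n_types")
  if (kind == "sequential") return(N * log2(n_types))
  lchoose(N + n_types - 1, N) / log(2)
}

#' Planetary replicator capacity
#'
#' How many replicator-scale assemblies fit in a slab of ocean surface:
#' \deqn{\mathrm{count} = \frac{\mathrm{area} \times \mathrm{depth}}
#'       {\mathrm{replicator\ volume} / \mathrm{volume\ fraction}},}
#' i.e. total water volume divided by the water volume carrying one
#' replicator. All lengths in SI units (`area_km2` converted as
#' \eqn{1\,\mathrm{km}^2 = 10^6\,\mathrm{m}^2}).
#'
#' @param area_km2 Surface area in km^2.
#' @param depth_m Depth of the counted layer in metres.
#' @param replicator_volume_m3 Volume of one replicator in m^3 (a 10 nm
#'   diameter micelle is about \eqn{5.2 \times 10^{-25}} m^3).
#' @param volume_fraction Fraction of the water volume occupied by
#'   replicators (default 1 means `replicator_volume_m3` is already the
#'   per-replicator share of water, e.g. \eqn{10^{-19}} m^3).
#' @return Number of replicators (double).
#' @examples
#' planetary_capacity(1e7, 1, 1e-19)           # 1e32
#' planetary_capacity(1e7, 1, 4 / 3 * pi * 5e-9^3, volume_fraction = 1e-5)
#' @export
planetary_capacity <- function(area_km2, depth_m, replicator_volume_m3,
                               volume_fraction = 1) {
  stop_if_not_positive(area_km2, "area_km2")
  stop_if_not_positive(depth_m, "depth_m")
  stop_if_not_positive(replicator_volume_m3, "replicator_volume_m3")
  stop_if_not_positive(volume_fraction, "volume_fraction")
  volume_m3 <- area_km2 * 1e6 * depth_m
  volume_m3 / (replicator_volume_m3 / volume_fraction)
}

#' Amphiphile concentration of a volume fraction
#'
#' Converts a volume fraction of dissolved/suspended amphiphile into a molar
#' concentration: \eqn{c = \phi \rho \cdot 1000 / M} mol/L with density
#' \eqn{\rho} in g/mL and molar mass \eqn{M} in g/mol. A pessimistically
#' dilute \eqn{\phi = 10^{-5}} of a 500 Da lipid is 20 uM.
#'
#' @param volume_fraction Dimensionless volume fraction (>= 0).
#' @param molar_mass_da Molar mass in g/mol (Da).
#' @param density_g_ml Density in g/mL (default 1).
#' @return Concentration in mol/L.
#' @examples
#' lipid_concentration(1e-5, 500) # 2e-5 M = 20 uM
#' @export
lipid_concentration <- function(volume_fraction, molar_mass_da,
                                density_g_ml = 1) {
  if (!is.numeric(volume_fraction) || volume_fraction < 0) {
    stop("`volume_fraction` must be non-negative", call. = FALSE)
  }
  stop_if_not_positive(molar_mass_da, "molar_mass_da")
  stop_if_not_positive(density_g_ml, "density_g_ml")
  volume_fraction * density_g_ml * 1000 / molar_mass_da
}
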