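#' Compositional similarity H
#'
#' The normalized dot product (cosine) of two compositional vectors,
#' \deqn{H(x, y) = \frac{x \cdot y}{\|x\| \|y\|} \in [0, 1],}
#' representing the angle between them in compositional space. `H` is
#' symmetric and invariant to assembly size, so it compares compositions of
#' assemblies at different growth stages.
#'
#' @param x,y Non-negative, non-zero numeric vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' similarity_H(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
similarity_H <- function(x, y) {
  x <- as.double(unclass(x)); y <- as.double(unclass(y))
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero vector has no direction", call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' Time correlation matrix of a trace
#'
#' All pairwise similarities \eqn{H} between the recorded generations: a
#' symmetric, unit-diagonal "carpet" in which composomes appear as
#' near-diagonal blocks of high similarity and off-diagonal blocks reveal
#' recurrences of the same composome.
#'
#' @param trace A [run_trace()] result (or a generations x types count
#'   matrix).
#' @return A generations x generations numeric matrix.
#' @export
carpet <- function(trace) {
  comp <- trace_matrix(trace)
  if (nrow(comp) < 2L) stop("need at least two generations", call. = FALSE)
  norm <- comp / sqrt(rowSums(comp^2))
  h <- tcrossprod(norm)
  h[h > 1] <- 1; h[h < 0] <- 0
  diag(h) <- 1
  h
}

trace_matrix <- function(trace) {
  if (inherits(trace, "gard_trace")) {
    m <- trace$composition
  } else if (inherits(trace, "pgard_trace")) {
    m <- cbind(trace$monomers, trace$dimers)
  } else if (is.matrix(trace)) {
    m <- trace
  } else stop("`trace` must be a gard_trace or a matrix", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Detect composome episodes in a trace
#'
#' A composome episode is a maximal run of at least `min_len` consecutive
#' generations whose compositions are all mutually similar: every pairwise
#' \eqn{H} within the run is at least `threshold`. Generations outside
#' episodes are drift. Episodes are maximal and non-overlapping; detection
#' scans forward and extends each candidate run while the incoming
#' generation stays similar to every generation already in it (all-pairs
#' criterion; `mode = "centroid"` instead requires similarity to the running
#' mean composition).
#'
#' @param trace A [run_trace()] result or count matrix.
#' @param threshold Similarity threshold in `(0, 1]` (default 0.9).
#' @param min_len Minimum episode length in generations (default 5).
#' @param mode `"pairs"` (default) or `"centroid"`.
#' @return A tibble of episodes: `start`, `end` (inclusive generation ids),
#'   `length`, `min_H` (minimum pairwise similarity within the episode),
#'   `n_mol` (mean per-generation restricted repertoire), `entropy` (of the
#'   mean composition), and `centroid` (list column, mean composition
#'   normalized to sum 1).
#' @export
detect_composomes <- function(trace, threshold = 0.9, min_len = 5L,
                              mode = c("pairs", "centroid")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  comp <- trace_matrix(trace)
  ngen <- nrow(comp)
  norm <- comp / sqrt(rowSums(comp^2))
  episodes <- list()
  start <- 1L
  while (start <= ngen) {
    end <- start
    if (mode == "pairs") {
      # extend while the candidate generation matches every member
      while (end < ngen) {
        cand <- norm[end + 1L, ]
        sims <- norm[start:end, , drop = FALSE] %*% cand
        if (min(sims) >= threshold) end <- end + 1L else break
      }
    } else {
      while (end < ngen) {
        centroid <- colMeans(comp[start:end, , drop = FALSE])
        if (similarity_H(comp[end + 1L, ], centroid) >= threshold) {
          end <- end + 1L
        } else break
      }
    }
    if (end - start + 1L >= min_len) {
      block <- norm[start:end, , drop = FALSE]
      min_h <- min(tcrossprod(block))
      rows <- comp[start:end, , drop = FALSE]
      centroid <- colMeans(rows)
      centroid <- centroid / sum(centroid)
      episodes[[length(episodes) + 1L]] <- tibble::tibble(
        start = start, end = end, length = end - start + 1L,
        min_H = min(min_h, 1),
        n_mol = mean(apply(rows, 1L, function(r) sum(r > 0))),
        entropy = assembly_entropy(centroid), centroid = list(centroid))
      start <- end + 1L
    } else {
      start <- start + 1L
    }
  }
  if (length(episodes) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), min_H = double(),
                          n_mol = double(), entropy = double(),
                          centroid = list()))
  }
  dplyr::bind_rows(episodes)
}

#' Cluster composome episodes into compotypes
#'
#' Greedy, time-ordered (first-fit) clustering: each episode joins the first
#' existing compotype whose centroid similarity is at least `threshold`,
#' otherwise it founds a new one. Centroids are running means of member
#' centroids (weighted by episode length, normalized to sum 1), so the
#' procedure is deterministic and order-stable.
#'
#' @param episodes A [detect_composomes()] tibble.
#' @param threshold Similarity threshold for joining a compotype.
#' @param n_generations Total generations of the source trace (used for the
#'   frequency column); defaults to the largest episode end.
#' @return A tibble of compotypes: `compotype` id, `n_episodes`,
#'   `generations` covered, `frequency` (fraction of all generations),
#'   `n_mol` (length-weighted mean restricted repertoire of the member
#'   episodes), `episodes` (list of member episode indices), and
#'   `centroid` (list column).
#' @export
cluster_compotypes <- function(episodes, threshold = 0.9,
                               n_generations = NULL) {
  if (nrow(episodes) == 0) stop("no episodes to cluster", call. = FALSE)
  if (is.null(n_generations)) n_generations <- max(episodes$end)
  centroids <- list()
  weights <- numeric()
  members <- list()
  for (e in seq_len(nrow(episodes))) {
    cen <- episodes$centroid[[e]]
    len <- episodes$length[e]
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (similarity_H(cen, centroids[[k]]) >= threshold) {
        new_w <- weights[k] + len
        centroids[[k]] <- (centroids[[k]] * weights[k] + cen * len) / new_w
        centroids[[k]] <- centroids[[k]] / sum(centroids[[k]])
        weights[k] <- new_w
        members[[k]] <- c(members[[k]], e)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- cen
      weights <- c(weights, len)
      members[[length(members) + 1L]] <- e
    }
  }
  tibble::tibble(
    compotype = seq_along(centroids),
    n_episodes = lengths(members),
    generations = vapply(members, function(m) sum(episodes$length[m]),
                         numeric(1)),
    frequency = vapply(members, function(m) sum(episodes$length[m]),
                       numeric(1)) / n_generations,
    n_mol = vapply(members, function(m) {
      stats::weighted.mean(episodes$n_mol[m], episodes$length[m])
    }, numeric(1)),
    episodes = members,
    centroid = centroids
  )
}

#' Restricted repertoire size
#'
#' The number of molecule types actually present in a composition
#' (\eqn{N_{MOL}}): strictly positive coordinates. Composomes have a
#' strongly restricted repertoire compared with randomly formed assemblies.
#'
#' @param x Non-negative numeric vector.
#' @return Integer count of present types.
#' @export
repertoire_size <- function(x) {
  x <- unclass(x)
  if (any(x < 0)) stop("negative counts", call. = FALSE)
  as.integer(sum(x > 0))
}

#' Moments of the random-assembly repertoire size
#'
#' For an assembly of `N` molecules drawn uniformly with replacement from
#' `n_types` types, the number of distinct types present has
#' \deqn{E[N_{MOL}] = N_G (1 - q), \quad q = (1 - 1/N_G)^N,}
#' \deqn{Var = N_G q (1 - q) + N_G (N_G - 1)(r - q^2), \quad
#'       r = (1 - 2/N_G)^N.}
#' This is the occupancy (birthday-type) problem; for \eqn{N = N_G = 100}
#' the expected repertoire is \eqn{63.4 \pm 3.1}, the yardstick against
#' which composomal repertoire restriction is measured.
#'
#' @param N Assembly size.
#' @param n_types Repertoire size \eqn{N_G}.
#' @return A list with `mean` and `sd`.
#' @export
expected_repertoire <- function(N, n_types) {
  stop_if_not_scalar_count(N, "N")
  stop_if_not_scalar_count(n_types, "n_types")
  q <- (1 - 1 / n_types)^N
  mean <- n_types * (1 - q)
  if (n_types == 1L) return(list(mean = 1, sd = 0))
  r <- (1 - 2 / n_types)^N
  v <- n_types * q * (1 - q) + n_types * (n_types - 1) * (r - q^2)
  list(mean = mean, sd = sqrt(max(v, 0)))
}

#' Shannon entropy of a composition
#'
#' \deqn{S = -\sum_{i: n_i > 0} \frac{n_i}{N} \ln \frac{n_i}{N}}
#' in nats by default (`base = 2` gives bits). Composomes, with their
#' restricted and skewed repertoires, have markedly lower entropy than
#' randomly formed assemblies of the same size — the local entropy decrease
#' of a dissipative system.
#'
#' @param x Non-negative numeric vector with positive sum.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Non-negative entropy.
#' @export
assembly_entropy <- function(x, base = exp(1)) {
  x <- as.double(unclass(x))
  N <- sum(x)
  if (N <= 0) stop("empty composition", call. = FALSE)
  p <- x[x > 0] / N
  -sum(p * log(p)) / log(base)
}

#' Canonical composome: leading eigenvector of the beta matrix
#'
#' The linearized no-fission growth dynamics converge in direction to the
#' eigenvector of \eqn{\beta} with the largest eigenvalue; for a strictly
#' positive matrix Perron-Frobenius guarantees this eigenvalue is real,
#' simple, and its eigenvector strictly positive. This "canonical composome"
#' is the attractor of unbroken growth, generally different from the
#' composomes selected by periodic fission.
#'
#' @param beta A square non-negative matrix (strictly positive for the
#'   Perron-Frobenius guarantee).
#' @return The leading eigenvector, non-negative and L1-normalized.
#' @export
canonical_composome <- function(beta) {
  m <- unclass(beta)
  if (any(rowSums(m) == 0)) {
    warning("matrix has all-zero rows (post-cutoff?): eigenvector may be degenerate")
  }
  e <- eigen(m)
  mods <- Mod(e$values)
  lead <- which.max(mods)
  if (sum(abs(mods - mods[lead]) < 1e-12 * max(mods)) > 1L) {
    stop("leading eigenvalue is not unique", call. = FALSE)
  }
  v <- e$vectors[, lead]
  if (max(abs(Im(v))) > 1e-8) stop("leading eigenvector is not real",
                                   call. = FALSE)
  v <- Re(v)
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  if (any(v < 0)) stop("leading eigenvector changes sign", call. = FALSE)
  v / sum(v)
}

#' Similarity to the compositional antipode
#'
#' For a chiral repertoire, the antipode of a composition swaps the counts
#' of every D/L enantiomer pair. \eqn{M = H(x, \sigma(x))} measures how
#' racemic a composition is: a perfectly racemic assembly is self-antipodal
#' (\eqn{M = 1}), a homochiral one over distinct scaffolds has \eqn{M = 0}.
#'
#' @param x Composition over the chiral repertoire.
#' @param chiral A [chiral_params()] (or a beta matrix built by
#'   [build_chiral_beta()]).
#' @return `M` in `[0, 1]`.
#' @export
antipode_similarity <- function(x, chiral) {
  cp <- as_chiral(chiral)
  x <- as.double(unclass(x))
  if (length(x) != cp$n_types) stop("length mismatch with chiral map",
                                    call. = FALSE)
  similarity_H(x, x[cp$antipode])
}

as_chiral <- function(chiral) {
  if (inherits(chiral, "chiral_params")) return(chiral)
  cp <- attr(chiral, "chiral")
  if (is.null(cp)) stop("no chiral map available", call. = FALSE)
  cp
}

#' Enantiomeric excess of a composition
#'
#' \deqn{ee = \frac{|\sum_D - \sum_L|}{\sum_D + \sum_L}}
#' over all scaffolds: 0 for a racemic assembly, 1 for a homochiral one.
#'
#' @inheritParams antipode_similarity
#' @return `ee` in `[0, 1]`.
#' @export
enantiomeric_excess <- function(x, chiral) {
  cp <- as_chiral(chiral)
  x <- as.double(unclass(x))
  if (length(x) != cp$n_types) stop("length mismatch with chiral map",
                                    call. = FALSE)
  d <- sum(x[seq_len(cp$scaffolds)])
  l <- sum(x[cp$scaffolds + seq_len(cp$scaffolds)])
  if (d + l == 0) stop("empty assembly", call. = FALSE)
  abs(d - l) / (d + l)
}
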