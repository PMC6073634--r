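#' Compositional state of a single assembly
#'
#' An assembly is the integer compositional vector
#' \eqn{\mathbf{n} = (n_1, \ldots, n_{N_G})}: `counts[i]` is the number of
#' molecules of type \eqn{A_i} currently inside. The total \eqn{N = \sum n_i}
#' is the assembly size.
#'
#' @param counts Non-negative integer vector of per-type counts.
#' @return An `assembly` object (an integer vector with class attribute).
#' @examples
#' a <- assembly(c(3, 0, 1))
#' assembly_size(a)
#' @export
assembly <- function(counts) {
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("assembly must contain at least one molecule",
                            call. = FALSE)
  structure(as.integer(counts), class = "assembly")
}

#' @rdname assembly
#' @param x An `assembly`.
#' @export
assembly_size <- function(x) sum(unclass(x))

#' @export
print.assembly <- function(x, ...) {
  present <- which(unclass(x) > 0)
  cat(sprintf("<assembly> N = %d over %d of %d types\n",
              assembly_size(x), length(present), length(unclass(x))))
  if (length(present) <= 20L) {
    cat("  ", paste(sprintf("%d:%d", present, unclass(x)[present]),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Seed a random assembly
#'
#' Draws `n_min` molecules uniformly with replacement from the `n_types`
#' repertoire — the random initial condition of every trace simulation.
#'
#' @param n_types Repertoire size.
#' @param n_min Number of molecules to draw.
#' @param seed Optional seed.
#' @return An [assembly()].
#' @export
seed_assembly <- function(n_types, n_min, seed = NULL) {
  stop_if_not_scalar_count(n_types, "n_types")
  stop_if_not_scalar_count(n_min, "n_min")
  counts <- with_seed(seed, cpp_seed_assembly(n_types, n_min))
  structure(as.integer(counts), class = "assembly")
}

#' Apply a compositional mutation
#'
#' A compositional mutation is a change in the count of one molecule type;
#' `delta` may be negative as long as the resulting count stays non-negative.
#'
#' @param x An [assembly()] (or plain count vector).
#' @param type 1-based compound index.
#' @param delta Integer change in count.
#' @return The mutated assembly.
#' @export
mutate_composition <- function(x, type, delta) {
  counts <- as.integer(unclass(x))
  stop_if_not_scalar_count(type, "type")
  if (type > length(counts)) stop("`type` out of range", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta != round(delta)) {
    stop("`delta` must be a single integer", call. = FALSE)
  }
  new <- counts[type] + as.integer(delta)
  if (new < 0) stop("mutation would give a negative count", call. = FALSE)
  counts[type] <- new
  structure(counts, class = "assembly")
}
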