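#' Sample a mutual-catalysis rate-enhancement matrix
#'
#' Draws an \eqn{N_G \times N_G} matrix of graded rate enhancements
#' \eqn{\beta_{ij}}, the catalysis exerted by in-assembly compound \eqn{A_j}
#' on the entry/exit of \eqn{A_i}. Elements are independent lognormal draws:
#' \eqn{\ln \beta_{ij} \sim \mathcal{N}(\mu, \sigma^2)}. The heavy right
#' tail of the lognormal (most catalytic interactions weak, a few strong) is
#' what makes composome emergence possible; a normal distribution of the same
#' mean largely abolishes compositional inheritance.
#'
#' @param n_types Repertoire size \eqn{N_G} (number of compound types).
#' @param mu,sigma Mean and standard deviation of \eqn{\ln \beta}. Defaults
#'   \eqn{\mu = -4}, \eqn{\sigma = 4} are the historical GARD values.
#' @param seed Optional integer seed; identical seeds give identical matrices.
#' @return A `beta_matrix`: a numeric matrix with distribution metadata
#'   (`mu`, `sigma`, `seed`) and a cutoff/depletion edit history attached as
#'   attributes.
#' @examples
#' b <- sample_beta(10, seed = 1)
#' range(b)
#' @seealso [apply_cutoff()], [deplete_compound()], [build_chiral_beta()]
#' @export
sample_beta <- function(n_types, mu = -4, sigma = 4, seed = NULL) {
  stop_if_not_scalar_count(n_types, "n_types")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  vals <- with_seed(seed, rlnorm(n_types * n_types, meanlog = mu, sdlog = sigma))
  m <- matrix(vals, nrow = n_types, ncol = n_types)
  new_beta_matrix(m, mu = mu, sigma = sigma, seed = seed)
}

new_beta_matrix <- function(m, mu = NA_real_, sigma = NA_real_, seed = NULL,
                            edits = list(), chiral = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m,
            mu = mu, sigma = sigma, seed = seed, edits = edits,
            chiral = chiral, class = c("beta_matrix", "matrix", "array"))
}

#' @export
as.matrix.beta_matrix <- function(x, ...) {
  matrix(as.vector(unclass(x)), nrow = nrow(x))
}

#' @export
print.beta_matrix <- function(x, ...) {
  ng <- nrow(x)
  cat(sprintf("<beta_matrix> %d x %d", ng, ng))
  if (!is.na(attr(x, "mu"))) {
    cat(sprintf("  lognormal(mu = %g, sigma = %g)", attr(x, "mu"),
                attr(x, "sigma")))
  }
  ed <- attr(x, "edits")
  if (length(ed)) cat(sprintf("  [%d edit(s)]", length(ed)))
  if (!is.null(attr(x, "chiral"))) cat("  chiral")
  cat("\n")
  cat(sprintf("  zero elements: %d, mean: %.4g, max: %.4g\n",
              sum(x == 0), mean(x), max(x)))
  invisible(x)
}

#' @export
tidy.beta_matrix <- function(x, ...) {
  ng <- nrow(x)
  tibble::tibble(
    target = rep(seq_len(ng), times = ng),
    catalyst = rep(seq_len(ng), each = ng),
    beta = as.vector(unclass(x))
  )
}

#' Normalize beta elements to their matrix mean
#'
#' The cutoff scale is defined on mean-normalized elements,
#' \eqn{\beta_{ij} / \bar\beta}, a scale-free choice recorded in the matrix
#' metadata.
#'
#' @param beta A [sample_beta()] matrix.
#' @return Numeric matrix of normalized elements.
#' @export
normalize_beta <- function(beta) {
  mb <- mean(beta)
  if (mb <= 0) stop("cannot normalize an all-zero matrix", call. = FALSE)
  unclass(beta) / mb
}

#' Zero out weak catalytic interactions
#'
#' Sets to zero every element whose mean-normalized value falls below
#' `threshold`, turning the fully connected graded network into a sparser one
#' (the graded analogue of a catalytic-closure cutoff).
#'
#' @param beta A `beta_matrix`.
#' @param threshold Non-negative cutoff on the normalized scale
#'   (element / matrix mean). `threshold = 0` leaves the matrix unchanged.
#' @return The edited `beta_matrix`; the edit is appended to its history.
#' @export
apply_cutoff <- function(beta, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  if (threshold == 0) return(beta)
  norm <- normalize_beta(beta)
  out <- unclass(beta)
  out[norm < threshold] <- 0
  new_beta_matrix(out,
                  mu = attr(beta, "mu"), sigma = attr(beta, "sigma"),
                  seed = attr(beta, "seed"),
                  edits = c(attr(beta, "edits"),
                            list(list(op = "cutoff", threshold = threshold))),
                  chiral = attr(beta, "chiral"))
}

#' Deplete a compound from the catalytic network
#'
#' Removes compound `compound` from the operative repertoire by zeroing its
#' entire row and column of the matrix: it neither receives nor exerts
#' catalysis. This is the matrix representation of depleting the compound
#' from the environment. Optionally the corresponding external concentration
#' can be zeroed too when the edited matrix is used through [gard_params()]
#' (see `zero_rho` there); the two are kinetically equivalent descriptions.
#'
#' @param beta A `beta_matrix`.
#' @param compound 1-based compound index in `1..N_G`.
#' @return The edited `beta_matrix`.
#' @export
deplete_compound <- function(beta, compound) {
  ng <- nrow(beta)
  stop_if_not_scalar_count(compound, "compound")
  if (compound > ng) stop("`compound` out of range", call. = FALSE)
  out <- unclass(beta)
  out[compound, ] <- 0
  out[, compound] <- 0
  new_beta_matrix(out,
                  mu = attr(beta, "mu"), sigma = attr(beta, "sigma"),
                  seed = attr(beta, "seed"),
                  edits = c(attr(beta, "edits"),
                            list(list(op = "deplete", compound = compound))),
                  chiral = attr(beta, "chiral"))
}

#' Enantiomer bookkeeping for chiral repertoires
#'
#' A chiral repertoire holds `scaffolds` distinct molecular scaffolds, each in
#' two enantiomers (D and L), so \eqn{N_G = 2 \times} `scaffolds`. Compounds
#' `1..scaffolds` are the D forms and `scaffolds+1..2*scaffolds` the matching
#' L forms; `antipode` is the index involution \eqn{\sigma} swapping them.
#'
#' @param scaffolds Number of distinct scaffolds.
#' @return A `chiral_params` list with `scaffolds`, `n_types` and `antipode`.
#' @export
chiral_params <- function(scaffolds) {
  stop_if_not_scalar_count(scaffolds, "scaffolds")
  n_types <- 2L * as.integer(scaffolds)
  antipode <- c(seq_len(scaffolds) + scaffolds, seq_len(scaffolds))
  structure(list(scaffolds = as.integer(scaffolds), n_types = n_types,
                 antipode = as.integer(antipode)),
            class = "chiral_params")
}

#' @export
print.chiral_params <- function(x, ...) {
  cat(sprintf("<chiral_params> %d scaffolds, N_G = %d (D: 1..%d, L: %d..%d)\n",
              x$scaffolds, x$n_types, x$scaffolds, x$scaffolds + 1L,
              x$n_types))
  invisible(x)
}

#' Build a mirror-symmetric chiral rate-enhancement matrix
#'
#' Constructs the \eqn{2 S \times 2 S} matrix for a racemic repertoire of `S`
#' scaffolds. Physics does not distinguish handedness, so the matrix obeys
#' exact mirror symmetry \eqn{\beta(i, j) = \beta(\sigma(i), \sigma(j))}
#' under the antipode map \eqn{\sigma}: a D-on-D interaction equals the
#' corresponding L-on-L one, and D-on-L equals L-on-D. Within- and
#' cross-handedness blocks are sampled independently from the same lognormal.
#'
#' @inheritParams sample_beta
#' @param scaffolds Number of distinct scaffolds (half the repertoire).
#' @return A `beta_matrix` with a [chiral_params()] object attached
#'   (retrievable via `attr(beta, "chiral")`).
#' @export
build_chiral_beta <- function(scaffolds, mu = -4, sigma = 4, seed = NULL) {
  cp <- chiral_params(scaffolds)
  s <- cp$scaffolds
  blocks <- with_seed(seed, list(
    same = matrix(rlnorm(s * s, mu, sigma), s, s),  # D on D == L on L
    cross = matrix(rlnorm(s * s, mu, sigma), s, s)  # L on D == D on L
  ))
  m <- rbind(cbind(blocks$same, blocks$cross),
             cbind(blocks$cross, blocks$same))
  new_beta_matrix(m, mu = mu, sigma = sigma, seed = seed, chiral = cp)
}

#' Read and write beta matrices as delimited text
#'
#' CSV with a header row of 1-based compound ids and a `#`-prefixed comment
#' block carrying the distribution metadata, so a written matrix reloads with
#' its provenance.
#'
#' @param beta A `beta_matrix`.
#' @param path File path.
#' @return `write_beta` returns `path` invisibly; `read_beta` returns a
#'   `beta_matrix`.
#' @export
write_beta <- function(beta, path) {
  meta <- sprintf("# gardsim beta_matrix mu=%g sigma=%g seed=%s edits=%d",
                  attr(beta, "mu"), attr(beta, "sigma"),
                  if (is.null(attr(beta, "seed"))) "NA" else attr(beta, "seed"),
                  length(attr(beta, "edits")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(seq_len(ncol(beta)), collapse = ","), con)
  utils::write.table(format(unclass(beta), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_beta
#' @export
read_beta <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  body <- lines[!is_meta]
  m <- as.matrix(utils::read.csv(textConnection(body), header = TRUE,
                                 check.names = FALSE))
  dimnames(m) <- NULL
  mu <- sigma <- NA_real_
  if (length(meta)) {
    mm <- regmatches(meta[1], regexec("mu=([-0-9.eE+]+) sigma=([-0-9.eE+]+)",
                                      meta[1]))[[1]]
    if (length(mm) == 3L) { mu <- as.numeric(mm[2]); sigma <- as.numeric(mm[3]) }
  }
  new_beta_matrix(m, mu = mu, sigma = sigma)
}
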