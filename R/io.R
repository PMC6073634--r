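#' Read and write traces as tidy delimited tables
#'
#' Traces are stored long-format (`generation`, `time`, `compound`, `count`)
#' with a `#`-prefixed header block carrying the parameter snapshot and
#' seed, so every output file is self-describing.
#'
#' @param trace A [run_trace()] result.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `gard_trace` (without the beta matrix — re-attach parameters via
#'   [gard_params()] if further simulation is needed).
#' @export
write_trace <- function(trace, path) {
  p <- trace$params
  meta <- c(
    sprintf("# gardsim trace n_types=%d n_max=%d n_min=%d", p$n_types,
            p$n_max, p$n_min),
    sprintf("# k_f=%s k_b=%s rho=%s", p$k_f[1], p$k_b[1], p$rho[1]),
    sprintf("# beta_mu=%g beta_sigma=%g seed=%s", attr(p$beta, "mu"),
            attr(p$beta, "sigma"),
            if (is.null(trace$seed)) "NA" else trace$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(tidy(trace)), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(textConnection(body))
  ngen <- max(df$generation)
  ng <- max(df$compound)
  comp <- matrix(0L, ngen, ng)
  comp[cbind(df$generation, df$compound)] <- df$count
  time <- df$time[!duplicated(df$generation)][order(unique(df$generation))]
  meta <- lines[startsWith(lines, "#")]
  nmax <- sum(comp[1, ])
  params <- list(n_types = ng, n_max = nmax, n_min = nmax %/% 2L,
                 meta = meta)
  new_gard_trace(comp, time, params)
}

#' Read and write run configurations
#'
#' YAML configurations with an explicit `seed` field drive the command-line
#' interface and make runs reproducible from a single file.
#'
#' @param config A named list.
#' @param path File path.
#' @return `read_config` returns the named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# build gard_params from a flat config list
params_from_config <- function(config) {
  ng <- config$n_types %||% 100L
  beta <- if (!is.null(config$beta_file)) {
    read_beta(config$beta_file)
  } else {
    sample_beta(ng, mu = config$mu %||% -4, sigma = config$sigma %||% 4,
                seed = config$beta_seed %||% config$seed)
  }
  gard_params(beta,
              n_max = config$n_max %||% nrow(beta),
              n_min = config$n_min %||% ((config$n_max %||% nrow(beta)) / 2),
              k_f = config$k_f %||% 1e-2, k_b = config$k_b %||% 1e-5,
              rho = config$rho %||% 1e-2,
              supply = config$supply %||% "infinite",
              budget = config$budget,
              fission = config$fission %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
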