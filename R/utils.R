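#' @useDynLib factorialMR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pnorm qnorm rbinom rexp rnorm runif sd var setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

MERSENNE31 <- 2147483647

#' Derive a reproducible substream seed from a master seed and a label
#'
#' One master seed drives a whole pipeline run; each stochastic component
#' (genotypes per score, covariates, biomarkers, survival per outcome,
#' simulation replicates) draws from its own substream so components can be
#' re-generated independently without disturbing one another. The substream
#' seed is a deterministic 31-bit hash of (seed, label), safe for
#' [set.seed()] on 32-bit R integers.
#'
#' @param seed master seed, a single integer.
#' @param label character scalar naming the component.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% MERSENNE31
  # mix with a large odd multiplier; doubles are exact well past 2^52 here
  as.integer((((seed %% MERSENNE31) * 48271) %% MERSENNE31 + h) %% MERSENNE31)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x >= 1))
    stop2(what, " must lie strictly in (0, 1)")
  invisible(x)
}

# FNV-1a hash of a character vector, as a hex string; used for run manifests.
fnv1a_hex <- function(lines) {
  h <- 2166136261
  for (b in utf8ToInt(paste(lines, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Serialize an R list to JSON preserving full double precision
#'
#' Numbers are written with 17 significant digits so that reading the file
#' back reproduces every IEEE double bit-for-bit; this underpins the
#' ground-truth sidecar round-trip guarantee.
#'
#' @param x a list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_exact <- function(x, path) {
  writeLines(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}
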