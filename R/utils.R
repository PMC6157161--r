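#' Inverse logit
#'
#' @param x numeric vector.
#' @return expit(x) = 1 / (1 + exp(-x)).
#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

#' Logit
#' @param p probabilities in (0, 1).
#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' A single master seed spawns named substreams (genotypes, phenotypes,
#' missingness, replicate indices) so that changing one scenario dimension
#' does not perturb the random draws of another.  The derivation is a small
#' deterministic integer hash kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @param index optional integer (e.g. replicate number) folded in.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.double(index)) %% m
  as.integer(h %% (m - 2) + 1)
}

# formats a numeric for TSV output at 6 significant digits, NA -> "NA"
format_num6 <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
  out
}

# simple timestamped logger; per-variant chatter only at level "debug"
ql_log <- function(level, msg, verbose = getOption("qltdt.verbose", "info")) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[verbose]]) {
    message(sprintf("[%s] %s", toupper(level), msg))
  }
  invisible(NULL)
}
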