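# Internal helpers: error classes, seed substreams, validation.

config_error <- function(msg) abort(msg, class = "imscore_config_error")
missing_data_error <- function(msg) abort(msg, class = "imscore_missing_data_error")
validation_error <- function(msg) abort(msg, class = "imscore_validation_error")
placement_error <- function(msg) abort(msg, class = "imscore_placement_error")
geometry_error <- function(msg) abort(msg, class = "imscore_geometry_error")
data_error <- function(msg) abort(msg, class = "imscore_data_error")
reconstruction_error <- function(msg) abort(msg, class = "imscore_reconstruction_error")

check_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    config_error(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(p)
}

#' Stable 31-bit hash of a character string
#'
#' Used to derive per-patient random substreams from a master seed, so that
#' enlarging a cohort does not reshuffle the patients already present.
#' @noRd
stable_hash <- function(s) {
  h <- 0
  for (x in utf8ToInt(s)) h <- (h * 31 + x) %% 2147483647
  h
}

# Lehmer scrambling rounds: nearby (master, id) combinations must map to
# well-separated seeds, since Mersenne-Twister initialisation does not
# decorrelate near-identical seeds. Exact in double arithmetic
# (2^31 * 48271 < 2^53).
scramble31 <- function(x) {
  for (i in 1:4) x <- (x * 48271 + 11) %% 2147483647
  x
}

substream_seed <- function(master_seed, id, stage) {
  h <- (scramble31(as.numeric(master_seed) %% 2147483647) +
          stable_hash(paste0(stage, "/", id))) %% 2147483647
  scramble31(h)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed_local <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Truncated-normal draw via inverse CDF; lower truncation only.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}
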