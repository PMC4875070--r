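# Internal helpers shared across modules.

# Truncated-normal draws via inverse-CDF so a single runif stream drives the
# generator (keeps simulate_cohort() reproducible across platforms).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Write through a temp file in the same directory, then rename: readers never
# observe a half-written artifact.
write_atomic <- function(path, write_fn) {
  tmp <- file.path(
    dirname(path),
    paste0(".", basename(path), ".tmp", Sys.getpid())
  )
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

stop_format <- function(msg) {
  abort(msg, class = "peakrpe_format_error")
}

stop_insufficient <- function(msg) {
  abort(msg, class = "peakrpe_insufficient_data")
}

# Normalise user-supplied scale labels to the canonical "CERT"/"EP".
match_scale <- function(scale) {
  s <- toupper(scale[[1]])
  if (!s %in% c("CERT", "EP")) {
    abort("`scale` must be \"CERT\" or \"EP\".")
  }
  s
}
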