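# One global seed per run, hashed into a named sub-stream per stage, so that
# adding draws to one stage never perturbs another.

substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.double(seed) %% 65011 + 1) * 30011 + h) %% 2147483647L
}

with_substream <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  force(code)
}

# truncated-normal draws by rejection; bounds far in the bulk, so cheap
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    idx <- which(out <= lower)
    if (length(idx) == 0) break
    out[idx] <- rnorm(length(idx), mean, sd)
  }
  out[out <= lower] <- lower + abs(out[out <= lower] - lower)
  out
}
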