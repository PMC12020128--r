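# Deterministic seed substreams. A single user seed is combined with string
# tags (module, purpose, index) so that module-level reruns reproduce the
# corresponding slice of a full-pipeline run without sharing RNG state.

#' Derive a reproducible sub-seed from a base seed and tags
#'
#' @param seed integer base seed
#' @param ... tags (strings or integers) naming the substream
#' @return an integer in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    for (code in utf8ToInt(paste0("|", as.character(tag)))) {
      h <- (h * 131 + code) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
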