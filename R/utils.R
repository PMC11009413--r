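#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed and a label
#'
#' One master seed spawns independent substreams per labelled task (e.g.
#' per assay/condition/replicate), so adding replicates never perturbs the
#' draws of existing ones. The hash is a plain polynomial rolling hash over
#' the label's bytes, folded with the master seed below 2^31.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483629 # prime below 2^31; keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a seed derived from (seed, label), restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, label, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

# stop() with sprintf formatting and no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
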