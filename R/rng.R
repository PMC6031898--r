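#' Derive a per-stream seed from a master seed
#'
#' Each (task, session) pair gets its own random stream so that adding or
#' reordering tasks never perturbs another task's schedule. The stream seed
#' is a stable polynomial hash of the stream id combined with the master
#' seed, reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param master_seed Non-negative integer master seed.
#' @param stream_id Character scalar naming the stream, e.g. `"abm/s01"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stream_seed(42, "abm/s01")
#' @export
stream_seed <- function(master_seed, stream_id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stream_id), length(stream_id) == 1L)
  m <- 2147483647  # 2^31 - 1; 31 * 2^31 < 2^53 so the update is exact
  h <- 0
  for (b in utf8ToInt(stream_id)) h <- (h * 31 + b) %% m
  as.integer((h + abs(as.double(master_seed))) %% m)
}

# Evaluate `expr` under a seeded RNG, restoring the caller's RNG state.
with_stream_seed <- function(master_seed, stream_id, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(master_seed, stream_id))
  expr
}
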