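# internal helpers

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# numerically stable log(sum(exp(x))) over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x != floor(x)) {
    rlang::abort(paste0("`", name, "` must be a single positive integer"))
  }
}

`%||%` <- rlang::`%||%`
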