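#' @importFrom stats quantile rnorm runif sd var median aov pt qt setNames
#' @importFrom utils count.fields read.delim write.table modifyList
#' @importFrom rlang .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mtoc <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mtocscreen_error")))
}

# Local RNG scope: evaluates expr under a fixed seed without touching the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
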