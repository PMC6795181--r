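#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor var median prcomp phyper p.adjust pnorm rnbinom rnorm
#'   rlnorm runif hclust as.dist cutree sd lm coef
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a root seed and a name
#'
#' All stochastic operations in the pipeline draw their seed from one root
#' seed plus a stage/key name, so adding or re-running a stage never perturbs
#' the randomness of another stage.
#'
#' @param root integer root seed.
#' @param ... character keys identifying the substream (stage, tissue, pair).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  key <- paste(c(format(root, scientific = FALSE), ...), collapse = "/")
  m <- 2147483647
  h <- abs(as.numeric(root)) %% m
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  force(code)
}

cx_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[coexcross] ", ...)
}

# geometric mean over strictly positive values; 0 if any entry is zero
geomean <- function(x) {
  if (any(x <= 0)) return(0)
  exp(mean(log(x)))
}
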