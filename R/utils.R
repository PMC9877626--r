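# Internal helpers: validation, RNG scoping, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never disturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop_config("`%s` must be an H x W x 3 array", arg)
  }
  if (!all(is.finite(img))) stop_config("`%s` contains non-finite values", arg)
  if (min(img) < 0 || max(img) > 1) {
    stop_config("`%s` must have values in [0, 1]", arg)
  }
  invisible(img)
}

assert_gray <- function(x, arg = "gray") {
  if (!is.matrix(x)) stop_config("`%s` must be an H x W matrix", arg)
  if (!all(is.finite(x))) stop_config("`%s` contains non-finite values", arg)
  invisible(x)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_config("`%s` must be a logical H x W matrix", arg)
  }
  invisible(mask)
}
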