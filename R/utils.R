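#' Derive a reproducible child seed from a master seed
#'
#' Counter-based derivation: the master seed is folded with each extra
#' integer key through a multiplicative congruential step modulo 2^31 - 1,
#' so replicates (and stages) get independent, reproducible seeds without
#' consuming the global RNG stream.
#'
#' @param master Integer master seed.
#' @param ... Integer keys (replicate number, stage index, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  keys <- as.double(unlist(list(...)))
  s <- (as.double(master) %% 2147483647) + 1
  for (k in keys) {
    # all intermediates stay below 2^53, so double arithmetic is exact
    s <- (s * 69069 + (k + 1) * 40503) %% 2147483647
    s <- (s * 18000 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

#' Evaluate with a private RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded stages do not perturb each other.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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

stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "clustgauge_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x > 0
}
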