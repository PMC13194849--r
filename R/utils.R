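## small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(structure(class = c("bmk_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_input(...)

## evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## named sub-seed derived from a master seed; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1000003 * as.double(k)) %% 2147483647)
}

## trapezoidal integral of piecewise-linear samples
trapz <- function(t, v) {
  n <- length(t)
  if (n < 2) return(0)
  sum((v[-1] + v[-n]) / 2 * diff(t))
}

## linear interpolation, erroring outside support
interp_lin <- function(t, v, at, what = "time") {
  if (any(at < t[1] - 1e-9) || any(at > t[length(t)] + 1e-9))
    stop_input(what, " outside curve support [", t[1], ", ", t[length(t)], "]")
  approx(t, v, xout = pmin(pmax(at, t[1]), t[length(t)]), ties = "ordered")$y
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
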