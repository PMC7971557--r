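# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  if (x < lower || x > upper)
    stop_field(field, sprintf("must be in [%s, %s]", lower, upper))
  if (!allow_zero && x == 0) stop_field(field, "must be non-zero")
  invisible(x)
}

check_probs <- function(p, field = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_field(field, "all values must lie in [0, 1]")
  invisible(p)
}

# One local RNG stream per generator call: seed explicitly, restore the
# caller's .Random.seed so generators never perturb global state.
with_seed <- function(seed, expr) {
  check_number(seed, "seed", integer = TRUE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# evenly spaced normal quantiles: deterministic draws with the stated mean/SD
spread_normal <- function(n, mean, sd) {
  if (n == 1L) return(mean)
  mean + sd * qnorm(ppoints(n))
}

fmt_sig <- function(x, digits = 6L) {
  ifelse(is.na(x), NA, signif(x, digits))
}
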