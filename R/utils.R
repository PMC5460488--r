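#' Derive a reproducible sub-seed from a master seed and a string tag
#'
#' Streams one master seed to independent per-component seeds (counts, sets,
#' scores, per-set bootstraps) so each component can be regenerated on its own
#' and per-set results do not depend on iteration order.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the component (e.g. a set id).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(tag))) h <- (h * 31 + code) %% m
  out <- ((abs(seed) %% m) * 2654435 + h * 97 + 1) %% m
  as.integer(out + (out == 0))
}

# shared argument checks -------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lower), format(upper)),
         call. = FALSE)
  invisible(x)
}

assert_probability <- function(x, name) assert_scalar_number(x, name, 0, 1)

# Spearman correlation via midranks; NA if either vector is constant.
spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}
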