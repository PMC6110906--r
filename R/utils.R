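stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (strict && x <= lower) stopf("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stopf("`%s` must be >= %g", name, lower)
  invisible(x)
}

# population (1/n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# standardize to mean 0, population sd 1; returns x unchanged if constant
standardize <- function(x) {
  s <- pop_sd(x)
  if (s < 1e-12) return(x - mean(x))
  (x - mean(x)) / s
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)
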