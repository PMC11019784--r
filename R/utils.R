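## Internal helpers shared across modules.

PROTON_MASS_DA <- 1.007276

#' @importFrom methods is new validObject
#' @importFrom stats residuals coef lm prcomp pt rlnorm rnorm runif sd var
#' @importFrom utils read.delim write.table
#' @importFrom tools md5sum
NULL

## Derive a per-stage RNG seed from the master seed so that independent
## stages (design, growth, features) draw from non-overlapping streams.
## Kept strictly below .Machine$integer.max.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Multiplicative log-normal noise factors with unit mean and the requested
## coefficient of variation. cv = 0 is the exact noiseless limit.
lognormalNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Consistent error style for tabular input validation: always names the
## file, row and field so malformed inputs are locatable.
ioStop <- function(file, row, field, msg) {
  stop(sprintf("%s [file '%s', row %s, field '%s']",
               msg, file, paste(row, collapse = ","), field),
       call. = FALSE)
}

assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

assertFraction <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}
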