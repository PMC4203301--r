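# Internal numeric helpers shared across modules.

invlogit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean +/- 1.96 * SE across a vector; returns c(mean, lo, hi)
mean_ci95 <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
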