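#' @keywords internal
"_PACKAGE"

## Deterministic per-call RNG streams: every generator draws from a seed
## derived from (config seed, call label, counter), so adding a generator
## call never perturbs the stream of another.

# polynomial string hash folded into [0, 2^31 - 2]
.hash_label <- function(label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  h
}

.stream_seed <- function(seed, label, counter = 0L) {
  as.integer((.hash_label(label) + as.numeric(seed) * 10007 +
                as.numeric(counter) * 97) %% 2147483647)
}

.with_stream <- function(cfg, label, expr, counter = 0L) {
  withr::with_seed(.stream_seed(cfg$seed, label, counter), expr)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample standard deviation / mean; NA when undefined
.cv <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}
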