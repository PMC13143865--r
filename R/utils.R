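`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "records") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

# Derive a 32-bit sub-seed from a base seed and a stream index.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
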