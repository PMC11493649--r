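#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm qnorm pt qt lm coef resid cooks.distance rnorm runif setNames sd median p.adjust
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed condition so callers can distinguish failure modes programmatically
mr_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mrscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) mr_abort(class, msg, ...)
  invisible(TRUE)
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0

# deterministic TSV writer shared by all exporters (byte-stable across runs)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
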