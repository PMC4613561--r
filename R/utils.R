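#' @keywords internal
"_PACKAGE"

# Truncate toward zero at `digits` decimals (display convention for critical
# correlation cutoffs; rounding would overstate the threshold).
trunc_digits <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# Coerce a two-level grouping to 0/1, keeping level names.
# `positive` names the class coded 1 (the "case" class).
encode_binary <- function(y, positive = NULL) {
  y <- as.character(y)
  lev <- unique(y)
  assert_that(length(lev) == 2L, "y must contain exactly two classes")
  if (is.null(positive)) positive <- sort(lev)[2L]
  assert_that(positive %in% lev, "positive class not present in y")
  negative <- setdiff(lev, positive)
  structure(as.numeric(y == positive),
            levels = c(negative, positive), positive = positive)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
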