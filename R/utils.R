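`%||%` <- function(a, b) if (is.null(a)) b else a

.check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65521 * 7919 + as.numeric(k) * 104729 + 17) %%
               2147483647)
}

.with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# fread from plain or gzip-compressed text; gzfile() reads both
.fread_any <- function(path, ...) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  data.table::fread(text = readLines(con, warn = FALSE), ...)
}

#' Inclusive length of a 1-based genomic interval
#'
#' Both ends are part of the interval, matching VCF/GFF3 coordinate
#' conventions: an interval covering a single base has length 1.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Integer number of bases covered.
#' @examples
#' interval_length(16366702, 16366705) # a 4-bp deletion interval
#' @export
interval_length <- function(start, end) {
  .check(is.numeric(start) && is.numeric(end), "start and end must be numeric")
  .check(all(start <= end), "interval start must not exceed end")
  as.integer(end - start + 1)
}
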