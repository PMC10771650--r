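#' Format a fraction as a whole-number percentage
#'
#' Report helper used throughout the package's summary tables: the proportion
#' `n/d` expressed on the 0-100 scale, rounded to `digits` decimals.
#'
#' @param n Numerator (count).
#' @param d Denominator (count, > 0).
#' @param digits Decimals kept after rounding (default 0).
#' @return Numeric percentage.
#' @examples
#' percent_of(233, 378) # 62
#' @export
percent_of <- function(n, d, digits = 0) {
  stopifnot(is.numeric(n), is.numeric(d), all(d > 0))
  round(100 * n / d, digits)
}

#' @rdname percent_of
#' @return `format_percent()` returns the same value as a "62%"-style string.
#' @export
format_percent <- function(n, d, digits = 0) {
  paste0(percent_of(n, d, digits), "%")
}

## 0-based half-open intervals are the internal coordinate convention; these
## helpers move between that convention and the 1-based IRanges world.
iv_to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

iranges_to_iv <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

## Total intersection length (bp) of two 0-based half-open interval sets.
intersect_bp <- function(a_start, a_end, b_start, b_end) {
  if (length(a_start) == 0L || length(b_start) == 0L) return(0L)
  ia <- IRanges::reduce(iv_to_iranges(a_start, a_end))
  ib <- IRanges::reduce(iv_to_iranges(b_start, b_end))
  sum(BiocGenerics::width(IRanges::intersect(ia, ib)))
}

## Deterministic stream seeds derived from one master seed, one per named
## output, so adding a stream never perturbs the others. Kept < 2^31.
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- utf8ToInt(stream)
  (as.integer(seed) %% 1000003L) * 1009L + sum(h * seq_along(h)) %% 99991L
}

## Short stable hash of an R object (config provenance in report headers).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x, give.attr = FALSE)), f)
  substr(unname(tools::md5sum(f)), 1, 8)
}

write_tsv_report <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
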