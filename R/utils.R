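`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical key string for a variant
#'
#' Variants are keyed as `chrom:pos:ref:alt` throughout the package; the key
#' is the join column between site tables, genotype matrices and annotation
#' tables.
#'
#' @param chrom,pos,ref,alt vectors of equal length (or a data frame with
#'   those columns passed as `chrom`).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L

#' @keywords internal
assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# Merge 1-based inclusive intervals; overlapping OR abutting (gap 0) merge.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

num_or_na <- function(x) {
  x[x %in% c("", ".", "-", "NA")] <- NA
  suppressWarnings(as.numeric(x))
}

chr_or_na <- function(x) {
  x[x %in% c("", ".", "-", "NA")] <- NA
  x
}
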