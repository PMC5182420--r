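#' Biallelic SNP genotype matrix
#'
#' Container for chip-style biallelic genotype calls over an ordered marker
#' map. Calls are alternate-allele dosages in \{0, 1, 2\} with `NA` for
#' missing; markers are rows, samples are columns.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp).
#'   Positions must be strictly increasing within each chromosome.
#' @param samples Character vector of unique sample ids.
#' @param calls Integer matrix, `nrow(markers)` x `length(samples)`, values
#'   in \{0, 1, 2, NA\}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, samples, calls) {
  .check(is.data.frame(markers) &&
           all(c("id", "chrom", "pos") %in% names(markers)),
         "markers must be a data.frame with columns id, chrom, pos")
  markers <- data.frame(id = as.character(markers$id),
                        chrom = as.character(markers$chrom),
                        pos = as.integer(markers$pos),
                        stringsAsFactors = FALSE)
  samples <- as.character(samples)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  .check(!anyDuplicated(markers$id), "duplicate marker ids")
  .check(!anyDuplicated(samples), "duplicate sample ids")
  .check(all(markers$pos >= 1L), "marker positions must be 1-based (>= 1)")
  .check(nrow(calls) == nrow(markers) && ncol(calls) == length(samples),
         "call matrix dimensions do not match markers x samples")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  .check(!any(bad), "genotype calls must be dosages 0/1/2 or missing")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    .check(all(diff(p) > 0),
           "marker positions not strictly increasing on chromosome %s", ch)
  }
  rownames(calls) <- markers$id
  colnames(calls) <- samples
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples on %d chromosome(s)\n",
              nrow(x$markers), length(x$samples),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' Write a genotype matrix to the tab-delimited dialect
#'
#' One row per marker: `chrom`, `pos`, `id`, then one column per sample with
#' dosage calls 0/1/2 and `.` for missing. Files ending in `.gz` are
#' gzip-compressed.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(x, path) {
  .check(inherits(x, "genotype_matrix"), "x must be a genotype_matrix")
  calls <- matrix(as.character(x$calls), nrow = nrow(x$calls))
  calls[is.na(calls)] <- "."
  out <- data.table::data.table(chrom = x$markers$chrom, pos = x$markers$pos,
                                id = x$markers$id)
  out <- cbind(out, data.table::as.data.table(calls))
  data.table::setnames(out, c("chrom", "pos", "id", x$samples))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from the tab-delimited dialect
#'
#' Strict reader for the format written by [write_genotype_matrix()]:
#' malformed rows, 0-based positions, unknown call symbols, duplicate marker
#' ids and non-monotone positions are rejected with the offending line
#' number. Plain and gzip-compressed files are accepted.
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  dt <- .fread_any(path, sep = "\t", colClasses = "character",
                   header = TRUE, na.strings = NULL)
  .check(ncol(dt) >= 4, "genotype file must have chrom, pos, id + >=1 sample")
  .check(identical(names(dt)[1:3], c("chrom", "pos", "id")),
         "genotype file header must start with: chrom, pos, id")
  samples <- names(dt)[-(1:3)]
  pos_chr <- dt[["pos"]]
  pos <- suppressWarnings(as.integer(pos_chr))
  bad <- which(is.na(pos) | pos < 1L)
  .check(length(bad) == 0,
         "invalid marker position '%s' at line %d",
         if (length(bad)) pos_chr[bad[1]] else "", bad[1] + 1L)
  ids <- dt[["id"]]
  dup <- which(duplicated(ids))
  .check(length(dup) == 0, "duplicate marker id '%s' at line %d",
         if (length(dup)) ids[dup[1]] else "", dup[1] + 1L)
  chrom <- dt[["chrom"]]
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nm <- idx[which(diff(pos[idx]) <= 0) + 1L]
    .check(length(nm) == 0,
           "non-monotone marker position at line %d (chromosome %s)",
           nm[1] + 1L, ch)
  }
  calls_chr <- as.matrix(dt[, -(1:3), with = FALSE])
  ok <- calls_chr %in% c("0", "1", "2", ".")
  if (!all(ok)) {
    first <- which(!ok)[1]
    row <- (first - 1L) %% nrow(calls_chr) + 1L
    stop(sprintf("unknown genotype call symbol '%s' at line %d",
                 calls_chr[first], row + 1L), call. = FALSE)
  }
  calls <- suppressWarnings(matrix(as.integer(calls_chr),
                                   nrow = nrow(calls_chr)))
  genotype_matrix(data.frame(id = ids, chrom = chrom, pos = pos),
                  samples, calls)
}
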