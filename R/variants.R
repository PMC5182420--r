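#' Multi-sample variant set
#'
#' In-memory representation of a multi-sample VCF: one row per record with
#' `chrom`, `pos` (1-based), `id`, `ref`, `alt` (comma-separated for
#' multi-allelic records, which are kept intact), plus an unphased genotype
#' matrix of "a/b" allele-index strings ("./." for missing). Phase
#' separators are accepted on input and discarded.
#'
#' @param records data.frame with columns chrom, pos, id, ref, alt.
#' @param gt Character matrix, `nrow(records)` x samples, entries like
#'   "0/1" or "./.".
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(records, gt) {
  .check(is.data.frame(records) &&
           all(c("chrom", "pos", "ref", "alt") %in% names(records)),
         "records must have columns chrom, pos, ref, alt")
  records <- data.frame(chrom = as.character(records$chrom),
                        pos = as.integer(records$pos),
                        id = as.character(records$id %||%
                                            rep(".", nrow(records))),
                        ref = toupper(as.character(records$ref)),
                        alt = toupper(as.character(records$alt)),
                        stringsAsFactors = FALSE)
  gt <- as.matrix(gt)
  .check(nrow(gt) == nrow(records), "genotype rows do not match records")
  .check(!is.null(colnames(gt)) && !anyDuplicated(colnames(gt)),
         "genotype matrix needs unique sample column names")
  if (nrow(records)) {
    .check(all(records$pos >= 1L), "positions must be >= 1")
    .check(all(nchar(records$ref) >= 1L), "reference alleles must be non-empty")
    .check(all(grepl("^[ACGT]+$", records$ref)),
           "reference alleles must be A/C/G/T")
    alts <- unlist(strsplit(records$alt, ",", fixed = TRUE))
    .check(all(grepl("^[ACGT]+$", alts)),
           "alternate alleles must be A/C/G/T")
    gt <- matrix(.normalise_gt(gt), nrow = nrow(gt),
                 dimnames = list(NULL, colnames(gt)))
  } else {
    rownames(gt) <- NULL
  }
  structure(list(records = records, gt = gt,
                 samples = colnames(gt)), class = "variant_set")
}

.normalise_gt <- function(g) {
  g <- gsub("|", "/", as.character(g), fixed = TRUE)
  g[is.na(g) | g == "." | g == "./."] <- "./."
  .check(all(grepl("^(\\.|[0-9]+)/(\\.|[0-9]+)$", g)),
         "malformed genotype string")
  g
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d record(s) x %d sample(s)\n",
              nrow(x$records), length(x$samples)))
  invisible(x)
}

# allele-index pair matrices (NA = missing allele)
.gt_alleles <- function(vs) {
  sp <- strsplit(as.vector(vs$gt), "/", fixed = TRUE)
  a1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2L)))
  dim(a1) <- dim(vs$gt); dim(a2) <- dim(vs$gt)
  dimnames(a1) <- dimnames(vs$gt); dimnames(a2) <- dimnames(vs$gt)
  list(a1 = a1, a2 = a2)
}

#' Read variants from a VCF 4.2 file
#'
#' Records are returned in file order; multi-allelic records are preserved;
#' genotype missing codes and phase separators are honoured. Plain and
#' gzip-compressed files are accepted.
#'
#' @param path VCF file.
#' @param sample_subset Optional character vector restricting (and
#'   ordering) the genotype columns; unknown samples are an error.
#' @return A [variant_set()].
#' @export
read_variants <- function(path, sample_subset = NULL) {
  .check(file.exists(path), "no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    .check(length(missing) == 0, "unknown sample(s) in subset: %s",
           paste(missing, collapse = ", "))
    samples <- sample_subset
  }
  if (n == 0) {
    gt <- matrix(character(0), nrow = 0, ncol = length(samples),
                 dimnames = list(NULL, samples))
    return(variant_set(data.frame(chrom = character(0), pos = integer(0),
                                  id = character(0), ref = character(0),
                                  alt = character(0)), gt))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  colnames(gt) <- colnames(v@gt)[-1]
  gt <- gt[, samples, drop = FALSE]
  variant_set(data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE),
              gt)
}

#' Write a variant set as VCF 4.2
#'
#' Output is gzip-compressed (use a `.vcf.gz` file name); all package
#' readers accept gzipped input.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path, contigs = NULL) {
  .check(inherits(vs, "variant_set"), "vs must be a variant_set")
  meta <- c("##fileformat=VCFv4.2",
            "##source=rohmap",
            if (!is.null(contigs))
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  n <- nrow(vs$records)
  fix <- cbind(CHROM = vs$records$chrom, POS = as.character(vs$records$pos),
               ID = vs$records$id, REF = vs$records$ref,
               ALT = vs$records$alt, QUAL = rep(".", n),
               FILTER = rep("PASS", n), INFO = rep(".", n))
  gt <- cbind(FORMAT = rep("GT", n), vs$gt)
  colnames(gt) <- c("FORMAT", vs$samples)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
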