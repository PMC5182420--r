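#' Transcript model
#'
#' Exon/CDS structure of a single transcript on a reference chromosome.
#' Exons and CDS intervals are stored in genomic ascending order with
#' 1-based inclusive coordinates; `strand` says how they are read.
#'
#' @param tx_id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns `start`, `end` (ordered,
#'   non-overlapping).
#' @param cds data.frame with columns `start`, `end`; every CDS interval must
#'   lie inside an exon.
#' @param gene_id Optional gene identifier.
#' @param complete If TRUE (default) the total CDS length must be a multiple
#'   of 3.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, chrom, strand, exons, cds,
                             gene_id = tx_id, complete = TRUE) {
  .check(strand %in% c("+", "-"), "strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  .check(all(exons$start <= exons$end) && all(exons$start >= 1),
         "malformed exon intervals")
  .check(all(cds$start <= cds$end), "malformed CDS intervals")
  if (nrow(exons) > 1)
    .check(all(exons$start[-1] > exons$end[-nrow(exons)]),
           "exons must be non-overlapping and ordered")
  for (i in seq_len(nrow(cds))) {
    inside <- any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
    .check(inside, "CDS interval %d-%d not contained in an exon",
           cds$start[i], cds$end[i])
  }
  cds_len <- sum(cds$end - cds$start + 1L)
  if (complete)
    .check(cds_len %% 3 == 0,
           "CDS length (%d) is not a multiple of 3", cds_len)
  structure(list(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds,
                 cds_length = cds_len),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s): %s:%d-%d [%s], %d exons, CDS %d bp\n",
              x$tx_id, x$gene_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

# CDS pieces in transcription order with cumulative CDS offsets.
.cds_pieces <- function(model) {
  p <- model$cds
  if (model$strand == "-") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  len <- p$end - p$start + 1L
  p$cds_start <- cumsum(c(0L, len[-length(len)])) + 1L
  p$cds_end <- cumsum(len)
  p
}

# 1-based CDS coordinate of genomic position g, or NA if non-coding.
genomic_to_cds <- function(model, g) {
  p <- .cds_pieces(model)
  hit <- which(p$start <= g & p$end >= g)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1]
  if (model$strand == "+") p$cds_start[i] + (g - p$start[i])
  else p$cds_start[i] + (p$end[i] - g)
}

# Genomic position of 1-based CDS coordinate idx.
cds_to_genomic <- function(model, idx) {
  p <- .cds_pieces(model)
  hit <- which(p$cds_start <= idx & p$cds_end >= idx)
  .check(length(hit) > 0, "CDS coordinate %d out of range", idx)
  i <- hit[1]
  if (model$strand == "+") p$start[i] + (idx - p$cds_start[i])
  else p$end[i] - (idx - p$cds_start[i])
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the CDS intervals in transcription order; minus-strand
#' models are reverse complemented. The result has length a multiple of 3
#' for complete models.
#'
#' @param model A [transcript_model()].
#' @param reference A [reference_bundle()] or named `DNAStringSet`.
#' @return Character string with the coding sequence.
#' @export
extract_cds <- function(model, reference) {
  seqs <- if (inherits(reference, "reference_bundle")) reference$sequences
          else reference
  .check(model$chrom %in% names(seqs),
         "chromosome %s absent from reference", model$chrom)
  chrseq <- seqs[[model$chrom]]
  .check(max(model$cds$end) <= length(chrseq) && min(model$cds$start) >= 1,
         "transcript %s has coordinates outside chromosome %s",
         model$tx_id, model$chrom)
  parts <- vapply(seq_len(nrow(model$cds)), function(i) {
    as.character(Biostrings::subseq(chrseq, model$cds$start[i],
                                    model$cds$end[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Translate a coding string with the standard nuclear code; "*" = stop.
# Trailing incomplete codons are dropped.
.translate_str <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return(character(0))
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Write transcript models to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with ID/Parent attributes.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path (`.gff3`, optionally `.gz`).
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(models, path) {
  if (inherits(models, "transcript_model")) models <- list(models)
  grl <- lapply(models, function(m) {
    n_ex <- nrow(m$exons)
    n_cds <- nrow(m$cds)
    gr <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(
        start = c(min(m$exons$start), min(m$exons$start),
                  m$exons$start, m$cds$start),
        end = c(max(m$exons$end), max(m$exons$end),
                m$exons$end, m$cds$end)),
      strand = m$strand)
    gr$type <- c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds))
    gr$ID <- c(m$gene_id, m$tx_id, rep(NA_character_, n_ex + n_cds))
    gr$Parent <- c(NA_character_, m$gene_id,
                   rep(m$tx_id, n_ex + n_cds))
    gr$phase <- NA_integer_
    if (n_cds > 0) {
      p <- .cds_pieces(m)
      phase <- (3L - (p$cds_start - 1L) %% 3L) %% 3L
      # map phases back to genomic-ascending CDS order
      ord <- if (m$strand == "-") rev(seq_len(n_cds)) else seq_len(n_cds)
      gr$phase[2L + n_ex + ord] <- phase
    }
    gr
  })
  grl <- unname(grl)
  gr <- if (length(grl) == 1) grl[[1]] else do.call(c, grl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Groups exon and CDS features by their mRNA parent and validates each
#' model (ordered non-overlapping exons, CDS contained in exons, complete
#' CDS a multiple of 3). Minus-strand exon order is normalised to genomic
#' ascending with the strand flag retained.
#'
#' @param path GFF3 file (plain or gzipped).
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  .check(length(mrna_idx) > 0, "no mRNA/transcript features in %s", path)
  models <- list()
  for (i in mrna_idx) {
    tx_id <- as.character(gr$ID[i])
    gene_id <- if (!is.na(parents[i])) parents[i] else tx_id
    kids <- which(parents == tx_id)
    ex <- kids[type[kids] == "exon"]
    cd <- kids[type[kids] == "CDS"]
    .check(length(ex) > 0, "transcript %s has no exons", tx_id)
    exons <- data.frame(start = GenomicRanges::start(gr)[ex],
                        end = GenomicRanges::end(gr)[ex])
    cds <- data.frame(start = GenomicRanges::start(gr)[cd],
                      end = GenomicRanges::end(gr)[cd])
    models[[tx_id]] <- transcript_model(
      tx_id, as.character(GenomicRanges::seqnames(gr)[i]),
      as.character(GenomicRanges::strand(gr)[i]), exons, cds,
      gene_id = gene_id)
  }
  models
}

#' Read a reference FASTA into a DNAStringSet
#' @param path FASTA file (plain or gzipped).
#' @return A named `DNAStringSet`.
#' @export
read_reference <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
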