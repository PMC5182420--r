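#' Simulation configuration for the gene-drop generator
#'
#' Defines the miniature genome the simulator works on: autosome lengths,
#' chip-like marker counts and spacing, the causal locus, founder haplotype
#' diversity, the Haldane recombination map (uniform cM/Mb) and per-call
#' missingness. Defaults describe a scaled-down study: 4 autosomes totalling
#' 15 Mb with 250 markers each, a causal locus inside the toy transcript on
#' chr2, and complete (post-QC-like) genotype calls.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`.
#' @param n_markers Markers per chromosome (scalar or per-chromosome vector).
#' @param marker_spacing "random" (sorted uniform draws) or "uniform".
#' @param causal_chrom,causal_pos Causal locus; defaults to the engineered
#'   frameshift site of the default transcript.
#' @param n_founder_haplotypes Size of the distinct founder-haplotype pool;
#'   `NULL` (default) gives every founder homologue its own haplotype.
#' @param cm_per_mb Uniform genetic map density (centimorgan per megabase).
#' @param missing_rate Per-call missingness fraction in `[0, 1]`.
#' @param maf_range Range of marker population allele frequencies used to
#'   draw founder haplotype alleles.
#' @param seed Integer seed used for marker map and founder haplotypes.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(chromosomes = data.frame(
                         chrom = c("chr1", "chr2", "chr3", "chr4"),
                         length_bp = c(4.5e6, 4e6, 3.5e6, 3e6)),
                       n_markers = 250,
                       marker_spacing = c("random", "uniform"),
                       causal_chrom = "chr2",
                       causal_pos = NULL,
                       n_founder_haplotypes = NULL,
                       cm_per_mb = 1,
                       missing_rate = 0,
                       maf_range = c(0.15, 0.85),
                       seed = 1) {
  marker_spacing <- match.arg(marker_spacing)
  .check(is.data.frame(chromosomes) &&
           all(c("chrom", "length_bp") %in% names(chromosomes)),
         "chromosomes must have columns chrom, length_bp")
  .check(missing_rate >= 0 && missing_rate <= 1,
         "missing_rate must be in [0, 1]")
  .check(cm_per_mb >= 0, "cm_per_mb must be >= 0")
  if (is.null(causal_pos)) {
    m <- transcript_spec_model(default_transcript_spec(chrom = causal_chrom))
    causal_pos <- cds_to_genomic(m, .engineered_site()$anchor_cds)
  }
  .check(causal_chrom %in% chromosomes$chrom,
         "causal chromosome %s is not a declared chromosome", causal_chrom)
  len <- chromosomes$length_bp[chromosomes$chrom == causal_chrom]
  .check(causal_pos >= 1 && causal_pos <= len,
         "causal position %d outside chromosome %s (length %d)",
         causal_pos, causal_chrom, len)
  n_markers <- rep_len(as.integer(n_markers), nrow(chromosomes))
  structure(list(chromosomes = data.frame(
                   chrom = as.character(chromosomes$chrom),
                   length_bp = as.integer(chromosomes$length_bp)),
                 n_markers = n_markers, marker_spacing = marker_spacing,
                 causal_chrom = causal_chrom,
                 causal_pos = as.integer(causal_pos),
                 n_founder_haplotypes = n_founder_haplotypes,
                 cm_per_mb = cm_per_mb, missing_rate = missing_rate,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic transcript specification
#'
#' Describes the exon/intron geometry of a synthetic transcript from which
#' [make_reference_bundle()] builds a concrete model and sequence.
#'
#' @param tx_id,gene_id Identifiers.
#' @param chrom Chromosome.
#' @param strand "+" or "-".
#' @param tx_start Genomic start (1-based) of the transcript.
#' @param exon_lengths Integer vector of exonic lengths in transcription
#'   order.
#' @param intron_lengths Intron lengths (one fewer than exons).
#' @param utr5_len,utr3_len Untranslated lengths at the transcript ends; the
#'   remainder is CDS and must be a multiple of 3.
#' @return Object of class `transcript_spec`.
#' @export
transcript_spec <- function(tx_id, gene_id, chrom, strand, tx_start,
                            exon_lengths, intron_lengths,
                            utr5_len = 0, utr3_len = 0) {
  .check(length(intron_lengths) == length(exon_lengths) - 1,
         "need one fewer intron than exons")
  .check(all(exon_lengths >= 1) && all(intron_lengths >= 1),
         "exon and intron lengths must be positive")
  cds_len <- sum(exon_lengths) - utr5_len - utr3_len
  .check(cds_len > 0, "UTRs leave no CDS")
  .check(cds_len %% 3 == 0, "CDS length (%d) is not a multiple of 3", cds_len)
  structure(list(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
                 strand = strand, tx_start = as.integer(tx_start),
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 cds_len = as.integer(cds_len)),
            class = "transcript_spec")
}

#' Default 18-exon toy transcript
#'
#' Mirrors, at toy scale, the geometry of a multi-exon kinase gene: 18
#' exons, a 471-codon protein (1416 bp CDS including the stop codon) and a
#' fourth exon large enough to host a frameshift deletion around codon 96.
#'
#' @param chrom Chromosome the transcript sits on.
#' @param tx_start Genomic start.
#' @param strand "+" or "-".
#' @return A [transcript_spec()].
#' @export
default_transcript_spec <- function(chrom = "chr2", tx_start = 2000000L,
                                    strand = "+") {
  transcript_spec(
    tx_id = "SGK3TOY.1", gene_id = "SGK3TOY", chrom = chrom, strand = strand,
    tx_start = tx_start,
    exon_lengths = c(150L, 90L, 90L, 120L, rep(73L, 13L), 157L),
    intron_lengths = rep_len(c(512L, 733L, 401L, 650L, 298L, 555L), 17L),
    utr5_len = 60L, utr3_len = 80L)
}

#' Build the concrete transcript model from a specification
#' @param spec A [transcript_spec()].
#' @return A [transcript_model()].
#' @export
transcript_spec_model <- function(spec) {
  .check(inherits(spec, "transcript_spec"), "spec must be a transcript_spec")
  n <- length(spec$exon_lengths)
  starts <- integer(n); ends <- integer(n)
  pos <- spec$tx_start
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + spec$exon_lengths[i] - 1L
    pos <- ends[i] + (if (i < n) spec$intron_lengths[i] else 0L) + 1L
  }
  # exons in transcription order
  ex_t <- if (spec$strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- cumsum(spec$exon_lengths[ex_t])
  t_from <- spec$utr5_len + 1L
  t_to <- sum(spec$exon_lengths) - spec$utr3_len
  cds <- list()
  off <- 0L
  for (k in seq_len(n)) {
    i <- ex_t[k]
    a <- off + 1L; b <- cum[k]           # transcript coords of exon k
    lo <- max(a, t_from); hi <- min(b, t_to)
    if (lo <= hi) {
      if (spec$strand == "+") {
        cds[[length(cds) + 1L]] <- c(starts[i] + (lo - a),
                                     starts[i] + (hi - a))
      } else {
        cds[[length(cds) + 1L]] <- c(ends[i] - (hi - a),
                                     ends[i] - (lo - a))
      }
    }
    off <- b
  }
  cds <- do.call(rbind, cds)
  transcript_model(spec$tx_id, spec$chrom, spec$strand,
                   data.frame(start = starts, end = ends),
                   data.frame(start = cds[, 1], end = cds[, 2]),
                   gene_id = spec$gene_id)
}

# Engineered frameshift site constants: deleting the 4 bases at CDS
# [del_cds_start, del_cds_end] (left-aligned, anchor base immediately
# before) of a CDS built by .build_cds_sequence() yields Val96GlyfsTer50.
.engineered_site <- function() {
  list(fs_codon = 96L, ter_offset = 50L,
       anchor_cds = 285L, del_cds_start = 286L, del_cds_end = 289L,
       del_len = 4L)
}

# Build a CDS (character string, length n_nt incl. final stop codon) with no
# internal stop. When engineer = TRUE the sequence around codon 96 is
# constrained so that deleting CDS bases 286-289 shifts the frame to
# Gly at 96 and reaches a stop exactly 50 new-frame codons in.
.build_cds_sequence <- function(n_nt, engineer = TRUE) {
  .check(n_nt %% 3 == 0, "CDS length must be a multiple of 3")
  n_cod <- n_nt %/% 3
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  codons <- c("ATG", sample(sense, n_cod - 2L, replace = TRUE), "TAA")
  site <- NULL
  if (engineer) {
    s <- .engineered_site()
    f <- s$fs_codon; ter <- s$ter_offset
    a <- 3L * f - 2L                      # CDS coord of codon f first base
    .check(n_cod >= (a + 9L + 3L * (ter - 2L) + 2L) %/% 3L + 1L,
           "CDS too short to host the engineered site")
    codons[f] <- "GTT"                    # Val96
    codons[f + 1L] <- "AGG"               # supplies the TTAG deleted bases
    # keep the deletion left-aligned at CDS 286 (anchor 285)
    while (substr(codons[f - 1L], 3, 3) == "A")
      codons[f - 1L] <- sample(sense, 1)
    # new-frame codon (fs_codon + k) reads wt nt a+7+3(k-1); the stop is
    # new-frame offset `ter`, i.e. mutant residue fs_codon + ter - 1
    stop_nt <- a + 7L + 3L * (ter - 2L)
    c_stop <- (stop_nt + 2L) %/% 3L       # codon holding the triplet's end-1
    sense_t <- sense[substr(sense, 1, 1) == "T"]
    sense_a <- sense[substr(sense, 1, 1) == "A"]
    repeat {
      codons[f + 2L] <- sample(sense_t, 1)          # first base T at nt a+6
      idx <- (f + 3L):(c_stop - 1L)
      codons[idx] <- sample(sense, length(idx), replace = TRUE)
      # place the TAA of the shifted frame across codons c_stop-? exactly
      seqstr <- paste(codons, collapse = "")
      substr(seqstr, stop_nt, stop_nt + 2L) <- "TAA"
      codons <- substring(seqstr, 3L * seq_len(n_cod) - 2L,
                          3L * seq_len(n_cod))
      ok_wt <- !any(gc[codons[-n_cod]] == "*")
      newframe <- substring(seqstr, a + 7L + 3L * (0:(ter - 3L)),
                            a + 9L + 3L * (0:(ter - 3L)))
      ok_new <- !any(gc[newframe] == "*")
      if (ok_wt && ok_new) break
    }
    site <- s
  }
  list(seq = paste(codons, collapse = ""), site = site)
}

.random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

#' Generate a synthetic reference bundle
#'
#' Builds random chromosome sequences for every chromosome declared in the
#' simulation config, constructs the transcript model from `spec`, writes an
#' internally stop-free CDS into the genome at the CDS coordinates (reverse
#' complemented on minus-strand models), and records the engineered
#' frameshift site. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param spec A [transcript_spec()]; default geometry hosts the engineered
#'   deletion site.
#' @param seed Integer seed.
#' @param engineer_site Engineer the Val96GlyfsTer50 deletion site into the
#'   CDS (requires the default-scale CDS length).
#' @return Object of class `reference_bundle`: `sequences` (DNAStringSet),
#'   `transcripts` (named list of models), `site` (engineered-site record
#'   with CDS and genomic coordinates, or NULL).
#' @export
make_reference_bundle <- function(config, spec = NULL, seed = 1,
                                  engineer_site = TRUE) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(spec))
    spec <- default_transcript_spec(chrom = config$causal_chrom)
  .check(inherits(spec, "transcript_spec"), "spec must be a transcript_spec")
  model <- transcript_spec_model(spec)
  .check(model$chrom %in% config$chromosomes$chrom,
         "transcript chromosome %s not declared in config", model$chrom)
  chr_len <- config$chromosomes$length_bp[
    config$chromosomes$chrom == model$chrom]
  .check(max(model$exons$end) <= chr_len,
         "transcript extends past chromosome end")
  .with_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(
      config$chromosomes$length_bp, .random_dna, character(1)))
    names(seqs) <- config$chromosomes$chrom
    built <- .build_cds_sequence(spec$cds_len, engineer = engineer_site)
    cds_seq <- built$seq
    # project the CDS string onto the genome
    p <- .cds_pieces(model)
    chrseq <- seqs[[model$chrom]]
    for (i in seq_len(nrow(p))) {
      piece <- substr(cds_seq, p$cds_start[i], p$cds_end[i])
      if (model$strand == "-")
        piece <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(piece)))
      chrseq <- Biostrings::replaceAt(
        chrseq, IRanges::IRanges(p$start[i], p$end[i]), piece)
    }
    seqs[[model$chrom]] <- chrseq
    site <- built$site
    if (!is.null(site)) {
      site$chrom <- model$chrom
      site$tx_id <- model$tx_id
      g <- vapply(c(site$anchor_cds, site$del_cds_start, site$del_cds_end),
                  function(i) cds_to_genomic(model, i), numeric(1))
      if (model$strand == "+") {
        site$anchor_pos <- as.integer(g[1])
        site$del_start <- as.integer(g[2])
        site$del_end <- as.integer(g[3])
      } else {
        # on the minus strand the CDS anchor sits genomically after the
        # deleted interval; re-anchor on the genomic left
        site$del_start <- as.integer(g[3])
        site$del_end <- as.integer(g[2])
        site$anchor_pos <- site$del_start - 1L
      }
    }
    bundle <- structure(list(sequences = seqs,
                             transcripts = stats::setNames(list(model),
                                                           model$tx_id),
                             site = site, config = config, spec = spec),
                        class = "reference_bundle")
    aa <- .translate_str(extract_cds(model, bundle))
    .check(!any(aa[-length(aa)] == "*"),
           "internal stop codon in constructed CDS")
    bundle
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf("reference_bundle: %d chromosome(s), %d transcript(s)%s\n",
              length(x$sequences), length(x$transcripts),
              if (!is.null(x$site)) sprintf(
                ", engineered frameshift site at %s:%d",
                x$site$chrom, x$site$del_start) else ""))
  invisible(x)
}

#' Write a reference bundle to FASTA + GFF3
#' @param bundle A [reference_bundle()].
#' @param fasta_path,gff3_path Output paths.
#' @return Named list of the two paths, invisibly.
#' @export
write_reference_bundle <- function(bundle, fasta_path, gff3_path) {
  .check(inherits(bundle, "reference_bundle"), "not a reference_bundle")
  Biostrings::writeXStringSet(bundle$sequences, fasta_path)
  write_transcripts(bundle$transcripts, gff3_path)
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}
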