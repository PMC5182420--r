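# A handcrafted two-exon plus-strand transcript for the example cases:
# chromosome of 120 bp, exon1 10-39 (CDS 13-39), exon2 60-95 (CDS 60-92).
example_tx <- function() {
  set.seed(404)
  utr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  # CDS: 20 codons, no internal stop
  cds <- paste0("ATG", "GCC", "GTT", "AGG", "TCA" , "")
  cds <- paste0("ATGGCCAAAGTTAGGTTTCTGGACGAGCTTAAACCAGGGATTCCAAGTCATGACTAA")
  stopifnot(nchar(cds) == 57)
  ex1_cds <- substr(cds, 1, 27)
  ex2_cds <- substr(cds, 28, 57)
  seq_str <- paste0(utr(9), utr(3), ex1_cds, utr(20), utr(0),
                    ex2_cds, utr(3), utr(25))
  # layout: 1-9 intergenic, exon1 = 10-39 (10-12 UTR5, 13-39 CDS),
  # intron 40-59, exon2 = 60-95 (60-89 CDS, 90-95... )
  seq_str <- paste0(substr(seq_str, 1, 120),
                    strrep("A", max(0, 120 - nchar(seq_str))))
  model <- transcript_model("ex.1", "chrE", "+",
                            exons = data.frame(start = c(10, 60),
                                               end = c(39, 95)),
                            cds = data.frame(start = c(13, 60),
                                             end = c(39, 89)))
  seqs <- Biostrings::DNAStringSet(seq_str)
  names(seqs) <- "chrE"
  list(model = model, seqs = seqs, seq_str = seq_str, cds = cds)
}

test_that("interval arithmetic is 1-based inclusive", {
  expect_identical(interval_length(16366702, 16366705), 4L)
  expect_identical(interval_length(15973319, 20794824), 4821506L)
  expect_gt(interval_length(15973319, 20794824), 4.8e6)
  expect_identical(interval_length(7, 7), 1L)
  expect_error(interval_length(10, 9), "start")
})

test_that("indel length mod 3 separates frameshift from in-frame classes", {
  tx <- example_tx()
  # 4-base deletion inside CDS (anchor at 16, deleting 17-20)
  del4 <- annotate_variant(list(chrom = "chrE", pos = 16,
                                ref = substr(tx$seq_str, 16, 20),
                                alt = substr(tx$seq_str, 16, 16)),
                           tx$model, tx$seqs)
  expect_identical(del4$class, "frameshift")
  # 3-base deletion at the same anchor is in-frame
  del3 <- annotate_variant(list(chrom = "chrE", pos = 16,
                                ref = substr(tx$seq_str, 16, 19),
                                alt = substr(tx$seq_str, 16, 16)),
                           tx$model, tx$seqs)
  expect_identical(del3$class, "inframe_deletion")
  # 2-base insertion shifts, 3-base insertion does not
  ins2 <- annotate_variant(list(chrom = "chrE", pos = 20,
                                ref = substr(tx$seq_str, 20, 20),
                                alt = paste0(substr(tx$seq_str, 20, 20),
                                             "CC")),
                           tx$model, tx$seqs)
  expect_identical(ins2$class, "frameshift")
  ins3 <- annotate_variant(list(chrom = "chrE", pos = 20,
                                ref = substr(tx$seq_str, 20, 20),
                                alt = paste0(substr(tx$seq_str, 20, 20),
                                             "CCA")),
                           tx$model, tx$seqs)
  expect_identical(ins3$class, "inframe_insertion")
})

test_that("SNV classes come from codon comparison", {
  tx <- example_tx()
  # CDS pos 7 starts codon 3 = AAA (Lys); genomic 13+6 = 19
  syn <- annotate_variant(list(chrom = "chrE", pos = 21, ref = "A",
                               alt = "G"),  # AAA -> AAG, both Lys
                          tx$model, tx$seqs)
  expect_identical(syn$class, "synonymous")
  expect_identical(syn$hgvs_p, "Lys3=")
  mis <- annotate_variant(list(chrom = "chrE", pos = 19, ref = "A",
                               alt = "G"),  # AAA -> GAA, Lys3Glu
                          tx$model, tx$seqs)
  expect_identical(mis$class, "missense")
  expect_identical(mis$hgvs_p, "Lys3Glu")
  stopg <- annotate_variant(list(chrom = "chrE", pos = 20, ref = "A",
                                 alt = "T"),  # AAA -> ATA? no: pos2 -> T
                            tx$model, tx$seqs)
  # AAA with middle base T -> ATA (Ile): missense, not stop
  expect_identical(stopg$class, "missense")
  # non-coding and intronic positions classify by region
  expect_identical(annotate_variant(list(chrom = "chrE", pos = 11,
                                         ref = "A", alt = "C"),
                                    tx$model, tx$seqs)$class, "noncoding")
  expect_identical(annotate_variant(list(chrom = "chrE", pos = 45,
                                         ref = "A", alt = "C"),
                                    tx$model, tx$seqs)$class, "intronic")
  expect_identical(annotate_variant(list(chrom = "chrE", pos = 3,
                                         ref = "A", alt = "C"),
                                    tx$model, tx$seqs)$class, "intergenic")
  expect_error(annotate_variant(list(chrom = "chrX", pos = 3, ref = "A",
                                     alt = "C"), tx$model, tx$seqs),
               "chromosome")
})

test_that("indels spanning a splice boundary are flagged, not translated", {
  tx <- example_tx()
  # deletion crossing the exon1/intron boundary (39/40)
  del <- annotate_variant(list(chrom = "chrE", pos = 37,
                               ref = substr(tx$seq_str, 37, 42),
                               alt = substr(tx$seq_str, 37, 37)),
                          tx$model, tx$seqs)
  expect_identical(del$class, "splice_region_unsupported")
  expect_true(is.na(del$protein_pos_first_affected))
})

test_that("annotation matches the full-rebuild oracle on random indels", {
  withr::with_seed(314, {
    for (rep in 1:80) {
      tx <- random_toy_transcript()
      v <- random_cds_indel(tx)
      got <- annotate_variant(list(chrom = "chrT", pos = v$pos,
                                   ref = v$ref, alt = v$alt),
                              tx$model, tx$seqs)
      want <- oracle_consequence(tx$seq_str, tx$model, v$pos, v$ref, v$alt)
      expect_identical(got$class, want$class)
      expect_identical(got$protein_pos_first_affected, want$first)
      if (got$class == "frameshift") {
        expect_identical(got$novel_peptide_length, want$novel)
        expect_identical(got$ter_position_mutant, want$ter)
      }
    }
  })
})

test_that("minus-strand annotation equals the plus-strand construction", {
  withr::with_seed(1234, {
    for (rep in 1:25) {
      tx <- random_toy_transcript()
      v <- random_cds_indel(tx)
      got <- annotate_variant(list(chrom = "chrT", pos = v$pos,
                                   ref = v$ref, alt = v$alt),
                              tx$model, tx$seqs)
      # reverse complement the whole construction: the consequence in CDS
      # space must be identical
      L <- nchar(tx$seq_str)
      rc <- orc_revcomp(tx$seq_str)
      flip <- function(x) L - x + 1L
      model_rc <- transcript_model(
        tx$model$tx_id, "chrT",
        if (tx$model$strand == "+") "-" else "+",
        exons = data.frame(start = flip(tx$model$exons$end),
                           end = flip(tx$model$exons$start)),
        cds = data.frame(start = flip(tx$model$cds$end),
                         end = flip(tx$model$cds$start)))
      # indel on the flipped genome: deleted/inserted sequence reverse
      # complemented, re-anchored on the left of the edited interval
      lr <- nchar(v$ref); la <- nchar(v$alt)
      if (lr > la) {
        d1 <- v$pos + 1L; d2 <- v$pos + lr - 1L
        nd1 <- flip(d2); nd2 <- flip(d1)
        pos_rc <- nd1 - 1L
        ref_rc <- substr(rc, pos_rc, nd2)
        alt_rc <- substr(rc, pos_rc, pos_rc)
      } else {
        ins <- substr(v$alt, 2, la)
        pos_rc <- flip(v$pos + 1L)
        ref_rc <- substr(rc, pos_rc, pos_rc)
        alt_rc <- paste0(ref_rc, orc_revcomp(ins))
      }
      seqs_rc <- Biostrings::DNAStringSet(rc)
      names(seqs_rc) <- "chrT"
      got_rc <- annotate_variant(list(chrom = "chrT", pos = pos_rc,
                                      ref = ref_rc, alt = alt_rc),
                                 model_rc, seqs_rc)
      expect_identical(got_rc$class, got$class)
      expect_identical(got_rc$protein_pos_first_affected,
                       got$protein_pos_first_affected)
      expect_identical(got_rc$novel_peptide_length,
                       got$novel_peptide_length)
      expect_identical(got_rc$ter_position_mutant, got$ter_position_mutant)
      expect_identical(got_rc$hgvs_p, got$hgvs_p)
    }
  })
})

test_that("HGVS strings follow the fs/missense/synonymous conventions", {
  fs <- rohmap:::.new_consequence("t", "frameshift",
                                  protein_pos_first_affected = 96L,
                                  ref_residue = "Val",
                                  first_alt_residue = "Gly",
                                  novel_peptide_length = 49L,
                                  ter_position_mutant = 145L)
  expect_identical(hgvs_protein(fs), "Val96GlyfsTer50")
  fs$ter_position_mutant <- NA_integer_
  fs$novel_peptide_length <- NA_integer_
  expect_identical(hgvs_protein(fs), "Val96GlyfsTer?")
  mis <- rohmap:::.new_consequence("t", "missense",
                                   protein_pos_first_affected = 10L,
                                   ref_residue = "Ala",
                                   first_alt_residue = "Thr")
  expect_identical(hgvs_protein(mis), "Ala10Thr")
  expect_error(hgvs_protein(rohmap:::.new_consequence("t", "missense")),
               "lacks")
  # strings parse back to their own fields
  m <- regmatches("Val96GlyfsTer50",
                  regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})fsTer(\\d+)$",
                          "Val96GlyfsTer50"))[[1]]
  expect_identical(m[2], "Val")
  expect_identical(as.integer(m[3]), 96L)
  expect_identical(m[4], "Gly")
  expect_identical(as.integer(m[5]), 50L)
})

test_that("domain fate follows the first affected residue", {
  fs <- rohmap:::.new_consequence("t", "frameshift",
                                  protein_pos_first_affected = 96L,
                                  ref_residue = "Val",
                                  first_alt_residue = "Gly")
  doms <- data.frame(name = c("catalytic", "signal", "hinge"),
                     start = c(100, 10, 90), end = c(300, 50, 120))
  fate <- domain_overlap(fs, doms)
  expect_identical(fate$status, c("lost", "intact", "truncated"))
})
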