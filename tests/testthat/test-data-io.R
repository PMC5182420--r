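test_that("genotype matrix round-trips through the tab-delimited dialect", {
  ped <- build_aht_like_pedigree(seed = 3, min_affected = 2)
  cfg <- sim_config(chromosomes = data.frame(chrom = c("chr1", "chr2"),
                                             length_bp = c(1e6, 1e6)),
                    n_markers = 60, causal_chrom = "chr2",
                    causal_pos = 5e5, missing_rate = 0.05, seed = 4)
  gm <- gene_drop(ped, cfg)$genotypes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(gm, path)
  back <- read_genotype_matrix(path)
  expect_identical(back$markers, gm$markers)
  expect_identical(back$samples, gm$samples)
  expect_identical(back$calls, gm$calls)
  # gzip round trip too
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_genotype_matrix(gm, gz)
  expect_identical(read_genotype_matrix(gz)$calls, gm$calls)
})

test_that("genotype reader rejects malformed files with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tid\tS1", "chr1\t0\tm1\t0"), path)
  expect_error(read_genotype_matrix(path), "position.*line 2")
  writeLines(c("chrom\tpos\tid\tS1", "chr1\t10\tm1\t0",
               "chr1\t5\tm2\t1"), path)
  expect_error(read_genotype_matrix(path), "non-monotone.*line 3")
  writeLines(c("chrom\tpos\tid\tS1", "chr1\t10\tm1\t0",
               "chr1\t20\tm1\t1"), path)
  expect_error(read_genotype_matrix(path), "duplicate marker id.*line 3")
  writeLines(c("chrom\tpos\tid\tS1", "chr1\t10\tm1\tX"), path)
  expect_error(read_genotype_matrix(path), "call symbol 'X' at line 2")
})

test_that("an 11-case matrix mirrors the study design cleanly", {
  calls <- matrix(0L, nrow = 5, ncol = 11)
  gm <- small_matrix(rep("chr29", 5), c(10, 20, 30, 40, 50), calls,
                     sprintf("AHT%02d", 1:11))
  expect_identical(length(gm$samples), 11L)
  prof <- case_heterozygosity(gm, gm$samples)
  expect_true(all(prof$he == 0))
})

test_that("VCF reading honours fixtures, subsets and empty bodies", {
  path <- withr::local_tempfile(fileext = ".vcf")
  samples <- c("CASE", sprintf("P%02d", 1:3))
  recs <- data.frame(chrom = "chr2", pos = c(100, 250), id = c("del1", "s1"),
                     ref = c("TGTTA", "G"), alt = c("T", "A"),
                     stringsAsFactors = FALSE)
  recs[samples] <- list(c("1/1", "0|1"), c("0/0", "./."), c("0/0", "1/1"),
                        c("0/0", "0/0"))
  write_tiny_vcf(path, recs, samples)
  vs <- read_variants(path)
  expect_identical(nrow(vs$records), 2L)
  expect_identical(vs$records$ref[1], "TGTTA")
  expect_identical(nchar(vs$records$ref[1]), 5L)  # 4 bp deletion + anchor
  expect_identical(unname(vs$gt[1, "CASE"]), "1/1")
  expect_identical(unname(vs$gt[2, "CASE"]), "0/1")  # phase sep dropped
  expect_identical(unname(vs$gt[2, "P01"]), "./.")
  sub <- read_variants(path, sample_subset = c("CASE", "P02"))
  expect_identical(sub$samples, c("CASE", "P02"))
  expect_error(read_variants(path, sample_subset = "NOPE"),
               "unknown sample")
  # header only, no records
  writeLines(readLines(path)[1:3], path)
  empty <- read_variants(path)
  expect_identical(nrow(empty$records), 0L)
  expect_identical(empty$samples, samples)
})

test_that("variant sets round-trip through VCF written by the package", {
  samples <- c("CASE", "P01")
  vs <- variant_set(data.frame(chrom = c("chr1", "chr1"), pos = c(5, 9),
                               id = c("a", "b"), ref = c("A", "CT"),
                               alt = c("G,T", "C")),
                    matrix(c("1/2", "0/0", "1/1", "0/1"), nrow = 2,
                           byrow = TRUE,
                           dimnames = list(NULL, samples)))
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_variants(vs, path)
  back <- read_variants(path)
  expect_identical(back$records$alt, c("G,T", "C"))  # multi-allelic intact
  expect_identical(back$gt, vs$gt)
})

test_that("GFF3 transcript models round-trip and group multi-exon features", {
  spec <- default_transcript_spec()
  model <- transcript_spec_model(spec)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_transcripts(list(model), path)
  back <- read_transcripts(path)
  expect_length(back, 1)
  m <- back[[1]]
  expect_identical(nrow(m$exons), 18L)  # 18 exon features, one model
  expect_identical(m$exons, model$exons)
  expect_identical(m$cds, model$cds)
  expect_identical(m$strand, model$strand)
  expect_identical(m$cds_length, 1416L)
})

test_that("invalid transcript structures are rejected", {
  expect_error(transcript_model("t", "c", "+",
                                exons = data.frame(start = c(1, 50),
                                                   end = c(60, 100)),
                                cds = data.frame(start = 10, end = 12)),
               "non-overlapping")
  expect_error(transcript_model("t", "c", "+",
                                exons = data.frame(start = 1, end = 100),
                                cds = data.frame(start = 90, end = 120)),
               "not contained")
  expect_error(transcript_model("t", "c", "+",
                                exons = data.frame(start = 1, end = 100),
                                cds = data.frame(start = 10, end = 13)),
               "multiple of 3")
})

test_that("CDS extraction respects strand and translates cleanly", {
  # plus strand single exon: CDS equals the reference slice
  seqs <- Biostrings::DNAStringSet(c(chrA = "TTATGGCCGAATAACC"))
  m_plus <- transcript_model("p", "chrA", "+",
                             exons = data.frame(start = 1, end = 16),
                             cds = data.frame(start = 3, end = 14))
  expect_identical(extract_cds(m_plus, seqs), "ATGGCCGAATAA")
  # minus strand: reverse complement of ascending concatenation
  m_minus <- transcript_model("m", "chrA", "-",
                              exons = data.frame(start = 1, end = 16),
                              cds = data.frame(start = 3, end = 14))
  expect_identical(
    extract_cds(m_minus, seqs),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGGCCGAATAA"))))
  # constructed bundles carry no internal stops (checked by translation)
  cfg <- sim_config(seed = 2)
  bundle <- make_reference_bundle(cfg, seed = 8)
  aa <- seqinr::translate(strsplit(
    extract_cds(bundle$transcripts[[1]], bundle), "")[[1]])
  expect_identical(sum(aa == "*"), 1L)
  expect_identical(aa[length(aa)], "*")
})

test_that("reference bundles are byte-identical for a fixed seed", {
  cfg <- sim_config(chromosomes = data.frame(chrom = "chr2",
                                             length_bp = 2.1e6),
                    n_markers = 50, causal_chrom = "chr2",
                    causal_pos = 2001990, seed = 1)
  b1 <- make_reference_bundle(cfg, seed = 3)
  b2 <- make_reference_bundle(cfg, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(b1$sequences, f1)
  Biostrings::writeXStringSet(b2$sequences, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
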