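# Independent oracles and fixture builders used across the suite.

# ---- run-scan oracle --------------------------------------------------
# Enumerates every maximal all-qualifying interval by prefix sums over all
# (i, j) pairs within a chromosome, independently of the scanner's
# run-length encoding route.
oracle_runs <- function(qualifying, chrom, min_run) {
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    q <- qualifying[idx]
    n <- length(q)
    cq <- cumsum(q)
    ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    full <- (cq[j] - c(0, cq)[i]) == (j - i + 1)
    left_max <- i == 1 | !q[pmax(i - 1, 1)]
    right_max <- j == n | !q[pmin(j + 1, n)]
    keep <- full & left_max & right_max & (j - i + 1) >= min_run
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start_index = idx[i[keep]],
                              end_index = idx[j[keep]])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_index = integer(0),
                      end_index = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random small case-group genotype matrix for scanner tests
random_scan_instance <- function(n_markers, n_samples, het_prob,
                                 missing_prob = 0) {
  n_chrom <- sample(1:3, 1)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_markers,
                       replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch)
    sort(sample.int(1e6, sum(chrom == ch)))))
  calls <- matrix(sample(c(0L, 1L, 2L), n_markers * n_samples,
                         replace = TRUE,
                         prob = c((1 - het_prob) / 2, het_prob,
                                  (1 - het_prob) / 2)),
                  nrow = n_markers)
  if (missing_prob > 0)
    calls[runif(length(calls)) < missing_prob] <- NA_integer_
  genotype_matrix(
    data.frame(id = sprintf("m%04d", seq_len(n_markers)), chrom = chrom,
               pos = pos),
    sprintf("S%02d", seq_len(n_samples)), calls)
}

# ---- consequence oracle ----------------------------------------------
# Full-genome rebuild: applies the edit to the chromosome string, shifts
# exon/CDS coordinates past the edit, re-extracts and translates the whole
# mutant CDS with seqinr, and derives the protein fields from the complete
# wild-type/mutant translations. Shares only the field conventions with the
# implementation, none of its code path.
orc_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

orc_extract_cds <- function(seq_str, cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  parts <- vapply(seq_len(nrow(cds)), function(i)
    substr(seq_str, cds$start[i], cds$end[i]), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") orc_revcomp(s) else s
}

orc_translate <- function(s) {
  n <- nchar(s) %/% 3
  if (n == 0) return(character(0))
  seqinr::translate(strsplit(substr(s, 1, 3 * n), "")[[1]])
}

oracle_consequence <- function(seq_str, model, pos, ref, alt) {
  stopifnot(substr(seq_str, pos, pos + nchar(ref) - 1) == ref)
  mut <- paste0(substr(seq_str, 1, pos - 1), alt,
                substr(seq_str, pos + nchar(ref), nchar(seq_str)))
  net <- nchar(alt) - nchar(ref)
  shift <- function(x) ifelse(x >= pos + nchar(ref), x + net, x)
  wt_cds <- orc_extract_cds(seq_str, model$cds, model$strand)
  mut_cds <- orc_extract_cds(mut, data.frame(start = shift(model$cds$start),
                                             end = shift(model$cds$end)),
                             model$strand)
  cls <- if (net %% 3 != 0) "frameshift"
         else if (net < 0) "inframe_deletion" else "inframe_insertion"
  wt_aa <- orc_translate(wt_cds)
  mut_aa <- orc_translate(mut_cds)
  nmin <- min(length(wt_aa), length(mut_aa))
  k <- which(wt_aa[seq_len(nmin)] != mut_aa[seq_len(nmin)])[1]
  if (is.na(k)) k <- nmin + 1L
  first <- k
  novel <- NA_integer_; ter <- NA_integer_
  if (cls == "frameshift") {
    stops <- which(mut_aa == "*")
    stops <- stops[stops >= k]
    if (length(stops)) {
      ter <- stops[1]
      novel <- ter - first
    }
  }
  list(class = cls, first = as.integer(first), novel = as.integer(novel),
       ter = as.integer(ter))
}

# random toy transcript on a short chromosome; exons are long enough that
# indels placed with an 8 bp margin cannot left-align across a boundary
random_toy_transcript <- function() {
  n_ex <- sample(1:4, 1)
  exon_lengths <- sample(45:90, n_ex, replace = TRUE)
  utr5 <- sample(0:12, 1)
  utr3 <- sample(0:12, 1)
  cds_len <- sum(exon_lengths) - utr5 - utr3
  trim <- cds_len %% 3
  utr3 <- utr3 + trim
  spec <- transcript_spec(
    tx_id = "toy.1", gene_id = "toy", chrom = "chrT",
    strand = sample(c("+", "-"), 1), tx_start = sample(50:200, 1),
    exon_lengths = exon_lengths,
    intron_lengths = if (n_ex > 1) sample(25:80, n_ex - 1, replace = TRUE)
                     else integer(0),
    utr5_len = utr5, utr3_len = utr3)
  model <- transcript_spec_model(spec)
  chrom_len <- max(model$exons$end) + 100L
  seq_str <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                   collapse = "")
  seqs <- Biostrings::DNAStringSet(seq_str)
  names(seqs) <- "chrT"
  list(model = model, seqs = seqs, seq_str = seq_str)
}

# random pure indel (VCF-style, left-anchored) strictly inside one CDS
# exon of the model, with margins keeping normalisation inside the exon
random_cds_indel <- function(tx) {
  model <- tx$model
  margin <- 8L
  repeat {
    row <- model$cds[sample(nrow(model$cds), 1), ]
    if (row$end - row$start + 1 < 2 * margin + 10) next
    if (runif(1) < 0.5) {                       # deletion
      L <- sample(1:6, 1)
      d1 <- sample((row$start + margin):(row$end - margin - L), 1)
      anchor <- d1 - 1L
      ref <- substr(tx$seq_str, anchor, d1 + L - 1L)
      alt <- substr(tx$seq_str, anchor, anchor)
    } else {                                    # insertion
      L <- sample(1:6, 1)
      anchor <- sample((row$start + margin):(row$end - margin - 1L), 1)
      ref <- substr(tx$seq_str, anchor, anchor)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
    }
    return(list(pos = anchor, ref = ref, alt = alt))
  }
}

# ---- misc fixtures ----------------------------------------------------
write_tiny_vcf <- function(path, records, samples) {
  # records: data.frame chrom,pos,id,ref,alt + genotype columns per sample
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i)
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT",
            unlist(records[i, samples])), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

small_matrix <- function(chrom, pos, calls, samples = NULL) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(calls)))
  genotype_matrix(data.frame(id = sprintf("m%03d", seq_along(chrom)),
                             chrom = chrom, pos = pos),
                  samples, calls)
}
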