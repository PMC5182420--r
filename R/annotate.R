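# three-letter amino-acid codes; "*" is rendered Ter per HGVS
.aa3 <- function(a) {
  if (is.na(a)) return(NA_character_)
  if (a == "*") return("Ter")
  unname(Biostrings::AMINO_ACID_CODE[a]) %||% "Xaa"
}

.new_consequence <- function(transcript_id, class,
                             protein_pos_first_affected = NA_integer_,
                             ref_residue = NA_character_,
                             first_alt_residue = NA_character_,
                             novel_peptide_length = NA_integer_,
                             ter_position_mutant = NA_integer_,
                             hgvs_p = NA_character_) {
  structure(list(transcript_id = transcript_id, class = class,
                 protein_pos_first_affected = protein_pos_first_affected,
                 ref_residue = ref_residue,
                 first_alt_residue = first_alt_residue,
                 novel_peptide_length = novel_peptide_length,
                 ter_position_mutant = ter_position_mutant,
                 hgvs_p = hgvs_p),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("consequence [%s] %s%s\n", x$transcript_id, x$class,
              if (!is.na(x$hgvs_p)) paste0(": p.", x$hgvs_p) else ""))
  invisible(x)
}

# Shared protein-arithmetic conventions, applied to aligned wild-type and
# mutant residue vectors starting at wild-type residue index `offset`:
# first affected = first residue where the translations differ (the shifted
# frame may initially reproduce wild-type residues); for frameshifts the
# mutant stop is the first "*" at/after it, Ter offset counts the first
# changed residue as 1, and the novel peptide is the run of changed
# residues before the stop.
.protein_fields <- function(wt_aa, mut_aa, offset, frameshift) {
  nmin <- min(length(wt_aa), length(mut_aa))
  k <- if (nmin > 0) which(wt_aa[seq_len(nmin)] != mut_aa[seq_len(nmin)])[1]
       else NA_integer_
  if (is.na(k)) {
    if (length(mut_aa) == length(wt_aa))
      return(list(first = NA_integer_, ref = NA_character_,
                  alt = NA_character_, novel = NA_integer_,
                  ter = NA_integer_))
    k <- nmin + 1L
  }
  first <- offset + k - 1L
  ref <- if (k <= length(wt_aa)) wt_aa[k] else NA_character_
  alt <- if (k <= length(mut_aa)) mut_aa[k] else NA_character_
  novel <- NA_integer_
  ter <- NA_integer_
  if (frameshift) {
    stops <- which(mut_aa == "*")
    stops <- stops[stops >= k]
    if (length(stops)) {
      ter <- offset + stops[1] - 1L
      novel <- ter - first
    }
  }
  list(first = first, ref = ref, alt = alt, novel = novel, ter = ter)
}

# Full-translation consequence of a CDS-level edit: rebuilds nothing
# incrementally, just translates both complete coding sequences. Used to
# record ground truth for planted variants.
.full_consequence <- function(wt_cds, mut_cds, transcript_id) {
  net <- nchar(mut_cds) - nchar(wt_cds)
  .check(net != 0, "full consequence requires an indel edit")
  cls <- if (net %% 3 != 0) "frameshift"
         else if (net < 0) "inframe_deletion" else "inframe_insertion"
  wt_aa <- .translate_str(wt_cds)
  mut_aa <- .translate_str(mut_cds)
  f <- .protein_fields(wt_aa, mut_aa, 1L, cls == "frameshift")
  cons <- .new_consequence(transcript_id, cls,
                           protein_pos_first_affected = f$first,
                           ref_residue = .aa3(f$ref),
                           first_alt_residue = .aa3(f$alt),
                           novel_peptide_length = f$novel,
                           ter_position_mutant = f$ter)
  cons$hgvs_p <- tryCatch(hgvs_protein(cons), error = function(e) NA_character_)
  cons
}

.exonic <- function(model, g) {
  any(model$exons$start <= g & model$exons$end >= g)
}

.in_tx <- function(model, g) {
  g >= min(model$exons$start) && g <= max(model$exons$end)
}

.noncoding_class <- function(model, g) {
  if (!.in_tx(model, g)) "intergenic"
  else if (.exonic(model, g)) "noncoding"
  else "intronic"
}

#' Annotate a variant against a transcript model
#'
#' Projects a normalised (left-anchored) SNV or pure indel onto the
#' transcript, classifies the coding effect, and for frameshifts rebuilds
#' and translates the mutant coding sequence from the first affected codon
#' to the first stop. Indels are left-aligned against the reference before
#' projection; the VCF anchor base is not part of the affected interval.
#' Indels spanning a CDS/intron or CDS/UTR boundary are not given protein
#' arithmetic: they are returned with class `splice_region_unsupported`.
#'
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (a single alternate allele).
#' @param model A [transcript_model()].
#' @param reference A [reference_bundle()] or named `DNAStringSet`.
#' @return A `consequence` object (see package docs): class, first affected
#'   residue, reference and first alternate residues, novel-peptide length,
#'   mutant stop position and HGVS p. string.
#' @export
annotate_variant <- function(variant, model, reference) {
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  .check(!grepl(",", alt, fixed = TRUE),
         "annotate one alternate allele at a time")
  .check(chrom == model$chrom,
         "variant chromosome %s does not match transcript chromosome %s",
         chrom, model$chrom)
  seqs <- if (inherits(reference, "reference_bundle")) reference$sequences
          else reference
  chrseq <- seqs[[chrom]]
  .check(!is.null(chrseq), "chromosome %s absent from reference", chrom)
  lr <- nchar(ref); la <- nchar(alt)

  if (lr == 1 && la == 1) {
    cidx <- genomic_to_cds(model, pos)
    if (is.na(cidx))
      return(.finish(.new_consequence(model$tx_id,
                                      .noncoding_class(model, pos))))
    wt <- extract_cds(model, reference)
    base <- if (model$strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
      else alt
    cod <- (cidx - 1L) %/% 3L + 1L
    off <- (cidx - 1L) %% 3L + 1L
    wt_codon <- substr(wt, 3L * cod - 2L, 3L * cod)
    mut_codon <- wt_codon
    substr(mut_codon, off, off) <- base
    wt_aa <- unname(Biostrings::GENETIC_CODE[wt_codon])
    mut_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
    cls <- if (wt_aa == mut_aa) "synonymous"
           else if (cod == 1L) "start_lost"
           else if (mut_aa == "*") "stop_gained"
           else if (wt_aa == "*") "stop_lost"
           else "missense"
    return(.finish(.new_consequence(
      model$tx_id, cls, protein_pos_first_affected = cod,
      ref_residue = .aa3(wt_aa), first_alt_residue = .aa3(mut_aa))))
  }

  .check(substr(ref, 1, 1) == substr(alt, 1, 1) && min(lr, la) == 1,
         "only left-anchored pure insertions/deletions are supported")

  if (lr > la) {                                    # deletion
    d1 <- pos + 1L; d2 <- pos + lr - 1L
    al <- .left_align_deletion(chrseq, d1, d2)
    d1 <- al[1]; d2 <- al[2]
    c1 <- genomic_to_cds(model, d1)
    c2 <- genomic_to_cds(model, d2)
    if (is.na(c1) && is.na(c2) &&
        !any(vapply(seq(d1, d2), function(g) !is.na(genomic_to_cds(model, g)),
                    logical(1)))) {
      cls <- .noncoding_class(model, d1)
      if (.noncoding_class(model, d2) != cls || !.same_exon_side(model, d1, d2))
        return(.finish(.new_consequence(model$tx_id,
                                        "splice_region_unsupported")))
      return(.finish(.new_consequence(model$tx_id, cls)))
    }
    if (is.na(c1) || is.na(c2) || abs(c2 - c1) != d2 - d1)
      return(.finish(.new_consequence(model$tx_id,
                                      "splice_region_unsupported")))
    ds <- min(c1, c2); de <- max(c1, c2)
    return(.finish(.indel_consequence(model, reference,
                                      del = c(ds, de), ins = "")))
  }

  # insertion: alt carries inserted bases after the anchor
  ins <- substr(alt, 2, la)
  p <- pos
  repeat {                                          # left-align genomically
    if (p <= 1) break
    anchor_base <- as.character(Biostrings::subseq(chrseq, p, p))
    if (substr(ins, nchar(ins), nchar(ins)) != anchor_base) break
    ins <- paste0(anchor_base, substr(ins, 1, nchar(ins) - 1L))
    p <- p - 1L
  }
  cL <- genomic_to_cds(model, p)
  cR <- genomic_to_cds(model, p + 1L)
  if (is.na(cL) && is.na(cR)) {
    cls <- .noncoding_class(model, p)
    return(.finish(.new_consequence(model$tx_id, cls)))
  }
  if (is.na(cL) || is.na(cR) || abs(cR - cL) != 1L)
    return(.finish(.new_consequence(model$tx_id,
                                    "splice_region_unsupported")))
  j <- min(cL, cR)
  ins_cds <- if (model$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
    else ins
  .finish(.indel_consequence(model, reference, del = NULL,
                             ins = ins_cds, after = j))
}

# both positions on the same side of every exon (no boundary between them)
.same_exon_side <- function(model, g1, g2) {
  for (i in seq_len(nrow(model$exons))) {
    in1 <- model$exons$start[i] <= g1 && model$exons$end[i] >= g1
    in2 <- model$exons$start[i] <= g2 && model$exons$end[i] >= g2
    if (in1 != in2) return(FALSE)
  }
  TRUE
}

# CDS-space indel consequence via partial mutant translation: translates
# only from the first codon overlapping the edit onward.
.indel_consequence <- function(model, reference, del, ins, after = NULL) {
  wt <- extract_cds(model, reference)
  n <- nchar(wt)
  if (!is.null(del)) {
    ds <- del[1]; de <- del[2]
    net <- nchar(ins) - (de - ds + 1L)
    c0 <- (ds - 1L) %/% 3L + 1L
    start_nt <- 3L * (c0 - 1L) + 1L
    tail_mut <- paste0(substr(wt, start_nt, ds - 1L), ins,
                       substr(wt, de + 1L, n))
  } else {
    net <- nchar(ins)
    c0 <- after %/% 3L + 1L
    start_nt <- 3L * (c0 - 1L) + 1L
    tail_mut <- paste0(substr(wt, start_nt, after), ins,
                       substr(wt, after + 1L, n))
  }
  frameshift <- net %% 3L != 0L
  cls <- if (frameshift) "frameshift"
         else if (net < 0) "inframe_deletion" else "inframe_insertion"
  wt_aa <- .translate_str(substr(wt, start_nt, n))
  mut_aa <- .translate_str(tail_mut)
  f <- .protein_fields(wt_aa, mut_aa, c0, frameshift)
  .new_consequence(model$tx_id, cls,
                   protein_pos_first_affected = f$first,
                   ref_residue = .aa3(f$ref),
                   first_alt_residue = .aa3(f$alt),
                   novel_peptide_length = f$novel,
                   ter_position_mutant = f$ter)
}

.finish <- function(cons) {
  cons$hgvs_p <- tryCatch(hgvs_protein(cons), error = function(e) NA_character_)
  cons
}

#' HGVS-style protein notation for a consequence
#'
#' Frameshift: `<Ref><Pos><Alt>fsTer<N>` where N counts the mutant stop
#' position in the new reading frame with the first changed residue as 1
#' (`fsTer?` when no downstream stop is reached); missense:
#' `<Ref><Pos><Alt>`; synonymous: `<Ref><Pos>=`; stop gain: `<Ref><Pos>Ter`.
#'
#' @param consequence A `consequence` from [annotate_variant()].
#' @return HGVS p. string (without the "p." prefix).
#' @export
hgvs_protein <- function(consequence) {
  x <- consequence
  .check(inherits(x, "consequence"), "not a consequence object")
  pos <- x$protein_pos_first_affected
  switch(x$class,
    frameshift = {
      .check(!is.na(pos) && !is.na(x$ref_residue),
             "frameshift consequence lacks protein-level fields")
      if (identical(x$first_alt_residue, "Ter"))
        return(paste0(x$ref_residue, pos, "Ter"))
      alt <- if (is.na(x$first_alt_residue)) "" else x$first_alt_residue
      ter <- if (is.na(x$ter_position_mutant)) "?" else
        as.character(x$ter_position_mutant - pos + 1L)
      paste0(x$ref_residue, pos, alt, "fsTer", ter)
    },
    missense = {
      .check(!is.na(pos) && !is.na(x$ref_residue) &&
               !is.na(x$first_alt_residue),
             "missense consequence lacks protein-level fields")
      paste0(x$ref_residue, pos, x$first_alt_residue)
    },
    synonymous = {
      .check(!is.na(pos) && !is.na(x$ref_residue),
             "synonymous consequence lacks protein-level fields")
      paste0(x$ref_residue, pos, "=")
    },
    stop_gained = paste0(x$ref_residue, pos, "Ter"),
    stop_lost = paste0("Ter", pos, x$first_alt_residue, "ext*?"),
    start_lost = paste0(x$ref_residue, pos, "?"),
    inframe_deletion = if (!is.na(pos))
      paste0(x$ref_residue, pos, "del") else NA_character_,
    inframe_insertion = if (!is.na(pos))
      paste0(x$ref_residue, pos, "ins") else NA_character_,
    NA_character_)
}

#' Classify protein-domain fate under a truncating consequence
#'
#' Domains entirely at/after the first affected residue are lost, domains
#' spanning it are truncated, domains entirely before it are intact.
#'
#' @param consequence A `consequence` with a first affected residue.
#' @param domains data.frame with columns `name`, `start`, `end` (1-based
#'   residue intervals in the wild-type protein).
#' @return data.frame with columns `name`, `status`.
#' @export
domain_overlap <- function(consequence, domains) {
  .check(inherits(consequence, "consequence"), "not a consequence object")
  p <- consequence$protein_pos_first_affected
  .check(!is.na(p), "consequence has no first affected residue")
  .check(all(c("name", "start", "end") %in% names(domains)),
         "domains must have columns name, start, end")
  status <- ifelse(domains$start >= p, "lost",
                   ifelse(domains$end < p, "intact", "truncated"))
  data.frame(name = domains$name, status = status,
             stringsAsFactors = FALSE)
}
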