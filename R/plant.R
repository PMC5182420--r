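# Left-align a pure deletion [d1, d2] (1-based, inclusive) against a
# chromosome sequence; returns the shifted interval.
.left_align_deletion <- function(chrseq, d1, d2) {
  s <- function(i) as.character(Biostrings::subseq(chrseq, i, i))
  while (d1 > 1L && s(d1 - 1L) == s(d2)) {
    d1 <- d1 - 1L
    d2 <- d2 - 1L
  }
  c(d1, d2)
}

#' Plant a private frameshift deletion into a synthetic variant file
#'
#' Builds a multi-sample variant set in which one case sample is homozygous
#' for a coding deletion that no panel sample carries, on a background of
#' variants shared with the panel at a configurable rate. Private
#' homozygous-alternate background variants are placed off the transcript's
#' chromosome, emulating genome-wide private variation outside the mapped
#' region. The ground truth of every record, including the expected
#' protein-level consequence of the planted deletion (computed by full
#' mutant-CDS translation), is retained.
#'
#' @param reference A [make_reference_bundle()] result.
#' @param panel_size Number of control-panel samples (>= 1); 89 emulates the
#'   size of a whole-genome contrast panel.
#' @param deletion_length Deleted bases; lengths not divisible by 3 shift
#'   the reading frame. Length 4 uses the engineered site when available.
#' @param case_id Sample name of the case.
#' @param cds_start Optional explicit CDS coordinate of the first deleted
#'   base; must lie inside a single CDS exon (otherwise an error).
#' @param n_background Number of background variants.
#' @param background_share_rate Fraction of background variants whose
#'   alternate allele is present in the panel.
#' @param panel_carriers Number of panel samples heterozygous for the
#'   planted allele (0 keeps it private).
#' @param include_planted Set FALSE to emit background only.
#' @param seed Integer seed.
#' @return Object of class `variant_fixture`: `variants` (a
#'   [variant_set()]), `truth` (planted-record description incl. expected
#'   HGVS p. string, and per-background-record privacy flags), `case_id`,
#'   `panel_ids`.
#' @export
plant_private_frameshift <- function(reference, panel_size = 89,
                                     deletion_length = 4,
                                     case_id = "CASE1",
                                     cds_start = NULL,
                                     n_background = 400,
                                     background_share_rate = 0.9,
                                     panel_carriers = 0,
                                     include_planted = TRUE,
                                     seed = 1) {
  .check(inherits(reference, "reference_bundle"), "not a reference_bundle")
  .check(panel_size >= 1, "panel_size must be >= 1")
  .check(deletion_length >= 1, "deletion_length must be >= 1")
  model <- reference$transcripts[[1]]
  chrs <- names(reference$sequences)
  chr_len <- stats::setNames(
    as.integer(Biostrings::width(reference$sequences)), chrs)
  site <- reference$site
  if (is.null(cds_start)) {
    if (!is.null(site) && deletion_length == site$del_len) {
      cds_start <- site$del_cds_start
    } else {
      cds_start <- (model$cds_length %/% 2) %/% 3 * 3 + 2L
    }
  }
  cds_end <- cds_start + deletion_length - 1L
  .check(cds_start >= 2 && cds_end <= model$cds_length,
         "deletion outside CDS")
  p <- .cds_pieces(model)
  piece <- which(p$cds_start <= cds_start & p$cds_end >= cds_end)
  .check(length(piece) == 1, "deletion outside CDS exon (spans a boundary)")

  g1 <- cds_to_genomic(model, cds_start)
  g2 <- cds_to_genomic(model, cds_end)
  d1 <- as.integer(min(g1, g2)); d2 <- as.integer(max(g1, g2))
  chrseq <- reference$sequences[[model$chrom]]
  al <- .left_align_deletion(chrseq, d1, d2)
  anchor <- al[1] - 1L
  .check(anchor >= 1, "deletion cannot be anchored at chromosome start")
  ref_allele <- as.character(Biostrings::subseq(chrseq, anchor, al[2]))
  alt_allele <- substr(ref_allele, 1, 1)

  # expected consequence from full mutant-CDS translation
  wt_cds <- extract_cds(model, reference)
  mut_cds <- paste0(substr(wt_cds, 1, cds_start - 1L),
                    substr(wt_cds, cds_end + 1L, nchar(wt_cds)))
  cons <- .full_consequence(wt_cds, mut_cds, model$tx_id)

  panel_ids <- sprintf("PANEL%03d", seq_len(panel_size))
  samples <- c(case_id, panel_ids)
  .with_seed(seed, {
    recs <- list(); gts <- list(); flags <- list()
    if (include_planted) {
      gt <- c("1/1", rep("0/0", panel_size))
      if (panel_carriers > 0)
        gt[1 + seq_len(min(panel_carriers, panel_size))] <- "0/1"
      recs[[1]] <- data.frame(chrom = model$chrom, pos = anchor,
                              id = "planted_fs", ref = ref_allele,
                              alt = alt_allele, stringsAsFactors = FALSE)
      gts[[1]] <- gt
      flags[[1]] <- data.frame(id = "planted_fs", role = "planted",
                               private = panel_carriers == 0,
                               stringsAsFactors = FALSE)
    }
    forbidden <- (anchor - 10L):(al[2] + 10L)
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(n_background)) {
      shared <- stats::runif(1) < background_share_rate
      case_gt <- sample(c("0/0", "0/1", "1/1"), 1,
                        prob = c(0.35, 0.35, 0.3))
      repeat {
        ch <- sample(chrs, 1, prob = chr_len / sum(chr_len))
        if (!shared && case_gt == "1/1") {
          # keep private hom-alt variation off the mapped chromosome
          others <- setdiff(chrs, model$chrom)
          if (length(others))
            ch <- sample(others, 1,
                         prob = chr_len[others] / sum(chr_len[others]))
          else case_gt <- "0/1"
        }
        pos <- sample.int(chr_len[[ch]] - 1L, 1) + 1L
        if (!(ch == model$chrom && pos %in% forbidden)) break
      }
      refb <- as.character(Biostrings::subseq(reference$sequences[[ch]],
                                              pos, pos))
      altb <- sample(setdiff(bases, refb), 1)
      if (shared) {
        f <- stats::runif(1, 0.05, 0.5)
        dose <- stats::rbinom(panel_size, 2L, f)
        if (all(dose == 0)) dose[sample.int(panel_size, 1)] <- 1L
        pgt <- c("0/0", "0/1", "1/1")[dose + 1L]
      } else {
        pgt <- rep("0/0", panel_size)
      }
      i <- length(recs) + 1L
      recs[[i]] <- data.frame(chrom = ch, pos = pos,
                              id = sprintf("bg%04d", k), ref = refb,
                              alt = altb, stringsAsFactors = FALSE)
      gts[[i]] <- c(case_gt, pgt)
      flags[[i]] <- data.frame(id = sprintf("bg%04d", k),
                               role = "background", private = !shared,
                               stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    gt <- do.call(rbind, gts)
    colnames(gt) <- samples
    ord <- order(match(records$chrom, chrs), records$pos)
    vs <- variant_set(records[ord, , drop = FALSE], gt[ord, , drop = FALSE])
    truth <- list(
      planted = if (include_planted) list(
        chrom = model$chrom, pos = as.integer(anchor), id = "planted_fs",
        ref = ref_allele, alt = alt_allele,
        cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
        deletion_length = as.integer(deletion_length),
        consequence = cons, hgvs_p = hgvs_protein(cons),
        panel_carriers = panel_carriers) else NULL,
      records = do.call(rbind, flags)[ord, , drop = FALSE])
    structure(list(variants = vs, truth = truth, case_id = case_id,
                   panel_ids = panel_ids),
              class = "variant_fixture")
  })
}

#' @export
print.variant_fixture <- function(x, ...) {
  cat(sprintf("variant_fixture: %d record(s), case %s vs %d panel samples%s\n",
              nrow(x$variants$records), x$case_id, length(x$panel_ids),
              if (!is.null(x$truth$planted))
                sprintf(", planted %s at %s:%d (%s)",
                        x$truth$planted$id, x$truth$planted$chrom,
                        x$truth$planted$pos, x$truth$planted$hgvs_p)
              else ""))
  invisible(x)
}
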