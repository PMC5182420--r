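#' Per-marker observed heterozygosity within the case group
#'
#' For each marker, He is the fraction of called case samples that are
#' heterozygous (dosage 1). This is observed, per-genotype heterozygosity —
#' not expected heterozygosity from allele frequencies — because the run
#' criterion is "every case homozygous" applied genotype by genotype.
#' Markers with fewer than `min_called` called cases are flagged ineligible;
#' the strict default (`min_called` = number of cases) makes any missing
#' case call disqualify the marker.
#'
#' @param matrix A [genotype_matrix()].
#' @param case_ids Non-empty subset of the matrix samples.
#' @param min_called Minimum called cases for a marker to be eligible;
#'   defaults to `length(case_ids)`.
#' @return data.frame of class `he_profile`: marker id/chrom/pos, n_called,
#'   n_missing, n_het, he, shared_hom (all called cases homozygous for the
#'   same allele), eligible.
#' @export
case_heterozygosity <- function(matrix, case_ids,
                                min_called = length(case_ids)) {
  .check(inherits(matrix, "genotype_matrix"), "matrix must be a genotype_matrix")
  .check(length(case_ids) > 0, "case set must be non-empty")
  missing <- setdiff(case_ids, matrix$samples)
  .check(length(missing) == 0, "case id(s) not in matrix: %s",
         paste(missing, collapse = ", "))
  calls <- matrix$calls[, case_ids, drop = FALSE]
  n_called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  n_hom0 <- rowSums(calls == 0L, na.rm = TRUE)
  n_hom2 <- rowSums(calls == 2L, na.rm = TRUE)
  he <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  prof <- data.frame(id = matrix$markers$id, chrom = matrix$markers$chrom,
                     pos = matrix$markers$pos,
                     n_called = as.integer(n_called),
                     n_missing = as.integer(length(case_ids) - n_called),
                     n_het = as.integer(n_het), he = he,
                     shared_hom = n_called > 0 &
                       (n_hom0 == n_called | n_hom2 == n_called),
                     eligible = n_called >= min_called,
                     stringsAsFactors = FALSE)
  class(prof) <- c("he_profile", "data.frame")
  prof
}

#' Scan parameters for homozygosity runs
#' @param min_run_snps Minimum contiguous qualifying markers for a reported
#'   run (noise floor; short homozygous runs abound genome-wide).
#' @param require_shared_allele Additionally require all cases to share the
#'   same homozygous allele at every marker (autozygosity-style filter;
#'   off by default since per-individual homozygosity is the primary
#'   criterion).
#' @return List of class `scan_params`.
#' @export
scan_params <- function(min_run_snps = 20, require_shared_allele = FALSE) {
  .check(min_run_snps >= 1, "min_run_snps must be >= 1")
  structure(list(min_run_snps = as.integer(min_run_snps),
                 require_shared_allele = isTRUE(require_shared_allele)),
            class = "scan_params")
}

#' Find maximal runs of case-group homozygosity
#'
#' A marker qualifies when it is eligible (enough called cases), He = 0,
#' and (optionally) all cases share the same homozygous allele. Runs are
#' maximal stretches of consecutive qualifying markers, never crossing a
#' chromosome boundary, with at least `min_run_snps` markers. Runs are
#' sorted by SNP count descending, ties by bp span descending, then genomic
#' order. Span is inclusive: last position - first position + 1.
#'
#' @param profile Output of [case_heterozygosity()] aligned to `matrix`.
#' @param matrix The [genotype_matrix()] the profile was computed from.
#' @param params A [scan_params()].
#' @return data.frame of class `homozygosity_runs`: chrom, start_index,
#'   end_index (row indices into the marker table), start_bp, end_bp,
#'   snp_count, span_bp, shared_allele_consistent.
#' @export
find_runs <- function(profile, matrix, params = scan_params()) {
  .check(inherits(profile, "he_profile"), "profile must be a he_profile")
  .check(inherits(matrix, "genotype_matrix"), "matrix must be a genotype_matrix")
  .check(nrow(profile) == nrow(matrix$markers) &&
           all(profile$id == matrix$markers$id),
         "profile is not aligned to the matrix markers")
  q <- profile$eligible & !is.na(profile$he) & profile$he == 0
  if (params$require_shared_allele) q <- q & profile$shared_hom
  out <- list()
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    r <- rle(q[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= params$min_run_snps)
    for (k in keep) {
      i1 <- idx[starts[k]]; i2 <- idx[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_index = i1, end_index = i2,
        start_bp = profile$pos[i1], end_bp = profile$pos[i2],
        snp_count = i2 - i1 + 1L,
        span_bp = interval_length(profile$pos[i1], profile$pos[i2]),
        shared_allele_consistent = all(profile$shared_hom[i1:i2]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    runs <- data.frame(chrom = character(0), start_index = integer(0),
                       end_index = integer(0), start_bp = integer(0),
                       end_bp = integer(0), snp_count = integer(0),
                       span_bp = integer(0),
                       shared_allele_consistent = logical(0))
  } else {
    runs <- do.call(rbind, out)
    ord <- order(-runs$snp_count, -runs$span_bp,
                 match(runs$chrom, unique(profile$chrom)), runs$start_bp)
    runs <- runs[ord, , drop = FALSE]
    rownames(runs) <- NULL
  }
  class(runs) <- c("homozygosity_runs", "data.frame")
  runs
}

#' Ranked run report
#'
#' @param runs Output of [find_runs()] (already in rank order).
#' @param top_k Number of runs to report.
#' @return data.frame with rank, chromosome, bp interval, snp_count,
#'   span_bp (inclusive convention, see column name), shared-allele flag.
#' @export
rank_report <- function(runs, top_k = 10) {
  .check(inherits(runs, "homozygosity_runs"), "runs must come from find_runs")
  n <- min(top_k, nrow(runs))
  out <- runs[seq_len(n), , drop = FALSE]
  data.frame(rank = seq_len(n), chrom = out$chrom,
             start_bp = out$start_bp, end_bp = out$end_bp,
             snp_count = out$snp_count,
             span_bp_inclusive = out$span_bp,
             shared_allele_consistent = out$shared_allele_consistent,
             stringsAsFactors = FALSE)
}

#' Plot the He profile along the genome
#'
#' He versus position, one panel per chromosome, with optional dotted
#' boundaries delimiting a candidate region and an optional second profile
#' overlaid for comparison (e.g. a reference panel).
#'
#' @param profile A `he_profile`.
#' @param highlight Optional list/data.frame with `chrom`, `start_bp`,
#'   `end_bp`.
#' @param overlay Optional second `he_profile` drawn in red.
#' @param path Output figure path (.png or .svg).
#' @return `path`, invisibly.
#' @export
he_profile_plot <- function(profile, highlight = NULL, overlay = NULL,
                            path = "he_profile.png") {
  .check(inherits(profile, "he_profile"), "profile must be a he_profile")
  .check(nrow(profile) > 0, "profile is empty")
  df <- data.frame(chrom = profile$chrom, pos = profile$pos / 1e6,
                   he = profile$he, series = "cases")
  if (!is.null(overlay))
    df <- rbind(df, data.frame(chrom = overlay$chrom,
                               pos = overlay$pos / 1e6, he = overlay$he,
                               series = "panel"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$he,
                                        colour = .data$series)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(cases = "#2166ac",
                                            panel = "#b2182b")) +
    ggplot2::labs(x = "position (Mb)", y = expression(H[e])) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = if (is.null(overlay)) "none" else
      "bottom")
  if (!is.null(highlight) && length(highlight) > 0) {
    hl <- as.data.frame(highlight)
    hl <- data.frame(chrom = hl$chrom,
                     xint = c(hl$start_bp, hl$end_bp) / 1e6)
    p <- p + ggplot2::geom_vline(data = hl,
                                 ggplot2::aes(xintercept = .data$xint),
                                 linetype = "dotted")
  }
  ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
  invisible(path)
}
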