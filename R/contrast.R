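#' Parameters for the case-versus-panel genotype contrast
#'
#' @param mode "allele_absent" (default, stricter): the case's homozygous
#'   alternate allele must not appear in any panel genotype.
#'   "genotype_absent": no panel sample may have the same genotype as the
#'   case (a panel heterozygote for the allele is tolerated), matching the
#'   behaviour of genotype-level contrast tools.
#' @param require_case_homozygous_alt Case must be homozygous for an
#'   alternate allele (a causal recessive allele absent from controls must
#'   be non-reference and two-copy in the case).
#' @param treat_panel_missing_as "absent" (default): missing panel
#'   genotypes do not count as carrying anything; "unknown_excludes":
#'   records with any missing panel genotype are dropped.
#' @param region Optional list/vector with `chrom`, `start`, `end`
#'   (1-based inclusive) applied as a final filter.
#' @return List of class `contrast_params`.
#' @export
contrast_params <- function(mode = c("allele_absent", "genotype_absent"),
                            require_case_homozygous_alt = TRUE,
                            treat_panel_missing_as = c("absent",
                                                       "unknown_excludes"),
                            region = NULL) {
  mode <- match.arg(mode)
  treat_panel_missing_as <- match.arg(treat_panel_missing_as)
  if (!is.null(region)) {
    region <- as.list(region)
    .check(all(c("chrom", "start", "end") %in% names(region)),
           "region needs chrom, start, end")
    .check(as.numeric(region$start) <= as.numeric(region$end),
           "region start must not exceed end")
  }
  structure(list(mode = mode,
                 require_case_homozygous_alt =
                   isTRUE(require_case_homozygous_alt),
                 treat_panel_missing_as = treat_panel_missing_as,
                 region = region),
            class = "contrast_params")
}

#' Contrast case genotypes against a control panel
#'
#' Retains variant records where the case is homozygous for an alternate
#' allele and that allele (allele_absent mode) or genotype (genotype_absent
#' mode) is absent from every panel sample. Multi-allelic records are
#' retained if the case-homozygous alternate passes. Per-stage counts are
#' reported and are non-increasing along the chain.
#'
#' @param variants A [variant_set()].
#' @param case_id Case sample name (must be in the file).
#' @param panel_ids Panel sample names, disjoint from the case.
#' @param params A [contrast_params()].
#' @return Object of class `candidate_set`: filtered `variants`, per-record
#'   provenance `flags`, `stages` (named counts), `params`.
#' @export
contrast <- function(variants, case_id, panel_ids,
                     params = contrast_params()) {
  .check(inherits(variants, "variant_set"), "variants must be a variant_set")
  .check(length(case_id) == 1 && case_id %in% variants$samples,
         "case sample '%s' missing from the variant file", case_id)
  missing <- setdiff(panel_ids, variants$samples)
  .check(length(missing) == 0, "panel sample(s) missing from file: %s",
         paste(missing, collapse = ", "))
  .check(!(case_id %in% panel_ids), "case and panel samples must be disjoint")
  n <- nrow(variants$records)
  al <- .gt_alleles(variants)
  ci <- match(case_id, variants$samples)
  pi <- match(panel_ids, variants$samples)
  case1 <- al$a1[, ci]; case2 <- al$a2[, ci]
  hom_alt <- !is.na(case1) & !is.na(case2) & case1 == case2 & case1 > 0L
  if (!params$require_case_homozygous_alt) {
    keep1 <- !is.na(case1) & !is.na(case2) &
      (case1 > 0L | case2 > 0L)
  } else {
    keep1 <- hom_alt
  }
  p1 <- al$a1[, pi, drop = FALSE]; p2 <- al$a2[, pi, drop = FALSE]
  a <- ifelse(hom_alt, case1, ifelse(!is.na(case1) & case1 > 0L, case1,
                                     case2))
  allele_in_panel <- rowSums((p1 == a) | (p2 == a), na.rm = TRUE) > 0
  same_gt_in_panel <- rowSums((pmin(p1, p2) == pmin(case1, case2)) &
                                (pmax(p1, p2) == pmax(case1, case2)),
                              na.rm = TRUE) > 0
  panel_missing <- rowSums(is.na(p1) | is.na(p2)) > 0
  private <- if (params$mode == "allele_absent") !allele_in_panel
             else !same_gt_in_panel
  keep2 <- keep1 & private
  if (params$treat_panel_missing_as == "unknown_excludes")
    keep2 <- keep2 & !panel_missing
  keep3 <- keep2
  if (!is.null(params$region)) {
    r <- params$region
    keep3 <- keep2 & variants$records$chrom == r$chrom &
      variants$records$pos >= r$start & variants$records$pos <= r$end
  }
  flags <- data.frame(id = variants$records$id,
                      chrom = variants$records$chrom,
                      pos = variants$records$pos,
                      case_hom_alt = hom_alt, private = private,
                      panel_missing = panel_missing,
                      retained = keep3, stringsAsFactors = FALSE)
  stages <- c(input = n, case_genotype = sum(keep1),
              private = sum(keep2), in_region = sum(keep3))
  if (is.null(params$region)) stages <- stages[1:3]
  kept <- which(keep3)
  out <- variant_set(variants$records[kept, , drop = FALSE],
                     variants$gt[kept, , drop = FALSE])
  structure(list(variants = out, flags = flags, stages = stages,
                 params = params, case_id = case_id,
                 panel_ids = panel_ids),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set stages:",
      paste(sprintf("%s=%d", names(x$stages), x$stages), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Restrict candidates to a genomic region
#'
#' Retains records whose anchored position lies inside the 1-based
#' inclusive interval; indels qualify via their anchor.
#'
#' @param candidates A `candidate_set` from [contrast()].
#' @param region List/vector with `chrom`, `start`, `end` (the `start_bp` /
#'   `end_bp` columns of a run report are also accepted).
#' @return A filtered `candidate_set` with an `in_region` stage count.
#' @export
intersect_region <- function(candidates, region) {
  .check(inherits(candidates, "candidate_set"), "not a candidate_set")
  region <- as.list(region)
  if (!is.null(region$start_bp)) region$start <- region$start_bp
  if (!is.null(region$end_bp)) region$end <- region$end_bp
  .check(all(c("chrom", "start", "end") %in% names(region)),
         "region needs chrom, start, end")
  .check(as.numeric(region$start) <= as.numeric(region$end),
         "region start must not exceed end")
  vs <- candidates$variants
  keep <- vs$records$chrom == region$chrom &
    vs$records$pos >= as.numeric(region$start) &
    vs$records$pos <= as.numeric(region$end)
  out <- candidates
  out$variants <- variant_set(vs$records[keep, , drop = FALSE],
                              vs$gt[keep, , drop = FALSE])
  out$flags$retained <- out$flags$retained &
    out$flags$id %in% vs$records$id[keep] &
    paste(out$flags$chrom, out$flags$pos) %in%
      paste(vs$records$chrom[keep], vs$records$pos[keep])
  out$stages <- c(out$stages, in_region = sum(keep))
  out$region <- region
  out
}

#' Staged contrast report with consequence classes
#'
#' Counts retained candidates by coding-consequence class; the
#' protein-altering classes sum to the total protein-altering count.
#'
#' @param candidates A `candidate_set`.
#' @param consequences Optional list of `consequence` objects aligned to the
#'   retained records (e.g. from [annotate_variant()]).
#' @return List of class `contrast_report`: `stages`, `by_class`
#'   (data.frame class/count), `n_protein_altering`.
#' @export
contrast_report <- function(candidates, consequences = NULL) {
  .check(inherits(candidates, "candidate_set"), "not a candidate_set")
  classes <- c("synonymous", "missense", "inframe_insertion",
               "inframe_deletion", "frameshift", "stop_gained", "stop_lost",
               "start_lost", "noncoding", "intronic", "intergenic",
               "splice_region_unsupported")
  counts <- stats::setNames(integer(length(classes)), classes)
  if (!is.null(consequences) && length(consequences)) {
    .check(length(consequences) == nrow(candidates$variants$records),
           "one consequence per retained record required")
    got <- table(vapply(consequences, function(x) x$class, character(1)))
    counts[names(got)] <- as.integer(got)
  }
  altering <- c("missense", "inframe_insertion", "inframe_deletion",
                "frameshift", "stop_gained", "stop_lost", "start_lost")
  structure(list(stages = candidates$stages,
                 by_class = data.frame(class = classes,
                                       count = as.integer(counts),
                                       stringsAsFactors = FALSE),
                 n_protein_altering = sum(counts[altering])),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("stages:", paste(sprintf("%s=%d", names(x$stages), x$stages),
                       collapse = " -> "), "\n")
  nz <- x$by_class[x$by_class$count > 0, , drop = FALSE]
  if (nrow(nz)) {
    cat("consequence classes:\n")
    for (i in seq_len(nrow(nz)))
      cat(sprintf("  %-26s %d\n", nz$class[i], nz$count[i]))
  }
  cat("protein-altering candidates:", x$n_protein_altering, "\n")
  invisible(x)
}
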