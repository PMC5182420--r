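#' Validate and normalise a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with paths to the
#' genotype matrix, case-id list, variant file, reference FASTA and
#' transcript GFF3, the VCF case/panel sample ids, optional domain table,
#' scan and contrast parameters, an output directory and a seed.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    .check(file.exists(config), "no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  .check(is.list(config), "config must be a list or YAML path")
  need <- c("genotypes", "cases", "vcf", "case_sample", "panel_samples",
            "fasta", "gff3", "out_dir")
  miss <- setdiff(need, names(config))
  .check(length(miss) == 0, "config missing field(s): %s",
         paste(miss, collapse = ", "))
  for (f in c("genotypes", "cases", "vcf", "fasta", "gff3"))
    .check(file.exists(config[[f]]), "config path %s does not exist: %s",
           f, config[[f]])
  if (!is.null(config$domains))
    .check(file.exists(config$domains), "domain table does not exist: %s",
           config$domains)
  scan <- config$scan %||% list()
  config$scan_params <- scan_params(
    min_run_snps = scan$min_run_snps %||% 20,
    require_shared_allele = scan$require_shared_allele %||% FALSE)
  config$min_called <- scan$min_called
  con <- config$contrast %||% list()
  config$contrast_params <- contrast_params(
    mode = con$mode %||% "allele_absent",
    treat_panel_missing_as = con$treat_panel_missing_as %||% "absent")
  config$seed <- as.integer(config$seed %||% 1L)
  config$log_level <- config$log_level %||% "info"
  structure(config, class = c("pipeline_config", "list"))
}

.log_stage <- function(cfg, stage, msg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[rohmap:%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full mapping pipeline: scan, contrast, intersect, annotate
#'
#' Computes the case-group He profile and homozygosity runs from the
#' genotype matrix, takes the rank-1 run as the mapped region, contrasts
#' the case sample against the control panel in the variant file,
#' intersects the private candidates with the region, annotates the
#' survivors against the transcript models and assembles a candidate
#' report. Deterministic given its inputs. If no run passes the scan
#' thresholds the report carries `no_mappable_region = TRUE` (not an
#' error).
#'
#' @param config A [pipeline_config()], raw list, or YAML path.
#' @return List of class `candidate_report`: `region` (rank-1 run),
#'   `runs` (ranked table), `he_profile`, `stages`, `candidates`
#'   (data.frame with consequence fields and HGVS strings),
#'   `contrast_report`, `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  stage <- "scan"
  report <- tryCatch({
    gm <- read_genotype_matrix(cfg$genotypes)
    cases <- readLines(cfg$cases, warn = FALSE)
    cases <- cases[nzchar(cases)]
    prof <- case_heterozygosity(gm, cases,
                                min_called = cfg$min_called %||%
                                  length(cases))
    runs <- find_runs(prof, gm, cfg$scan_params)
    .log_stage(cfg, stage, "%d case samples, %d markers, %d run(s)",
               length(cases), nrow(gm$markers), nrow(runs))
    if (nrow(runs) == 0) {
      return(structure(list(no_mappable_region = TRUE, runs = runs,
                            he_profile = prof,
                            provenance = .provenance(cfg)),
                       class = "candidate_report"))
    }
    region <- list(chrom = runs$chrom[1], start = runs$start_bp[1],
                   end = runs$end_bp[1])

    stage <- "contrast"
    panel_ids <- readLines(cfg$panel_samples, warn = FALSE)
    panel_ids <- panel_ids[nzchar(panel_ids)]
    vs <- read_variants(cfg$vcf)
    cs <- contrast(vs, cfg$case_sample, panel_ids, cfg$contrast_params)
    .log_stage(cfg, stage, "%s", paste(sprintf("%s=%d", names(cs$stages),
                                               cs$stages), collapse = " -> "))

    stage <- "intersect"
    cs <- intersect_region(cs, region)

    stage <- "annotate"
    reference <- read_reference(cfg$fasta)
    models <- read_transcripts(cfg$gff3)
    domains <- if (!is.null(cfg$domains))
      as.data.frame(data.table::fread(cfg$domains)) else NULL
    recs <- cs$variants$records
    cand_rows <- list()
    consequences <- list()
    for (i in seq_len(nrow(recs))) {
      alts <- strsplit(recs$alt[i], ",", fixed = TRUE)[[1]]
      overlapping <- Filter(function(m) {
        m$chrom == recs$chrom[i] &&
          recs$pos[i] >= min(m$exons$start) - 5000 &&
          recs$pos[i] <= max(m$exons$end) + 5000
      }, models)
      for (alt in alts) {
        v <- list(chrom = recs$chrom[i], pos = recs$pos[i],
                  ref = recs$ref[i], alt = alt)
        cons_list <- if (length(overlapping))
          lapply(overlapping, function(m) annotate_variant(v, m, reference))
          else list(.new_consequence(NA_character_, "intergenic"))
        for (cons in cons_list) {
          dom <- if (!is.null(domains) &&
                     !is.na(cons$protein_pos_first_affected))
            paste(sprintf("%s:%s", domain_overlap(cons, domains)$name,
                          domain_overlap(cons, domains)$status),
                  collapse = ",") else NA_character_
          cand_rows[[length(cand_rows) + 1L]] <- data.frame(
            chrom = recs$chrom[i], pos = recs$pos[i], id = recs$id[i],
            ref = recs$ref[i], alt = alt,
            transcript = cons$transcript_id %||% NA_character_,
            class = cons$class,
            protein_pos = cons$protein_pos_first_affected,
            hgvs_p = cons$hgvs_p, domains = dom,
            stringsAsFactors = FALSE)
          consequences[[length(consequences) + 1L]] <- cons
        }
      }
    }
    candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
      data.frame(chrom = character(0), pos = integer(0), id = character(0),
                 ref = character(0), alt = character(0),
                 transcript = character(0), class = character(0),
                 protein_pos = integer(0), hgvs_p = character(0),
                 domains = character(0))
    # one consequence per retained record for the staged report: use the
    # first (alt, transcript) combination of each record
    rep_cons <- consequences[!duplicated(paste(candidates$chrom,
                                               candidates$pos))]
    crep <- contrast_report(cs, rep_cons)
    .log_stage(cfg, stage, "%d candidate annotation row(s)",
               nrow(candidates))
    structure(list(no_mappable_region = FALSE,
                   region = region, runs = rank_report(runs, top_k = 10),
                   he_profile = prof, stages = cs$stages,
                   candidates = candidates, contrast_report = crep,
                   provenance = .provenance(cfg)),
              class = "candidate_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report
}

.provenance <- function(cfg) {
  paths <- c("genotypes", "cases", "vcf", "fasta", "gff3")
  sums <- vapply(paths, function(f) unname(tools::md5sum(cfg[[f]])),
                 character(1))
  list(package_version = as.character(utils::packageVersion("rohmap")),
       input_md5 = stats::setNames(sums, paths),
       config = cfg[setdiff(names(cfg),
                            c("scan_params", "contrast_params"))],
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.candidate_report <- function(x, ...) {
  if (isTRUE(x$no_mappable_region)) {
    cat("candidate_report: no mappable region\n")
    return(invisible(x))
  }
  cat(sprintf("candidate_report: rank-1 region %s:%d-%d (%d SNPs, %d bp)\n",
              x$region$chrom, x$region$start, x$region$end,
              x$runs$snp_count[1], x$runs$span_bp_inclusive[1]))
  cat("stages:", paste(sprintf("%s=%d", names(x$stages), x$stages),
                       collapse = " -> "), "\n")
  cat(sprintf("%d candidate annotation row(s)\n", nrow(x$candidates)))
  prot <- x$candidates[!x$candidates$class %in%
                         c("noncoding", "intronic", "intergenic",
                           "synonymous"), , drop = FALSE]
  for (i in seq_len(nrow(prot)))
    cat(sprintf("  %s:%d %s>%s  %s  %s  p.%s\n", prot$chrom[i], prot$pos[i],
                prot$ref[i], prot$alt[i], prot$transcript[i], prot$class[i],
                prot$hgvs_p[i]))
  invisible(x)
}

#' Write the candidate report to an output directory
#'
#' Emits ranked runs, the He table, the candidate table and a YAML report
#' body. The YAML body is byte-stable across reruns except for the
#' timestamp, which can be suppressed.
#'
#' @param report A `candidate_report`.
#' @param out_dir Output directory (created if needed).
#' @param include_timestamp Include the run timestamp in the YAML body.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, include_timestamp = TRUE) {
  .check(inherits(report, "candidate_report"), "not a candidate_report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$runs))
    data.table::fwrite(report$runs, file.path(out_dir, "runs.tsv"),
                       sep = "\t")
  if (!is.null(report$he_profile))
    data.table::fwrite(report$he_profile, file.path(out_dir, "he.tsv"),
                       sep = "\t")
  if (!is.null(report$candidates))
    data.table::fwrite(report$candidates,
                       file.path(out_dir, "candidates.tsv"), sep = "\t")
  body <- report[setdiff(names(report), c("he_profile", "runs",
                                          "candidates"))]
  if (!include_timestamp) body$provenance$timestamp <- NULL
  body$provenance$config <- lapply(body$provenance$config, function(x)
    if (is.character(x) || is.numeric(x) || is.logical(x)) x else NULL)
  yaml::write_yaml(body, file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}

#' Generate a complete synthetic demo study
#'
#' Builds a small end-to-end fixture: a multi-generation pedigree with at
#' least 8 affected dogs, gene-dropped chip genotypes, a reference bundle
#' with the toy 18-exon transcript, a multi-sample VCF with the planted
#' private frameshift (case = one affected dog, panel of 20 genomes), the
#' ground-truth sidecars and a ready-to-run pipeline config. Deterministic
#' per seed; runs in well under a minute.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param panel_size Panel genomes in the VCF.
#' @param panel_carriers Panel samples carrying the planted allele
#'   (0 keeps it private; use 1 to break privacy deliberately).
#' @param n_background Background variant count in the VCF.
#' @return List with `dir`, `config` (path), `truth` (pedigree, gene-drop
#'   truth, planted-variant truth), `paths`.
#' @export
make_demo <- function(seed = 1, dir = tempfile("rohmap_demo_"),
                      panel_size = 20, panel_carriers = 0,
                      n_background = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- build_aht_like_pedigree(min_affected = 8,
                                 seed = .sub_seed(seed, 1))
  cfg <- sim_config(seed = .sub_seed(seed, 2))
  gd <- gene_drop(ped, cfg)
  bundle <- make_reference_bundle(cfg, seed = .sub_seed(seed, 3))
  affected <- ped$id[ped$phenotype == "affected"]
  cases <- utils::tail(affected, 11)       # up to 11 chip-typed cases
  case_sample <- utils::tail(affected, 1)  # the whole-genome-sequenced case
  fix <- plant_private_frameshift(bundle, panel_size = panel_size,
                                  case_id = case_sample,
                                  n_background = n_background,
                                  panel_carriers = panel_carriers,
                                  seed = .sub_seed(seed, 4))
  paths <- list(
    pedigree = file.path(dir, "pedigree.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    cases = file.path(dir, "cases.txt"),
    vcf = file.path(dir, "variants.vcf.gz"),
    fasta = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "transcripts.gff3"),
    panel = file.path(dir, "panel_samples.txt"),
    truth_segments = file.path(dir, "truth_segments.tsv"),
    truth_causal = file.path(dir, "truth_causal.tsv"),
    truth_variant = file.path(dir, "truth_variant.tsv"),
    config = file.path(dir, "config.yaml"))
  write_pedigree(ped, paths$pedigree)
  write_genotype_matrix(gd$genotypes, paths$genotypes)
  writeLines(cases, paths$cases)
  contigs <- stats::setNames(cfg$chromosomes$length_bp,
                             cfg$chromosomes$chrom)
  write_variants(fix$variants, paths$vcf, contigs = contigs)
  write_reference_bundle(bundle, paths$fasta, paths$gff3)
  writeLines(fix$panel_ids, paths$panel)
  data.table::fwrite(gd$truth$segments, paths$truth_segments, sep = "\t")
  data.table::fwrite(data.frame(individual = names(gd$truth$causal),
                                causal_dosage = unname(gd$truth$causal)),
                     paths$truth_causal, sep = "\t")
  pl <- fix$truth$planted
  data.table::fwrite(data.frame(
    key = c("chrom", "pos", "ref", "alt", "cds_start", "cds_end",
            "deletion_length", "hgvs_p", "class"),
    value = c(pl$chrom, pl$pos, pl$ref, pl$alt, pl$cds_start, pl$cds_end,
              pl$deletion_length, pl$hgvs_p, pl$consequence$class)),
    paths$truth_variant, sep = "\t")
  config <- list(genotypes = paths$genotypes, cases = paths$cases,
                 vcf = paths$vcf, case_sample = case_sample,
                 panel_samples = paths$panel, fasta = paths$fasta,
                 gff3 = paths$gff3, out_dir = file.path(dir, "out"),
                 scan = list(min_run_snps = 20),
                 contrast = list(mode = "allele_absent"),
                 seed = seed, log_level = "quiet")
  yaml::write_yaml(config, paths$config)
  list(dir = dir, config = paths$config, paths = paths,
       truth = list(pedigree = ped, gene_drop = gd$truth,
                    planted = fix$truth$planted,
                    records = fix$truth$records,
                    case_sample = case_sample, cases = cases,
                    sim_config = cfg, bundle_site = bundle$site))
}
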