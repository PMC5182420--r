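#' @keywords internal
# Poisson crossover counts under the Haldane (no interference) model.
.haldane_crossovers <- function(map_length_morgans, n = 1) {
  stats::rpois(n, map_length_morgans)
}

# One gamete from a parent's two homologues (segment tables start/end/hap
# tiling [1, L]). When `required_hom` is given, the starting phase is chosen
# so that the homologue present at `causal_pos` is the required one; with
# crossover positions independent of phase this samples the correct
# conditional distribution.
.gamete <- function(h1, h2, L, morgans, required_hom = NULL,
                    causal_pos = NULL) {
  k <- .haldane_crossovers(morgans)
  bp <- if (k > 0) sort(ceiling(stats::runif(k) * (L - 1L))) else integer(0)
  if (is.null(required_hom)) {
    s <- sample(1:2, 1)
  } else {
    parity <- sum(bp < causal_pos)
    s <- if (parity %% 2 == 0) required_hom else 3L - required_hom
  }
  cuts <- c(0L, bp, L)
  segs <- vector("list", length(cuts) - 1L)
  hom <- s
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i] + 1L
    hi <- cuts[i + 1L]
    if (lo > hi) { hom <- 3L - hom; next }
    h <- if (hom == 1L) h1 else h2
    keep <- h$end >= lo & h$start <= hi
    part <- h[keep, , drop = FALSE]
    part$start[1] <- max(part$start[1], lo)
    part$end[nrow(part)] <- min(part$end[nrow(part)], hi)
    segs[[i]] <- part
    hom <- 3L - hom
  }
  out <- do.call(rbind, segs)
  # merge adjacent segments with identical founder haplotype
  if (nrow(out) > 1) {
    same <- c(FALSE, out$hap[-1] == out$hap[-nrow(out)])
    grp <- factor(cumsum(!same), levels = unique(cumsum(!same)))
    out <- data.frame(start = as.integer(tapply(out$start, grp, min)),
                      end = as.integer(tapply(out$end, grp, max)),
                      hap = out$hap[!same],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Gene-drop simulation down a pedigree
#'
#' Assigns labelled haplotypes to founders, transmits them through every
#' meiosis with Haldane-model recombination (crossover count Poisson with
#' mean equal to the map length, no interference), conditions transmissions
#' at the causal locus on the causal-allele carriage recorded in the
#' pedigree, reads chip-like biallelic genotypes off the dropped haplotypes
#' and applies independent per-call missingness. Identical
#' (pedigree, config) input gives identical output.
#'
#' @param ped A [pedigree()] with causal carriage columns populated.
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `gene_drop_truth`: inherited-segment table per individual and
#'   homologue, causal dosages, marker map and config).
#' @export
gene_drop <- function(ped, config) {
  .check(inherits(ped, "pedigree"), "ped must be a pedigree")
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  .check(!anyNA(ped$causal_pat) && !anyNA(ped$causal_mat),
         "pedigree lacks causal-allele carriage (simulated pedigrees only)")
  chroms <- config$chromosomes
  .with_seed(config$seed, {
    # marker map
    maps <- lapply(seq_len(nrow(chroms)), function(i) {
      n <- config$n_markers[i]
      L <- chroms$length_bp[i]
      pos <- if (config$marker_spacing == "random")
        sort(sample.int(L, n, useHash = TRUE)) else
        as.integer(round(seq(L / (2 * n), L - L / (2 * n), length.out = n)))
      .check(all(diff(pos) > 0), "marker positions collide; reduce n_markers")
      data.frame(id = sprintf("%s_m%04d", chroms$chrom[i], seq_len(n)),
                 chrom = chroms$chrom[i], pos = pos,
                 stringsAsFactors = FALSE)
    })
    markers <- do.call(rbind, maps)

    founders <- ped$id[ped$founder]
    hom_labels <- as.vector(t(outer(founders, c(".p", ".m"), paste0)))
    n_hom <- length(hom_labels)
    carrier_hom <- c(ped$id[ped$founder & ped$causal_pat == 1L] %0%
                       ".p", ped$id[ped$founder & ped$causal_mat == 1L] %0%
                       ".m")
    K <- config$n_founder_haplotypes %||% n_hom
    K <- max(2L, min(K, n_hom))
    pool_of <- stats::setNames(integer(n_hom), hom_labels)
    pool_of[] <- NA_integer_
    pool_of[carrier_hom] <- 1L
    free <- setdiff(hom_labels, carrier_hom)
    pool_of[free] <- if (K >= n_hom) seq_along(free) + 1L else
      sample(2:K, length(free), replace = TRUE)

    # founder haplotype alleles per chromosome: K x n_markers
    n_pool <- max(pool_of)
    pool_alleles <- lapply(seq_len(nrow(chroms)), function(i) {
      n <- config$n_markers[i]
      p <- stats::runif(n, config$maf_range[1], config$maf_range[2])
      matrix(stats::rbinom(n_pool * n, 1L, rep(p, each = n_pool)),
             nrow = n_pool)
    })

    n_ind <- nrow(ped)
    calls <- matrix(NA_integer_, nrow = nrow(markers), ncol = n_ind,
                    dimnames = list(markers$id, ped$id))
    seg_rows <- list()
    for (ci in seq_len(nrow(chroms))) {
      ch <- chroms$chrom[ci]
      L <- chroms$length_bp[ci]
      morgans <- L / 1e6 * config$cm_per_mb / 100
      is_causal_chr <- identical(ch, config$causal_chrom)
      mp <- maps[[ci]]$pos
      homs <- vector("list", n_ind)
      names(homs) <- ped$id
      for (i in seq_len(n_ind)) {
        id <- ped$id[i]
        if (ped$founder[i]) {
          homs[[i]] <- list(
            data.frame(start = 1L, end = L, hap = paste0(id, ".p"),
                       stringsAsFactors = FALSE),
            data.frame(start = 1L, end = L, hap = paste0(id, ".m"),
                       stringsAsFactors = FALSE))
        } else {
          s <- match(ped$sire[i], ped$id)
          d <- match(ped$dam[i], ped$id)
          req_p <- req_m <- NULL
          if (is_causal_chr) {
            if (ped$causal_pat[s] != ped$causal_mat[s])
              req_p <- if (ped$causal_pat[i] == ped$causal_pat[s]) 1L else 2L
            if (ped$causal_pat[d] != ped$causal_mat[d])
              req_m <- if (ped$causal_mat[i] == ped$causal_pat[d]) 1L else 2L
          }
          homs[[i]] <- list(
            .gamete(homs[[s]][[1]], homs[[s]][[2]], L, morgans, req_p,
                    config$causal_pos),
            .gamete(homs[[d]][[1]], homs[[d]][[2]], L, morgans, req_m,
                    config$causal_pos))
        }
      }
      # genotypes at markers
      row_off <- if (ci == 1) 0L else sum(config$n_markers[1:(ci - 1)])
      for (i in seq_len(n_ind)) {
        dose <- integer(length(mp))
        for (h in 1:2) {
          seg <- homs[[i]][[h]]
          idx <- findInterval(mp, seg$start)
          pidx <- pool_of[seg$hap[idx]]
          dose <- dose + pool_alleles[[ci]][cbind(pidx, seq_along(mp))]
        }
        calls[row_off + seq_along(mp), i] <- dose
        for (h in 1:2) {
          seg <- homs[[i]][[h]]
          seg_rows[[length(seg_rows) + 1L]] <- list(
            individual = rep(ped$id[i], nrow(seg)),
            homologue = rep(c("pat", "mat")[h], nrow(seg)),
            chrom = rep(ch, nrow(seg)), start = seg$start, end = seg$end,
            hap = seg$hap)
        }
      }
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(calls)) < config$missing_rate
      calls[drop] <- NA_integer_
    }
    segments <- data.frame(
      individual = unlist(lapply(seg_rows, `[[`, "individual")),
      homologue = unlist(lapply(seg_rows, `[[`, "homologue")),
      chrom = unlist(lapply(seg_rows, `[[`, "chrom")),
      start = unlist(lapply(seg_rows, `[[`, "start")),
      end = unlist(lapply(seg_rows, `[[`, "end")),
      hap = unlist(lapply(seg_rows, `[[`, "hap")),
      stringsAsFactors = FALSE)
    truth <- structure(
      list(segments = segments,
           causal = causal_dosage(ped),
           carrier_haplotypes = carrier_hom,
           causal_chrom = config$causal_chrom,
           causal_pos = config$causal_pos,
           config = config),
      class = "gene_drop_truth")
    list(genotypes = genotype_matrix(markers, ped$id, calls), truth = truth)
  })
}

# small helper: paste suffix onto possibly-empty vector
`%0%` <- function(x, suffix) if (length(x)) paste0(x, suffix) else character(0)

#' @export
print.gene_drop_truth <- function(x, ...) {
  cat(sprintf(
    "gene_drop_truth: %d segments, %d individuals, causal %s:%d\n",
    nrow(x$segments), length(x$causal), x$causal_chrom, x$causal_pos))
  invisible(x)
}
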