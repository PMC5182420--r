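#' Pedigree container
#'
#' A pedigree is a data.frame with one row per individual, parents listed
#' before offspring. Columns: `id`, `sire`, `dam` (NA for founders), `sex`
#' ("M"/"F"), `phenotype` ("affected"/"unaffected"/"unknown"), `founder`
#' (logical), `generation` (integer), and the per-homologue causal-allele
#' carriage used by the gene-drop simulator: `causal_pat`, `causal_mat`
#' (0/1; NA when unknown, e.g. for pedigrees read from disk).
#'
#' @param df data.frame as described above.
#' @return Object of class `pedigree`.
#' @export
pedigree <- function(df) {
  need <- c("id", "sire", "dam", "sex", "phenotype")
  .check(is.data.frame(df) && all(need %in% names(df)),
         "pedigree needs columns: %s", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (is.null(df$founder)) df$founder <- is.na(df$sire) & is.na(df$dam)
  if (is.null(df$generation)) df$generation <- NA_integer_
  if (is.null(df$causal_pat)) df$causal_pat <- NA_integer_
  if (is.null(df$causal_mat)) df$causal_mat <- NA_integer_
  .check(!anyDuplicated(df$id), "duplicate individual ids")
  .check(all(df$sex %in% c("M", "F")), "sex must be 'M' or 'F'")
  .check(all(df$phenotype %in% c("affected", "unaffected", "unknown")),
         "phenotype must be affected/unaffected/unknown")
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    for (p in c(df$sire[i], df$dam[i])) {
      if (!is.na(p))
        .check(p %in% seen,
               "parent '%s' of '%s' is not listed earlier in the pedigree",
               p, df$id[i])
    }
    seen <- c(seen, df$id[i])
  }
  .check(all(is.na(df$sire[df$founder]) & is.na(df$dam[df$founder])),
         "founders must have no parents")
  # parents listed strictly earlier => no individual can be its own ancestor
  structure(df, class = c("pedigree", "data.frame"))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf(
    "pedigree: %d individuals (%d founders, %d affected), %d generations\n",
    nrow(x), sum(x$founder), sum(x$phenotype == "affected"),
    length(unique(x$generation))))
  invisible(x)
}

#' Causal-allele dosage per individual
#' @param ped A [pedigree()] with causal carriage columns populated.
#' @return Named integer vector of dosages (0/1/2).
#' @export
causal_dosage <- function(ped) {
  .check(inherits(ped, "pedigree"), "ped must be a pedigree")
  stats::setNames(ped$causal_pat + ped$causal_mat, ped$id)
}

#' Simulate a breed history pedigree for a recessive founder mutation
#'
#' Emulates the breeding structure behind a young hairless breed: a single
#' founder female carries one copy of the causal allele; carriers and
#' affected dogs are preferentially mated across generations ("careful
#' backcrossing"), unrelated coated outcross founders enter the gene pool in
#' later generations, and popular sires are reused across many matings.
#' Phenotype is fully penetrant recessive: affected iff two causal copies.
#'
#' The construction is retried with derived sub-seeds (deterministically)
#' until the pedigree contains at least `min_affected` affected individuals.
#'
#' @param n_generations Number of offspring generations (>= 2).
#' @param litter_size Offspring per mating.
#' @param matings_per_generation Matings per generation (>= 1).
#' @param backcross_rate Fraction of matings that pair two carrier-line
#'   (carrier or affected) individuals.
#' @param outcross_rate Fraction of matings (generation >= 3) that bring in a
#'   new unrelated non-carrier founder.
#' @param popular_sire_rate Probability that a mating reuses the generation's
#'   designated popular sire.
#' @param min_affected Minimum affected individuals required.
#' @param seed Integer seed; same seed, same pedigree.
#' @param max_tries Attempts before giving up.
#' @return A [pedigree()].
#' @export
build_aht_like_pedigree <- function(n_generations = 6, litter_size = 4,
                                    matings_per_generation = 6,
                                    backcross_rate = 0.6,
                                    outcross_rate = 0.15,
                                    popular_sire_rate = 0.5,
                                    min_affected = 1,
                                    seed = 1, max_tries = 50) {
  .check(n_generations >= 2, "n_generations must be >= 2")
  .check(litter_size >= 1, "litter_size must be >= 1 (no offspring possible)")
  .check(matings_per_generation >= 1, "matings_per_generation must be >= 1")
  .check(backcross_rate >= 0 && backcross_rate <= 1 &&
           outcross_rate >= 0 && outcross_rate <= 1 &&
           popular_sire_rate >= 0 && popular_sire_rate <= 1,
         "rates must be in [0, 1]")
  for (try in seq_len(max_tries)) {
    ped <- .with_seed(.sub_seed(seed, 811 * (try - 1L)), {
      .build_pedigree_once(n_generations, litter_size,
                           matings_per_generation, backcross_rate,
                           outcross_rate, popular_sire_rate)
    })
    if (!is.null(ped) && sum(ped$phenotype == "affected") >= min_affected)
      return(pedigree(ped))
  }
  stop(sprintf(
    "could not build a pedigree with >= %d affected in %d attempts",
    min_affected, max_tries), call. = FALSE)
}

.build_pedigree_once <- function(n_generations, litter_size,
                                 matings_per_generation, backcross_rate,
                                 outcross_rate, popular_sire_rate) {
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("D%04d", counter)
  }
  rows <- list()
  add <- function(id, sire, dam, sex, cp, cm, founder, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex,
      phenotype = if (cp + cm == 2L) "affected" else "unaffected",
      founder = founder, generation = gen,
      causal_pat = cp, causal_mat = cm, stringsAsFactors = FALSE)
  }
  # founder carrier female (one causal copy, maternal homologue by
  # convention) and an unrelated non-carrier founder male
  f0 <- new_id(); add(f0, NA, NA, "F", 0L, 1L, TRUE, 0L)
  m0 <- new_id(); add(m0, NA, NA, "M", 0L, 0L, TRUE, 0L)
  gen_members <- list(`0` = c(f0, m0))
  df <- function() do.call(rbind, rows)

  for (g in seq_len(n_generations)) {
    prev <- gen_members[[as.character(g - 1L)]]
    pool <- df()
    pool <- pool[pool$id %in% c(prev, f0), , drop = FALSE]
    dos <- pool$causal_pat + pool$causal_mat
    males <- pool$id[pool$sex == "M"]
    females <- pool$id[pool$sex == "F"]
    if (!length(males) || !length(females)) return(NULL)
    carrier_m <- pool$id[pool$sex == "M" & dos >= 1]
    carrier_f <- pool$id[pool$sex == "F" & dos >= 1]
    pop_sire <- if (length(carrier_m)) sample(carrier_m, 1) else
      sample(males, 1)
    kids <- character(0)
    for (k in seq_len(matings_per_generation)) {
      u <- stats::runif(1)
      if (g >= 3 && u < outcross_rate) {
        # unrelated coated founder enters the gene pool
        nf <- new_id()
        nf_sex <- sample(c("M", "F"), 1)
        add(nf, NA, NA, nf_sex, 0L, 0L, TRUE, g - 1L)
        if (nf_sex == "M") {
          sire <- nf
          dam <- if (length(carrier_f)) sample(carrier_f, 1) else
            sample(females, 1)
        } else {
          dam <- nf
          sire <- if (length(carrier_m)) sample(carrier_m, 1) else
            sample(males, 1)
        }
      } else if (u < outcross_rate + backcross_rate || g == 1) {
        sire <- if (length(carrier_m)) sample(carrier_m, 1) else
          sample(males, 1)
        dam <- if (length(carrier_f)) sample(carrier_f, 1) else
          sample(females, 1)
      } else {
        sire <- sample(males, 1)
        dam <- sample(females, 1)
      }
      if (stats::runif(1) < popular_sire_rate) sire <- pop_sire
      srow <- pool[pool$id == sire, ]
      drow <- pool[pool$id == dam, ]
      if (!nrow(srow)) srow <- df()[df()$id == sire, ]
      if (!nrow(drow)) drow <- df()[df()$id == dam, ]
      for (j in seq_len(litter_size)) {
        cp <- if (stats::runif(1) < 0.5) srow$causal_pat else srow$causal_mat
        cm <- if (stats::runif(1) < 0.5) drow$causal_pat else drow$causal_mat
        id <- new_id()
        add(id, sire, dam, sample(c("M", "F"), 1), as.integer(cp),
            as.integer(cm), FALSE, g)
        kids <- c(kids, id)
      }
    }
    gen_members[[as.character(g)]] <- kids
  }
  df()
}

#' Write a pedigree to 5-column tab-delimited format
#'
#' Columns: id, sire, dam, sex, phenotype; `0` denotes a missing parent.
#' @param ped A [pedigree()].
#' @param path Output path (`.gz` for compression).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  .check(inherits(ped, "pedigree"), "ped must be a pedigree")
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex, phenotype = ped$phenotype)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a 5-column tab-delimited pedigree
#' @param path File path (plain or gzipped).
#' @return A [pedigree()]; causal carriage columns are NA.
#' @export
read_pedigree <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  dt <- .fread_any(path, sep = "\t", colClasses = "character",
                   header = TRUE)
  .check(all(c("id", "sire", "dam", "sex", "phenotype") %in% names(dt)),
         "pedigree file must have columns id, sire, dam, sex, phenotype")
  df <- as.data.frame(dt)
  df$sire[df$sire == "0"] <- NA
  df$dam[df$dam == "0"] <- NA
  pedigree(df)
}
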