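.COAT_LOCI <- list(
  RSPO2 = c("ancestral", "insertion"),  # furnishings, dominant insertion
  FGF5 = c("short", "long"),            # coat length, recessive long
  KRT71 = c("straight", "curl"),        # curl, needs long coat to show
  FOXI3 = c("wildtype", "dup"),         # semi-dominant hairlessness (CED)
  SGK3 = c("wildtype", "del"))          # recessive hairlessness

#' Five-locus coat genotype
#'
#' Diploid allele pair per locus for the five pelage genes: RSPO2
#' (ancestral/insertion), FGF5 (short/long), KRT71 (straight/curl), FOXI3
#' (wildtype/dup), SGK3 (wildtype/del). A locus may be NULL (unknown).
#'
#' @param RSPO2,FGF5,KRT71,FOXI3,SGK3 Character vectors of exactly two
#'   alleles, or NULL.
#' @return Named list of class `coat_genotype`.
#' @export
coat_genotype <- function(RSPO2 = c("ancestral", "ancestral"),
                          FGF5 = c("short", "short"),
                          KRT71 = c("straight", "straight"),
                          FOXI3 = c("wildtype", "wildtype"),
                          SGK3 = c("wildtype", "wildtype")) {
  g <- list(RSPO2 = RSPO2, FGF5 = FGF5, KRT71 = KRT71, FOXI3 = FOXI3,
            SGK3 = SGK3)
  for (locus in names(g)) {
    if (is.null(g[[locus]])) next
    .check(length(g[[locus]]) == 2,
           "locus %s needs exactly two alleles", locus)
    bad <- setdiff(g[[locus]], .COAT_LOCI[[locus]])
    .check(length(bad) == 0, "unknown allele '%s' at locus %s",
           if (length(bad)) bad[1] else "", locus)
  }
  structure(g, class = "coat_genotype")
}

#' Predict pelage phenotype from a five-locus genotype
#'
#' Deterministic rule engine, applied in priority order:
#' \enumerate{
#'   \item FOXI3 dup/dup: embryonic lethal (no live homozygotes).
#'   \item FOXI3 dup/wildtype: CED-type hairlessness (semi-dominant).
#'   \item SGK3 del/del: recessive hairlessness.
#'   \item Otherwise a coated dog: furnishings iff at least one RSPO2
#'     insertion allele (dominant); long coat iff FGF5 long/long
#'     (recessive); curl expressed iff at least one KRT71 curl allele AND
#'     the coat is long — short fur is not long enough to curl, so curl is
#'     masked on short-coated carriers.
#' }
#' Hairless and lethal outcomes mask the length and curl fields.
#'
#' @param genotype A [coat_genotype()].
#' @return List of class `coat_phenotype` with fields `viability`
#'   ("viable"/"embryonic_lethal"), `hairless` ("none"/"CED_hairless"/
#'   "recessive_hairless"), `furnishings` (logical or "masked"), `length`
#'   ("short"/"long"/"masked"), `curl` ("straight"/"curly"/"masked").
#' @export
predict_coat <- function(genotype) {
  .check(inherits(genotype, "coat_genotype"),
         "genotype must be a coat_genotype")
  g <- genotype
  has <- function(locus, allele) !is.null(g[[locus]]) &&
    sum(g[[locus]] == allele) >= 1
  hom <- function(locus, allele) !is.null(g[[locus]]) &&
    all(g[[locus]] == allele)
  pheno <- function(viability, hairless, furnishings, length, curl)
    structure(list(viability = viability, hairless = hairless,
                   furnishings = furnishings, length = length, curl = curl),
              class = "coat_phenotype")
  if (hom("FOXI3", "dup"))
    return(pheno("embryonic_lethal", "masked", "masked", "masked", "masked"))
  furn <- if (is.null(g$RSPO2)) NA else has("RSPO2", "insertion")
  if (has("FOXI3", "dup"))
    return(pheno("viable", "CED_hairless", furn, "masked", "masked"))
  if (hom("SGK3", "del"))
    return(pheno("viable", "recessive_hairless", furn, "masked", "masked"))
  len <- if (is.null(g$FGF5)) NA_character_ else
    if (hom("FGF5", "long")) "long" else "short"
  curl <- if (is.null(g$KRT71) || is.na(len)) NA_character_
          else if (identical(len, "long"))
            (if (has("KRT71", "curl")) "curly" else "straight")
          else if (has("KRT71", "curl")) "masked" else "straight"
  pheno("viable", "none", furn, len, curl)
}

#' @export
print.coat_phenotype <- function(x, ...) {
  cat(sprintf(
    "coat_phenotype: %s, hairless=%s, furnishings=%s, length=%s, curl=%s\n",
    x$viability, x$hairless, as.character(x$furnishings),
    as.character(x$length), as.character(x$curl)))
  invisible(x)
}

#' Enumerate all five-locus genotype combinations and their phenotypes
#'
#' Each locus contributes three unordered genotype states (ref/ref,
#' ref/alt, alt/alt), so the table has 3^5 = 243 rows. The set of distinct
#' viable phenotypes is finite and closed under the rules.
#'
#' @return data.frame with one genotype column per locus (e.g. "del/del")
#'   and the predicted phenotype fields.
#' @export
enumerate_phenotype_table <- function() {
  states <- lapply(.COAT_LOCI, function(alleles) {
    list(c(alleles[1], alleles[1]), c(alleles[1], alleles[2]),
         c(alleles[2], alleles[2]))
  })
  grid <- expand.grid(RSPO2 = 1:3, FGF5 = 1:3, KRT71 = 1:3, FOXI3 = 1:3,
                      SGK3 = 1:3)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    alleles <- lapply(names(.COAT_LOCI), function(locus)
      states[[locus]][[grid[i, locus]]])
    names(alleles) <- names(.COAT_LOCI)
    ph <- predict_coat(do.call(coat_genotype, alleles))
    cbind(as.data.frame(lapply(alleles, paste, collapse = "/"),
                        stringsAsFactors = FALSE),
          data.frame(viability = ph$viability, hairless = ph$hairless,
                     furnishings = as.character(ph$furnishings),
                     length = as.character(ph$length),
                     curl = as.character(ph$curl),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
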