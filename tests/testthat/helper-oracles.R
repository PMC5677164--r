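# Independent brute-force oracles.  These deliberately avoid the package's
# vector arithmetic: gametes are enumerated as allele strings and progeny
# genotypes are assembled by sorting allele pairs, so agreement with the
# package is a genuine cross-check.

# all gametes of a parent with their Mendelian probabilities
oracle_gametes <- function(genotype) {
  parts <- strsplit(genotype, ";", fixed = TRUE)[[1]]
  a1 <- strsplit(parts[1], "")[[1]]
  a2 <- strsplit(parts[2], "")[[1]]
  out <- list()
  for (x in a1) for (y in a2) {
    key <- paste(x, y, sep = ";")
    out[[key]] <- (out[[key]] %||% 0) + 0.25
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# union of two gamete pools (named lists/vectors of class -> prob),
# enumerated over all ordered pairs
oracle_union <- function(female, male) {
  out <- setNames(numeric(9), TWO_LOCUS_GENOTYPES)
  for (fg in names(female)) for (mg in names(male)) {
    p <- female[[fg]] * male[[mg]]
    if (p == 0) next
    fa <- strsplit(fg, ";", fixed = TRUE)[[1]]
    ma <- strsplit(mg, ";", fixed = TRUE)[[1]]
    geno <- paste(
      paste(sort(c(fa[1], ma[1])), collapse = ""),
      paste(sort(c(fa[2], ma[2])), collapse = ""), sep = ";")
    out[geno] <- out[geno] + p
  }
  out
}

# null-model progeny distribution by exhaustive enumeration
oracle_progeny <- function(mother, father) {
  oracle_union(oracle_gametes(mother), oracle_gametes(father))
}

# every unordered two-locus genotype label
all_two_locus_genotypes <- function() TWO_LOCUS_GENOTYPES
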