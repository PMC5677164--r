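#' trdcross: two-locus transmission ratio distortion in experimental crosses
#'
#' Tools for dissecting transmission ratio distortion (TRD) at a pair of
#' epistatically interacting loci, built around the *hms1*-*hms2* hybrid
#' sterility system of *Mimulus guttatus* (allele symbol `G`) and
#' *M. nasutus* (allele symbol `N`).  The package covers the full analysis
#' chain: Mendelian and random-union-of-gametes null expectations, a
#' selection-modified transmission model (gametic incompatibility, drive at
#' *hms1*, background-dependent zygotic lethality), estimation of
#' transmitted gamete-class frequencies from backcross progeny, chi-square
#' goodness-of-fit machinery, flanking-marker genotype inference, and a
#' multinomial crossing-design simulator.
#'
#' @section Canonical orderings:
#' All length-4 gamete vectors use the order `G;G, G;N, N;G, N;N`
#' (*hms1* allele first).  All length-9 two-locus genotype vectors use the
#' order `GG;GG, GG;GN, GG;NN, GN;GG, GN;GN, GN;NN, NN;GG, NN;GN, NN;NN`.
#'
#' @keywords internal
"_PACKAGE"

# ---- canonical label sets -------------------------------------------------

#' Canonical label sets for genotypes and gametes
#'
#' Constants fixing the ordering used by every vector in the package:
#' single-locus diploid genotypes, the four two-locus gamete classes
#' (*hms1* allele; *hms2* allele), and the nine two-locus genotypes
#' (*hms1* genotype; *hms2* genotype).
#'
#' @format Character vectors.
#' @name orderings
NULL

#' @rdname orderings
#' @export
GENOTYPES <- c("GG", "GN", "NN")

#' @rdname orderings
#' @export
GAMETE_CLASSES <- c("G;G", "G;N", "N;G", "N;N")

#' @rdname orderings
#' @export
TWO_LOCUS_GENOTYPES <- paste(rep(GENOTYPES, each = 3), rep(GENOTYPES, 3),
                             sep = ";")

# internal: allele codes
ALLELES <- c("G", "N")

#' Construct/validate a two-locus genotype label
#'
#' A two-locus genotype is written `"<hms1>;<hms2>"`, e.g. `"GN;NN"` for a
#' plant heterozygous at *hms1* and homozygous *M. nasutus* at *hms2*.
#' Heterozygotes are unordered: `"NG"` is normalised to `"GN"`.
#'
#' @param hms1,hms2 single-locus genotypes (`"GG"`, `"GN"`/`"NG"`, `"NN"`),
#'   or `hms1` alone may be a full `"GN;NN"`-style label.
#' @return A validated genotype label (character scalar).
#' @examples
#' tl_genotype("GN", "NN")
#' tl_genotype("NG;GG")   # normalised to "GN;GG"
#' @export
tl_genotype <- function(hms1, hms2 = NULL) {
  if (is.null(hms2)) {
    parts <- strsplit(hms1, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("genotype label must be of the form 'GN;NN'", call. = FALSE)
    hms1 <- parts[1]; hms2 <- parts[2]
  }
  norm1 <- norm_geno(hms1); norm2 <- norm_geno(hms2)
  paste(norm1, norm2, sep = ";")
}

norm_geno <- function(g) {
  g <- toupper(trimws(g))
  if (g == "NG") g <- "GN"
  if (!g %in% GENOTYPES)
    stop("invalid genotype code '", g, "' (expected GG, GN or NN)",
         call. = FALSE)
  g
}

split_genotype <- function(genotype) {
  genotype <- tl_genotype(genotype)
  strsplit(genotype, ";", fixed = TRUE)[[1]]
}

# per-locus Mendelian segregation margin: P(transmit G), P(transmit N)
segregation_margin <- function(g) {
  switch(g,
         GG = c(G = 1, N = 0),
         GN = c(G = 0.5, N = 0.5),
         NN = c(G = 0, N = 1))
}

# ---- containers -----------------------------------------------------------

#' Gamete pool: frequencies of the four two-locus gamete classes
#'
#' @param freqs numeric length-4 vector over [GAMETE_CLASSES] (order
#'   `G;G, G;N, N;G, N;N`); must be non-negative and sum to 1 within `tol`.
#' @param sex `"male"` or `"female"` (which gametophyte the pool describes).
#' @param n optional count of progeny the pool was estimated from.
#' @param tol tolerance on the unit-sum check.
#' @return A `gamete_pool`: named numeric vector with attributes `sex`, `n`.
#' @examples
#' gamete_pool(c(0.25, 0.25, 0.25, 0.25), sex = "male")
#' @export
gamete_pool <- function(freqs, sex = c("male", "female"), n = NA_integer_,
                        tol = 1e-9) {
  sex <- match.arg(sex)
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L)
    stop("a gamete pool has exactly 4 class frequencies", call. = FALSE)
  if (any(freqs < 0))
    stop("gamete-class frequencies must be non-negative", call. = FALSE)
  if (abs(sum(freqs) - 1) > tol)
    stop("gamete-class frequencies must sum to 1 (got ", sum(freqs), ")",
         call. = FALSE)
  structure(stats::setNames(freqs, GAMETE_CLASSES),
            sex = sex, n = n, class = "gamete_pool")
}

#' @export
print.gamete_pool <- function(x, digits = 3, ...) {
  cat("<gamete_pool> sex =", attr(x, "sex"))
  if (!is.na(attr(x, "n"))) cat(", n =", attr(x, "n"))
  cat("\n")
  print(round(stats::setNames(as.numeric(x), GAMETE_CLASSES), digits))
  invisible(x)
}

#' Genotype distribution over the nine two-locus classes
#'
#' @param freqs numeric length-9 vector over [TWO_LOCUS_GENOTYPES]; must be
#'   non-negative and sum to 1 within `tol`.
#' @param tol tolerance on the unit-sum check.
#' @return A `genotype_dist`: named numeric vector.
#' @export
genotype_distribution <- function(freqs, tol = 1e-9) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 9L)
    stop("a two-locus genotype distribution has 9 classes", call. = FALSE)
  if (any(freqs < 0))
    stop("genotype frequencies must be non-negative", call. = FALSE)
  if (abs(sum(freqs) - 1) > tol)
    stop("genotype frequencies must sum to 1 (got ", sum(freqs), ")",
         call. = FALSE)
  structure(stats::setNames(freqs, TWO_LOCUS_GENOTYPES),
            class = "genotype_dist")
}

#' @export
print.genotype_dist <- function(x, digits = 4, ...) {
  cat("<genotype_dist> (hms1;hms2)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# ---- null expectations ----------------------------------------------------

#' Allele frequencies from single-locus genotype counts
#'
#' @param counts genotype counts in `GG, GN, NN` order (names optional).
#' @return Named numeric `c(G = , N = )`; `G` is
#'   `(2 n_GG + n_GN) / (2 N)`.
#' @examples
#' allele_freq_from_genotypes(c(GG = 1207, GN = 3018, NN = 1262))
#' @export
allele_freq_from_genotypes <- function(counts) {
  counts <- genotype_counts3(counts)
  n <- sum(counts)
  if (n <= 0) stop("empty sample: all genotype counts are zero", call. = FALSE)
  p <- (2 * counts[["GG"]] + counts[["GN"]]) / (2 * n)
  c(G = p, N = 1 - p)
}

genotype_counts3 <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L)
    stop("expected 3 genotype counts (GG, GN, NN)", call. = FALSE)
  if (any(counts < 0))
    stop("genotype counts must be non-negative", call. = FALSE)
  stats::setNames(counts, GENOTYPES)
}

#' Random-union-of-gametes genotype expectation at one locus
#'
#' Hardy-Weinberg-style expectation `(p^2, 2p(1-p), (1-p)^2)` for the
#' random union of two gametes carrying allele `G` with frequency `p`.
#'
#' @param freq_G frequency of the `G` allele, in \[0, 1\].
#' @return Named numeric over `GG, GN, NN`; sums to 1 exactly.
#' @examples
#' random_union_expectation(0.49)
#' @export
random_union_expectation <- function(freq_G) {
  if (!is.finite(freq_G) || freq_G < 0 || freq_G > 1)
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  p <- freq_G
  c(GG = p^2, GN = 2 * p * (1 - p), NN = (1 - p)^2)
}

#' Mendelian gamete pool of a two-locus genotype
#'
#' Independent assortment (the two loci sit on different chromosomes):
#' the pool is the outer product of the per-locus segregation margins, with
#' a homozygote transmitting its allele with probability 1 and a
#' heterozygote transmitting each allele with probability 1/2.
#'
#' @param parent two-locus genotype label, e.g. `"GN;GN"`.
#' @param sex sex of the parent the pool belongs to.
#' @return A [gamete_pool()].
#' @examples
#' mendelian_gamete_pool("GN;GN")
#' mendelian_gamete_pool("GG;GN")
#' @export
mendelian_gamete_pool <- function(parent, sex = c("male", "female")) {
  sex <- match.arg(sex)
  g <- split_genotype(parent)
  m1 <- segregation_margin(g[1])
  m2 <- segregation_margin(g[2])
  # hms1-major: G;G, G;N, N;G, N;N
  freqs <- rep(m1, each = 2) * rep(m2, times = 2)
  gamete_pool(freqs, sex = sex)
}

#' Mendelian F2 two-locus genotype distribution
#'
#' Expectation for the self of a double heterozygote under free
#' recombination and no selection: double homozygotes 1/16, single-locus
#' heterozygote classes 1/8, the double heterozygote 1/4.
#'
#' @return A [genotype_distribution()].
#' @export
mendelian_f2_distribution <- function() {
  m <- c(GG = 0.25, GN = 0.5, NN = 0.25)
  genotype_distribution(rep(m, each = 3) * rep(m, times = 3))
}

#' Two-locus genotype expectation from per-locus allele frequencies
#'
#' Product of the two single-locus random-union expectations, assuming
#' independent assortment of the unlinked loci.
#'
#' @param p1 `G`-allele frequency at *hms1*.
#' @param p2 `G`-allele frequency at *hms2*.
#' @return A [genotype_distribution()].
#' @examples
#' two_locus_expectation_from_allele_freqs(0.49, 0.62)
#' @export
two_locus_expectation_from_allele_freqs <- function(p1, p2) {
  e1 <- random_union_expectation(p1)
  e2 <- random_union_expectation(p2)
  freqs <- rep(e1, each = 3) * rep(e2, times = 3)
  genotype_distribution(freqs)
}
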