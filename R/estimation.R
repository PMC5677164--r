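# Inverting observed cross data into gamete-pool estimates and model-based
# expectations.  In a backcross to a homozygous recurrent parent every
# progeny genotype identifies the gamete transmitted by the heterozygous
# (IL) parent, so two-locus gamete-class frequencies can be read off
# directly from progeny counts.

#' Backcross record
#'
#' One backcross of a (partially) heterozygous introgression-line (IL)
#' parent to a fully homozygous recurrent parent, with progeny genotype
#' counts.
#'
#' @param il_genotype two-locus genotype of the IL parent.
#' @param il_sex `"female"` (IL used as dam) or `"male"` (IL as sire).
#' @param recurrent recurrent parent line: `"G"` (genotype `GG;GG`) or
#'   `"N"` (`NN;NN`).
#' @param counts named progeny genotype counts; names are two-locus labels
#'   (`"GN;GN"` style).  Classes not named are taken as zero.
#' @param label optional cross label.
#' @param background optional background flag carried to model fits.
#' @return A `backcross_record`.
#' @examples
#' backcross_record("GN;GN", "female", "G",
#'                  c("GG;GG" = 91, "GG;GN" = 59, "GN;GG" = 70,
#'                    "GN;GN" = 73))
#' @export
backcross_record <- function(il_genotype, il_sex = c("female", "male"),
                             recurrent = c("G", "N"), counts,
                             label = NULL, background = "F1") {
  il_sex <- match.arg(il_sex)
  recurrent <- match.arg(recurrent)
  il_genotype <- tl_genotype(il_genotype)
  counts <- full_genotype_counts(counts)
  if (sum(counts) <= 0) stop("no usable progeny", call. = FALSE)
  rec_geno <- if (recurrent == "G") "GG;GG" else "NN;NN"
  structure(list(il_genotype = il_genotype, il_sex = il_sex,
                 recurrent = recurrent, recurrent_genotype = rec_geno,
                 counts = counts, n = sum(counts),
                 label = label %||% paste(il_genotype, il_sex, "x", recurrent),
                 background = background),
            class = "backcross_record")
}

#' @export
print.backcross_record <- function(x, ...) {
  cat("<backcross_record>", x$label, " (IL ", x$il_genotype, " as ",
      x$il_sex, ", recurrent ", x$recurrent, ", N = ", x$n, ")\n", sep = "")
  print(x$counts[x$counts > 0])
  invisible(x)
}

# expand a possibly partial named count vector to all 9 classes
full_genotype_counts <- function(counts) {
  if (is.null(names(counts)))
    stop("progeny counts must be named by two-locus genotype", call. = FALSE)
  nm <- vapply(names(counts), tl_genotype, character(1))
  if (anyDuplicated(nm)) stop("duplicated genotype class", call. = FALSE)
  out <- stats::setNames(numeric(9), TWO_LOCUS_GENOTYPES)
  out[nm] <- as.numeric(counts)
  if (any(out < 0)) stop("counts must be non-negative", call. = FALSE)
  out
}

#' Gamete transmitted by the segregating parent of a backcross
#'
#' Deterministic subtraction of the recurrent parent's known gamete from a
#' progeny genotype.
#'
#' @param progeny progeny two-locus genotype label.
#' @param recurrent_gamete gamete class contributed by the recurrent
#'   parent, e.g. `"G;G"`.
#' @return The gamete class (one of [GAMETE_CLASSES]) contributed by the
#'   other parent.  Errors with `"non-parental genotype"` when the progeny
#'   genotype cannot contain the recurrent gamete (a genotyping error or
#'   contamination flag).
#' @examples
#' transmitted_gamete("GN;GN", "G;G")   # "N;N"
#' @export
transmitted_gamete <- function(progeny, recurrent_gamete) {
  g <- split_genotype(progeny)
  rg <- strsplit(recurrent_gamete, ";", fixed = TRUE)[[1]]
  if (length(rg) != 2L || !all(rg %in% ALLELES))
    stop("invalid gamete class '", recurrent_gamete, "'", call. = FALSE)
  other <- character(2)
  for (i in 1:2) {
    alleles <- strsplit(g[i], "")[[1]]
    hit <- match(rg[i], alleles)
    if (is.na(hit))
      stop("non-parental genotype: progeny ", tl_genotype(progeny),
           " cannot contain recurrent gamete ", recurrent_gamete,
           call. = FALSE)
    other[i] <- alleles[-hit]
  }
  paste(other, collapse = ";")
}

#' Estimate transmitted gamete-class frequencies from a backcross
#'
#' Maps each progeny genotype to the gamete contributed by the IL parent
#' and returns the relative frequencies of the four gamete classes.
#'
#' @param record a [backcross_record()].
#' @return A [gamete_pool()] with attribute `n` (total progeny), sexed by
#'   the IL parent's role in the cross.
#' @examples
#' r <- backcross_record("GN;GN", "female", "G",
#'                       c("GG;GG" = 91, "GG;GN" = 59, "GN;GG" = 70,
#'                         "GN;GN" = 73))
#' estimate_gamete_freqs(r)
#' @export
estimate_gamete_freqs <- function(record) {
  stopifnot(inherits(record, "backcross_record"))
  rec_gamete <- if (record$recurrent == "G") "G;G" else "N;N"
  tallies <- stats::setNames(numeric(4), GAMETE_CLASSES)
  nz <- which(record$counts > 0)
  for (i in nz) {
    gam <- transmitted_gamete(TWO_LOCUS_GENOTYPES[i], rec_gamete)
    tallies[gam] <- tallies[gam] + record$counts[i]
  }
  n <- sum(tallies)
  if (n <= 0) stop("no usable progeny", call. = FALSE)
  gamete_pool(tallies / n, sex = record$il_sex, n = n)
}

#' Average gamete pools across crosses
#'
#' @param pools list of [gamete_pool()]s (or plain length-4 frequency
#'   vectors) of the same sex.
#' @param weighting `"unweighted"` (arithmetic mean of frequencies, the
#'   reporting convention for cross averages) or `"count"` (weighted by
#'   each pool's `n`).
#' @return Named numeric length-4 average frequency vector.
#' @export
average_pools <- function(pools, weighting = c("unweighted", "count")) {
  weighting <- match.arg(weighting)
  if (length(pools) < 1L) stop("need at least one pool", call. = FALSE)
  sexes <- unique(unlist(lapply(pools, function(p) attr(p, "sex"))))
  if (length(sexes) > 1L)
    stop("cannot average pools of mixed sexes", call. = FALSE)
  mat <- do.call(rbind, lapply(pools, function(p) {
    p <- as.numeric(p)
    if (length(p) != 4L) stop("each pool must have 4 classes", call. = FALSE)
    p
  }))
  w <- if (weighting == "count") {
    ns <- vapply(pools, function(p) as.numeric(attr(p, "n") %||% NA_real_),
                 numeric(1))
    if (anyNA(ns))
      stop("count weighting needs an `n` attribute on every pool",
           call. = FALSE)
    ns / sum(ns)
  } else rep(1 / nrow(mat), nrow(mat))
  stats::setNames(as.vector(crossprod(mat, w)), GAMETE_CLASSES)
}

#' Expected selfed-progeny genotype distribution from measured pools
#'
#' Union of an empirical female and male gamete pool, collapsed to
#' unordered two-locus genotypes — the same kernel as
#' [progeny_distribution()], but driven by measured transmission instead
#' of a parametric model.
#'
#' @param female,male length-4 gamete-class frequency vectors (e.g. from
#'   [estimate_gamete_freqs()] or [average_pools()]).  Vectors are
#'   renormalised, so rounded published frequencies may be used directly.
#' @return A [genotype_distribution()].
#' @examples
#' f2_expectation_from_pools(c(0.33, 0.18, 0.25, 0.24),
#'                           c(0.34, 0.08, 0.30, 0.28))
#' @export
f2_expectation_from_pools <- function(female, male) {
  female <- as.numeric(female); male <- as.numeric(male)
  stopifnot(length(female) == 4L, length(male) == 4L,
            all(female >= 0), all(male >= 0))
  freqs <- union_of_pools(female / sum(female), male / sum(male))
  genotype_distribution(freqs)
}

#' Renormalise an expected distribution after removing lethal classes
#'
#' Sets the lethal classes to zero and divides the survivors by their
#' total mass, preserving the ratios among surviving classes.  The input
#' need not sum exactly to 1 (published, rounded columns are accepted).
#'
#' @param expected length-9 expected frequency vector (named or in
#'   canonical [TWO_LOCUS_GENOTYPES] order).
#' @param lethal_classes character vector of genotype labels to remove,
#'   e.g. all *hms1*-GG classes.
#' @return Named numeric length-9 vector summing to 1.
#' @export
lethality_renormalize <- function(expected, lethal_classes = character(0)) {
  expected <- as.numeric(expected)
  if (length(expected) != 9L)
    stop("expected vector must cover the 9 two-locus classes", call. = FALSE)
  out <- stats::setNames(expected, TWO_LOCUS_GENOTYPES)
  if (length(lethal_classes)) {
    lethal_classes <- vapply(lethal_classes, tl_genotype, character(1))
    out[lethal_classes] <- 0
  }
  total <- sum(out)
  if (total <= 0) stop("all classes are lethal", call. = FALSE)
  out / total
}

#' Genotype labels homozygous or heterozygous for a pattern at one locus
#'
#' Convenience selector: all two-locus genotype labels whose *hms1* (or
#' *hms2*) genotype equals `genotype`.
#'
#' @param locus `"hms1"` or `"hms2"`.
#' @param genotype single-locus genotype.
#' @return Character vector of labels.
#' @examples
#' genotype_classes("hms1", "GG")
#' @export
genotype_classes <- function(locus = c("hms1", "hms2"), genotype) {
  locus <- match.arg(locus)
  genotype <- norm_geno(genotype)
  g1 <- rep(GENOTYPES, each = 3)
  g2 <- rep(GENOTYPES, times = 3)
  TWO_LOCUS_GENOTYPES[if (locus == "hms1") g1 == genotype else g2 == genotype]
}

#' Fraction of G alleles transmitted by the segregating parent
#'
#' @param record a [backcross_record()].
#' @param locus `"hms1"` or `"hms2"`; the IL parent must be heterozygous
#'   there.
#' @return Fraction of progeny that received a `G` allele at `locus` from
#'   the IL parent.
#' @export
allele_transmission_fraction <- function(record, locus = c("hms1", "hms2")) {
  locus <- match.arg(locus)
  cnt <- transmitted_allele_counts(record, locus)
  cnt[["G"]] / sum(cnt)
}

# counts of G and N alleles transmitted by the IL parent at one locus
transmitted_allele_counts <- function(record, locus) {
  stopifnot(inherits(record, "backcross_record"))
  il <- split_genotype(record$il_genotype)
  li <- if (locus == "hms1") 1L else 2L
  if (il[li] != "GN")
    stop("locus ", locus, " is not segregating in the IL parent",
         call. = FALSE)
  rec_gamete <- if (record$recurrent == "G") "G;G" else "N;N"
  cnt <- c(G = 0, N = 0)
  for (i in which(record$counts > 0)) {
    gam <- transmitted_gamete(TWO_LOCUS_GENOTYPES[i], rec_gamete)
    allele <- strsplit(gam, ";", fixed = TRUE)[[1]][li]
    cnt[allele] <- cnt[allele] + record$counts[i]
  }
  cnt
}

#' Percent undertransmission relative to an expected frequency
#'
#' `100 * (expected - observed) / expected`; positive values indicate
#' undertransmission of the focal allele, negative values
#' overtransmission.
#'
#' @param observed observed allele frequency.
#' @param expected expected (null) frequency, default Mendelian 0.5.
#' @return Signed percent undertransmission.
#' @examples
#' undertransmission(0.12)   # 76
#' @export
undertransmission <- function(observed, expected = 0.5) {
  if (any(expected <= 0)) stop("expected frequency must be > 0", call. = FALSE)
  100 * (expected - observed) / expected
}

# ---- maximum-likelihood model fitting -------------------------------------

#' Cross dataset for likelihood fitting
#'
#' A minimal container pairing parental genotypes (and background) with
#' progeny genotype counts; [backcross_record()]s are accepted wherever a
#' `cross_data` is, with the IL parent placed on the side given by
#' `il_sex`.
#'
#' @param mother,father parental two-locus genotype labels.
#' @param counts named progeny genotype counts.
#' @param background background flag for the lethality rule.
#' @param label optional label.
#' @return A `cross_data` list.
#' @export
cross_data <- function(mother, father, counts, background = "F1",
                       label = NULL) {
  structure(list(mother = tl_genotype(mother), father = tl_genotype(father),
                 counts = full_genotype_counts(counts),
                 background = background,
                 label = label %||% paste(mother, "x", father)),
            class = "cross_data")
}

as_cross_data <- function(x) {
  if (inherits(x, "cross_data")) return(x)
  if (inherits(x, "backcross_record")) {
    if (x$il_sex == "female")
      return(cross_data(x$il_genotype, x$recurrent_genotype, x$counts,
                        background = x$background, label = x$label))
    return(cross_data(x$recurrent_genotype, x$il_genotype, x$counts,
                      background = x$background, label = x$label))
  }
  stop("expected a cross_data or backcross_record", call. = FALSE)
}

# multinomial log-likelihood of all records under a parameter vector
model_loglik <- function(par, records, base_model) {
  m <- base_model
  for (nm in names(par)) {
    if (nm == "k_drive" && !is.null(names(m$k_drive))) {
      # conditioned drive: fitted value applies where the base model
      # deviates from 0.5, i.e. replace all non-default entries
      m$k_drive[m$k_drive != 0.5] <- par[[nm]]
    } else {
      m[[nm]] <- par[[nm]]
    }
  }
  ll <- 0
  for (r in records) {
    p <- tryCatch(
      progeny_distribution(r$mother, r$father, m, r$background),
      error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    nz <- r$counts > 0
    if (any(p[nz] <= 0)) return(-Inf)
    ll <- ll + sum(r$counts[nz] * log(p[nz]))
  }
  ll
}

#' Maximum-likelihood fit of transmission-model parameters
#'
#' Maximises the joint multinomial log-likelihood of one or more cross
#' datasets under [progeny_distribution()], over a chosen subset of
#' parameters.  Optimisation is a deterministic coarse grid search over
#' \[0, 1\] followed by box-constrained local refinement
#' (`stats::optim`, L-BFGS-B), which is ample for these smooth, low-
#' dimensional likelihoods.
#'
#' @param records list of [cross_data()] and/or [backcross_record()]s.
#' @param free character vector naming the free parameters, a subset of
#'   `c("s_male", "s_female", "k_drive")`.
#' @param base_model [transmission_model()] supplying the fixed
#'   parameters (including any lethality rule and the structure of a
#'   conditioned `k_drive`).
#' @param grid_step spacing of the coarse grid on \[0, 1\].
#' @return List with `model` (fitted [transmission_model()]), `estimates`
#'   (named numeric), `loglik`, and `grid_loglik` (best grid value).
#'   Errors when a requested parameter has no effect on any record's
#'   likelihood (non-identifiable), naming the offending parameters.
#' @export
fit_model_ml <- function(records,
                         free = c("s_male", "s_female", "k_drive"),
                         base_model = transmission_model(),
                         grid_step = 0.1) {
  free <- match.arg(free, several.ok = TRUE)
  if (length(records) < 1L) stop("need at least one dataset", call. = FALSE)
  records <- lapply(records, as_cross_data)

  start <- stats::setNames(rep(0.5, length(free)), free)
  # identifiability: each free parameter must move the likelihood
  dead <- vapply(free, function(nm) {
    lo <- start; hi <- start
    lo[nm] <- 0.02; hi[nm] <- 0.98
    isTRUE(all.equal(model_loglik(lo, records, base_model),
                     model_loglik(hi, records, base_model), tolerance = 1e-12))
  }, logical(1))
  if (any(dead))
    stop("non-identifiable parameter(s): ",
         paste(free[dead], collapse = ", "),
         " (no effect on the likelihood of these data)", call. = FALSE)

  axis <- seq(0, 1, by = grid_step)
  grid <- as.matrix(do.call(expand.grid, rep(list(axis), length(free))))
  colnames(grid) <- free
  gll <- apply(grid, 1, function(row)
    model_loglik(stats::setNames(row, free), records, base_model))
  best <- which.max(gll)

  eps <- 1e-6
  opt <- stats::optim(
    par = pmin(pmax(grid[best, ], eps), 1 - eps),
    fn = function(p) -model_loglik(stats::setNames(p, free), records,
                                   base_model),
    method = "L-BFGS-B", lower = eps, upper = 1 - eps)
  est <- stats::setNames(opt$par, free)

  fitted <- base_model
  for (nm in free) {
    if (nm == "k_drive" && !is.null(names(fitted$k_drive))) {
      fitted$k_drive[fitted$k_drive != 0.5] <- est[[nm]]
    } else fitted[[nm]] <- est[[nm]]
  }
  list(model = fitted, estimates = est, loglik = -opt$value,
       grid_loglik = gll[best])
}
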