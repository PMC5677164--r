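# Pearson chi-square goodness-of-fit machinery.  The statistic is computed
# directly (sum (O - E)^2 / E) rather than through chisq.test because the
# analyses need df overrides (e.g. df = 8 for the nine two-locus classes,
# df = 5 after removing three lethal classes) and exclusion of classes with
# expected frequency zero.  No continuity correction is applied, the usual
# practice for multi-class goodness of fit.

#' Goodness-of-fit result
#'
#' Container returned by the chi-square tests: Pearson statistic, degrees
#' of freedom, upper-tail p-value, the observed and expected count
#' vectors, and a label for the expectation source.
#'
#' @param chi2,df,p statistic, degrees of freedom, p-value.
#' @param observed,expected count vectors (expected on the count scale).
#' @param expectation_label e.g. `"mendelian"`, `"allele_freq"`,
#'   `"backcross"`, `"backcross+lethal"`, `"custom"`.
#' @return A `gof_result`.
#' @keywords internal
gof_result <- function(chi2, df, p, observed, expected,
                       expectation_label = "custom") {
  stopifnot(chi2 >= -1e-12, df >= 1, p >= 0, p <= 1)
  structure(list(chi2 = max(chi2, 0), df = as.integer(df), p = p,
                 observed = observed, expected = expected,
                 expectation_label = expectation_label),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, digits = 4, ...) {
  cat("<gof_result> vs ", x$expectation_label, ": chi2 = ",
      format(round(x$chi2, digits)), ", d.f. = ", x$df,
      ", P = ", format.pval(x$p, digits = 3), " ",
      star_code(x$p), "\n", sep = "")
  invisible(x)
}

#' Significance star coding
#'
#' Thresholds 0.05, 0.01, 0.005, 0.0001 map to one to four stars,
#' matching the conventional footnote coding of crossing tables.
#'
#' @param p p-value(s).
#' @return Character vector of `""` to `"****"`.
#' @export
star_code <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) "****"
    else if (pp < 0.005) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else ""
  }, character(1))
}

#' Pearson chi-square goodness-of-fit test
#'
#' Compares observed counts with an expected frequency distribution.
#' Classes with expected frequency zero are excluded from both the
#' statistic and the degrees of freedom (it is an error to observe counts
#' in such a class); by default `df = (number of classes with E > 0) - 1`,
#' overridable for model-constrained expectations.
#'
#' @param observed count vector.
#' @param expected expected frequencies (rescaled to sum to 1 over the
#'   included classes) or expected counts; same length as `observed`.
#' @param df_override optional degrees of freedom.
#' @param expectation_label label recorded in the result.
#' @param warn_small warn when any expected count is below 5.
#' @return A [gof_result].
#' @examples
#' chi2_gof(c(60, 40), c(0.5, 0.5))   # chi2 = 4, df = 1
#' @export
chi2_gof <- function(observed, expected, df_override = NULL,
                     expectation_label = "custom", warn_small = TRUE) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length", call. = FALSE)
  n <- sum(observed)
  if (n <= 0) stop("no observations", call. = FALSE)
  if (any(expected < 0)) stop("negative expected frequency", call. = FALSE)
  zero <- expected == 0
  if (any(zero & observed > 0))
    stop("impossible class observed: nonzero count where expected ",
         "frequency is 0", call. = FALSE)
  obs <- observed[!zero]
  exp_counts <- expected[!zero] / sum(expected[!zero]) * n
  if (warn_small && any(exp_counts < 5))
    warning("some expected counts are below 5; the chi-square ",
            "approximation may be poor", call. = FALSE)
  chi2 <- sum((obs - exp_counts)^2 / exp_counts)
  df <- if (!is.null(df_override)) df_override else length(obs) - 1L
  if (df < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  gof_result(chi2, df, stats::pchisq(chi2, df, lower.tail = FALSE),
             observed = observed, expected = expected / sum(expected[!zero]) * n,
             expectation_label = expectation_label)
}

#' Allele-frequency chi-square test at one locus
#'
#' Tests the 2N allele counts implied by single-locus genotype counts
#' against a 1:1 expectation (1 d.f.).
#'
#' @param counts genotype counts in `GG, GN, NN` order.
#' @param expected_G expected `G`-allele frequency (default 0.5).
#' @return A [gof_result].
#' @examples
#' allele_freq_test(c(GG = 2085, GN = 2634, NN = 768))
#' @export
allele_freq_test <- function(counts, expected_G = 0.5) {
  counts <- genotype_counts3(counts)
  alleles <- c(G = 2 * counts[["GG"]] + counts[["GN"]],
               N = counts[["GN"]] + 2 * counts[["NN"]])
  chi2_gof(alleles, c(expected_G, 1 - expected_G),
           expectation_label = "allele_freq", warn_small = FALSE)
}

#' Homozygote-deficit test for selfed progeny
#'
#' For the selfed progeny of a parent heterozygous at a focal locus,
#' reports the signed deviation of the focal homozygote class from its
#' Mendelian expectation of 0.25, together with a chi-square test of the
#' genotype counts against 1:2:1 — the test used to map TRD in
#' recombinant-derived selfed families.
#'
#' @param counts genotype counts at the focal locus (`GG, GN, NN`).
#' @param target focal homozygote class, `"NN"` or `"GG"`.
#' @return List with `deviation` (observed fraction minus 0.25) and `gof`
#'   (a [gof_result] vs 1:2:1).
#' @examples
#' homozygote_deficit_test(c(GG = 40, GN = 70, NN = 10), target = "NN")
#' @export
homozygote_deficit_test <- function(counts, target = c("NN", "GG")) {
  target <- match.arg(target)
  counts <- genotype_counts3(counts)
  n <- sum(counts)
  if (n <= 0) stop("no observations", call. = FALSE)
  dev <- counts[[target]] / n - 0.25
  gof <- chi2_gof(counts, c(0.25, 0.5, 0.25),
                  expectation_label = "mendelian", warn_small = FALSE)
  list(deviation = unname(dev), gof = gof)
}

#' Heterogeneity of allelic transmission across crosses
#'
#' Contingency chi-square (no continuity correction) of transmitted
#' G/N allele counts across two or more backcrosses segregating at a
#' locus: tests whether the crosses share a common transmission ratio.
#'
#' @param records list of [backcross_record()]s (>= 2), each with the IL
#'   parent heterozygous at `locus`.
#' @param locus `"hms1"` or `"hms2"`.
#' @return A [gof_result] (df = number of crosses - 1).
#' @export
heterogeneity_test <- function(records, locus = c("hms1", "hms2")) {
  locus <- match.arg(locus)
  if (length(records) < 2L)
    stop("heterogeneity test needs at least 2 crosses", call. = FALSE)
  tab <- do.call(rbind, lapply(records, transmitted_allele_counts,
                               locus = locus))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  gof_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
             observed = tab, expected = ct$expected,
             expectation_label = "homogeneity")
}

#' Starred goodness-of-fit results table
#'
#' Flattens a list of [gof_result]s into a reporting data frame with the
#' conventional star coding; optionally appends Bonferroni-adjusted
#' p-values.
#'
#' @param results named list of `gof_result`s.
#' @param bonferroni add a `p_bonferroni` column.
#' @return A data frame with columns `test`, `expectation`, `chi2`, `df`,
#'   `p`, `stars` (and optionally `p_bonferroni`).
#' @export
gof_table <- function(results, bonferroni = FALSE) {
  stopifnot(length(results) >= 1)
  nm <- names(results) %||% paste0("test", seq_along(results))
  out <- data.frame(
    test = nm,
    expectation = vapply(results, function(r) r$expectation_label,
                         character(1)),
    chi2 = vapply(results, function(r) r$chi2, numeric(1)),
    df = vapply(results, function(r) r$df, integer(1)),
    p = vapply(results, function(r) r$p, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$stars <- star_code(out$p)
  if (bonferroni)
    out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out
}
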