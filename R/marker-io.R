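# Marker-level genotype handling.  Focal-locus genotypes are inferred from
# pairs of flanking markers (e.g. M8/M24 around hms1, M51/MgSTS193 around
# hms2): an individual is called only when both flanks agree; a crossover
# between the flanks makes the call ambiguous and the individual is
# excluded from transmission counts.  The residual miscall risk is the
# double-crossover probability, the product of the two intermarker
# recombination fractions under no interference.

#' Infer a focal-locus genotype from two flanking markers
#'
#' Returns the shared genotype when the two flanks agree, the string
#' `"recombinant"` when they disagree (a crossover occurred between the
#' flanks), and `NA` when either flank is unscored.  Vectorised and
#' symmetric in its arguments.
#'
#' @param flank_left,flank_right genotype calls at the two flanking
#'   markers (`"GG"`, `"GN"`/`"NG"`, `"NN"`, or `NA`).
#' @return Character vector of genotype calls, `"recombinant"`, or `NA`.
#' @examples
#' infer_locus_genotype(c("GN", "GG", NA), c("GN", "GN", "GG"))
#' @export
infer_locus_genotype <- function(flank_left, flank_right) {
  stopifnot(length(flank_left) == length(flank_right))
  mapply(function(l, r) {
    if (is.na(l) || is.na(r)) return(NA_character_)
    l <- norm_geno(l); r <- norm_geno(r)
    if (l == r) l else "recombinant"
  }, flank_left, flank_right, USE.NAMES = FALSE)
}

#' Filter recombinant individuals from a marker table
#'
#' Infers the genotype at each requested locus from its flanking-marker
#' columns, drops individuals recombinant at any requested locus, and
#' reports per-locus exclusion counts.  Retained genotype calls are
#' passed through unchanged.
#'
#' @param records data frame, one row per individual, containing the
#'   flanking-marker columns named in `loci`.
#' @param loci named list mapping locus name to its two flanking-marker
#'   column names, e.g.
#'   `list(hms1 = c("M8", "M24"), hms2 = c("M51", "MgSTS193"))`.
#' @param drop_missing also drop individuals with a missing call at any
#'   requested locus (default `FALSE`: missing calls are retained as
#'   `NA`).
#' @return List with `retained` (the filtered data frame, plus one
#'   inferred `<locus>` column per requested locus) and `report` (named
#'   integer vector of recombinants excluded per locus, plus
#'   `n_input`/`n_retained` attributes).
#' @export
filter_recombinants <- function(records,
                                loci = list(hms1 = c("M8", "M24"),
                                            hms2 = c("M51", "MgSTS193")),
                                drop_missing = FALSE) {
  stopifnot(is.data.frame(records), length(loci) >= 1)
  calls <- list()
  for (locus in names(loci)) {
    mk <- loci[[locus]]
    if (!all(mk %in% names(records)))
      stop("marker column(s) missing for locus ", locus, ": ",
           paste(setdiff(mk, names(records)), collapse = ", "),
           call. = FALSE)
    calls[[locus]] <- infer_locus_genotype(records[[mk[1]]],
                                           records[[mk[2]]])
  }
  recomb <- vapply(calls, function(x) !is.na(x) & x == "recombinant",
                   logical(nrow(records)))
  recomb <- matrix(recomb, nrow = nrow(records))
  keep <- rowSums(recomb) == 0
  if (drop_missing) {
    miss <- vapply(calls, is.na, logical(nrow(records)))
    keep <- keep & rowSums(matrix(miss, nrow = nrow(records))) == 0
  }
  report <- stats::setNames(colSums(recomb), names(loci))
  if (all(!keep))
    warning("all individuals are recombinant at a requested locus",
            call. = FALSE)
  retained <- records[keep, , drop = FALSE]
  for (locus in names(loci)) retained[[locus]] <- calls[[locus]][keep]
  attr(report, "n_input") <- nrow(records)
  attr(report, "n_retained") <- nrow(retained)
  list(retained = retained, report = report)
}

#' Double-crossover miscall probability between flanking markers
#'
#' Probability that a gamete recombines in both intermarker intervals
#' (product rule, no interference), producing concordant flanks that
#' miscall the focal locus.
#'
#' @param r_left,r_right recombination fractions of the two intervals, in
#'   \[0, 0.5\].
#' @return `r_left * r_right`.
#' @examples
#' double_crossover_error_rate(0.09, 0.09)   # 0.0081 (< 1%)
#' @export
double_crossover_error_rate <- function(r_left, r_right) {
  if (any(!is.finite(c(r_left, r_right))) ||
      any(c(r_left, r_right) < 0) || any(c(r_left, r_right) > 0.5))
    stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
  r_left * r_right
}

#' Proportion with exact binomial confidence interval
#'
#' Clopper-Pearson interval via [stats::binom.test()]; used e.g. for the
#' proportion of lines retaining a heterozygous introgression.
#'
#' @param k number of successes.
#' @param n total trials (> 0).
#' @param conf_level confidence level.
#' @return List with `estimate`, `lower`, `upper`, `k`, `n`.
#' @examples
#' proportion_with_ci(5, 175)   # 2.9% of introgression lines
#' @export
proportion_with_ci <- function(k, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(estimate = k / n,
       lower = bt$conf.int[1], upper = bt$conf.int[2], k = k, n = n)
}

# ---- delimited-text genotype count tables ---------------------------------

#' Read a two-locus genotype count table
#'
#' Two dialects are supported and auto-detected:
#' * **long**: columns `cross_id, genotype_hms1, genotype_hms2, count`;
#' * **wide**: a `cross_id` column plus nine columns named by two-locus
#'   genotype (`GG.GG` ... `NN.NN`, `;` or `.` separated).
#'
#' @param path file path (comma- or tab-delimited, auto-detected from the
#'   extension: `.tsv`/`.txt` is tab).
#' @return Named list of length-9 count vectors, one per `cross_id`, in
#'   canonical [TWO_LOCUS_GENOTYPES] order.
#' @export
read_genotype_counts <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("cross_id", "genotype_hms1", "genotype_hms2", "count")
  if (all(long_cols %in% names(df))) {
    out <- lapply(split(df, df$cross_id), function(d) {
      counts <- stats::setNames(
        d$count, mapply(tl_genotype, d$genotype_hms1, d$genotype_hms2))
      full_genotype_counts(counts)
    })
    return(out[unique(df$cross_id)])
  }
  if (!"cross_id" %in% names(df))
    stop("genotype count table needs a cross_id column", call. = FALSE)
  geno_cols <- setdiff(names(df), "cross_id")
  canon <- vapply(geno_cols,
                  function(x) tl_genotype(gsub("[._]", ";", x)),
                  character(1))
  if (!setequal(canon, TWO_LOCUS_GENOTYPES))
    stop("wide table must have one column per two-locus genotype",
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    full_genotype_counts(stats::setNames(as.numeric(df[i, geno_cols]),
                                         canon))
  })
  stats::setNames(out, df$cross_id)
}

#' Write a two-locus genotype count table
#'
#' @param counts named list of length-9 count vectors (as returned by
#'   [read_genotype_counts()] or built from [simulate_cross()] output).
#' @param path output file (`.tsv`/`.txt` is tab-delimited, otherwise
#'   comma).
#' @param format `"long"` or `"wide"` (see [read_genotype_counts()]).
#' @return `path`, invisibly.
#' @export
write_genotype_counts <- function(counts, path, format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(is.list(counts), !is.null(names(counts)))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  if (format == "long") {
    df <- do.call(rbind, lapply(names(counts), function(id) {
      cc <- full_genotype_counts(counts[[id]])
      g <- do.call(rbind, strsplit(names(cc), ";", fixed = TRUE))
      data.frame(cross_id = id, genotype_hms1 = g[, 1],
                 genotype_hms2 = g[, 2], count = as.numeric(cc),
                 stringsAsFactors = FALSE)
    }))
  } else {
    mat <- do.call(rbind, lapply(counts, full_genotype_counts))
    df <- data.frame(cross_id = names(counts), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("cross_id", gsub(";", ".", TWO_LOCUS_GENOTYPES,
                                    fixed = TRUE))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw marker table with a line-to-allele map
#'
#' Reads a delimited table (one row per individual, one column per
#' marker) whose genotype codes are `AA`, `AB`, `BB`, `NA` and remaps
#' them to the package's `GG`/`GN`/`NN` algebra.  For within-species
#' crosses the same machinery maps e.g. IM62/IM767 codes onto `G`/`N`.
#'
#' @param path file path.
#' @param allele_map named character vector mapping input codes to
#'   genotype codes; the default maps `AA -> GG`, `AB -> GN`, `BB -> NN`.
#' @param id_col name of the individual-id column (left unmapped).
#' @return Data frame with remapped marker columns.
#' @export
read_marker_table <- function(path,
                              allele_map = c(AA = "GG", AB = "GN",
                                             BA = "GN", BB = "NN"),
                              id_col = "individual_id") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  for (col in setdiff(names(df), id_col)) {
    vals <- df[[col]]
    bad <- !is.na(vals) & !vals %in% names(allele_map)
    if (any(bad))
      stop("unmapped genotype code(s) in column ", col, ": ",
           paste(unique(vals[bad]), collapse = ", "), call. = FALSE)
    df[[col]] <- unname(allele_map[vals])
  }
  df
}

# ---- transmission-model config files --------------------------------------

#' Serialize a transmission model to a YAML config file
#'
#' The config schema has top-level keys `s_male`, `s_female`, `k_drive`
#' (a number, or a mapping from parent *hms2* genotype to a number) and
#' optionally `lethal` with keys `hms1`, `hms2`, `background`,
#' `penetrance`.
#'
#' @param model a [transmission_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "transmission_model"))
  x <- list(s_male = model$s_male, s_female = model$s_female,
            k_drive = if (is.null(names(model$k_drive)))
              unname(model$k_drive) else as.list(model$k_drive))
  if (!is.null(model$lethal))
    x$lethal <- Filter(Negate(is.null), unclass(model$lethal))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  k <- x$k_drive %||% 0.5
  if (is.list(k)) k <- unlist(k)
  lethal <- NULL
  if (!is.null(x$lethal))
    lethal <- lethal_rule(hms1 = x$lethal$hms1, hms2 = x$lethal$hms2,
                          background = x$lethal$background,
                          penetrance = x$lethal$penetrance %||% 1)
  transmission_model(s_male = x$s_male %||% 0,
                     s_female = x$s_female %||% 0,
                     k_drive = k, lethal = lethal)
}
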