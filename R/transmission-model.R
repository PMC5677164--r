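# Selection-modified gamete pools and progeny genotype distributions.
#
# Three TRD mechanisms are parameterised:
#   (1) gametic incompatibility: the G;N gamete class (G at hms1 with N at
#       hms2) dies with sex-specific penetrance s_male / s_female;
#   (2) drive-like overtransmission of G at hms1 from heterozygotes,
#       optionally conditioned on the parent's hms2 genotype;
#   (3) zygotic lethality of a progeny genotype class in a given genetic
#       background (e.g. hms1 GG homozygotes on an M. nasutus background).
# Order of operations: drive reweighting, then gametic selection, then
# renormalisation.  The order is a modelling convention (overtransmission is
# treated as acting at gamete formation, incompatibility at gamete
# survival); it is not identifiable from progeny data alone.

#' Zygotic lethality rule
#'
#' A predicate over progeny two-locus genotypes plus a cross-level genetic
#' background flag.  A progeny genotype matches when every non-`NULL`
#' condition holds; matching zygotes die with probability `penetrance`.
#'
#' @param hms1,hms2 required single-locus genotype (`"GG"`, `"GN"`, `"NN"`)
#'   at each locus, or `NULL` for "any".
#' @param background required background flag (conventionally `"G"`,
#'   `"N"`, or `"F1"`), or `NULL` for "any background".
#' @param penetrance probability in \[0, 1\] that a matching zygote dies.
#' @return A `lethal_rule` list.
#' @examples
#' # hms1 GG homozygotes die on an M. nasutus background
#' lethal_rule(hms1 = "GG", background = "N")
#' @export
lethal_rule <- function(hms1 = NULL, hms2 = NULL, background = NULL,
                        penetrance = 1) {
  if (!is.null(hms1)) hms1 <- norm_geno(hms1)
  if (!is.null(hms2)) hms2 <- norm_geno(hms2)
  stopifnot(is.numeric(penetrance), penetrance >= 0, penetrance <= 1)
  structure(list(hms1 = hms1, hms2 = hms2, background = background,
                 penetrance = penetrance),
            class = "lethal_rule")
}

# per-genotype death probability vector (length 9) for a background
lethal_weights <- function(rule, background) {
  dead <- numeric(9)
  if (is.null(rule)) return(dead)
  if (!is.null(rule$background) &&
      (is.null(background) || !identical(rule$background, background)))
    return(dead)
  g1 <- rep(GENOTYPES, each = 3)
  g2 <- rep(GENOTYPES, times = 3)
  hit <- rep(TRUE, 9)
  if (!is.null(rule$hms1)) hit <- hit & g1 == rule$hms1
  if (!is.null(rule$hms2)) hit <- hit & g2 == rule$hms2
  dead[hit] <- rule$penetrance
  dead
}

#' Two-locus transmission model
#'
#' @param s_male,s_female penetrance in \[0, 1\] of gametic inviability for
#'   the `G;N` gamete class through pollen and ovules respectively.
#' @param k_drive transmission probability of the `G` allele at *hms1* from
#'   a heterozygous parent (0.5 = Mendelian).  Either a scalar, or a named
#'   vector keyed by the parent's *hms2* genotype
#'   (e.g. `c(GG = 0.5, GN = 0.5, NN = 0.65)`) for background-conditioned
#'   drive; missing names fall back to 0.5.
#' @param lethal a [lethal_rule()] (or `NULL` for no zygotic lethality).
#' @return A `transmission_model`.  The default arguments give the null
#'   model, which reproduces Mendelian expectations exactly.
#' @examples
#' transmission_model()                       # null model
#' transmission_model(s_male = 0.9, s_female = 0.3,
#'                    k_drive = c(NN = 0.65),
#'                    lethal = lethal_rule(hms1 = "GG", background = "N"))
#' @export
transmission_model <- function(s_male = 0, s_female = 0, k_drive = 0.5,
                               lethal = NULL) {
  stopifnot(s_male >= 0, s_male <= 1, s_female >= 0, s_female <= 1,
            all(k_drive >= 0), all(k_drive <= 1))
  if (!is.null(lethal) && !inherits(lethal, "lethal_rule"))
    stop("`lethal` must be a lethal_rule() or NULL", call. = FALSE)
  structure(list(s_male = s_male, s_female = s_female,
                 k_drive = k_drive, lethal = lethal),
            class = "transmission_model")
}

#' @export
print.transmission_model <- function(x, ...) {
  cat("<transmission_model>\n")
  cat("  s_male  =", x$s_male, "  s_female =", x$s_female, "\n")
  if (length(x$k_drive) == 1L && is.null(names(x$k_drive))) {
    cat("  k_drive =", x$k_drive, "\n")
  } else {
    cat("  k_drive =", paste(names(x$k_drive), x$k_drive, sep = ":",
                             collapse = ", "), "(by parent hms2)\n")
  }
  if (is.null(x$lethal)) {
    cat("  lethal  = none\n")
  } else {
    cat("  lethal  = hms1:", x$lethal$hms1 %||% "*",
        " hms2:", x$lethal$hms2 %||% "*",
        " background:", x$lethal$background %||% "*",
        " penetrance:", x$lethal$penetrance, "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resolve the drive coefficient for a parent's hms2 genotype
drive_coef <- function(model, parent_hms2) {
  k <- model$k_drive
  if (length(k) == 1L && is.null(names(k))) return(unname(k))
  if (parent_hms2 %in% names(k)) unname(k[[parent_hms2]]) else 0.5
}

#' Gamete pool surviving drive and gametic selection
#'
#' Starts from the Mendelian pool of `parent`; if the parent is
#' heterozygous at *hms1*, the *hms1* margin is reweighted to
#' `(k_drive, 1 - k_drive)`; the `G;N` class is then multiplied by
#' `1 - s_sex`.  Viability is the total surviving mass and the returned
#' pool is renormalised.
#'
#' @param parent two-locus genotype label.
#' @param sex `"male"` (pollen) or `"female"` (ovules).
#' @param model a [transmission_model()].
#' @return A `viability_prediction`: list with elements `viability`
#'   (fraction of surviving gametes), `pool` (renormalised [gamete_pool()],
#'   or `NULL` when sterile), and `sterile` (logical).
#' @examples
#' m <- transmission_model(s_male = 1)
#' selected_gamete_pool("GN;GN", "male", m)   # viability 0.75
#' @export
selected_gamete_pool <- function(parent, sex = c("male", "female"),
                                 model = transmission_model()) {
  sex <- match.arg(sex)
  g <- split_genotype(parent)
  m1 <- segregation_margin(g[1])
  if (g[1] == "GN") {
    k <- drive_coef(model, g[2])
    m1 <- c(G = k, N = 1 - k)
  }
  m2 <- segregation_margin(g[2])
  freqs <- rep(m1, each = 2) * rep(m2, times = 2)
  s <- if (sex == "male") model$s_male else model$s_female
  freqs[2] <- freqs[2] * (1 - s)              # G;N class
  viability <- sum(freqs)
  pool <- if (viability > 0)
    gamete_pool(freqs / viability, sex = sex) else NULL
  structure(list(viability = viability, pool = pool,
                 sterile = viability == 0, parent = tl_genotype(parent),
                 sex = sex),
            class = "viability_prediction")
}

#' @export
print.viability_prediction <- function(x, digits = 3, ...) {
  cat("<viability_prediction>", x$parent, "via", x$sex, "gametes\n")
  cat("  viability =", round(x$viability, digits),
      if (x$sterile) " (sterile)" else "", "\n")
  if (!is.null(x$pool)) print(x$pool, digits = digits)
  invisible(x)
}

#' Progeny genotype distribution of a cross under a transmission model
#'
#' Takes the outer product of the mother's and father's surviving gamete
#' pools, collapses ordered unions to unordered genotypes, applies the
#' model's zygotic lethality rule in the given background, and
#' renormalises.
#'
#' @param mother,father parental two-locus genotype labels.
#' @param model a [transmission_model()].
#' @param background background flag of the progeny (conventionally
#'   `"G"`, `"N"`, or `"F1"`), matched against the model's lethal rule.
#' @return A [genotype_distribution()].
#' @examples
#' progeny_distribution("GN;GN", "GN;GN")           # Mendelian F2
#' m <- transmission_model(lethal = lethal_rule(hms1 = "GG",
#'                                              background = "N"))
#' progeny_distribution("GN;GN", "GN;GN", m, background = "N")
#' @export
progeny_distribution <- function(mother, father,
                                 model = transmission_model(),
                                 background = "F1") {
  fp <- selected_gamete_pool(mother, "female", model)
  mp <- selected_gamete_pool(father, "male", model)
  if (fp$sterile || mp$sterile)
    stop("cross infeasible: ",
         if (fp$sterile) "mother" else "father",
         " produces no viable gametes under this model", call. = FALSE)
  freqs <- union_of_pools(fp$pool, mp$pool)
  dead <- lethal_weights(model$lethal, background)
  freqs <- freqs * (1 - dead)
  total <- sum(freqs)
  if (total <= 0)
    stop("cross infeasible: all progeny classes are lethal", call. = FALSE)
  genotype_distribution(freqs / total)
}

# outer product of two gamete pools collapsed to the 9 unordered two-locus
# genotypes (hms1-major order); shared kernel for model-based and
# empirical-pool expectations
union_of_pools <- function(female, male) {
  out <- numeric(9)
  # gamete class index -> per-locus allele (1 = G, 2 = N)
  a1 <- c(1, 1, 2, 2)   # hms1 allele of classes G;G G;N N;G N;N
  a2 <- c(1, 2, 1, 2)   # hms2 allele
  # genotype index at one locus from two allele indices: GG=1, GN=2, NN=3
  gidx <- function(x, y) ifelse(x == y, ifelse(x == 1, 1L, 3L), 2L)
  for (i in 1:4) for (j in 1:4) {
    p <- female[i] * male[j]
    if (p == 0) next
    k <- (gidx(a1[i], a1[j]) - 1L) * 3L + gidx(a2[i], a2[j])
    out[k] <- out[k] + p
  }
  out
}

#' Transmitted allele frequencies predicted from observed pollen viability
#'
#' Inverts an observed viability into predicted per-locus transmission,
#' attributing sterility to the incompatible `G;N` gamete class first:
#' starting from the Mendelian pool, the `G;N` class is killed up to its
#' Mendelian share; any residual observed sterility is divided equally
#' among the remaining classes.  Returns the `G`-allele frequency of the
#' surviving pool at each locus segregating in the parent.
#'
#' @param parent two-locus genotype label (heterozygous at >= 1 locus).
#' @param observed_viability observed fraction of viable gametes, in (0, 1].
#' @return List with `pool` (surviving [gamete_pool()]), `freq_G` (named
#'   numeric `c(hms1 = , hms2 = )`, `NA` at a non-segregating locus), and
#'   `residual_sterility` (sterility beyond the `G;N` Mendelian share).
#' @examples
#' # hms1-GG; hms2-GN pollen parent at 64% viability: G expected in 78%
#' predict_transmission_from_viability("GG;GN", 0.64)$freq_G
#' @export
predict_transmission_from_viability <- function(parent, observed_viability) {
  g <- split_genotype(parent)
  if (!any(g == "GN"))
    stop("parent must be heterozygous at at least one locus", call. = FALSE)
  if (!is.finite(observed_viability) || observed_viability <= 0 ||
      observed_viability > 1)
    stop("observed viability must lie in (0, 1]", call. = FALSE)
  pool <- unclass(mendelian_gamete_pool(parent))
  sterility <- 1 - observed_viability
  gn_share <- pool[["G;N"]]
  if (sterility <= gn_share) {
    if (sterility > 0 && all(g == "GN"))
      warning("observed sterility is below the Mendelian share of the ",
              "G;N class; attributing all of it to that class",
              call. = FALSE)
    pool[["G;N"]] <- gn_share - sterility
    residual <- 0
  } else {
    pool[["G;N"]] <- 0
    residual <- sterility - gn_share
    survivors <- which(pool > 0)
    pool[survivors] <- pool[survivors] - residual / length(survivors)
    if (any(pool < 0))
      stop("residual sterility exceeds the surviving classes", call. = FALSE)
  }
  surviving <- sum(pool)
  norm <- pool / surviving
  freq_G <- c(
    hms1 = if (g[1] == "GN") unname(norm[["G;G"]] + norm[["G;N"]]) else NA_real_,
    hms2 = if (g[2] == "GN") unname(norm[["G;G"]] + norm[["N;G"]]) else NA_real_)
  list(pool = gamete_pool(norm, sex = "male"),
       freq_G = freq_G, residual_sterility = residual,
       viability = surviving)
}

#' Recoverable genotype classes under a model and background
#'
#' The set of two-locus genotypes with nonzero expected frequency among
#' the selfed progeny of a double heterozygote under `model` in the given
#' background; e.g. with complete *hms1*-GG lethality on an `"N"`
#' background, only six classes can be recovered.
#'
#' @param model a [transmission_model()].
#' @param background background flag.
#' @return Character vector of genotype labels (subset of
#'   [TWO_LOCUS_GENOTYPES]).
#' @export
ils_feasible_genotypes <- function(model = transmission_model(),
                                   background = "F1") {
  d <- progeny_distribution("GN;GN", "GN;GN", model, background)
  names(d)[unclass(d) > 0]
}
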