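# SNP-by-SNP estimators: excess-homozygosity F_HOM and the VanRaden
# method-I genomic relationship matrix with F_GRM = G_ii - 1.

#' Expected homozygote count under Hardy-Weinberg equilibrium
#'
#' E_HOM(i) = sum over loci non-missing in i of p_j^2 + (1 - p_j)^2, with
#' p_j the reference-allele frequency at locus j.
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA (used for the
#'   missingness mask).
#' @param freqs Per-marker reference-allele frequencies; defaults to
#'   in-sample frequencies. Frequencies of exactly 0 or 1 contribute a
#'   certain homozygote (probability 1) with a warning: such markers
#'   should have been removed by the MAF filter.
#' @return Numeric vector of expected homozygote counts, one per
#'   individual.
#' @export
expected_hom <- function(geno, freqs = allele_freqs(geno)) {
  stopifnot(length(freqs) == ncol(geno))
  if (any(freqs <= 0 | freqs >= 1, na.rm = TRUE)) {
    warning("monomorphic marker(s) present (freq 0 or 1); each contributes ",
            "an expected homozygote with probability 1")
  }
  h <- freqs^2 + (1 - freqs)^2
  mask <- !is.na(geno)
  as.vector(mask %*% h)
}

#' Per-individual homozygosity statistics
#'
#' @inheritParams expected_hom
#' @return data.frame `id`, `o_hom` (observed homozygotes), `m` (non-missing
#'   loci), `e_hom` (HWE expectation).
#' @export
hom_stats <- function(geno, freqs = allele_freqs(geno)) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  data.frame(id = ids,
             o_hom = rowSums(geno != 1, na.rm = TRUE),
             m = rowSums(!is.na(geno)),
             e_hom = expected_hom(geno, freqs),
             stringsAsFactors = FALSE)
}

#' Excess-homozygosity inbreeding coefficient F_HOM
#'
#' F_HOM(i) = (O_HOM - E_HOM) / (m - E_HOM): the method-of-moments
#' coefficient from observed versus HWE-expected homozygosity. Negative
#' values are legitimate (fewer homozygotes than expected). Individuals
#' with m = E_HOM (undefined denominator) are reported `NA`.
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA, or a data.frame of
#'   precomputed statistics from [hom_stats()].
#' @param freqs Optional per-marker reference-allele frequencies (e.g.
#'   founder frequencies); defaults to in-sample.
#' @return data.frame `id`, `f_hom`.
#' @export
f_hom <- function(geno, freqs = NULL) {
  st <- if (is.data.frame(geno)) geno else {
    if (is.null(freqs)) hom_stats(geno) else hom_stats(geno, freqs)
  }
  denom <- st$m - st$e_hom
  f <- ifelse(denom <= .Machine$double.eps * pmax(st$m, 1), NA_real_,
              (st$o_hom - st$e_hom) / denom)
  data.frame(id = st$id, f_hom = f, stringsAsFactors = FALSE)
}

#' VanRaden method-I genomic relationship matrix
#'
#' G = Z Z' / (2 * sum p_j (1 - p_j)) with Z the genotype matrix centred
#' by twice the allele frequency. Missing genotypes are set to the
#' frequency expectation 2 p_j (zero after centring), the standard
#' VanRaden handling.
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA; markers must be
#'   polymorphic in the frequencies used.
#' @param freqs Per-marker reference-allele frequencies; default in-sample.
#' @return Object of class `grm`: list with `G` (dense symmetric matrix),
#'   `denom` (scaling denominator) and `ids`.
#' @export
vanraden_grm <- function(geno, freqs = allele_freqs(geno)) {
  stopifnot(length(freqs) == ncol(geno))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (!is.finite(denom) || denom <= 0) {
    stop("zero GRM denominator: no polymorphic markers in the supplied frequencies")
  }
  Z <- sweep(geno, 2, 2 * freqs)
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, denom = denom, ids = ids), class = "grm")
}

#' Genomic-relationship inbreeding coefficient F_GRM
#'
#' F_GRM(i) = G_ii - 1, the deviation of genomic self-relatedness from 1.
#' Negative values reflect individuals less homozygous than expected at
#' the population allele frequencies.
#'
#' @param grm A `grm` from [vanraden_grm()].
#' @return data.frame `id`, `f_grm`.
#' @export
f_grm <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  data.frame(id = grm$ids, f_grm = unname(diag(grm$G)) - 1,
             stringsAsFactors = FALSE)
}

#' Export a GRM in long format
#'
#' @param grm A `grm` object.
#' @return data.frame `i`, `j`, `value` over the lower triangle incl.
#'   diagonal.
#' @export
grm_long <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  idx <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  data.frame(i = grm$ids[idx[, 1]], j = grm$ids[idx[, 2]],
             value = grm$G[idx], stringsAsFactors = FALSE)
}
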