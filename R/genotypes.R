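# Genotype/map ingestion (PLINK text dialect) and the SNP-array QC cascade.

#' Read genotypes from PED/MAP text files
#'
#' Parses the whitespace-delimited PED/MAP dialect: MAP columns
#' `chrom, id, genetic_pos, bp`; PED columns `fid, iid, sire, dam, sex,
#' pheno` followed by two allele columns per marker. Allele coding is
#' deterministic: the first non-missing allele seen at a marker is the
#' reference unless `ref_alleles` supplies one; `0` denotes a missing
#' allele and any genotype with a missing allele is coded `NA`.
#'
#' @param ped_file Path to the .ped file.
#' @param map_file Path to the .map file.
#' @param ref_alleles Optional character vector, one reference allele per
#'   marker (names = marker ids or positional).
#' @return list with `geno` (individuals x markers integer matrix of
#'   reference-allele counts 0/1/2/NA) and `map` (data.frame `chrom`, `id`,
#'   `position_bp`, `genetic_pos_morgan`).
#' @export
read_genotypes <- function(ped_file, map_file, ref_alleles = NULL) {
  map <- utils::read.table(map_file, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "bp"))
  map <- data.frame(chrom = as.character(map$chrom), id = as.character(map$id),
                    position_bp = as.integer(map$bp),
                    genetic_pos_morgan = as.numeric(map$cm) / 100,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_file)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  geno <- matrix(NA_integer_, n, m)
  ids <- character(n)
  ref <- rep(NA_character_, m)
  alt <- rep(NA_character_, m)
  if (!is.null(ref_alleles)) {
    if (!is.null(names(ref_alleles))) {
      ref[match(names(ref_alleles), map$id)] <- unname(ref_alleles)
    } else {
      ref[seq_along(ref_alleles)] <- ref_alleles
    }
  }
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop(sprintf("ped line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(tok)))
    }
    ids[i] <- tok[2]
    a1 <- tok[seq(7, by = 2, length.out = m)]
    a2 <- tok[seq(8, by = 2, length.out = m)]
    miss <- a1 == "0" | a2 == "0"
    for (j in which(!miss)) {
      for (al in c(a1[j], a2[j])) {
        if (is.na(ref[j])) ref[j] <- al
        else if (is.na(alt[j]) && al != ref[j]) alt[j] <- al
        else if (al != ref[j] && al != alt[j]) {
          stop(sprintf("marker %s is not biallelic (alleles %s, %s, %s)",
                       map$id[j], ref[j], alt[j], al))
        }
      }
    }
    g <- (a1 == ref) + (a2 == ref)
    g[miss] <- NA_integer_
    geno[i, ] <- as.integer(g)
  }
  if (anyDuplicated(ids)) stop("duplicated individual ids in ped file")
  dimnames(geno) <- list(ids, map$id)
  list(geno = geno, map = map)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_genotypes()]; reference allele written as "A", the
#' alternative as "B", missing as "0 0".
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA.
#' @param map Marker map data.frame (`chrom`, `id`, `position_bp`,
#'   optionally `genetic_pos_morgan`).
#' @param prefix Output path prefix; writes `<prefix>.ped`, `<prefix>.map`.
#' @param ped Optional `pedigree` supplying sire/dam/sex columns.
#' @return Invisibly, the two file paths.
#' @export
write_genotypes <- function(geno, map, prefix, ped = NULL) {
  cm <- if (!is.null(map$genetic_pos_morgan)) map$genetic_pos_morgan * 100 else 0
  utils::write.table(
    data.frame(map$chrom, map$id, cm, map$position_bp),
    paste0(prefix, ".map"), quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(geno)
  sire <- dam <- rep("0", length(ids))
  sexc <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[i]), "0", ped$sire[i])
    dam <- ifelse(is.na(ped$dam[i]), "0", ped$dam[i])
    sexc <- c(male = "1", female = "2", unknown = "0")[ped$sex[i]]
  }
  al <- matrix("0", nrow(geno), 2 * ncol(geno))
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, "A", "B"))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, "A", "B"))
    al[, 2 * j - 1] <- a1
    al[, 2 * j] <- a2
  }
  out <- cbind(ids, ids, sire, dam, sexc, "0", al)
  utils::write.table(out, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one (the SNP-array convention for HWE filtering).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  ## feasible het counts share the parity of the rare allele count
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1) + h * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Default genotype QC thresholds
#'
#' @param snp_call_rate_min Minimum per-SNP call rate (default 0.90).
#' @param hwe_p_min Minimum HWE exact p-value (default 1e-6).
#' @param ind_missing_max Maximum per-individual missing fraction (0.10).
#' @param maf_min Minimum minor allele frequency (0.01).
#' @param dup_pi_hat PI_HAT above which a pair is flagged as a potential
#'   duplicate (0.95); report-only.
#' @param het_z Absolute F_HOM z-score flagging heterozygosity outliers (3);
#'   report-only.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.90, hwe_p_min = 1e-6,
                          ind_missing_max = 0.10, maf_min = 0.01,
                          dup_pi_hat = 0.95, het_z = 3) {
  stopifnot(snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            ind_missing_max >= 0, ind_missing_max <= 1,
            maf_min >= 0, maf_min <= 1)
  list(snp_call_rate_min = snp_call_rate_min, hwe_p_min = hwe_p_min,
       ind_missing_max = ind_missing_max, maf_min = maf_min,
       dup_pi_hat = dup_pi_hat, het_z = het_z)
}

#' Sample allele frequencies
#'
#' Reference-allele frequency per marker from non-missing genotypes of the
#' currently retained individuals.
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA.
#' @return Numeric vector, one frequency per marker (NaN where all missing).
#' @export
allele_freqs <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

#' Genotype quality-control cascade
#'
#' Applies, in a fixed documented order: restriction to autosomes, SNP call
#' rate, HWE exact test, individual missingness, and MAF. A single pass is
#' made (per-SNP statistics are not recomputed after individual removal).
#'
#' @param geno Individuals x markers matrix of 0/1/2/NA.
#' @param map Marker map as from [read_genotypes()].
#' @param thresholds From [qc_thresholds()].
#' @param autosomes Chromosome labels regarded as autosomal; defaults to
#'   all-numeric labels.
#' @return list with filtered `geno`, `map`, and `log` (data.frame of step,
#'   items removed, count remaining).
#' @export
qc_cascade <- function(geno, map, thresholds = qc_thresholds(),
                       autosomes = NULL) {
  stopifnot(ncol(geno) == nrow(map))
  steps <- list()
  note <- function(step, removed, n_snp, n_ind) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, removed = removed, snps_left = n_snp, inds_left = n_ind,
      stringsAsFactors = FALSE)
  }
  if (is.null(autosomes)) {
    keep <- grepl("^[0-9]+$", map$chrom)
  } else {
    keep <- map$chrom %in% autosomes
  }
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("autosomes", sum(!keep), ncol(geno), nrow(geno))

  call_rate <- 1 - colMeans(is.na(geno))
  keep <- call_rate >= thresholds$snp_call_rate_min
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("snp_call_rate", sum(!keep), ncol(geno), nrow(geno))

  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_exact_test(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- hwe_p >= thresholds$hwe_p_min
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("hwe", sum(!keep), ncol(geno), nrow(geno))

  ind_miss <- rowMeans(is.na(geno))
  keep_ind <- ind_miss <= thresholds$ind_missing_max
  geno <- geno[keep_ind, , drop = FALSE]
  note("individual_missingness", sum(!keep_ind), ncol(geno), nrow(geno))

  p <- allele_freqs(geno)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= thresholds$maf_min
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("maf", sum(!keep), ncol(geno), nrow(geno))

  if (ncol(geno) == 0) stop("no markers left after quality control")
  rownames(map) <- NULL
  list(geno = geno, map = map, log = do.call(rbind, steps))
}

#' Pairwise IBS/IBD screen for duplicates and close relatives
#'
#' Method-of-moments decomposition of observed identity-by-state counts
#' into IBD-sharing probabilities (Z0, Z1, Z2), with PI_HAT = Z1/2 + Z2.
#' Expected IBS-given-IBD probabilities use sample allele counts with the
#' without-replacement correction, so estimates stay unbiased in small
#' cohorts. Estimates are truncated to the simplex. Pairs with PI_HAT at
#' or above the duplicate threshold are flagged; the screen is
#' report-only.
#'
#' @param geno QC-passed genotype matrix (0/1/2/NA).
#' @param dup_pi_hat Flagging threshold (default 0.95).
#' @return data.frame `id1`, `id2`, `n_snps`, `z0`, `z1`, `z2`, `pi_hat`,
#'   `flagged`.
#' @export
ibs_screen <- function(geno, dup_pi_hat = 0.95) {
  n <- nrow(geno)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  x <- colSums(geno, na.rm = TRUE)                 # reference allele count
  tot <- 2 * colSums(!is.na(geno))                 # total alleles observed
  y <- tot - x
  ok <- tot >= 4 & x > 0 & y > 0
  geno <- geno[, ok, drop = FALSE]
  x <- x[ok]; y <- y[ok]; tot <- tot[ok]
  ## per-locus P(IBS = k | IBD = z): falling-factorial allele-count form
  d4 <- tot * (tot - 1) * (tot - 2) * (tot - 3)
  d3 <- tot * (tot - 1) * (tot - 2)
  p0_ibs0 <- 2 * x * (x - 1) * y * (y - 1) / d4
  p0_ibs1 <- (4 * x * (x - 1) * (x - 2) * y + 4 * x * y * (y - 1) * (y - 2)) / d4
  p1_ibs1 <- (2 * x * (x - 1) * y + 2 * x * y * (y - 1)) / d3
  p0_ibs2 <- 1 - p0_ibs0 - p0_ibs1
  p1_ibs2 <- 1 - p1_ibs1
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    gi <- geno[i, ]
    for (j in (i + 1):n) {
      gj <- geno[j, ]
      use <- !is.na(gi) & !is.na(gj)
      d <- abs(gi[use] - gj[use])
      ibs0 <- d == 2
      ibs2 <- d == 0
      ibs1 <- !ibs0 & !ibs2
      L <- sum(use)
      e0_0 <- sum(p0_ibs0[use]); e0_1 <- sum(p0_ibs1[use]); e0_2 <- sum(p0_ibs2[use])
      e1_1 <- sum(p1_ibs1[use]); e1_2 <- sum(p1_ibs2[use])
      z0 <- sum(ibs0) / e0_0
      z1 <- (sum(ibs1) - z0 * e0_1) / e1_1
      z2 <- (sum(ibs2) - z0 * e0_2 - z1 * e1_2) / L
      z <- pmax(c(z0, z1, z2), 0)
      z <- z / sum(z)
      k <- k + 1L
      out[[k]] <- data.frame(id1 = ids[i], id2 = ids[j], n_snps = L,
                             z0 = z[1], z1 = z[2], z2 = z[3],
                             pi_hat = z[2] / 2 + z[3],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$flagged <- res$pi_hat >= dup_pi_hat
  res
}

#' Heterozygosity outlier screen
#'
#' Flags individuals whose F_HOM lies more than `z` sample standard
#' deviations from the cohort mean; report-only.
#'
#' @param geno QC-passed genotype matrix.
#' @param z Absolute z-score threshold (default 3).
#' @return data.frame `id`, `f_hom`, `z`, `flagged`.
#' @export
het_outliers <- function(geno, z = 3) {
  f <- f_hom(geno)
  zz <- (f$f_hom - mean(f$f_hom, na.rm = TRUE)) / stats::sd(f$f_hom, na.rm = TRUE)
  data.frame(id = f$id, f_hom = f$f_hom, z = zz,
             flagged = !is.na(zz) & abs(zz) > z, stringsAsFactors = FALSE)
}
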