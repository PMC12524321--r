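# Sliding-window detection of runs of homozygosity (ROH), segment
# length-classing and F_ROH.

#' ROH scan parameters
#'
#' Defaults follow the SNP-array convention for medium-density equine
#' panels: 50-SNP sliding windows with at most one heterozygous and five
#' missing calls, a 5% per-SNP hit-rate threshold, segments of at least
#' 1 Mb and 15 SNPs, a maximum internal gap of 1 Mb, a density cap of one
#' SNP per 200 kb, and an autosomal genome length of 2410 Mb.
#'
#' @param min_length_bp,min_snps,max_gap_bp,max_density_bp_per_snp Segment
#'   filters.
#' @param window_snps,window_max_het,window_max_missing Sliding-window
#'   definition.
#' @param hit_threshold Fraction of homozygous windows containing a SNP
#'   required to flag it.
#' @param genome_length_bp Autosomal genome length used as the F_ROH
#'   denominator.
#' @return Named list of parameters.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 15, max_gap_bp = 1e6,
                       max_density_bp_per_snp = 2e5, window_snps = 50,
                       window_max_het = 1, window_max_missing = 5,
                       hit_threshold = 0.05, genome_length_bp = 2.41e9) {
  stopifnot(min_length_bp > 0, min_snps > 0, max_gap_bp > 0,
            max_density_bp_per_snp > 0, window_snps > 0,
            hit_threshold > 0, hit_threshold <= 1, genome_length_bp > 0)
  list(min_length_bp = min_length_bp, min_snps = min_snps,
       max_gap_bp = max_gap_bp,
       max_density_bp_per_snp = max_density_bp_per_snp,
       window_snps = window_snps, window_max_het = window_max_het,
       window_max_missing = window_max_missing,
       hit_threshold = hit_threshold, genome_length_bp = genome_length_bp)
}

#' ROH length classes and inbreeding-age labels
#'
#' Half-open classes 1-<2, 2-<4, 4-<8, 8-<16 and >=16 Mb; longer segments
#' reflect more recent common ancestors (>=16 Mb very recent, 8-<16 recent,
#' 4-<8 intermediate, 1-<4 ancient).
#'
#' @param length_bp Numeric vector of segment lengths in bp.
#' @return data.frame `length_class` (factor) and `age_label` (factor).
#' @export
roh_length_class <- function(length_bp) {
  breaks <- c(1e6, 2e6, 4e6, 8e6, 16e6, Inf)
  labs <- c("1-<2Mb", "2-<4Mb", "4-<8Mb", "8-<16Mb", ">=16Mb")
  ages <- c("ancient", "ancient", "intermediate", "recent", "very recent")
  cls <- cut(length_bp, breaks = breaks, labels = labs, right = FALSE)
  data.frame(length_class = cls,
             age_label = factor(ages[as.integer(cls)], levels = unique(ages)))
}

#' Per-SNP homozygous-run flags from a sliding-window scan
#'
#' Windows of `window_snps` consecutive SNPs are slid along the chromosome;
#' only fully contained windows are formed. A window is homozygous if it
#' contains at most `window_max_het` heterozygous and `window_max_missing`
#' missing calls. Each SNP's hit rate is the fraction of windows containing
#' it that are homozygous; the SNP is flagged when the rate reaches
#' `hit_threshold`. Chromosomes shorter than one window yield no flags.
#'
#' @param geno Genotype vector (0/1/2/NA) of one individual on one
#'   chromosome, position-sorted.
#' @param params From [roh_params()].
#' @return Logical vector of per-SNP flags.
#' @export
window_flags <- function(geno, params = roh_params()) {
  L <- length(geno)
  w <- params$window_snps
  flags <- logical(L)
  if (L < w) return(flags)
  n_win <- L - w + 1L
  het <- as.integer(!is.na(geno) & geno == 1)
  mis <- as.integer(is.na(geno))
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  win_het <- cs_het[(w + 1):(L + 1)] - cs_het[1:n_win]
  win_mis <- cs_mis[(w + 1):(L + 1)] - cs_mis[1:n_win]
  ok <- win_het <= params$window_max_het & win_mis <= params$window_max_missing
  cs_ok <- c(0, cumsum(ok))
  s <- seq_len(L)
  lo <- pmax(1L, s - w + 1L)          # first window containing SNP s
  hi <- pmin(n_win, s)                # last window containing SNP s
  n_cover <- hi - lo + 1L
  n_hit <- cs_ok[hi + 1L] - cs_ok[lo]
  flags <- n_hit / n_cover >= params$hit_threshold
  flags
}

#' Assemble ROH segments from per-SNP flags
#'
#' Maximal runs of flagged SNPs are split where the gap between adjacent
#' SNPs exceeds `max_gap_bp`, then filtered on minimum length, minimum SNP
#' count and SNP density. Segment span is `end_bp - start_bp + 1` over the
#' bounding SNPs. Heterozygous or missing SNPs inside a flagged run stay in
#' the segment and count towards `n_snps` (their admissibility is governed
#' by the window flags).
#'
#' @param flags Logical per-SNP flags from [window_flags()].
#' @param pos_bp Positions of the SNPs (sorted, same length as `flags`).
#' @param params From [roh_params()].
#' @return data.frame `start_bp`, `end_bp`, `n_snps`, `length_bp` (possibly
#'   zero rows).
#' @export
assemble_segments <- function(flags, pos_bp, params = roh_params()) {
  stopifnot(length(flags) == length(pos_bp), !is.unsorted(pos_bp))
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0))
  if (!any(flags)) return(empty)
  idx <- which(flags)
  brk <- c(0, which(diff(idx) > 1 | diff(pos_bp[idx]) > params$max_gap_bp),
           length(idx))
  out <- list()
  for (k in seq_len(length(brk) - 1)) {
    run <- idx[(brk[k] + 1):brk[k + 1]]
    start <- pos_bp[run[1]]; end <- pos_bp[run[length(run)]]
    len <- end - start + 1
    ns <- length(run)
    if (len >= params$min_length_bp && ns >= params$min_snps &&
        len / ns <= params$max_density_bp_per_snp) {
      out[[length(out) + 1L]] <- data.frame(start_bp = start, end_bp = end,
                                            n_snps = ns, length_bp = len)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect runs of homozygosity for all individuals
#'
#' Runs [window_flags()] and [assemble_segments()] per individual and
#' chromosome and attaches length classes.
#'
#' @param geno Individuals x markers matrix (0/1/2/NA).
#' @param map Marker map (`chrom`, `position_bp`), column-aligned to
#'   `geno`.
#' @param params From [roh_params()].
#' @return data.frame `id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`, `length_class`, `age_label`.
#' @export
detect_roh <- function(geno, map, params = roh_params()) {
  stopifnot(ncol(geno) == nrow(map))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  chroms <- unique(map$chrom)
  out <- list()
  for (ch in chroms) {
    jj <- which(map$chrom == ch)
    jj <- jj[order(map$position_bp[jj])]
    pos <- map$position_bp[jj]
    for (i in seq_len(nrow(geno))) {
      fl <- window_flags(geno[i, jj], params)
      seg <- assemble_segments(fl, pos, params)
      if (nrow(seg)) {
        seg <- cbind(id = ids[i], chrom = ch, seg, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(id = character(0), chrom = character(0),
                            start_bp = numeric(0), end_bp = numeric(0),
                            n_snps = integer(0), length_bp = numeric(0)),
                 roh_length_class(numeric(0))))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, ids), res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  cbind(res, roh_length_class(res$length_bp))
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' F_ROH(i) = total ROH length / autosomal genome length, partitioned
#' additively into the five length classes (class columns sum to the
#' total exactly).
#'
#' @param segments Segment table from [detect_roh()].
#' @param ids Individuals to report (keeps zero rows for segment-free
#'   individuals); defaults to those present in `segments`.
#' @param params From [roh_params()] (source of the genome length).
#' @return data.frame `id`, `f_roh` and one `f_roh_<class>` column per
#'   length class.
#' @export
f_roh <- function(segments, ids = unique(segments$id), params = roh_params()) {
  L <- params$genome_length_bp
  labs <- levels(roh_length_class(numeric(0))$length_class)
  cols <- paste0("f_roh_", gsub("[-<>=]", "", labs))
  out <- data.frame(id = ids, f_roh = 0, stringsAsFactors = FALSE)
  for (cc in cols) out[[cc]] <- 0
  if (nrow(segments)) {
    for (k in seq_along(labs)) {
      sel <- segments$length_class == labs[k]
      agg <- tapply(segments$length_bp[sel], segments$id[sel], sum)
      i <- match(names(agg), ids)
      keep <- !is.na(i)
      out[[cols[k]]][i[keep]] <- unname(agg[keep]) / L
    }
    out$f_roh <- rowSums(out[, cols, drop = FALSE])
  }
  out
}
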