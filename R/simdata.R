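# Synthetic-data generator: pedigree simulation with planned
# consanguineous matings, and gene-dropping of recombining genotypes with
# founder-allele labels, so that realised autozygosity is known exactly.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study cohort for a small closed
#' population: a 200-individual mixed-design cohort (outbred controls,
#' planted full-sib-mating offspring, and a deep-background closed line)
#' genotyped on 10 chromosomes of 1 Morgan (100 Mb) with 2,000 SNPs each,
#' founder minor allele frequencies uniform on `[0.05, 0.5]`, genotyping
#' error 0.001 and missing rate 0.005.
#'
#' @param mating_design `"study"` (mixed design above), `"random"`
#'   (monogamous random pairing per generation), or a named list of
#'   planted-mating counts (`full_sib`, `half_sib`, `parent_offspring`),
#'   each count giving offspring bred from fresh unrelated founders.
#' @param n_founders,n_generations,n_per_generation Random-design sizes.
#' @param study Sizes of the study design: outbred offspring, full-sib
#'   offspring, background-cohort offspring, and the background line's
#'   founders, generations and per-generation size.
#' @param n_chromosomes,chrom_length_bp,n_snps_per_chrom Genome layout
#'   (markers on a regular grid).
#' @param maf_min Founder reference-allele frequencies ~ `U[maf_min, 0.5]`.
#' @param error_rate Probability a genotype has one allele mis-read.
#' @param missing_rate Probability a genotype is set missing.
#' @param morgan_per_bp Genetic map constant (1 cM/Mb default).
#' @param seed Mandatory integer seed.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(mating_design = "study",
                       n_founders = 100, n_generations = 2,
                       n_per_generation = 50,
                       study = list(n_outbred = 50, n_fullsib = 75,
                                    n_background = 75, bg_founders = 10,
                                    bg_generations = 10, bg_size = 20),
                       n_chromosomes = 10, chrom_length_bp = 1e8,
                       n_snps_per_chrom = 2000, maf_min = 0.05,
                       error_rate = 0.001, missing_rate = 0.005,
                       morgan_per_bp = 1e-8, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_chromosomes > 0, chrom_length_bp > 0, n_snps_per_chrom > 0,
            maf_min > 0, maf_min <= 0.5, error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, morgan_per_bp > 0)
  structure(list(mating_design = mating_design, n_founders = n_founders,
                 n_generations = n_generations,
                 n_per_generation = n_per_generation, study = study,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = n_snps_per_chrom, maf_min = maf_min,
                 error_rate = error_rate, missing_rate = missing_rate,
                 morgan_per_bp = morgan_per_bp, seed = as.integer(seed)),
            class = "sim_config")
}

## internal pedigree builder state: rows appended as id/sire/dam/sex/year/group
.ped_builder <- function() {
  rows <- list()
  counter <- 0L
  add <- function(sire, dam, sex, year, group) {
    counter <<- counter + 1L
    id <- sprintf("I%04d", counter)
    rows[[counter]] <<- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                                   birth_year = year, group = group,
                                   stringsAsFactors = FALSE)
    id
  }
  list(add = add, table = function() do.call(rbind, rows))
}

.add_founders <- function(b, n, year, group) {
  vapply(seq_len(n), function(i) {
    b$add(NA_character_, NA_character_,
          if (i %% 2 == 1) "male" else "female", year, group)
  }, character(1))
}

## monogamous random pairing of the previous generation; offspring
## distributed round-robin over couples
.random_generation <- function(b, prev, sexes, n_off, year, group) {
  males <- prev[sexes == "male"]
  females <- prev[sexes == "female"]
  nc <- min(length(males), length(females))
  couples <- cbind(sample(males)[seq_len(nc)], sample(females)[seq_len(nc)])
  vapply(seq_len(n_off), function(k) {
    cp <- couples[(k - 1L) %% nc + 1L, ]
    b$add(cp[1], cp[2], if (k %% 2 == 1) "male" else "female", year, group)
  }, character(1))
}

#' Simulate a pedigree under a mating design
#'
#' Founders are unrelated; planned consanguineous matings are realised
#' exactly. Birth years advance by 5 per generation from 2000. The
#' returned pedigree carries `group` and `birth_year` columns identifying
#' the design role of each individual.
#'
#' @param cfg A [sim_config()] (the seed is applied).
#' @return A topologically ordered `pedigree` data.frame.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  b <- .ped_builder()
  des <- cfg$mating_design
  if (identical(des, "random")) {
    gen <- .add_founders(b, cfg$n_founders, 2000, "founder")
    sexes <- ifelse(seq_along(gen) %% 2 == 1, "male", "female")
    for (g in seq_len(cfg$n_generations)) {
      gen <- .random_generation(b, gen, sexes, cfg$n_per_generation,
                                2000 + 5 * g, paste0("gen", g))
      sexes <- ifelse(seq_along(gen) %% 2 == 1, "male", "female")
    }
  } else if (identical(des, "study")) {
    s <- cfg$study
    ## outbred controls: one offspring per fresh founder couple
    for (k in seq_len(s$n_outbred)) {
      f <- .add_founders(b, 2, 2000, "founder")
      b$add(f[1], f[2], if (k %% 2 == 1) "male" else "female", 2010, "outbred")
    }
    ## planted full-sib matings: sib pairs bred from fresh founders,
    ## three offspring per pair
    n_pairs <- ceiling(s$n_fullsib / 3)
    made <- 0L
    for (k in seq_len(n_pairs)) {
      f <- .add_founders(b, 2, 2000, "founder")
      sib1 <- b$add(f[1], f[2], "male", 2005, "sib_parent")
      sib2 <- b$add(f[1], f[2], "female", 2005, "sib_parent")
      for (j in seq_len(min(3L, s$n_fullsib - made))) {
        b$add(sib1, sib2, if (j %% 2 == 1) "male" else "female", 2010, "fullsib")
        made <- made + 1L
      }
    }
    ## deep background: closed random-mating line
    gen <- .add_founders(b, s$bg_founders, 1950, "founder")
    sexes <- ifelse(seq_along(gen) %% 2 == 1, "male", "female")
    for (g in seq_len(s$bg_generations)) {
      grp <- if (g == s$bg_generations) "background" else paste0("bg_gen", g)
      n_off <- if (g == s$bg_generations) s$n_background else s$bg_size
      gen <- .random_generation(b, gen, sexes, n_off, 1950 + 5 * g, grp)
      sexes <- ifelse(seq_along(gen) %% 2 == 1, "male", "female")
    }
  } else if (is.list(des)) {
    mk <- function(type, n) {
      for (k in seq_len(n)) {
        f <- .add_founders(b, 2, 2000, "founder")
        if (type == "full_sib") {
          s1 <- b$add(f[1], f[2], "male", 2005, "planted_parent")
          s2 <- b$add(f[1], f[2], "female", 2005, "planted_parent")
          b$add(s1, s2, "male", 2010, "full_sib")
        } else if (type == "half_sib") {
          f3 <- .add_founders(b, 1, 2000, "founder")
          ## shared sire, two dams
          s1 <- b$add(f[1], f[2], "male", 2005, "planted_parent")
          s2 <- b$add(f[1], f3[1], "female", 2005, "planted_parent")
          b$add(s1, s2, "male", 2010, "half_sib")
        } else if (type == "parent_offspring") {
          s1 <- b$add(f[1], f[2], "female", 2005, "planted_parent")
          b$add(f[1], s1, "male", 2010, "parent_offspring")
        } else stop("unknown planted mating type: ", type)
      }
    }
    for (nm in names(des)) mk(nm, des[[nm]])
  } else stop("unknown mating design")

  tab <- b$table()
  if (is.null(tab)) stop("mating design produced no individuals")
  ped <- data.frame(id = tab$id, sire = tab$sire, dam = tab$dam,
                    sex = tab$sex,
                    birth_date = as.Date(paste0(tab$birth_year, "-06-15")),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "group") <- stats::setNames(tab$group, tab$id)
  attr(ped, "birth_year") <- stats::setNames(tab$birth_year, tab$id)
  ped
}

## one meiosis on one chromosome: Haldane crossovers (Poisson, no
## interference). Returns the gamete's founder-label segments plus the
## crossover record (which parent haplotype each interval came from).
.meiosis <- function(h1, h2, len_bp, morgan_len) {
  k <- stats::rpois(1, morgan_len)
  cuts <- if (k > 0) sort(stats::runif(k, 0, len_bp)) else numeric(0)
  xends <- c(cuts, len_bp)
  first <- sample.int(2L, 1L)
  xhap <- as.integer((seq_along(xends) + first) %% 2L + 1L)
  ends <- numeric(0); src <- integer(0)
  a <- 0
  haps <- list(h1, h2)
  for (i in seq_along(xends)) {
    bnd <- xends[i]
    h <- haps[[xhap[i]]]
    i1 <- findInterval(a, h$ends, left.open = FALSE) + 1L
    ## first segment with end > a
    while (i1 <= length(h$ends) && h$ends[i1] <= a) i1 <- i1 + 1L
    repeat {
      e <- min(h$ends[i1], bnd)
      ends <- c(ends, e); src <- c(src, h$src[i1])
      if (e >= bnd) break
      i1 <- i1 + 1L
    }
    a <- bnd
  }
  ## merge adjacent equal labels
  keep <- c(src[-1] != src[-length(src)], TRUE)
  list(ends = ends[keep], src = src[keep], xends = xends, xhap = xhap)
}

.seg_at <- function(x, ends) {
  i <- findInterval(x, ends) + 1L
  pmin(i, length(ends))
}

#' Gene-drop genotypes through a simulated pedigree
#'
#' Founder haplotypes carry unique labels and alleles drawn from the
#' founder frequencies; each meiosis places crossovers as a Poisson
#' process on the genetic map (no interference). Genotypes are allele
#' sums; genotyping error (symmetric single-allele flip) and missingness
#' are applied after the truth is recorded. The truth set contains, per
#' individual, the exact autozygous fraction and the list of autozygous
#' tracts with generations-to-coalescence.
#'
#' @param ped Pedigree from [simulate_pedigree()] (or any topologically
#'   ordered `pedigree`).
#' @param cfg The [sim_config()] used (genome layout, rates; the seed is
#'   NOT reapplied here so that a pipeline run draws pedigree and
#'   genotypes from one stream).
#' @return list with `geno` (all pedigree individuals x markers, 0/1/2/NA),
#'   `map`, `truth` (list `per_ind`, `tracts`), and `founder_freqs`.
#' @export
gene_drop <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  C <- cfg$n_chromosomes
  len <- cfg$chrom_length_bp
  mlen <- len * cfg$morgan_per_bp
  spacing <- len / cfg$n_snps_per_chrom
  pos <- round(spacing * (seq_len(cfg$n_snps_per_chrom) - 1) + spacing / 2)

  founders <- which(is.na(si) & is.na(di))
  fhap <- matrix(NA_integer_, n, 2)
  fhap[founders, ] <- matrix(seq_len(2 * length(founders)), ncol = 2, byrow = TRUE)

  map <- do.call(rbind, lapply(seq_len(C), function(cc) {
    data.frame(chrom = as.character(cc),
               id = sprintf("snp%d_%d", cc, seq_along(pos)),
               position_bp = pos,
               genetic_pos_morgan = pos * cfg$morgan_per_bp,
               stringsAsFactors = FALSE)
  }))

  geno <- matrix(NA_integer_, n, C * length(pos),
                 dimnames = list(ped$id, map$id))
  founder_freqs <- numeric(C * length(pos))
  tracts <- list()
  auto_bp <- numeric(n)
  haps_store <- vector("list", C) # kept per chromosome for coalescence

  for (cc in seq_len(C)) {
    p <- stats::runif(length(pos), cfg$maf_min, 0.5)
    founder_freqs[(cc - 1) * length(pos) + seq_along(pos)] <- p
    fall <- matrix(stats::rbinom(2 * length(founders) * length(pos), 1L,
                                 rep(p, each = 2 * length(founders))),
                   nrow = 2 * length(founders))
    haps <- vector("list", n)
    for (i in seq_len(n)) {
      if (is.na(si[i])) { # founder
        haps[[i]] <- list(
          list(ends = len, src = fhap[i, 1], xends = NULL, xhap = NULL),
          list(ends = len, src = fhap[i, 2], xends = NULL, xhap = NULL))
      } else {
        hs <- haps[[si[i]]]; hd <- haps[[di[i]]]
        haps[[i]] <- list(.meiosis(hs[[1]], hs[[2]], len, mlen),
                          .meiosis(hd[[1]], hd[[2]], len, mlen))
      }
    }
    haps_store[[cc]] <- haps
    jcols <- (cc - 1) * length(pos) + seq_along(pos)
    for (i in seq_len(n)) {
      s1 <- haps[[i]][[1]]$src[.seg_at(pos, haps[[i]][[1]]$ends)]
      s2 <- haps[[i]][[2]]$src[.seg_at(pos, haps[[i]][[2]]$ends)]
      a1 <- fall[cbind(s1, seq_along(pos))]
      a2 <- fall[cbind(s2, seq_along(pos))]
      geno[i, jcols] <- a1 + a2
      ## autozygous tracts: intervals where the founder labels agree
      bnd <- sort(unique(c(haps[[i]][[1]]$ends, haps[[i]][[2]]$ends)))
      mids <- (c(0, bnd[-length(bnd)]) + bnd) / 2
      eq <- haps[[i]][[1]]$src[.seg_at(mids, haps[[i]][[1]]$ends)] ==
            haps[[i]][[2]]$src[.seg_at(mids, haps[[i]][[2]]$ends)]
      if (any(eq)) {
        r <- rle(eq)
        e2 <- cumsum(r$lengths)
        s2i <- e2 - r$lengths + 1
        for (seg in which(r$values)) {
          a <- if (s2i[seg] == 1) 0 else bnd[s2i[seg] - 1]
          bpo <- bnd[e2[seg]]
          tracts[[length(tracts) + 1L]] <- data.frame(
            id = ped$id[i], chrom = as.character(cc), start_bp = a,
            end_bp = bpo, length_bp = bpo - a, g = NA_real_,
            stringsAsFactors = FALSE)
          auto_bp[i] <- auto_bp[i] + (bpo - a)
        }
      }
    }
  }

  tr <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(id = character(0), chrom = character(0), start_bp = numeric(0),
               end_bp = numeric(0), length_bp = numeric(0), g = numeric(0))

  ## generations-to-coalescence at each tract midpoint
  if (nrow(tr)) {
    path_up <- function(i, hap, cc, x) {
      nodes <- integer(0)
      repeat {
        nodes <- c(nodes, 2L * i + hap)
        h <- haps_store[[cc]][[i]][[hap]]
        parent <- if (hap == 1L) si[i] else di[i]
        if (is.na(parent)) break
        hap <- h$xhap[.seg_at(x, h$xends)]
        i <- parent
      }
      nodes
    }
    for (k in seq_len(nrow(tr))) {
      i <- idx[tr$id[k]]
      cc <- as.integer(tr$chrom[k])
      x <- (tr$start_bp[k] + tr$end_bp[k]) / 2
      p1 <- path_up(i, 1L, cc, x)
      p2 <- path_up(i, 2L, cc, x)
      g1 <- which(p1 %in% p2)[1]
      g2 <- match(p1[g1], p2)
      tr$g[k] <- ((g1 - 1) + (g2 - 1)) / 2
    }
  }

  genome_bp <- C * len
  true_f_ped <- diag(build_a_matrix(ped)) - 1
  per_ind <- data.frame(id = ped$id, true_f = auto_bp / genome_bp,
                        f_ped_full = unname(true_f_ped),
                        stringsAsFactors = FALSE)

  ## genotyping error: flip one allele of a fraction error_rate of calls
  if (cfg$error_rate > 0) {
    hit <- which(stats::runif(length(geno)) < cfg$error_rate)
    if (length(hit)) {
      g <- geno[hit]
      up <- stats::runif(length(hit)) < 0.5
      g <- ifelse(g == 0L, 1L, ifelse(g == 2L, 1L, ifelse(up, 2L, 0L)))
      geno[hit] <- g
    }
  }
  if (cfg$missing_rate > 0) {
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  }

  list(geno = geno, map = map,
       truth = list(per_ind = per_ind, tracts = tr,
                    genome_bp = genome_bp),
       founder_freqs = founder_freqs)
}

#' Tract length by generations-to-coalescence
#'
#' Summarises the true autozygous tracts by coalescence age; mean tract
#' length is expected to decline with age, approximately 100/(2g) cM for
#' tracts coalescing g generations back.
#'
#' @param truth Truth set from [gene_drop()].
#' @param morgan_per_bp Map constant used in the simulation.
#' @return data.frame `g`, `n_tracts`, `mean_length_bp`, `mean_length_cm`,
#'   `expected_cm`.
#' @export
truth_age_profile <- function(truth, morgan_per_bp = 1e-8) {
  tr <- truth$tracts
  if (!nrow(tr)) {
    return(data.frame(g = numeric(0), n_tracts = integer(0),
                      mean_length_bp = numeric(0), mean_length_cm = numeric(0),
                      expected_cm = numeric(0)))
  }
  gs <- sort(unique(tr$g))
  out <- do.call(rbind, lapply(gs, function(g) {
    sel <- tr$g == g
    data.frame(g = g, n_tracts = sum(sel),
               mean_length_bp = mean(tr$length_bp[sel]))
  }))
  out$mean_length_cm <- out$mean_length_bp * morgan_per_bp * 100
  out$expected_cm <- 100 / (2 * out$g)
  out
}

#' Write a simulated study to disk
#'
#' One call producing a complete desk-scale study: PED/MAP genotypes,
#' the pedigree as CSV, and the truth set (per-individual autozygous
#' fractions and IBD tracts) as TSV.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param drop Result of [gene_drop()] on that pedigree.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study <- function(ped, drop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_genotypes(drop$geno, drop$map, file.path(dir, "study"),
                           ped = ped)
  pedcsv <- file.path(dir, "pedigree.csv")
  df <- as.data.frame(ped)
  df$group <- unname(attr(ped, "group")[df$id])
  utils::write.csv(df, pedcsv, row.names = FALSE)
  truthtsv <- file.path(dir, "truth.tsv")
  utils::write.table(drop$truth$per_ind, truthtsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tractstsv <- file.path(dir, "tracts.tsv")
  utils::write.table(drop$truth$tracts, tractstsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(paths, pedcsv, truthtsv, tractstsv))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent draws Binomial(2, p_j) per individual and locus: the null
#' model with no inbreeding, used to calibrate frequency-based
#' estimators.
#'
#' @param n Number of individuals.
#' @param freqs Reference-allele frequencies per locus.
#' @return Individuals x loci integer matrix of 0/1/2.
#' @export
sim_hwe_genotypes <- function(n, freqs) {
  m <- length(freqs)
  matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n,
         dimnames = list(paste0("ind", seq_len(n)), NULL))
}
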