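# Multi-class homozygosity-by-descent (HBD) hidden Markov model:
# exponential rate classes, genotyping-error emissions, forward-backward
# posteriors, EM for mixing weights, Viterbi segments and class-wise F_HBD.

#' Specify an HBD mixture model
#'
#' `K` hidden classes with exponentially increasing rate parameters
#' R_k = 2^k; classes 1..K-1 are HBD (expected segment length about 1/R_k
#' Morgan, proxying roughly R_k/2 generations to the common ancestor) and
#' class K is non-HBD. Genotyping error enters the HBD emissions; genetic
#' distances come from physical positions via a constant Morgan/bp factor
#' (1 cM/Mb by default) unless the marker map carries genetic positions
#' and `use_genetic_map` is set.
#'
#' @param K Number of classes (default 10, rates 2..1024).
#' @param rates Strictly increasing rate parameters, length `K`.
#' @param mix Initial mixing weights (simplex); default uniform.
#' @param err Genotyping error rate in `[0, 0.01]` (default 0.001).
#' @param morgan_per_bp Physical-to-genetic conversion (default 1e-8).
#' @param use_genetic_map Use `map$genetic_pos_morgan` when valid.
#' @return Object of class `hbd_model`.
#' @export
hbd_model <- function(K = 10, rates = 2^seq_len(K), mix = rep(1 / K, K),
                      err = 0.001, morgan_per_bp = 1e-8,
                      use_genetic_map = FALSE) {
  stopifnot(K >= 2, length(rates) == K, all(diff(rates) > 0),
            length(mix) == K, all(mix >= 0), abs(sum(mix) - 1) < 1e-8,
            err >= 0, err <= 0.01, morgan_per_bp > 0)
  structure(list(K = K, rates = rates, mix = mix / sum(mix), err = err,
                 morgan_per_bp = morgan_per_bp,
                 use_genetic_map = use_genetic_map),
            class = "hbd_model")
}

#' Emission probabilities of the HBD model
#'
#' HBD classes emit a copied allele observed twice with error: P(hom-ref) =
#' p(1-e) + p^2 e, P(hom-alt) = q(1-e) + q^2 e, P(het) = 2pq e. The
#' non-HBD class emits Hardy-Weinberg genotype probabilities. Missing
#' genotypes emit 1 in every state. Each state's three genotype
#' probabilities sum to one.
#'
#' @param geno Genotype vector (0/1/2/NA).
#' @param freqs Reference-allele frequency per locus, strictly inside
#'   (0, 1).
#' @param model An `hbd_model`.
#' @return Matrix loci x classes of emission probabilities.
#' @export
emission_probs <- function(geno, freqs, model) {
  stopifnot(inherits(model, "hbd_model"), length(geno) == length(freqs))
  if (any(freqs <= 0 | freqs >= 1 | is.na(freqs))) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  p <- freqs; q <- 1 - p; e <- model$err
  L <- length(geno); K <- model$K
  hbd <- cbind(q * (1 - e) + q^2 * e,   # genotype 0 (hom alt)
               2 * p * q * e,           # genotype 1 (het)
               p * (1 - e) + p^2 * e)   # genotype 2 (hom ref)
  nohbd <- cbind(q^2, 2 * p * q, p^2)
  E <- matrix(1, L, K)
  obs <- !is.na(geno)
  gi <- geno[obs] + 1L
  pick <- cbind(which(obs), gi)
  for (k in seq_len(K - 1)) E[obs, k] <- hbd[pick]
  E[obs, K] <- nohbd[pick]
  E
}

.hbd_distances <- function(map, model) {
  if (model$use_genetic_map && !is.null(map$genetic_pos_morgan) &&
      !anyNA(map$genetic_pos_morgan)) {
    d <- diff(map$genetic_pos_morgan)
  } else {
    d <- diff(map$position_bp) * model$morgan_per_bp
  }
  pmax(d, 0)
}

## split column indices of the map by chromosome, positions sorted
.chrom_blocks <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chrom), function(jj) {
    jj[order(map$position_bp[jj])]
  })
}

## precompute per-chromosome emissions and stay probabilities: they depend
## only on genotypes, frequencies, error rate and rates — not on the
## mixing weights — so EM iterations can reuse them
.hbd_prep <- function(geno, map, freqs, model) {
  lapply(.chrom_blocks(map), function(jj) {
    E <- emission_probs(geno[jj], freqs[jj], model)
    d <- .hbd_distances(map[jj, , drop = FALSE], model)
    stay <- if (length(jj) > 1) exp(-outer(d, model$rates)) else
      matrix(0, 0, model$K)
    list(jj = jj, E = E, stay = stay)
  })
}

.fb_run <- function(prep, mix, n_loci, K) {
  gamma <- matrix(NA_real_, n_loci, K)
  loglik <- 0
  reset <- numeric(K)
  for (b in prep) {
    r <- .fb_cpp(b$E, b$stay, mix)
    if (!is.finite(r$loglik)) stop("non-finite HBD likelihood")
    gamma[b$jj, ] <- r$gamma
    loglik <- loglik + r$loglik
    reset <- reset + r$reset_expect
  }
  list(loglik = loglik, gamma = gamma, reset_expect = reset)
}

#' Forward-backward pass of the HBD model
#'
#' Computes the scaled forward-backward recursions per chromosome
#' (chromosomes are independent) and returns the total log-likelihood and
#' per-locus class posteriors for one individual.
#'
#' @param geno Genotype vector (0/1/2/NA) aligned to `map` rows.
#' @param map Marker map (`chrom`, `position_bp`), sorted within
#'   chromosome.
#' @param freqs Reference-allele frequencies per locus.
#' @param model An `hbd_model`.
#' @return list with `loglik`, `gamma` (loci x classes, in `map` row
#'   order) and `reset_expect` (expected class draws, the EM sufficient
#'   statistic).
#' @export
forward_backward <- function(geno, map, freqs, model) {
  stopifnot(length(geno) == nrow(map))
  .fb_run(.hbd_prep(geno, map, freqs, model), model$mix, nrow(map), model$K)
}

#' Fit HBD mixing weights by expectation-maximisation
#'
#' Rates stay fixed; only the mixing weights are estimated. The
#' log-likelihood is non-decreasing across iterations; fitting stops when
#' its change falls below `tol` or after `max_iter` iterations. A weight
#' collapsing to zero is floored at 1e-12 and the weights renormalised,
#' with a warning.
#'
#' @param geno Genotype vector for one individual, or an individuals x
#'   markers matrix for a pooled fit across individuals.
#' @param map Marker map aligned to the genotype columns.
#' @param freqs Allele frequencies per locus.
#' @param model Starting `hbd_model` (fixed rates).
#' @param max_iter,tol Stopping rule (defaults 1000, 1e-6).
#' @return The fitted `hbd_model`, with attributes `loglik` (final) and
#'   `loglik_trace`.
#' @export
em_fit <- function(geno, map, freqs, model, max_iter = 1000, tol = 1e-6) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  stopifnot(ncol(geno) == nrow(map))
  preps <- lapply(seq_len(nrow(geno)), function(i) {
    .hbd_prep(geno[i, ], map, freqs, model)
  })
  .em_run(preps, ncol(geno), model, max_iter, tol)
}

## EM over the concatenated independent blocks (chromosomes, possibly of
## several individuals); the heavy loop lives in C++
.em_run <- function(preps, n_loci, model, max_iter, tol) {
  Es <- list(); stays <- list(); lens <- integer(0)
  for (pp in preps) {
    for (b in pp) {
      Es[[length(Es) + 1L]] <- b$E
      stays[[length(stays) + 1L]] <- rbind(b$stay, rep(0, model$K))
      lens <- c(lens, nrow(b$E))
    }
  }
  r <- .em_cpp(do.call(rbind, Es), do.call(rbind, stays), lens,
               model$mix, as.integer(max_iter), tol)
  if (r$floored) warning("mixing weight(s) collapsed to zero; floored at 1e-12")
  model$mix <- as.numeric(r$mix)
  attr(model, "loglik") <- r$loglik_trace[length(r$loglik_trace)]
  attr(model, "loglik_trace") <- as.numeric(r$loglik_trace)
  model
}

#' Most probable state path (Viterbi decoding)
#'
#' @inheritParams forward_backward
#' @return Integer vector of class indices (1..K, K = non-HBD), in `map`
#'   row order.
#' @export
viterbi_path <- function(geno, map, freqs, model) {
  stopifnot(length(geno) == nrow(map))
  .viterbi_run(.hbd_prep(geno, map, freqs, model), model$mix, nrow(map))
}

.viterbi_run <- function(prep, mix, n_loci) {
  path <- integer(n_loci)
  for (b in prep) path[b$jj] <- .viterbi_cpp(b$E, b$stay, mix)
  path
}

#' HBD segments from the Viterbi path
#'
#' Decodes the most probable state path per chromosome; maximal runs of
#' the same HBD class become segments bounded by the flanking marker
#' positions.
#'
#' @inheritParams forward_backward
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`, `class` (index), `rate`.
#' @export
viterbi_segments <- function(geno, map, freqs, model) {
  stopifnot(length(geno) == nrow(map))
  .segments_from_path(viterbi_path(geno, map, freqs, model), map, model)
}

.segments_from_path <- function(full_path, map, model) {
  out <- list()
  for (jj in .chrom_blocks(map)) {
    path <- full_path[jj]
    pos <- map$position_bp[jj]
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values < model$K)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = map$chrom[jj[1]],
        start_bp = pos[starts[seg]], end_bp = pos[ends[seg]],
        n_snps = r$lengths[seg],
        length_bp = pos[ends[seg]] - pos[starts[seg]] + 1,
        class = r$values[seg], rate = model$rates[r$values[seg]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      length_bp = numeric(0), class = integer(0),
                      rate = numeric(0)))
  }
  do.call(rbind, out)
}

#' Age-group presets for HBD rate classes
#'
#' Two published groupings of rate classes into inbreeding-age labels are
#' available: `"methods"` (very recent R2-R8, recent R16-R64, intermediate
#' R128-R256, ancient R512 and above) and `"results"` (very recent R2-R4,
#' intermediate R8-R32, ancient R64 and above).
#'
#' @param rates HBD-class rates (the non-HBD class excluded).
#' @param preset `"methods"` or `"results"`, or a function mapping a rate
#'   to a group label.
#' @return Character vector of group labels, one per rate.
#' @export
hbd_age_groups <- function(rates, preset = "methods") {
  if (is.function(preset)) return(vapply(rates, preset, character(1)))
  switch(match.arg(preset, c("methods", "results")),
    methods = ifelse(rates <= 8, "very recent",
              ifelse(rates <= 64, "recent",
              ifelse(rates <= 256, "intermediate", "ancient"))),
    results = ifelse(rates <= 4, "very recent",
              ifelse(rates <= 32, "intermediate", "ancient")))
}

#' Class-wise and age-grouped F_HBD from posteriors
#'
#' F_HBD for class k is the average posterior probability of class k over
#' all autosomal markers; the total is the sum over HBD classes, and age
#' groups partition the same sum.
#'
#' @param gamma Posterior matrix (loci x classes) from
#'   [forward_backward()].
#' @param model The `hbd_model` used.
#' @param preset Age-group preset, see [hbd_age_groups()].
#' @return list with `total`, `by_class` (named by rate) and `by_age`.
#' @export
f_hbd <- function(gamma, model, preset = "methods") {
  stopifnot(ncol(gamma) == model$K)
  cls <- colMeans(gamma)[-model$K]
  names(cls) <- paste0("R", model$rates[-model$K])
  groups <- hbd_age_groups(model$rates[-model$K], preset)
  by_age <- tapply(cls, groups, sum)
  list(total = sum(cls), by_class = cls,
       by_age = by_age[unique(groups)])
}

#' Run the HBD model over a cohort
#'
#' For each individual: optionally fit the mixing weights by EM (the
#' standard per-individual usage), then compute posteriors, class-wise
#' F_HBD and Viterbi segments.
#'
#' @param geno Individuals x markers matrix (0/1/2/NA).
#' @param map Marker map aligned to columns.
#' @param model Starting `hbd_model`.
#' @param freqs Allele frequencies; default in-sample.
#' @param fit Fit mixing weights per individual (default TRUE).
#' @param preset Age-group preset.
#' @param max_iter,tol EM stopping rule passed to [em_fit()].
#' @return list with `table` (data.frame: `id`, `f_hbd`, per-class and
#'   per-age-group columns, `loglik`) and `segments` (Viterbi segment
#'   table with `id` column).
#' @export
run_hbd <- function(geno, map, model = hbd_model(),
                    freqs = allele_freqs(geno), fit = TRUE,
                    preset = "methods", max_iter = 1000, tol = 1e-6) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(geno)))
  rows <- list()
  segs <- list()
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    prep <- .hbd_prep(g, map, freqs, model)
    ## per-individual fits routinely empty several classes; the floor
    ## warning is suppressed here as it is the norm, not a fault
    mod <- if (fit) suppressWarnings(
      .em_run(list(prep), length(g), model, max_iter, tol)) else model
    fb <- .fb_run(prep, mod$mix, length(g), mod$K)
    fh <- f_hbd(fb$gamma, mod, preset)
    row <- data.frame(id = ids[i], f_hbd = fh$total, stringsAsFactors = FALSE)
    for (nm in names(fh$by_class)) row[[paste0("f_hbd_", nm)]] <- fh$by_class[[nm]]
    for (nm in names(fh$by_age)) {
      row[[paste0("f_hbd_", gsub(" ", "_", nm))]] <- fh$by_age[[nm]]
    }
    row$loglik <- fb$loglik
    rows[[i]] <- row
    ss <- .segments_from_path(.viterbi_run(prep, mod$mix, length(g)),
                              map, mod)
    if (nrow(ss)) segs[[length(segs) + 1L]] <- cbind(id = ids[i], ss,
                                                     stringsAsFactors = FALSE)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(id = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_bp = numeric(0),
               class = integer(0), rate = numeric(0))
  rownames(segments) <- NULL
  list(table = do.call(rbind, rows), segments = segments)
}
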