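# Independent oracles used against the package implementations: brute-force
# enumeration for the HMM, exhaustive window/segment scans for ROH, a
# recurrence-based HWE enumeration, and a Monte-Carlo gene-dropping kinship
# estimator for the A-matrix. These deliberately share no code with R/.

## ---- pedigree helpers -------------------------------------------------

make_ped <- function(id, sire = NA, dam = NA, sex = NULL, birth = NULL) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   sire = as.character(rep_len(sire, n)),
                   dam = as.character(rep_len(dam, n)),
                   sex = if (is.null(sex)) rep("unknown", n) else rep_len(sex, n),
                   birth_date = if (is.null(birth)) as.Date(rep(NA, n)) else
                     as.Date(rep_len(birth, n)),
                   stringsAsFactors = FALSE)
  class(df) <- c("pedigree", "data.frame")
  df
}

## random topologically ordered pedigree of n individuals
random_ped <- function(n, p_parent = 0.7) {
  sex <- rep(c("male", "female"), length.out = n)
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[1:(i - 1)] == "male")
    females <- which(sex[1:(i - 1)] == "female")
    if (length(males) && length(females) && runif(1) < p_parent) {
      sire[i] <- as.character(males[sample.int(length(males), 1)])
      dam[i] <- as.character(females[sample.int(length(females), 1)])
    }
  }
  make_ped(as.character(1:n), sire, dam, sex)
}

## Monte-Carlo gene-dropping estimate of the additive relationship matrix:
## drop one unlinked locus nrep times, A_ij = 2 * kinship.
mc_amatrix <- function(ped, nrep = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  h1 <- matrix(0L, nrep, n)
  h2 <- matrix(0L, nrep, n)
  nal <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      h1[, i] <- nal + 1L
      h2[, i] <- nal + 2L
      nal <- nal + 2L
    } else {
      pick <- runif(nrep) < 0.5
      h1[, i] <- ifelse(pick, h1[, si[i]], h2[, si[i]])
      pick <- runif(nrep) < 0.5
      h2[, i] <- ifelse(pick, h1[, di[i]], h2[, di[i]])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        x <- 1 + (h1[, i] == h2[, i])
      } else {
        x <- ((h1[, i] == h1[, j]) + (h1[, i] == h2[, j]) +
              (h2[, i] == h1[, j]) + (h2[, i] == h2[, j])) / 2
      }
      est[i, j] <- est[j, i] <- mean(x)
      se[i, j] <- se[j, i] <- sd(x) / sqrt(nrep)
    }
  }
  list(est = est, se = se)
}

## ---- HWE oracle -------------------------------------------------------

## enumeration over heterozygote counts using the ratio recurrence
## (independent arithmetic from the lgamma route in the package)
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  h <- seq(rare %% 2, rare, by = 2)
  u <- numeric(length(h))
  u[1] <- 1
  if (length(h) > 1) {
    for (k in 2:length(h)) {
      hp <- h[k - 1]
      naa_p <- (nA - hp) / 2
      nbb_p <- (na - hp) / 2
      u[k] <- u[k - 1] * 4 * naa_p * nbb_p / ((hp + 1) * (hp + 2))
    }
  }
  pr <- u / sum(u)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

## ---- ROH oracles ------------------------------------------------------

oracle_window_flags <- function(geno, params) {
  L <- length(geno)
  w <- params$window_snps
  flags <- logical(L)
  if (L < w) return(flags)
  n_win <- L - w + 1
  ok <- logical(n_win)
  for (s in seq_len(n_win)) {
    win <- geno[s:(s + w - 1)]
    ok[s] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  for (j in seq_len(L)) {
    covering <- intersect(seq_len(n_win), (j - w + 1):j)
    flags[j] <- mean(ok[covering]) >= params$hit_threshold
  }
  flags
}

oracle_segments <- function(flags, pos, params) {
  out <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                    n_snps = integer(0), length_bp = numeric(0))
  run <- integer(0)
  flush <- function(run, out) {
    if (!length(run)) return(out)
    len <- pos[run[length(run)]] - pos[run[1]] + 1
    if (len >= params$min_length_bp && length(run) >= params$min_snps &&
        len / length(run) <= params$max_density_bp_per_snp) {
      out <- rbind(out, data.frame(start_bp = pos[run[1]],
                                   end_bp = pos[run[length(run)]],
                                   n_snps = length(run), length_bp = len))
    }
    out
  }
  for (j in seq_along(flags)) {
    if (flags[j]) {
      if (length(run) && pos[j] - pos[run[length(run)]] > params$max_gap_bp) {
        out <- flush(run, out)
        run <- integer(0)
      }
      run <- c(run, j)
    } else {
      out <- flush(run, out)
      run <- integer(0)
    }
  }
  flush(run, out)
}

## ---- HBD HMM oracles --------------------------------------------------

## emission probabilities restated from the model definition
oracle_emission <- function(g, p, k, K, err) {
  q <- 1 - p
  if (is.na(g)) return(1)
  if (k < K) {
    c(q * (1 - err) + q^2 * err, 2 * p * q * err, p * (1 - err) + p^2 * err)[g + 1]
  } else {
    c(q^2, 2 * p * q, p^2)[g + 1]
  }
}

## exhaustive K^L path enumeration: loglik, posteriors, best path
oracle_hmm <- function(geno, pos, freqs, rates, mix, err, morgan_per_bp = 1e-8) {
  K <- length(rates)
  L <- length(geno)
  d <- diff(pos) * morgan_per_bp
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  probs <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    pr <- mix[st[1]] * oracle_emission(geno[1], freqs[1], st[1], K, err)
    for (t in 2:L) {
      stay <- exp(-rates[st[t - 1]] * d[t - 1])
      tr <- (1 - stay) * mix[st[t]] + if (st[t] == st[t - 1]) stay else 0
      pr <- pr * tr * oracle_emission(geno[t], freqs[t], st[t], K, err)
    }
    probs[r] <- pr
  }
  tot <- sum(probs)
  gamma <- matrix(0, L, K)
  for (t in seq_len(L)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(probs[paths[, t] == k]) / tot
  }
  best <- which.max(probs)
  list(loglik = log(tot), gamma = gamma, path = unname(paths[best, ]),
       best_logprob = log(probs[best]))
}

## simulate genotypes from the HBD generative process along one chromosome
## (used for parameter-recovery and classification checks)
sim_hbd_chain <- function(pos, freqs, rates, mix, err, morgan_per_bp = 1e-8) {
  L <- length(pos)
  state <- integer(L)
  K <- length(rates)
  d <- c(0, diff(pos)) * morgan_per_bp
  state[1] <- sample.int(K, 1, prob = mix)
  for (t in 2:L) {
    if (runif(1) < exp(-rates[state[t - 1]] * d[t])) {
      state[t] <- state[t - 1]
    } else {
      state[t] <- sample.int(K, 1, prob = mix)
    }
  }
  g <- integer(L)
  for (t in seq_len(L)) {
    p <- freqs[t]; q <- 1 - p
    pr <- if (state[t] < K) {
      c(q * (1 - err) + q^2 * err, 2 * p * q * err, p * (1 - err) + p^2 * err)
    } else {
      c(q^2, 2 * p * q, p^2)
    }
    g[t] <- sample(0:2, 1, prob = pr)
  }
  list(geno = g, state = state)
}

## Jaccard index between two segment sets on one genome
jaccard_segments <- function(a, b) {
  ## a, b: data.frames with chrom, start, end columns (bp)
  inter <- 0; len_a <- 0; len_b <- 0
  chroms <- union(a$chrom, b$chrom)
  for (cc in chroms) {
    sa <- a[a$chrom == cc, ]; sb <- b[b$chrom == cc, ]
    len_a <- len_a + sum(sa$end - sa$start)
    len_b <- len_b + sum(sb$end - sb$start)
    for (i in seq_len(nrow(sa))) {
      for (j in seq_len(nrow(sb))) {
        inter <- inter + max(0, min(sa$end[i], sb$end[j]) -
                                max(sa$start[i], sb$start[j]))
      }
    }
  }
  uni <- len_a + len_b - inter
  if (uni == 0) return(1)
  inter / uni
}
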