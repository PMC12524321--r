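# The homozygosity-by-descent hidden Markov model.

toy_map <- function(pos, chrom = "1") {
  data.frame(chrom = chrom, position_bp = pos,
             genetic_pos_morgan = pos * 1e-8, stringsAsFactors = FALSE)
}

test_that("emission probabilities close to one per state and match the model", {
  m <- hbd_model(K = 3, rates = c(2, 8, 512), err = 0.001)
  E <- emission_probs(c(0L, 1L, 2L, NA), rep(0.3, 4), m)
  # missing emits 1 everywhere
  expect_equal(E[4, ], rep(1, 3))
  # non-HBD class: HWE probabilities
  expect_equal(E[2, 3], 2 * 0.3 * 0.7)
  # HBD het needs an error
  m0 <- hbd_model(K = 3, rates = c(2, 8, 512), err = 0)
  E0 <- emission_probs(1L, 0.5, m0)
  expect_equal(E0[1, 1], 0)
  expect_equal(E0[1, 3], 0.5)
  # genotype probabilities sum to 1 in every state
  for (p in c(0.1, 0.5, 0.9)) {
    Ez <- emission_probs(0:2, rep(p, 3), m)
    expect_equal(colSums(Ez), rep(1, 3))
  }
  expect_error(emission_probs(0L, 1, m), "strictly in")
})

test_that("a single marker gives the emission-weighted prior", {
  m <- hbd_model(K = 3, rates = c(4, 64, 1024), mix = c(0.2, 0.3, 0.5))
  fb <- forward_backward(2L, toy_map(1e6), 0.4, m)
  e <- emission_probs(2L, 0.4, m)[1, ]
  expect_equal(fb$loglik, log(sum(m$mix * e)))
  expect_equal(fb$gamma[1, ], m$mix * e / sum(m$mix * e))
})

test_that("forward-backward and Viterbi match exhaustive path enumeration", {
  set.seed(131)
  for (r in 1:12) {
    K <- 3
    L <- sample(5:6, 1)
    rates <- sort(2^sample(1:10, K))
    mix <- runif(K); mix <- mix / sum(mix)
    err <- runif(1, 0, 0.01)
    pos <- sort(sample(1:5e7, L))
    freqs <- runif(L, 0.1, 0.9)
    geno <- sample(c(0:2, NA), L, replace = TRUE)
    m <- hbd_model(K = K, rates = rates, mix = mix, err = err)
    fb <- forward_backward(geno, toy_map(pos), freqs, m)
    oo <- oracle_hmm(geno, pos, freqs, rates, mix, err)
    expect_equal(fb$loglik, oo$loglik, tolerance = 1e-10)
    expect_equal(unname(fb$gamma), oo$gamma, tolerance = 1e-10)
    vit <- viterbi_path(geno, toy_map(pos), freqs, m)
    expect_equal(vit, oo$path)
    # total likelihood dominates the best single path
    expect_gte(fb$loglik, oo$best_logprob - 1e-12)
  }
})

test_that("a long heterozygous stretch carries almost no HBD posterior", {
  m <- hbd_model()
  pos <- seq(1e5, by = 1e5, length.out = 100)
  fb <- forward_backward(rep(1L, 100), toy_map(pos), rep(0.5, 100), m)
  expect_true(all(rowSums(fb$gamma[, -m$K, drop = FALSE]) < 0.01))
  # and posteriors stay normalised
  expect_equal(rowSums(fb$gamma), rep(1, 100), tolerance = 1e-10)
})

test_that("EM increases the likelihood and recovers mixing weights", {
  set.seed(137)
  rates <- c(16, 512)
  mix_true <- c(0.35, 0.65)
  pos <- seq(5e4, by = 5e4, length.out = 2000)
  freqs <- runif(2000, 0.2, 0.8)
  G <- t(vapply(1:50, function(i) {
    sim_hbd_chain(pos, freqs, rates, mix_true, err = 0.001)$geno
  }, integer(2000)))
  m0 <- hbd_model(K = 2, rates = rates, mix = c(0.5, 0.5), err = 0.001)
  fit <- em_fit(G, toy_map(pos), freqs, m0, max_iter = 200, tol = 1e-6)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))          # monotone up to rounding
  expect_equal(fit$mix, mix_true, tolerance = 0.05, ignore_attr = TRUE)
  # restarting at the fitted optimum moves the likelihood less than tol
  refit <- em_fit(G, toy_map(pos), freqs, fit, max_iter = 5, tol = 1e-6)
  rt <- attr(refit, "loglik_trace")
  expect_lte(length(rt), 2)
  expect_lt(abs(rt[length(rt)] - trace[length(trace)]), 1e-4)
})

test_that("Viterbi segments cover planted homozygous stretches", {
  set.seed(139)
  m <- hbd_model(K = 3, rates = c(32, 256, 1024), err = 0.001)
  pos <- seq(5e4, by = 5e4, length.out = 150)
  freqs <- rep(0.5, 150)
  # heterozygous flanks around a fully homozygous 50-marker core
  g <- c(rep(1L, 50), rep(0L, 50), rep(1L, 50))
  segs <- viterbi_segments(g, toy_map(pos), freqs, m)
  expect_equal(nrow(segs), 1)
  expect_lte(segs$start_bp, pos[51])
  expect_gte(segs$end_bp, pos[100])
  # all-het individual: no HBD segments
  expect_equal(nrow(viterbi_segments(rep(1L, 150), toy_map(pos), freqs, m)), 0)
})

test_that("doubling distances is equivalent to halving rates", {
  set.seed(149)
  L <- 300
  pos <- sort(sample(1:2e7, L))
  freqs <- runif(L, 0.2, 0.8)
  g <- sample(c(0:2, NA), L, replace = TRUE, prob = c(0.4, 0.2, 0.35, 0.05))
  rates <- 2^(1:5)
  m1 <- hbd_model(K = 5, rates = rates / 2)
  m2 <- hbd_model(K = 5, rates = rates)
  fb1 <- forward_backward(g, toy_map(2 * pos), freqs, m1)
  fb2 <- forward_backward(g, toy_map(pos), freqs, m2)
  ## same transition kernel: exp(-(R/2)(2d)) = exp(-R d)
  expect_equal(fb1$loglik, fb2$loglik, tolerance = 1e-12)
  expect_equal(fb1$gamma, fb2$gamma, tolerance = 1e-12)
})

test_that("class-wise F_HBD partitions into age groups exactly", {
  m <- hbd_model()
  set.seed(151)
  gamma <- matrix(rgamma(50 * 10, 1), 50, 10)
  gamma <- gamma / rowSums(gamma)
  fh <- f_hbd(gamma, m, preset = "methods")
  expect_equal(sum(fh$by_class), fh$total, tolerance = 1e-12)
  expect_equal(sum(fh$by_age), fh$total, tolerance = 1e-12)
  expect_named(fh$by_age, c("very recent", "recent", "intermediate", "ancient"))
  fh2 <- f_hbd(gamma, m, preset = "results")
  expect_equal(sum(fh2$by_age), fh2$total, tolerance = 1e-12)
  expect_named(fh2$by_age, c("very recent", "intermediate", "ancient"))
  # degenerate posteriors
  g0 <- matrix(0, 5, 10); g0[, 10] <- 1
  expect_equal(f_hbd(g0, m)$total, 0)
  g1 <- matrix(0, 5, 10); g1[, 1] <- 1
  fh1 <- f_hbd(g1, m)
  expect_equal(fh1$total, 1)
  expect_equal(unname(fh1$by_age["very recent"]), 1)
})

test_that("deep-coalescence autozygosity avoids the very recent classes", {
  set.seed(157)
  # tracts coalescing ~32 generations back: segment rate about 64
  pos <- seq(5e4, by = 5e4, length.out = 2000)
  freqs <- runif(2000, 0.2, 0.8)
  m <- hbd_model()
  mass_recent <- mass_total <- 0
  for (i in 1:10) {
    sim <- sim_hbd_chain(pos, freqs, rates = c(64, 1024), mix = c(0.3, 0.7),
                         err = 0.001)
    # empty classes routinely collapse here; the floor warning is expected
    fit <- suppressWarnings(
      em_fit(sim$geno, toy_map(pos), freqs, m, max_iter = 100))
    fb <- forward_backward(sim$geno, toy_map(pos), freqs, fit)
    fh <- f_hbd(fb$gamma, fit, preset = "methods")
    mass_recent <- mass_recent + unname(fh$by_age["very recent"])
    mass_total <- mass_total + fh$total
  }
  expect_lt(mass_recent / mass_total, 0.10)
})
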