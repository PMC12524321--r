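# PED/MAP parsing, the HWE exact test, the QC cascade and the IBS screen.

write_fixture <- function(ped_lines, map_lines, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  pedf <- file.path(dir, "toy.ped")
  mapf <- file.path(dir, "toy.map")
  writeLines(ped_lines, pedf)
  writeLines(map_lines, mapf)
  list(ped = pedf, map = mapf)
}

test_that("PED/MAP parsing codes alleles deterministically", {
  f <- write_fixture(
    c("F 1 0 0 1 0  A A  G T  0 0",
      "F 2 0 0 2 0  A C  T G  T T"),
    c("1 snp1 0 1000", "1 snp2 0 2000", "2 snp3 0 500"))
  g <- read_genotypes(f$ped, f$map)
  expect_equal(dim(g$geno), c(2L, 3L))
  # first-seen allele is reference: snp1 ref A, snp2 ref G, snp3 ref T
  expect_equal(unname(g$geno[1, ]), c(2L, 1L, NA))   # "0 0" is missing
  # swapped allele order ("T G" vs "G T") codes identically
  expect_equal(unname(g$geno[2, 2]), 1L)
  # re-read gives identical coding
  g2 <- read_genotypes(f$ped, f$map)
  expect_identical(g$geno, g2$geno)
  # reference-allele override flips the coding
  g3 <- read_genotypes(f$ped, f$map, ref_alleles = c(snp1 = "C"))
  expect_equal(unname(g3$geno[1, 1]), 0L)
})

test_that("malformed PED input is rejected with a useful message", {
  f <- write_fixture(
    c("F 1 0 0 1 0  A A  G T",
      "F 2 0 0 2 0  A C  T G"),
    c("1 snp1 0 1000", "1 snp2 0 2000", "2 snp3 0 500"))
  expect_error(read_genotypes(f$ped, f$map), "line 1")
  f2 <- write_fixture(c("F 1 0 0 1 0  A A", "F 2 0 0 2 0  C G"),
                      c("1 snp1 0 1000"))
  expect_error(read_genotypes(f2$ped, f2$map), "not biallelic")
})

test_that("genotype round-trip through PED/MAP preserves the matrix", {
  set.seed(5)
  geno <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 4, 15,
                 dimnames = list(paste0("i", 1:4), paste0("s", 1:15)))
  map <- data.frame(chrom = rep(c("1", "2"), c(8, 7)),
                    id = paste0("s", 1:15),
                    position_bp = rep(seq(1e5, by = 1e5, length.out = 8), 2)[1:15],
                    genetic_pos_morgan = 0)
  dir <- withr::local_tempdir()
  write_genotypes(geno, map, file.path(dir, "rt"))
  g <- read_genotypes(file.path(dir, "rt.ped"), file.path(dir, "rt.map"),
                      ref_alleles = rep("A", 15))
  expect_equal(unname(g$geno), unname(geno))
  expect_equal(g$map$position_bp, map$position_bp)
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)          # monomorphic
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)       # two-config enumeration
  expect_equal(hwe_exact_test(25, 50, 25), 1)        # modal configuration
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
  # spot-check against the independent recurrence oracle
  set.seed(9)
  for (r in 1:50) {
    n <- sample(3:40, 1)
    cnt <- as.vector(stats::rmultinom(1, n, c(0.3, 0.45, 0.25)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("the QC cascade filters in the documented order and is idempotent", {
  set.seed(31)
  n <- 20
  geno <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  map <- data.frame(chrom = c("1", "1", "1", "X", "1", "1"),
                    id = paste0("s", 1:6),
                    position_bp = c(1:3 * 1e5, 1e5, 4e5, 5e5),
                    genetic_pos_morgan = 0)
  geno[1:3, 2] <- NA                       # snp2 call rate 17/20 = 0.85
  geno[, 3] <- rep(c(0L, 2L), 10)          # snp3 wildly out of HWE
  geno[, 5] <- c(1L, rep(0L, n - 1))       # snp5 MAF = 1/40 = 0.025 (kept)
  geno[, 6] <- c(rep(0L, n))               # snp6 monomorphic (MAF 0)
  geno[7, c(1, 2, 3)] <- NA                # individual 7 missing 3/6 = 50%
  colnames(geno) <- map$id
  rownames(geno) <- paste0("i", 1:n)

  # at n = 20 the most extreme HWE departure has p = 1.34e-6, so raise the
  # HWE threshold slightly to exercise that filter too
  qc <- qc_cascade(geno, map, qc_thresholds(hwe_p_min = 1e-4))
  expect_false("s4" %in% qc$map$id)        # non-autosomal
  expect_false("s2" %in% qc$map$id)        # call rate below 90%
  expect_false("s3" %in% qc$map$id)        # zero hets, far out of HWE
  expect_false("s6" %in% qc$map$id)        # MAF 0
  expect_true("s5" %in% qc$map$id)
  expect_false("i7" %in% rownames(qc$geno))
  expect_equal(qc$log$step,
               c("autosomes", "snp_call_rate", "hwe",
                 "individual_missingness", "maf"))
  # idempotence
  qc2 <- qc_cascade(qc$geno, qc$map, qc_thresholds(hwe_p_min = 1e-4))
  expect_identical(qc2$geno, qc$geno)
  expect_identical(qc2$map, qc$map)
  # everything filtered -> hard error
  expect_error(qc_cascade(geno[, 6, drop = FALSE], map[6, ], qc_thresholds()),
               "no markers left")
})

test_that("individual removal never changes marker coding", {
  set.seed(41)
  geno <- matrix(rbinom(200, 2, 0.5), 10, 20)
  map <- data.frame(chrom = "1", id = paste0("s", 1:20),
                    position_bp = 1:20 * 1e5, genetic_pos_morgan = 0)
  rownames(geno) <- paste0("i", 1:10); colnames(geno) <- map$id
  qc <- qc_cascade(geno, map)
  qc_drop <- qc_cascade(geno[-3, ], map)
  shared <- intersect(qc$map$id, qc_drop$map$id)
  expect_identical(qc$geno[-3, shared], qc_drop$geno[, shared])
})

test_that("the IBS screen recovers duplicates, unrelateds and parent-offspring", {
  set.seed(53)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  # two unrelated founders + an exact copy of founder 1 + an offspring of 1 and 2
  f1a <- rbinom(m, 1, p); f1b <- rbinom(m, 1, p)
  f2a <- rbinom(m, 1, p); f2b <- rbinom(m, 1, p)
  transmit <- function(a, b) ifelse(runif(m) < 0.5, a, b)
  off <- transmit(f1a, f1b) + transmit(f2a, f2b)
  geno <- rbind(ind1 = f1a + f1b, ind2 = f2a + f2b,
                copy1 = f1a + f1b, off = off)
  res <- ibs_screen(geno, dup_pi_hat = 0.95)
  pick <- function(a, b) res[(res$id1 == a & res$id2 == b) |
                             (res$id1 == b & res$id2 == a), ]
  expect_equal(pick("ind1", "copy1")$pi_hat, 1.0)
  expect_true(pick("ind1", "copy1")$flagged)
  expect_lt(pick("ind1", "ind2")$pi_hat, 0.1)
  expect_equal(pick("ind1", "off")$pi_hat, 0.5, tolerance = 0.1)
  expect_false(any(res$pi_hat < 0 | res$pi_hat > 1))
})

test_that("heterozygosity outliers are flagged but not excluded", {
  set.seed(61)
  geno <- matrix(rbinom(50 * 400, 2, 0.5), 50, 400)
  geno[1, ] <- 0L  # fully homozygous outlier
  rownames(geno) <- paste0("i", 1:50)
  out <- het_outliers(geno, z = 3)
  expect_true(out$flagged[out$id == "i1"])
  expect_lt(sum(out$flagged), 5)
})
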