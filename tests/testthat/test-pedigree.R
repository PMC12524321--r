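# Pedigree QC, ancestor tracing, the numerator relationship matrix and F_PED.

test_that("validation severs, flags and logs the studbook inconsistencies", {
  raw <- data.frame(
    id         = c("A", "B", "C", "C", "D", "E", "F", "G"),
    sire       = c(NA, NA, "C", "C", "A", "A", "A", "B"),
    dam        = c(NA, NA, "B", "B", "A", "B", "B", "B"),
    sex        = c("male", "male", "female", "female", "banana", "male", "female", "male"),
    birth_date = c("2000-05-01", "2000-05-01", "2004-01-01", "2004-01-01",
                   "2005-01-01", "2001-01-01", NA, "1492-01-01"),
    stringsAsFactors = FALSE)
  v <- validate_pedigree(raw)
  rep <- v$report
  ped <- v$pedigree

  # duplicate row dropped and logged once
  expect_equal(sum(rep$issue == "duplicate"), 1)
  expect_equal(sum(ped$id == "C"), 1)
  # self-parent severed
  expect_true("self-parent" %in% rep$issue[rep$id == "C"])
  expect_true(is.na(ped$sire[ped$id == "C"]))
  # sire == dam severs both links
  d_row <- ped[ped$id == "D", ]
  expect_true("sire-equals-dam" %in% rep$issue[rep$id == "D"])
  expect_true(is.na(d_row$sire) && is.na(d_row$dam))
  # invalid sex recoded to unknown and logged
  expect_true("invalid-sex" %in% rep$issue[rep$id == "D"])
  expect_equal(ped$sex[ped$id == "D"], "unknown")
  # dam B recorded male: parental-sex mismatch flagged but link kept
  mism <- rep[rep$issue == "parental-sex-mismatch", ]
  expect_true("C" %in% mism$id)
  expect_equal(ped$dam[ped$id == "C"], "B")
  # E born only 1 year after its sire A: implausible age, link severed
  expect_true("implausible-parental-age" %in% rep$issue[rep$id == "E"])
  expect_true(is.na(ped$sire[ped$id == "E"]))
  # F has no birth date: flagged, links kept
  expect_true("missing-birth-date" %in% rep$issue[rep$id == "F"])
  expect_equal(ped$sire[ped$id == "F"], "A")
  # G's birth year 1492 is unrealistic
  expect_true("unrealistic-birth-date" %in% rep$issue[rep$id == "G"])
})

test_that("pedigree cycles are severed at the newest edge or reported", {
  raw <- data.frame(id = c("X", "Y", "Z"), sire = c("Z", "X", "Y"),
                    dam = c(NA, NA, NA), stringsAsFactors = FALSE)
  v <- validate_pedigree(raw)
  expect_true("cycle" %in% v$report$issue)
  expect_equal(nrow(v$pedigree), 3)
  # result is orderable: A-matrix construction succeeds
  expect_silent(build_a_matrix(v$pedigree))
})

test_that("ancestor tracing honours the generation horizon", {
  # chain of 7: I6 -> I5 -> ... -> I0 (sire-line only)
  ids <- paste0("I", 0:6)
  ped <- make_ped(ids, sire = c(NA, ids[-7]), dam = NA,
                  sex = "male")
  expect_equal(nrow(trace_ancestors(ped, "I0", 5)), 1)       # founder
  expect_equal(sort(trace_ancestors(ped, "I2", 1)$id), c("I1", "I2"))
  sub <- trace_ancestors(ped, "I6", 5)
  expect_setequal(sub$id, paste0("I", 1:6))                  # 6th ancestor excluded
  expect_true(is.na(sub$sire[sub$id == "I1"]))               # severed at horizon
  expect_error(trace_ancestors(ped, "nope", 5), "unknown id")
})

test_that("generation depth and completeness follow the ancestor slots", {
  ped <- make_ped(c("gs", "gd", "s", "d", "x", "y"),
                  sire = c(NA, NA, "gs", NA, "s", NA),
                  dam  = c(NA, NA, "gd", NA, "d", NA))
  gm <- generation_metrics(ped)
  expect_equal(gm[gm$id == "y", c("depth", "complete")],
               data.frame(depth = 0L, complete = 0L), ignore_attr = TRUE)
  expect_equal(gm[gm$id == "s", c("depth", "complete")],
               data.frame(depth = 1L, complete = 1L), ignore_attr = TRUE)
  # sire known to 2 generations, dam a founder: depth 2, complete 1;
  # with the dam unknown entirely, complete drops to 0
  expect_equal(gm[gm$id == "x", "depth"], 2L)
  ped2 <- make_ped(c("gs", "gd", "s", "x"),
                   sire = c(NA, NA, "gs", "s"), dam = c(NA, NA, "gd", NA))
  gm2 <- generation_metrics(ped2, "x")
  expect_equal(gm2$depth, 2L)
  expect_equal(gm2$complete, 0L)
  # property: complete <= depth everywhere on random pedigrees
  set.seed(7)
  for (r in 1:10) {
    rp <- random_ped(20)
    g <- generation_metrics(rp)
    expect_true(all(g$complete <= g$depth))
  }
})

test_that("the tabular A-matrix reproduces the classic identities", {
  # full sibs mated: offspring F = 0.25
  ped <- make_ped(c("A", "B", "C", "D", "E"),
                  sire = c(NA, NA, "A", "A", "C"),
                  dam  = c(NA, NA, "B", "B", "D"))
  A <- build_a_matrix(ped)
  expect_equal(unname(A["E", "E"]), 1.25)
  expect_equal(unname(A["C", "C"]), 1.0)       # outbred founder cross
  # parent-offspring mating
  ped <- make_ped(c("A", "B", "C", "E"),
                  sire = c(NA, NA, "A", "A"), dam = c(NA, NA, "B", "C"))
  expect_equal(unname(build_a_matrix(ped)["E", "E"]), 1.25)
  # half sibs mated: offspring F = 0.125
  ped <- make_ped(c("A", "B", "B2", "C", "D", "E"),
                  sire = c(NA, NA, NA, "A", "A", "C"),
                  dam  = c(NA, NA, NA, "B", "B2", "D"))
  expect_equal(unname(build_a_matrix(ped)["E", "E"]), 1.125)
  # unordered input is rejected with advice
  bad <- make_ped(c("E", "A", "B"), sire = c("A", NA, NA), dam = c("B", NA, NA))
  expect_error(build_a_matrix(bad), "topologically")
})

test_that("A matches Monte-Carlo gene-dropping on a random pedigree", {
  set.seed(11)
  ped <- random_ped(15)
  A <- build_a_matrix(ped)
  mc <- mc_amatrix(ped, nrep = 2e4)
  dev <- abs(A - mc$est) / pmax(mc$se, 1e-12)
  exact0 <- mc$se == 0
  expect_true(all(A[exact0] == mc$est[exact0]))
  expect_true(max(dev[!exact0]) < 4)  # 4 SE at this replicate count
})

test_that("F_PED is invariant to record order and respects the completeness filter", {
  set.seed(21)
  ped <- random_ped(25)
  A <- build_a_matrix(ped)
  ref <- f_ped(A, ped, min_complete_generations = 0)
  perm <- sample(nrow(ped))
  v <- validate_pedigree(as.data.frame(ped)[perm, ])
  A2 <- build_a_matrix(v$pedigree)
  got <- f_ped(A2, v$pedigree, ids = ref$id, min_complete_generations = 0)
  expect_equal(got$f_ped, ref$f_ped)
  # completeness filter: a fully complete 4-generation pedigree (16
  # founders collapsing down) is missing at threshold 5, present at 4
  n_gen <- 4
  rows <- list()
  make_layer <- function(g) paste0("L", g, "_", seq_len(2^(n_gen - g)))
  for (ind in make_layer(0)) rows[[ind]] <- data.frame(id = ind, sire = NA, dam = NA)
  for (g in 1:n_gen) {
    prev <- make_layer(g - 1)
    for (k in seq_along(make_layer(g))) {
      ind <- make_layer(g)[k]
      rows[[ind]] <- data.frame(id = ind, sire = prev[2 * k - 1], dam = prev[2 * k])
    }
  }
  ped4 <- do.call(rbind, rows)
  v4 <- validate_pedigree(ped4)
  A4 <- build_a_matrix(v4$pedigree)
  top <- make_layer(n_gen)
  expect_true(is.na(f_ped(A4, v4$pedigree, top, 5)$f_ped))
  expect_false(is.na(f_ped(A4, v4$pedigree, top, 4)$f_ped))
  # non-inbred individual reports 0
  expect_equal(f_ped(A4, v4$pedigree, top, 4)$f_ped, 0)
})

test_that("severing links never increases F_PED", {
  set.seed(33)
  for (r in 1:5) {
    ped <- random_ped(20)
    A <- build_a_matrix(ped)
    f0 <- f_ped(A, ped, min_complete_generations = 0)$f_ped
    cand <- which(!is.na(ped$sire))
    i <- cand[sample.int(length(cand), 1)]
    ped2 <- ped
    ped2$sire[i] <- NA
    A2 <- build_a_matrix(ped2)
    f1 <- f_ped(A2, ped2, min_complete_generations = 0)$f_ped
    expect_true(all(f1 <= f0 + 1e-12))
  }
})
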