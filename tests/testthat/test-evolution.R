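# Codon alignment back-threading and dN/dS estimation.

test_that("backtranslation threads codons and validates consistency", {
  dna_a <- "ATGAAAGTT"          # M K V
  dna_b <- "ATGGTT"             # M V
  aln_a <- "MKV"; aln_b <- "M-V"
  bt <- backtranslateAlignment(aln_a, aln_b, dna_a, dna_b)
  expect_equal(bt$codon_a, "ATGAAAGTT")
  expect_equal(bt$codon_b, "ATG---GTT")
  expect_equal(nchar(bt$codon_a), 3 * nchar(aln_a))
  # terminal stop codons are stripped transparently
  bt2 <- backtranslateAlignment(aln_a, aln_b, paste0(dna_a, "TAA"),
                                paste0(dna_b, "TGA"))
  expect_equal(bt2$codon_a, bt$codon_a)
  # shuffled DNA fails with the position named
  expect_error(backtranslateAlignment(aln_a, aln_b, "ATGGTTAAA", dna_b),
               "codon 2")
  expect_error(backtranslateAlignment("MKV", "MKV", "ATGTAAGTTTAA",
                                      "ATGAAAGTT"),
               "internal stop codon at codon 2")
})

test_that("trivial codon pairs give the expected dN/dS signatures", {
  for (method in c("ng86", "yn00")) {
    same <- estimateDnds("ATGAAAGTTCCC", "ATGAAAGTTCCC", method)
    expect_equal(same$dN, 0)
    expect_equal(same$dS, 0)
    expect_true(is.na(same$omega))   # undefined at dS = 0
    expect_false(same$saturated)
  }
  # one synonymous third-position change: dN = 0, dS > 0
  syn <- estimateDnds("ATGAAAGTT", "ATGAAGGTT", "ng86")  # AAA->AAG syn
  expect_equal(syn$dN, 0)
  expect_gt(syn$dS, 0)
  expect_error(estimateDnds("---", "---"), "no alignable codons")
})

test_that("ng86 equals the exhaustive pathway-enumeration oracle", {
  set.seed(61)
  for (rep in 1:6) {
    a <- random_cds(40)
    b <- evolveCodonSequence(a, t = 0.4, kappa = 2, omega = 0.6,
                             seed = 600 + rep)
    got <- estimateDnds(a, b, "ng86")
    orc <- oracle_ng86(a, b)
    expect_equal(got$S, orc$S, tolerance = 1e-10)
    expect_equal(got$Sd, orc$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, orc$Nd, tolerance = 1e-10)
    expect_equal(got$dS, orc$dS, tolerance = 1e-10)
    expect_equal(got$dN, orc$dN, tolerance = 1e-10)
  }
})

test_that("both estimators are symmetric in sequence order", {
  set.seed(62)
  a <- random_cds(120)
  b <- evolveCodonSequence(a, 0.25, 2, 0.4, seed = 99)
  for (method in c("ng86", "yn00")) {
    e1 <- estimateDnds(a, b, method)
    e2 <- estimateDnds(b, a, method)
    expect_equal(e1$dN, e2$dN, tolerance = 1e-12)
    expect_equal(e1$dS, e2$dS, tolerance = 1e-12)
  }
})

test_that("yn00 and ng86 distances agree in the kappa=1 neutral limit", {
  set.seed(63)
  rel_diff <- function(x, y) abs(x - y) / pmax(abs(y), 1e-9)
  ds_diffs <- dn_diffs <- numeric(0)
  a <- random_cds(600)
  for (rep in 1:6) {
    b <- evolveCodonSequence(a, 0.3, kappa = 1, omega = 1, seed = 700 + rep)
    ey <- estimateDnds(a, b, "yn00")
    en <- estimateDnds(a, b, "ng86")
    ds_diffs <- c(ds_diffs, rel_diff(ey$dS, en$dS))
    dn_diffs <- c(dn_diffs, rel_diff(ey$dN, en$dN))
  }
  expect_lt(mean(ds_diffs), 0.05)
  expect_lt(mean(dn_diffs), 0.05)
})

test_that("saturation fraction rises with divergence time", {
  set.seed(64)
  a <- random_cds(150)
  frac_sat <- vapply(c(0.2, 0.8, 2.0, 4.0), function(t) {
    sat <- vapply(1:12, function(i) {
      b <- evolveCodonSequence(a, t, 2, 0.5, seed = 1000 * t + i)
      estimateDnds(a, b, "ng86")$saturated
    }, logical(1))
    mean(sat)
  }, numeric(1))
  expect_true(all(diff(frac_sat) >= 0))
  expect_equal(frac_sat[1], 0)
  expect_equal(frac_sat[4], 1)
})

test_that("selection summaries discard saturated pairs and order groups", {
  est <- data.frame(
    role = c("MTase", "MTase", "REase", "REase", "MTase"),
    rm_type = "II",
    dS = c(0.3, 0.4, 0.35, 0.3, 1.2),
    omega = c(0.10, 0.12, 0.45, 0.50, 0.9),
    saturated = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  sm <- summarizeSelection(est)
  expect_equal(sm$n_discarded_saturated, 1L)
  grp <- sm$groups
  expect_equal(grp$n[grp$role == "MTase"], 2L)   # saturated pair dropped
  expect_lt(grp$mean_omega[grp$role == "MTase"],
            grp$mean_omega[grp$role == "REase"])
  # dS exactly 1 is retained under the strict > 1 reading
  est2 <- est; est2$dS[5] <- 1.0; est2$saturated[5] <- FALSE
  expect_equal(summarizeSelection(est2)$n_discarded_saturated, 0L)
  # all-identical pairs: omega undefined everywhere, empty summary, no crash
  est3 <- data.frame(role = "MTase", rm_type = "II", dS = 0,
                     omega = NA_real_, saturated = FALSE)
  sm3 <- summarizeSelection(est3)
  expect_equal(nrow(sm3$groups), 0L)
})

test_that("simulated group omegas are ordered and separable at n=30", {
  set.seed(65)
  sim_omega <- function(om, n, seed0) {
    vapply(seq_len(n), function(i) {
      a <- random_cds(200)
      b <- evolveCodonSequence(a, 0.3, 2, om, seed = seed0 + i)
      estimateDnds(a, b, "yn00")$omega
    }, numeric(1))
  }
  o1 <- sim_omega(0.1, 30, 8000)
  o2 <- sim_omega(0.5, 30, 9000)
  expect_lt(mean(o1), mean(o2))
  tr <- mannWhitneyU(o1, o2, "two")
  expect_lt(tr$p_value, 0.05)
})
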