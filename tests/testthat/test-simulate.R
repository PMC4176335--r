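# Generator contracts: determinism, tier identities, planted-spacing
# self-validation, codon-process behavior.

test_that("reference library tiers hit their identity targets", {
  lib <- shared_lib()
  info <- lib$info
  for (fk in sample(lib$classes$founder_key, 6)) {
    founder <- lib$seqs[[sprintf("ref_%s_f", fk)]]
    for (tier in c(95, 70, 40)) {
      copy <- lib$seqs[[sprintf("ref_%s_t%02d", fk, tier)]]
      st <- pairwiseAlign(setNames(founder, "f"), setNames(copy, "c"),
                          "global_endgapfree")
      expect_gte(st$identity, tier / 100 - 0.05)
    }
  }
  # distinct roles share no founder: cross-class identity far below the
  # role-call regime (no shared 4-mer seeds at all for most pairs)
  f1 <- lib$seqs[["ref_MTase_II_a_f"]]
  f2 <- lib$seqs[["ref_REase_I_f"]]
  st <- pairwiseAlign(setNames(f1, "a"), setNames(f2, "b"), "local")
  expect_lt(st$identity * st$query_coverage, 0.2)
})

test_that("the same seed reproduces identical genomes and spacers", {
  lib <- shared_lib()
  s1 <- simulateGenome(lib, genomePlan("gd", "cladeA"), seed = 77)
  s2 <- simulateGenome(lib, genomePlan("gd", "cladeA"), seed = 77)
  expect_identical(geneTable(s1$genome), geneTable(s2$genome))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateGenome(lib, genomePlan("gd", "cladeA"), seed = 78)
  expect_false(identical(geneTable(s1$genome), geneTable(s3$genome)))
  # library generation is byte-deterministic through the FASTA writer
  td <- withr::local_tempdir()
  writeReferenceFasta(buildReferenceLibrary(5), file.path(td, "a.faa"))
  writeReferenceFasta(buildReferenceLibrary(5), file.path(td, "b.faa"))
  expect_identical(readBin(file.path(td, "a.faa"), "raw", 1e6),
                   readBin(file.path(td, "b.faa"), "raw", 1e6))
})

test_that("planted spacings are verified against the emitted genome", {
  lib <- shared_lib()
  sim <- simulateGenome(lib, genomePlan("gv", "cladeB"), seed = 21)
  tg <- sim$truth$genes
  for (rep in replicons(sim$genome)) {
    tr <- tg[tg$replicon_id == repliconId(rep), ]
    n <- nGenes(rep)
    rm_tr <- tr[tr$role %in% c("REase", "MTase") &
                  tr$rm_type %in% c("I", "II", "III"), ]
    for (i in which(rm_tr$feature_kind == "solitary")) {
      cog <- if (rm_tr$role[i] == "MTase") "REase" else "MTase"
      others <- rm_tr$rank[rm_tr$role == cog]
      if (length(others))
        expect_gte(min(rankDistance(rm_tr$rank[i], others, n, TRUE)), 10)
    }
    for (f in unique(rm_tr$feature[rm_tr$feature_kind == "ambiguous"])) {
      rk <- sort(rm_tr$rank[rm_tr$feature %in% f])
      expect_gte(diff(range(rk)), 4)
      expect_lt(diff(range(rk)), 10)
    }
  }
  # spacer truth identities are exact arithmetic over the planted mutations
  ds <- shared_dataset()
  expect_equal(ds$spacer_truth$expected_identity[
    ds$spacer_truth$spacer_id == "sp_mut3"], 29 / 32)
})

test_that("clade truth is self-consistent and zero-event clades are trivial", {
  cl <- shared_clade()
  tg <- cl$truth$genes
  # every truth-table gene id exists in the emitted genomes
  expect_true(all(tg$gene_id %in% geneTable(cl$gs)$gene_id))
  # every deleted ancestor is missing from at least one strain, hence
  # excluded from the core
  for (d in cl$truth$deleted) {
    strains_with <- unique(tg$genome_id[tg$ancestor_id %in% d])
    expect_lt(length(strains_with), length(cl$gs))
  }
  expect_length(intersect(cl$truth$core_ids, cl$truth$deleted), 0)
  # insertion sizes recorded as region lengths match the plan's supports
  reg <- cl$truth$regions
  expect_true(all(reg$length_genes[reg$class == "complete" & !reg$is_probe]
                  %in% (2 + cladePlan()$complete_extra)))
  expect_true(all(reg$length_genes[reg$class == "solitary"]
                  %in% cladePlan()$solitary_size))
  # zero events: the core is the entire ancestor
  plan0 <- cladePlan(n_strains = 3, n_core = 24)
  plan0$insertion_slots <- integer(0)
  plan0$deletion_slots <- integer(0)
  plan0$inversion_len <- 0
  cl0 <- simulateClade(shared_lib(), plan0, seed = 4)
  expect_equal(length(cl0$truth$core_ids), 24L)
  cm0 <- suppressWarnings(coreGenome(cl0$gs))
  expect_equal(length(unique(cm0$core_id)), 24L)
})

test_that("the codon process respects its limiting behaviors", {
  set.seed(91)
  dna <- random_cds(80)
  expect_identical(evolveCodonSequence(dna, 0, 2, 0.5, seed = 1), dna)
  # omega = 0 forbids amino-acid change
  ev <- evolveCodonSequence(dna, 1.0, 2, 0, seed = 2)
  tr <- function(x) paste(Biostrings::GENETIC_CODE[
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))], collapse = "")
  expect_identical(tr(ev), tr(dna))
  expect_false(identical(ev, dna))
  # substitution counts scale with t (more divergence at larger t)
  d_small <- mean(strsplit(evolveCodonSequence(dna, 0.05, 2, 1, seed = 3), "")[[1]] !=
                    strsplit(dna, "")[[1]])
  d_large <- mean(strsplit(evolveCodonSequence(dna, 1.5, 2, 1, seed = 3), "")[[1]] !=
                    strsplit(dna, "")[[1]])
  expect_lt(d_small, d_large)
  expect_error(evolveCodonSequence("ATGTAA", 0.1, 2, 1), "stop")
})

test_that("uniform placement nulls carry no type-category association", {
  loc <- simulateUniformPlacement(500, seed = 6)
  expect_equal(nrow(loc), 500L)
  er <- enrichmentFromLocations(loc)$enrichment
  # all O/E near 1 at this sample size; no systematic deviation
  big <- er[er$expected >= 10, ]
  expect_true(all(abs(big$oe_ratio - 1) < 0.8))
})
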