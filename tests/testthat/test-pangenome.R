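# Positional orthology, core genome, pan families, integration regions.

make_genome_from_prots <- function(id, prots, circular = TRUE) {
  n <- length(prots)
  genes <- data.frame(
    gene_id = sprintf("%s_g%03d", id, seq_len(n)),
    rank = seq_len(n) - 1L,
    start = seq(100, by = 400, length.out = n),
    end = seq(100, by = 400, length.out = n) + 299L,
    strand = "+", protein = unname(prots), dna = NA_character_,
    stringsAsFactors = FALSE)
  Genome(id, "toy", list(Replicon(paste0(id, "_chr"), "chromosome",
                                  400 * n + 500, circular, genes)))
}

test_that("identical genomes are positionally orthologous gene by gene", {
  set.seed(51)
  prots <- vapply(1:20, function(i) random_protein(80), "")
  ga <- make_genome_from_prots("A", prots)
  gb <- make_genome_from_prots("B", prots)
  po <- positionalOrthologs(ga, gb)
  expect_equal(nrow(po), 20L)
  expect_true(all(po$synteny_support >= 4))
  expect_true(all(sub("A_", "", po$gene_a) == sub("B_", "", po$gene_b)))
})

test_that("synteny support threshold keeps pairs at four, drops below", {
  # linear replicons; a transplanted gene far from its neighborhood keeps a
  # BBH but loses synteny support
  set.seed(52)
  prots <- vapply(1:24, function(i) random_protein(80), "")
  ga <- make_genome_from_prots("A", prots, circular = FALSE)
  # genome B: same order but gene 12 moved to the end (no shared neighbors)
  reordered <- c(prots[1:11], prots[13:24], prots[12])
  gb <- make_genome_from_prots("B", reordered, circular = FALSE)
  po <- positionalOrthologs(ga, gb)
  moved_a <- "A_g012"
  expect_false(moved_a %in% po$gene_a)   # BBH exists but support < 4
  expect_true("A_g005" %in% po$gene_a)
  bb <- bbhPairs(setNames(geneTable(ga)$protein, geneTable(ga)$gene_id),
                 setNames(geneTable(gb)$protein, geneTable(gb)$gene_id))
  expect_true(moved_a %in% bb$gene_a)
})

test_that("core genome is the intersection across strains", {
  set.seed(53)
  prots <- setNames(vapply(1:15, function(i) random_protein(80), ""),
                    sprintf("p%02d", 1:15))
  gA <- make_genome_from_prots("sA", prots)
  gB <- make_genome_from_prots("sB", prots)
  gC <- make_genome_from_prots("sC", prots[-8])   # strain C lacks gene 8
  expect_warning(cm <- coreGenome(GenomeSet(list(gA, gB, gC))), "only 3")
  core_ranks <- unique(cm$core_id)
  expect_equal(length(core_ranks), 14L)
  expect_false("sA_g008" %in% core_ranks)
  # each core gene has exactly one ortholog per strain
  tab <- table(cm$core_id, cm$genome_id)
  expect_true(all(tab == 1))
})

test_that("planted clade core is recovered exactly despite rearrangements", {
  cl <- shared_clade()
  cm <- coreGenome(cl$gs)
  tg <- cl$truth$genes
  anc_of <- setNames(tg$ancestor_id, tg$gene_id)
  found <- sort(stats::na.omit(unname(anc_of[unique(cm$core_id)])))
  expect_equal(found, sort(cl$truth$core_ids))
  expect_lte(length(unique(cm$core_id)), min(vapply(
    names(cl$gs), function(s) nGenes(cl$gs[[s]]), 0L)))
})

test_that("pan families partition genes; core families span all strains", {
  cl <- shared_clade()
  pan <- panFamilies(cl$gs, identity_min = 0.8)
  fam <- pan$families
  gt <- geneTable(cl$gs)
  expect_setequal(fam$gene_id, gt$gene_id)
  expect_equal(anyDuplicated(fam$gene_id), 0L)
  # families holding a core gene in every strain have presence 1
  cm <- coreGenome(cl$gs)
  core_genes <- cm$gene_id
  core_fams <- unique(fam$family_id[fam$gene_id %in% core_genes])
  pres <- tapply(fam$strain_presence, fam$family_id, unique)
  expect_true(all(pres[core_fams] == 1))
  # stringent families refine relaxed families on the same hit table
  pan40 <- panFamilies(cl$gs, identity_min = 0.4, hits = pan$hits)
  m80 <- setNames(fam$family_id, fam$gene_id)
  m40 <- setNames(pan40$families$family_id, pan40$families$gene_id)
  expect_true(all(tapply(m40[names(m80)], m80,
                         function(v) length(unique(v))) == 1))
})

test_that("family R-M content labels separate planted lineages", {
  cl <- shared_clade()
  roles <- assignRolesGenomeSet(cl$gs, shared_lib())
  det <- detectRMSystems(cl$gs, roles)
  pan <- panFamilies(cl$gs, identity_min = 0.8)
  cls <- classifyRMFamilies(pan, det, core_map = coreGenome(cl$gs))
  tab <- cls$family_content
  # the solitary lineage (distinct founder) is solitary_only, never mixed
  sol_fams <- unique(pan$families$family_id[
    pan$families$gene_id %in% det$solitary$gene_id])
  expect_true(all(tab$rm_content[tab$family_id %in% sol_fams] ==
                    "solitary_only"))
  comp_genes <- det$components$gene_id[
    det$components$system_id %in%
      det$systems$system_id[det$systems$complete]]
  comp_fams <- unique(pan$families$family_id[
    pan$families$gene_id %in% comp_genes])
  expect_true(all(tab$rm_content[tab$family_id %in% comp_fams] ==
                    "complete_only"))
  expect_equal(cls$summary$fraction_complete_families_mixed, 0)
  # accessory systems are never in the core
  expect_equal(cls$summary$fraction_systems_in_core, 0)
})

test_that("integration regions recover planted insertion lengths exactly", {
  cl <- shared_clade()
  roles <- assignRolesGenomeSet(cl$gs, shared_lib())
  det <- detectRMSystems(cl$gs, roles)
  cm <- coreGenome(cl$gs)
  regions <- integrationRegions(rmElements(det), cm, cl$gs)
  truth <- cl$truth$regions
  truth_rm <- truth[truth$class %in% c("complete", "solitary"), ]
  ok <- regions[!regions$excluded, ]
  # region lengths of retained regions equal planted lengths as multisets,
  # per genome and class
  for (sid in unique(truth_rm$genome_id)) {
    for (klass in c("complete", "solitary")) {
      t_len <- sort(truth_rm$length_genes[truth_rm$genome_id == sid &
                                            truth_rm$class == klass &
                                            !truth_rm$breakpoint])
      g_len <- sort(ok$length_genes[ok$genome_id == sid & ok$class == klass])
      expect_equal(g_len, t_len)
    }
  }
  # probe regions sit at disrupted core pairs: flagged and excluded
  probes <- truth[truth$is_probe, ]
  for (i in seq_len(nrow(probes))) {
    pr <- probes[i, ]
    got <- regions[regions$genome_id == pr$genome_id & regions$breakpoint, ]
    expect_gte(nrow(got), 1L)
  }
  expect_true(all(regions$excluded[regions$breakpoint]))
})

test_that("species-direction comparison has closed-form binomial p-values", {
  mk <- function(species, class, L) data.frame(
    element_id = paste0(species, class, L), species = species, class = class,
    length_genes = L, breakpoint = FALSE, excluded = FALSE)
  # 10 species, complete smaller in all -> one-sided p = 0.5^10
  regs <- do.call(rbind, lapply(sprintf("s%02d", 1:10), function(s)
    rbind(mk(s, "complete", 2), mk(s, "solitary", 6))))
  res <- compareRegionSizes(regs)
  expect_equal(res$n_smaller_complete, 10L)
  expect_equal(res$test$p_value, 0.5^10)
  # split 5/10: no signal
  regs2 <- do.call(rbind, lapply(1:10, function(i) {
    s <- sprintf("s%02d", i)
    if (i <= 5) rbind(mk(s, "complete", 2), mk(s, "solitary", 6))
    else rbind(mk(s, "complete", 6), mk(s, "solitary", 2))
  }))
  res2 <- compareRegionSizes(regs2)
  expect_gt(res2$test$p_value, 0.5)
})
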