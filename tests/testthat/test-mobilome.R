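# Plasmid MOB typing, integron and competence detection, spacer matching and
# MGE enrichment.

toy_mob_roles <- function(replicon, roles_vec) {
  g <- replicon@genes
  data.frame(gene_id = g$gene_id, rank = g$rank,
             role = c(roles_vec, rep("other", nrow(g) - length(roles_vec))),
             rm_type = "none", stringsAsFactors = FALSE)
}

test_that("plasmids classify MOB+ with a relaxase or full conjugation set", {
  pl <- toy_replicon(10, "p1", kind = "plasmid")
  expect_equal(classifyPlasmidMob(pl, toy_mob_roles(pl, "relaxase")),
               "MOB_plus")
  expect_equal(classifyPlasmidMob(
    pl, toy_mob_roles(pl, c("conjugation:T4CP", "conjugation:MPF"))),
    "MOB_plus")
  expect_equal(classifyPlasmidMob(pl, toy_mob_roles(pl, "conjugation:T4CP")),
               "MOB_minus")
  expect_equal(classifyPlasmidMob(pl, toy_mob_roles(pl, character(0))),
               "MOB_minus")
  chr <- toy_replicon(10, "c1", kind = "chromosome")
  expect_error(classifyPlasmidMob(chr, toy_mob_roles(chr, "relaxase")),
               "plasmids only")
})

test_that("planted MOB labels are recovered exactly on the dataset", {
  ds <- shared_dataset()
  mob <- classifyMobGenomeSet(ds$gs, shared_roles())
  truth <- ds$truth$mob
  m <- merge(mob, truth, by = c("genome_id", "replicon_id"),
             suffixes = c("_called", "_true"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$mob_called == m$mob_true))
})

test_that("integron loci require both recombinase and integron signals", {
  r <- toy_replicon(12, "chrI")
  roles <- toy_roles(r)
  roles$has_integrase_tyr[roles$rank == 3] <- TRUE      # alone: no call
  roles$has_integron_signature[roles$rank == 5] <- TRUE # alone: no call
  roles$has_integrase_tyr[roles$rank == 8] <- TRUE
  roles$has_integron_signature[roles$rank == 8] <- TRUE
  roles$has_integrase_tyr[roles$rank == 10] <- TRUE
  roles$has_integron_signature[roles$rank == 10] <- TRUE
  loci <- detectIntegrons(r, roles)
  expect_equal(sort(loci$rank), c(8, 10))
})

test_that("competence loci enforce gap, size and mandatory-component rules", {
  comp <- competenceComponents("positive")
  mand <- setdiff(comp$components, comp$facultative)
  r <- toy_replicon(60, "chrC")
  mk_roles <- function(placement) {
    roles <- toy_roles(r)
    for (i in seq_along(placement))
      roles$role[roles$rank == placement[i]] <- mand[i]
    roles
  }
  # 7 mandatory components at offsets <= 5 -> one locus
  ranks_ok <- c(5, 7, 10, 14, 18, 23, 28)
  loci <- detectCompetenceLoci(r, mk_roles(ranks_ok), "positive")
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_genes, 7L)
  # only 5 components -> below min_genes, no locus
  loci5 <- detectCompetenceLoci(r, mk_roles(ranks_ok[1:5]), "positive")
  expect_equal(nrow(loci5), 0L)
  # a gap of 6 splits the run; neither side satisfies the rules
  ranks_gap <- c(5, 7, 10, 14, 20, 25, 30)  # 14 -> 20 exceeds max_gap 5
  lg <- detectCompetenceLoci(r, mk_roles(ranks_gap), "positive")
  expect_equal(nrow(lg), 0L)
  # missing one mandatory component (facultative present instead): no locus
  roles_fac <- mk_roles(ranks_ok[1:6])
  roles_fac$role[roles_fac$rank == 33] <- comp$facultative
  expect_equal(nrow(detectCompetenceLoci(r, roles_fac, "positive")), 0L)
  expect_error(competenceComponents("weird"))
})

test_that("spacer matches honor identity and length thresholds on both strands", {
  set.seed(13)
  gene <- random_cds(120)
  sub <- function(from, len = 32) substr(gene, from, from + len - 1)
  mutate_nt <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  rc <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  spacers <- c(exact = sub(10), mut3 = mutate_nt(sub(50), c(7, 15, 25)),
               mut4 = mutate_nt(sub(90), c(6, 13, 20, 27)),
               revc = rc(sub(130)),
               part = paste0(substr(gene, 170, 195), "GGCCGG"))
  mm <- matchSpacers(spacers, c(g = gene))
  mm <- mm[order(mm$spacer_id), ]
  expect_equal(mm$identity[mm$spacer_id == "exact"], 1)
  expect_true(mm$retained[mm$spacer_id == "exact"])
  expect_equal(mm$identity[mm$spacer_id == "mut3"], 29 / 32)
  expect_true(mm$retained[mm$spacer_id == "mut3"])
  expect_equal(mm$identity[mm$spacer_id == "mut4"], 28 / 32)
  expect_false(mm$retained[mm$spacer_id == "mut4"])
  expect_true(mm$retained[mm$spacer_id == "revc"])
  expect_equal(mm$strand[mm$spacer_id == "revc"], "-")
  expect_gte(mm$length_diff[mm$spacer_id == "part"], 0.1)
  expect_false(mm$retained[mm$spacer_id == "part"])
  # retained set shrinks (weakly) as min_identity rises
  counts <- vapply(c(0.8, 0.9, 0.95, 1), function(th)
    sum(matchSpacers(spacers, c(g = gene), min_identity = th)$retained), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("O/E enrichment follows the expected-count construction", {
  # closed-form example: 100 Type II systems, 5% of all systems on plasmids,
  # 8 observed -> expected 5, O/E 1.6
  loc <- rbind(
    data.frame(rm_type = "II", category = rep("plasmid", 8)),
    data.frame(rm_type = "II", category = rep("chromosome", 92)),
    data.frame(rm_type = "I", category = rep("plasmid", 2)),
    data.frame(rm_type = "I", category = rep("chromosome", 98)))
  er <- enrichmentFromLocations(loc)$enrichment
  row <- er[er$rm_type == "II" & er$category == "plasmid", ]
  expect_equal(row$expected, 100 * 10 / 200)
  expect_equal(row$oe_ratio, 8 / 5)
  # observed == expected -> O/E exactly 1
  loc2 <- data.frame(rm_type = rep(c("I", "II"), each = 10),
                     category = rep(c("chromosome", "plasmid"), 10))
  er2 <- enrichmentFromLocations(loc2)$enrichment
  expect_true(all(abs(er2$oe_ratio - 1) < 1e-12))
  # expected counts per type always sum to the type total
  set.seed(3)
  loc3 <- simulateUniformPlacement(150, seed = 3)
  er3 <- enrichmentFromLocations(loc3)$enrichment
  sums <- tapply(er3$expected, er3$rm_type, sum)
  tots <- table(loc3$rm_type)
  expect_equal(as.numeric(sums[names(tots)]), as.numeric(tots))
})

test_that("system and solitary locations respect MGE spans and Table-1 logic", {
  ds <- shared_dataset()
  det <- shared_detection()
  enr <- mgeEnrichment(det, ds$gs, ds$mges)
  truth <- ds$truth
  # planted ICE systems are located in ICE_IME; prophage solitaries in prophage
  ice_sys <- truth$systems$component_genes[grepl("_ice", truth$systems$feature)]
  ice_ids <- det$systems$system_id[det$systems$component_genes %in% ice_sys]
  expect_true(all(enr$locations$category[
    enr$locations$system_id %in% ice_ids] == "ICE_IME"))
  pro_sol <- truth$solitary$gene_id[grepl("_pro", truth$solitary$feature)]
  expect_true(all(enr$solitary_locations$category[
    enr$solitary_locations$gene_id %in% pro_sol] == "prophage"))
  # location categories partition the complete systems
  expect_equal(nrow(enr$locations),
               sum(det$systems$complete & !det$systems$mixed))
  # chromosome + plasmid + prophage + ICE_IME + phage solitary tallies
  # conserve the global solitary count
  expect_equal(sum(enr$densities$n_solitary), nrow(det$solitary))
})
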