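# R-M system assembly, solitary calls, co-localization and census.

test_that("cognate pairs assemble into systems only below the gap threshold", {
  r <- toy_replicon(40)
  # MTase at 5, REase at 8: offset 3 < 4 -> one complete Type II system
  roles <- toy_roles(r, list(list(rank = 5, role = "MTase", rm_type = "II"),
                             list(rank = 8, role = "REase", rm_type = "II")))
  asm <- assembleRMSystems(r, roles, genome_id = "gX")
  expect_equal(nrow(asm$systems), 1L)
  expect_equal(asm$systems$rm_type, "II")
  expect_true(asm$systems$complete)
  expect_equal(asm$systems$n_components, 2L)
  # offset 5: no system, two unassigned components
  roles2 <- toy_roles(r, list(list(rank = 5, role = "MTase", rm_type = "II"),
                              list(rank = 10, role = "REase", rm_type = "II")))
  asm2 <- assembleRMSystems(r, roles2, genome_id = "gX")
  expect_equal(nrow(asm2$systems), 0L)
  expect_equal(nrow(asm2$unassigned), 2L)
})

test_that("Type I systems absorb multiple S genes; IIC and IV stand alone", {
  r <- toy_replicon(40)
  roles <- toy_roles(r, list(
    list(rank = 20, role = "MTase", rm_type = "I"),
    list(rank = 21, role = "S", rm_type = "I"),
    list(rank = 22, role = "REase", rm_type = "I"),
    list(rank = 23, role = "S", rm_type = "I"),
    list(rank = 3, role = "IIC", rm_type = "none"),
    list(rank = 33, role = "TypeIV_REase", rm_type = "none")))
  asm <- assembleRMSystems(r, roles, genome_id = "gX")
  expect_equal(sort(asm$systems$rm_type), c("I", "IIC", "IV"))
  t1 <- asm$systems[asm$systems$rm_type == "I", ]
  expect_equal(t1$n_components, 4L)
  expect_equal(t1$n_s_genes, 2L)
  expect_true(all(asm$systems$complete))
})

test_that("M+S-only Type I clusters are incomplete and excluded from census", {
  r <- toy_replicon(40)
  roles <- toy_roles(r, list(list(rank = 10, role = "MTase", rm_type = "I"),
                             list(rank = 11, role = "S", rm_type = "I")))
  asm <- assembleRMSystems(r, roles, genome_id = "gX")
  expect_equal(nrow(asm$systems), 1L)
  expect_false(asm$systems$complete)
})

test_that("clusters with conflicting R-M types are flagged mixed", {
  r <- toy_replicon(40)
  roles <- toy_roles(r, list(list(rank = 10, role = "MTase", rm_type = "I"),
                             list(rank = 11, role = "REase", rm_type = "II")))
  expect_warning(asm <- assembleRMSystems(r, roles, genome_id = "gX"),
                 "conflicting")
  expect_true(asm$systems$mixed)
})

test_that("II/IV-ambiguous REases resolve by genomic context", {
  r <- toy_replicon(40)
  roles <- toy_roles(r, list(list(rank = 10, role = "MTase", rm_type = "II"),
                             list(rank = 12, role = "REase", rm_type = "II"),
                             list(rank = 30, role = "REase", rm_type = "II")))
  roles$ambiguous_ii_iv[roles$rank %in% c(12, 30)] <- TRUE
  asm <- assembleRMSystems(r, roles, genome_id = "gX")
  # with MTase in range -> Type II system; isolated -> Type IV entry
  expect_equal(sort(asm$systems$rm_type), c("II", "IV"))
})

test_that("solitary and ambiguous calls partition by cognate distance", {
  r <- toy_replicon(60)
  roles <- toy_roles(r, list(list(rank = 5, role = "MTase", rm_type = "II"),
                             list(rank = 25, role = "REase", rm_type = "II")))
  asm <- assembleRMSystems(r, roles, genome_id = "gX")
  so <- callSolitary(r, roles, asm, genome_id = "gX")
  expect_equal(sort(so$solitary$gene_id),
               sort(r@genes$gene_id[r@genes$rank %in% c(5, 25)]))
  # cognate at offset 4: ambiguous band [4, 10)
  roles2 <- toy_roles(r, list(list(rank = 5, role = "MTase", rm_type = "II"),
                              list(rank = 9, role = "REase", rm_type = "II")))
  asm2 <- assembleRMSystems(r, roles2, genome_id = "gX")
  so2 <- callSolitary(r, roles2, asm2, genome_id = "gX")
  expect_equal(nrow(so2$solitary), 0L)
  expect_equal(nrow(so2$ambiguous), 2L)
  expect_true(all(so2$ambiguous$nearest_cognate_distance == 4))
  # no REase at all: every unassigned MTase is solitary
  roles3 <- toy_roles(r, list(list(rank = 5, role = "MTase", rm_type = "II"),
                              list(rank = 40, role = "MTase", rm_type = "II")))
  asm3 <- assembleRMSystems(r, roles3, genome_id = "gX")
  so3 <- callSolitary(r, roles3, asm3, genome_id = "gX")
  expect_equal(nrow(so3$solitary), 2L)
})

test_that("every planted component gene ends in exactly one category", {
  ds <- shared_dataset()
  det <- shared_detection()
  roles <- shared_roles()
  rm_genes <- roles$gene_id[roles$role %in% c("REase", "MTase", "S") &
                              roles$rm_type %in% c("I", "II", "III")]
  in_sys <- det$components$gene_id
  in_sol <- det$solitary$gene_id
  in_amb <- det$ambiguous$gene_id
  counts <- (rm_genes %in% in_sys) + (rm_genes %in% in_sol) +
    (rm_genes %in% in_amb)
  expect_true(all(counts == 1))
})

test_that("co-localization fractions equal a brute-force all-pairs scan", {
  ds <- shared_dataset()
  det <- shared_detection()
  for (nb in c(10, 50)) {
    cl <- colocalizationPairs(det, ds$gs, nb)
    # oracle: quadratic scan over systems per replicon
    systems <- det$systems[!det$systems$mixed, ]
    comp <- det$components
    hit <- character(0)
    for (rid in unique(systems$replicon_id)) {
      ss <- systems[systems$replicon_id == rid, ]
      if (nrow(ss) < 2) next
      rep <- getReplicon(ds$gs, rid)
      for (i in seq_len(nrow(ss))) for (j in seq_len(nrow(ss))) {
        if (i >= j) next
        ri <- comp$rank[comp$system_id == ss$system_id[i]]
        rj <- comp$rank[comp$system_id == ss$system_id[j]]
        dmin <- min(vapply(ri, function(x)
          min(rankDistance(x, rj, nGenes(rep), isCircular(rep))), 0L))
        if (dmin < nb) hit <- union(hit, c(ss$system_id[i], ss$system_id[j]))
      }
    }
    expect_equal(cl$fraction_colocalized, length(hit) / nrow(systems))
    expect_equal(nrow(cl$pairs) > 0, length(hit) > 0)
  }
})

test_that("census densities recompute from counts and sizes", {
  ds <- shared_dataset()
  census <- rmCensus(ds$gs, shared_detection())
  pg <- census$per_genome
  expect_equal(pg$density, pg$n_total / pg$size_mb)
  expect_equal(sum(pg[, paste0("n_", c("I", "II", "IIC", "III", "IV"))]),
               sum(pg$n_total))
  # both clades have >= 10 genomes, so both appear in the clade summary
  expect_setequal(census$per_clade$clade, c("cladeA", "cladeB"))
  # clade summary conservation over qualifying clades
  expect_equal(sum(census$per_clade$mean_count * census$per_clade$n_genomes),
               sum(pg$n_total[pg$clade %in% census$per_clade$clade]))
  # a clade below the size threshold is excluded
  census9 <- rmCensus(ds$gs, shared_detection(), min_clade_size = 11)
  expect_equal(nrow(census9$per_clade), 0L)
})

test_that("IIC fusion scan flags planted fusions of split Type II systems", {
  ds <- shared_dataset()
  det <- shared_detection()
  scan <- iicFusionScan(det, ds$gs)
  # every planted IIC is a fusion of the IIC founders, not of the split
  # Type II founders, except by shared ancestry none exists: flagged fraction
  # reflects sequence similarity to two-gene systems
  expect_true(all(scan$table$best_similarity >= 0 &
                    scan$table$best_similarity <= 1))
  # a literal fusion of a planted two-gene system clears the 50% similarity
  # flag, while an unrelated protein does not
  sys2 <- det$systems[det$systems$rm_type == "II" &
                        det$systems$n_components == 2, ][1, ]
  gt <- geneTable(ds$gs)
  prot <- setNames(gt$protein, gt$gene_id)
  parts <- strsplit(sys2$component_genes, ",")[[1]]
  fused <- paste0(prot[[parts[1]]], prot[[parts[2]]])
  st <- alignStats(setNames(fused, "f"),
                   c(prot[parts], fused = paste(prot[parts], collapse = "")),
                   "local")
  expect_true(max(st$similarity) > 0.5)
  st0 <- alignStats(setNames(random_protein(400, seed = 77), "bg"),
                    c(fused = fused), "local")
  expect_true(max(st0$similarity * st0$query_coverage) < 0.5)
})
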