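## Multi-genome datasets, clade simulation with core/accessory structure,
## spacer planting, and lightweight statistical study generators.

#' Simulate a multi-genome dataset with planted features and spacers
#'
#' Generates \code{n_genomes} genomes in two clades with per-genome feature
#' plans drawn from the default plan (all genomes carry Type II systems;
#' competence loci, integrons, cas and argo markers are planted on half the
#' genomes each so co-occurrence tests have both groups), plus a CRISPR
#' spacer set copied from a planted R-M gene of the first genome with
#' controlled mutation and truncation, and the union of all MGE span tables.
#'
#' @param lib reference library.
#' @param n_genomes number of genomes (split into two clades).
#' @param seed RNG seed.
#' @return list: gs (\linkS4class{GenomeSet}), truth (combined truth tables),
#'   mges, spacers (named DNA vector), spacer_truth, lib.
#' @export
simulateDataset <- function(lib, n_genomes = 20, seed = 1) {
  .with_seed(seed, {
    genomes <- list(); truths <- list()
    half <- ceiling(n_genomes / 2)
    for (i in seq_len(n_genomes)) {
      gid <- sprintf("g%02d", i)
      plan <- genomePlan(gid, if (i <= half) "cladeA" else "cladeB")
      # vary the plan so genomes differ in content
      if (i %% 2 == 0) plan$competence <- FALSE
      if (i %% 3 == 0) plan$integron <- FALSE
      if (i %% 4 == 0) plan$cas <- FALSE
      if (i %% 5 == 0) plan$argo <- FALSE
      if (i %% 2 == 1) plan$plasmids <- c("plus", "minus") else
        plan$plasmids <- "minus"
      if (i %% 3 == 1)
        plan$systems <- plan$systems[1:4]  # fewer systems on some genomes
      sim <- .simulate_genome_inner(lib, plan)
      genomes[[gid]] <- sim$genome
      truths[[gid]] <- sim$truth
    }
    gs <- GenomeSet(genomes)
    truth <- list(
      genes = do.call(rbind, lapply(truths, `[[`, "genes")),
      systems = do.call(rbind, lapply(truths, `[[`, "systems")),
      solitary = do.call(rbind, lapply(truths, `[[`, "solitary")),
      ambiguous = do.call(rbind, lapply(truths, `[[`, "ambiguous")),
      mob = do.call(rbind, lapply(truths, `[[`, "mob")))
    rownames(truth$systems) <- NULL
    mges <- do.call(rbind, lapply(truths, `[[`, "mges"))
    rownames(mges) <- NULL
    sp <- .plant_spacers(gs, truth)
    list(gs = gs, truth = truth, mges = mges, spacers = sp$spacers,
         spacer_truth = sp$truth, lib = lib)
  })
}

# Spacer plan: copies of a planted system MTase gene of the first genome.
#  - exact 32-nt copy (retained, identity 1)
#  - 3 interior mutations (29/32 = 0.906, retained)
#  - 4 interior mutations (28/32 = 0.875, rejected on identity)
#  - exact copy on the reverse strand (retained)
#  - 26-nt gene match padded with 6 random nt (span 26/32: rejected on
#    length difference)
.plant_spacers <- function(gs, truth) {
  tg <- truth$genes
  src <- tg[tg$feature_kind %in% "system" & tg$role == "MTase" &
              tg$genome_id == tg$genome_id[1], , drop = FALSE]
  src <- src[order(src$gene_id), , drop = FALSE][1, ]
  gt <- geneTable(gs)
  dna <- gt$dna[gt$gene_id == src$gene_id]
  sub32 <- function(from) substr(dna, from, from + 31)
  mutate_nt <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  rc <- function(s) as.character(reverseComplement(DNAString(s)))
  spacers <- c(
    sp_exact = sub32(10),
    sp_mut3 = mutate_nt(sub32(60), c(6, 16, 26)),
    sp_mut4 = mutate_nt(sub32(110), c(4, 12, 20, 28)),
    sp_rc = rc(sub32(160)),
    sp_trunc = paste0(substr(dna, 210, 235),
                      paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                            collapse = "")))
  truth_tab <- data.frame(
    spacer_id = names(spacers), source_gene = src$gene_id,
    n_mutations = c(0L, 3L, 4L, 0L, 0L),
    expected_identity = c(1, 29 / 32, 28 / 32, 1, 1),
    expected_length_diff = c(0, 0, 0, 0, 6 / 32),
    retained = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    strand = c("+", "+", "+", "-", "+"), stringsAsFactors = FALSE)
  list(spacers = spacers, truth = truth_tab)
}

#' Write spacers as FASTA
#' @param spacers named DNA character vector.
#' @param path output path.
#' @export
writeSpacerFasta <- function(spacers, path) {
  Biostrings::writeXStringSet(DNAStringSet(spacers), path)
  invisible(path)
}

#' Write an MGE span table as TSV
#' @param mges MGE table (\code{\link{readMgeTable}} schema).
#' @param path output path.
#' @export
writeMgeTable <- function(mges, path) {
  con <- file(path, open = "wb")
  write.table(mges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

## ---- clade simulation ------------------------------------------------------

#' Default clade simulation plan
#'
#' @param n_strains number of strains (star clade from one ancestor).
#' @param n_core ancestral gene count.
#' @return configuration list for \code{\link{simulateClade}}.
#' @export
cladePlan <- function(n_strains = 7, n_core = 64) {
  list(n_strains = n_strains, n_core = n_core,
       core_len_range = c(60, 90),
       t = 0.04, kappa = 2, omega = 0.2,
       identity = 0.92,
       insertion_slots = c(36, 47, 58),
       complete_extra = 0:2,        # complete insertion size = 2 + extra
       solitary_size = 5:8,
       background_size = 2:5,
       deletion_slots = c(32, 42),
       inversion_len = 4,
       # non-overlapping per-strain inversion blocks in a dedicated zone:
       # overlapping inversions would genuinely destroy positional orthology
       # at the overlap, so the planted-core truth would no longer be
       # recoverable by construction
       inversion_starts = function(s) 2 + 4 * (s - 1))
}

#' Simulate a clade of strains from a common ancestor
#'
#' An ancestor of \code{n_core} genes evolves into \code{n_strains} star-tree
#' strains. Each strain receives: codon divergence of every retained
#' ancestral gene (\code{\link{evolveCodonSequence}} at the configured t,
#' kappa, omega); three accessory insertions between fixed consecutive
#' ancestral genes (one carrying a complete Type II system, one a solitary
#' MTase from an unrelated founder, one background-only; insertion sizes are
#' the true integration-region lengths); one deletion of an ancestral gene;
#' one inversion of a block of ancestral genes at a strain-specific position;
#' and one breakpoint-probe insertion (a solitary MTase) placed at a core
#' pair that another strain's inversion disrupts, so breakpoint flagging is
#' exercised. The truth lists the exact shared (core) gene set, every
#' insertion's region length and flanks, and all disrupted core pairs.
#'
#' @param lib reference library.
#' @param plan configuration (\code{\link{cladePlan}}).
#' @param seed RNG seed.
#' @param clade clade label.
#' @return list: gs (\linkS4class{GenomeSet}), truth (core_ids, regions,
#'   breakpoint_pairs, ancestor_ids, deleted).
#' @export
simulateClade <- function(lib, plan = cladePlan(), seed = 1,
                          clade = "cladeSim") {
  .with_seed(seed, {
    .set_active_library(lib)
    n_core <- plan$n_core
    anc_len <- sample(plan$core_len_range[1]:plan$core_len_range[2], n_core,
                      replace = TRUE)
    anc_dna <- vapply(anc_len, .random_codons, character(1))
    anc_ids <- sprintf("anc%03d", seq_len(n_core) - 1L)
    strains <- list(); region_rows <- list(); bp_pairs <- list()
    deleted_any <- character()
    inv_start <- vapply(seq_len(plan$n_strains), plan$inversion_starts,
                        numeric(1))
    for (s in seq_len(plan$n_strains)) {
      sid <- sprintf("s%02d", s)
      order_idx <- seq_len(n_core)   # modifications in ancestor-index space
      if (plan$inversion_len > 0) {
        a <- inv_start[s]; b <- a + plan$inversion_len - 1L
        stopifnot(b < n_core)
        order_idx[(a + 1):(b + 1)] <- rev(order_idx[(a + 1):(b + 1)])
        # disrupted core-order pairs from this strain's inversion
        bp_pairs[[s]] <- rbind(
          data.frame(f1 = anc_ids[a], f2 = anc_ids[a + 1], strain = sid),
          data.frame(f1 = anc_ids[b + 1], f2 = anc_ids[b + 2], strain = sid))
      }
      if (length(plan$deletion_slots)) {
        del <- plan$deletion_slots[(s - 1) %% length(plan$deletion_slots) + 1]
        deleted_any <- union(deleted_any, anc_ids[del + 1])
        order_idx <- order_idx[order_idx != del + 1]
      }
      # insertion plan: content class per fixed slot, shuffled per strain
      slots <- plan$insertion_slots
      classes <- if (length(slots))
        sample(c("complete", "solitary", "background"))[seq_along(slots)]
      else character(0)
      ins <- list()
      for (k in seq_along(slots))
        ins[[length(ins) + 1L]] <- list(slot = slots[k], class = classes[k])
      if (plan$inversion_len > 0) {
        sprev <- ((s - 2) %% plan$n_strains) + 1  # previous strain's inversion
        ins[[length(ins) + 1L]] <- list(slot = unname(inv_start[sprev] - 1L),
                                        class = "probe")
      }
      # build the strain gene list
      genes <- list()
      for (idx in order_idx) {
        dna <- evolveCodonSequence(anc_dna[idx], plan$t, plan$kappa,
                                   plan$omega)
        genes[[length(genes) + 1L]] <- c(
          .gene_record(.translate_cds(dna), dna),
          list(anc = anc_ids[idx]))
      }
      # insert accessory blocks after the gene with the slot's ancestor id
      for (insert in ins) {
        anchor <- anc_ids[insert$slot + 1]
        pos <- which(vapply(genes, function(g) identical(g$anc, anchor),
                            logical(1)))
        stopifnot(length(pos) == 1)
        blk <- .clade_insertion_block(lib, insert$class, plan, sid)
        for (j in seq_along(blk$genes))
          blk$genes[[j]]$anc <- NA_character_
        genes <- append(genes, blk$genes, after = pos)
        region_rows[[length(region_rows) + 1L]] <- data.frame(
          genome_id = sid, slot = insert$slot, class = blk$class_label,
          flank_left = anchor, flank_right = anc_ids[insert$slot + 2],
          length_genes = length(blk$genes),
          is_probe = insert$class == "probe", stringsAsFactors = FALSE)
      }
      rep <- .materialize_replicon(genes, sprintf("%s_chr", sid),
                                   "chromosome", circular = TRUE)
      # carry ancestor mapping into the truth
      rep$truth$ancestor_id <- vapply(genes, function(g)
        g$anc %||% NA_character_, character(1))
      rep$truth$genome_id <- sid
      strains[[sid]] <- list(
        genome = Genome(sid, clade, list(rep$replicon)), truth = rep$truth)
    }
    gs <- GenomeSet(lapply(strains, `[[`, "genome"))
    core_ids <- setdiff(anc_ids, deleted_any)
    bp <- do.call(rbind, bp_pairs)
    if (is.null(bp))
      bp <- data.frame(f1 = character(), f2 = character(), strain = character())
    regions <- do.call(rbind, region_rows)
    if (is.null(regions))
      regions <- data.frame(genome_id = character(), slot = integer(),
                            class = character(), flank_left = character(),
                            flank_right = character(), length_genes = integer(),
                            is_probe = logical())
    # a planted region is a truth breakpoint if its flank pair is disrupted
    # in at least one OTHER strain
    regions$breakpoint <- vapply(seq_len(nrow(regions)), function(i) {
      hit <- (bp$f1 == regions$flank_left[i] &
                bp$f2 == regions$flank_right[i]) |
        (bp$f2 == regions$flank_left[i] & bp$f1 == regions$flank_right[i])
      any(hit & bp$strain != regions$genome_id[i])
    }, logical(1))
    gene_truth <- do.call(rbind, lapply(strains, `[[`, "truth"))
    for (sid in names(strains))
      .validate_plant(strains[[sid]]$genome,
                      list(genes = strains[[sid]]$truth))
    list(gs = gs,
         truth = list(core_ids = core_ids, ancestor_ids = anc_ids,
                      deleted = deleted_any, regions = regions,
                      breakpoint_pairs = bp, genes = gene_truth))
  })
}

.clade_insertion_block <- function(lib, class, plan, sid) {
  if (class == "complete") {
    extra <- sample(plan$complete_extra, 1)
    genes <- c(list(
      .planted_gene(lib, "MTase_II_a", plan$identity, "MTase", "II",
                    paste0(sid, "_cins"), "system"),
      .planted_gene(lib, "REase_II_a", plan$identity, "REase", "II",
                    paste0(sid, "_cins"), "system")),
      replicate(extra, .background_gene(), simplify = FALSE))
    list(genes = genes, class_label = "complete")
  } else if (class == "solitary") {
    size <- sample(plan$solitary_size, 1)
    genes <- c(list(
      .planted_gene(lib, "MTase_II_b", plan$identity, "MTase", "II",
                    paste0(sid, "_sins"), "solitary")),
      replicate(size - 1, .background_gene(), simplify = FALSE))
    list(genes = genes, class_label = "solitary")
  } else if (class == "probe") {
    # a complete system placed at a core pair that another strain's inversion
    # disrupts, to exercise breakpoint flagging
    genes <- list(
      .planted_gene(lib, "MTase_II_a", plan$identity, "MTase", "II",
                    paste0(sid, "_probe"), "system"),
      .planted_gene(lib, "REase_II_a", plan$identity, "REase", "II",
                    paste0(sid, "_probe"), "system"))
    list(genes = genes, class_label = "complete")
  } else {
    size <- sample(plan$background_size, 1)
    list(genes = replicate(size, .background_gene(), simplify = FALSE),
         class_label = "background")
  }
}

## ---- lightweight statistical study generators ------------------------------

#' Simulate per-species integration-region tables for the direction test
#'
#' Emulates the planted insertion-size distributions of many species without
#' building full genomes: per species, region lengths for complete systems
#' and solitary genes are drawn from the clade generator's insertion-size
#' distributions (complete systems in shorter insertions). The output feeds
#' \code{\link{compareRegionSizes}} directly.
#'
#' @param n_species number of species.
#' @param n_each regions per class per species.
#' @param complete_sizes,solitary_sizes planted insertion-size supports.
#' @param seed RNG seed.
#' @return integration-region table with a species column.
#' @export
simulateRegionStudy <- function(n_species = 10, n_each = 3,
                                complete_sizes = 2:4, solitary_sizes = 5:8,
                                seed = 1) {
  .with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%02d", s)
      for (k in seq_len(n_each)) {
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = sprintf("%s_c%d", sp, k), species = sp,
          class = "complete",
          length_genes = sample(complete_sizes, 1),
          breakpoint = FALSE, excluded = FALSE, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = sprintf("%s_s%d", sp, k), species = sp,
          class = "solitary",
          length_genes = sample(solitary_sizes, 1),
          breakpoint = FALSE, excluded = FALSE, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate system locations placed uniformly across MGE categories
#'
#' Null model for the enrichment analysis: each system's category is drawn
#' independently of its type, so observed/expected ratios fluctuate around 1
#' by multinomial sampling only.
#'
#' @param n_systems number of systems.
#' @param type_probs named probabilities over R-M types.
#' @param category_probs named probabilities over location categories.
#' @param seed RNG seed.
#' @return data.frame(rm_type, category) suitable for
#'   \code{\link{enrichmentFromLocations}}.
#' @export
simulateUniformPlacement <- function(n_systems = 200,
                                     type_probs = c(I = 0.3, II = 0.4,
                                                    IIC = 0.1, III = 0.1,
                                                    IV = 0.1),
                                     category_probs = c(chromosome = 0.7,
                                                        plasmid = 0.1,
                                                        prophage = 0.1,
                                                        ICE_IME = 0.1),
                                     seed = 1) {
  .with_seed(seed, data.frame(
    rm_type = sample(names(type_probs), n_systems, replace = TRUE,
                     prob = type_probs),
    category = sample(names(category_probs), n_systems, replace = TRUE,
                      prob = category_probs),
    stringsAsFactors = FALSE))
}
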