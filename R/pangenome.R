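## Positional-orthology core genomes, dual-threshold pan-genome families,
## R-M family classification and integration-region analysis.

.proteome <- function(genome) {
  gt <- geneTable(genome)
  setNames(gt$protein, gt$gene_id)
}

.gene_geometry <- function(genome) {
  gt <- geneTable(genome)
  geo <- list()
  for (r in replicons(genome))
    geo[[repliconId(r)]] <- list(n = nGenes(r), circular = isCircular(r))
  list(replicon = setNames(gt$replicon_id, gt$gene_id),
       rank = setNames(gt$rank, gt$gene_id), geo = geo)
}

#' Positional orthologs between two genomes
#'
#' Bidirectional best hits (end-gap-free global alignment, at least
#' \code{min_similarity} similarity, at most \code{max_length_diff} relative
#' length difference) retained only when supported by conserved gene
#' neighborhood: at least \code{min_support} other BBH pairs must lie within
#' \code{window} genes (upstream or downstream) of both members. Requiring
#' support around both members, with the support threshold below half the
#' neighborhood diameter, keeps orthologs at rearrangement-block edges.
#'
#' @param genome_a,genome_b \linkS4class{Genome} objects.
#' @param min_similarity,max_length_diff BBH filters.
#' @param window neighborhood half-width in genes (5 up, 5 down).
#' @param min_support minimum number of supporting BBH pairs.
#' @return data.frame: gene_a, gene_b, similarity, length_diff,
#'   synteny_support.
#' @export
positionalOrthologs <- function(genome_a, genome_b, min_similarity = 0.8,
                                max_length_diff = 0.2, window = 5,
                                min_support = 4) {
  bbh <- bbhPairs(.proteome(genome_a), .proteome(genome_b),
                  min_similarity, max_length_diff)
  if (!nrow(bbh)) {
    bbh$synteny_support <- integer(0)
    return(bbh[, c("gene_a", "gene_b", "similarity", "length_diff",
                   "synteny_support")])
  }
  ga <- .gene_geometry(genome_a); gb <- .gene_geometry(genome_b)
  ra <- ga$rank[bbh$gene_a]; rb <- gb$rank[bbh$gene_b]
  pa <- ga$replicon[bbh$gene_a]; pb <- gb$replicon[bbh$gene_b]
  P <- nrow(bbh)
  support <- integer(P)
  for (i in seq_len(P)) {
    geoa <- ga$geo[[pa[i]]]; geob <- gb$geo[[pb[i]]]
    same_a <- pa == pa[i]; same_b <- pb == pb[i]
    da <- rep(Inf, P); db <- rep(Inf, P)
    da[same_a] <- rankDistance(ra[same_a], ra[i], geoa$n, geoa$circular)
    db[same_b] <- rankDistance(rb[same_b], rb[i], geob$n, geob$circular)
    support[i] <- sum(da <= window & db <= window) - 1L  # exclude self
  }
  bbh$synteny_support <- support
  out <- bbh[support >= min_support,
             c("gene_a", "gene_b", "similarity", "length_diff",
               "synteny_support"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core genome by intersection of pairwise positional-ortholog lists
#'
#' The pivot genome is compared to every other strain; core genes are the
#' pivot genes with a positional ortholog in all of them. The returned core
#' map gives, for every core gene, its gene id, replicon and rank in every
#' strain (including the pivot).
#'
#' @param gs \linkS4class{GenomeSet} (a warning is issued below
#'   \code{min_strains} genomes).
#' @param pivot genome id; defaults to the lexicographically first.
#' @param min_strains advisory minimum number of strains.
#' @param ... passed to \code{\link{positionalOrthologs}}.
#' @return data.frame: core_id, genome_id, gene_id, replicon_id, rank.
#' @export
coreGenome <- function(gs, pivot = NULL, min_strains = 7, ...) {
  ids <- sort(names(gs@genomes))
  if (is.null(pivot)) pivot <- ids[1]
  if (!pivot %in% ids) stop("pivot genome not in set: ", pivot)
  if (length(ids) < min_strains)
    warning("core genome built from only ", length(ids), " strains")
  others <- setdiff(ids, pivot)
  maps <- list()
  for (oid in others) {
    po <- positionalOrthologs(gs[[pivot]], gs[[oid]], ...)
    maps[[oid]] <- setNames(po$gene_b, po$gene_a)
  }
  core_ids <- Reduce(intersect, c(list(names(.proteome(gs[[pivot]]))),
                                  lapply(maps, names)))
  core_ids <- sort(core_ids)
  rows <- list()
  geo_cache <- lapply(gs@genomes, .gene_geometry)
  add_row <- function(core_id, gid, gene_id) {
    geo <- geo_cache[[gid]]
    rows[[length(rows) + 1L]] <<- data.frame(
      core_id = core_id, genome_id = gid, gene_id = gene_id,
      replicon_id = unname(geo$replicon[gene_id]),
      rank = unname(geo$rank[gene_id]), stringsAsFactors = FALSE)
  }
  for (cid in core_ids) {
    add_row(cid, pivot, cid)
    for (oid in others) add_row(cid, oid, unname(maps[[oid]][cid]))
  }
  if (!length(rows))
    return(data.frame(core_id = character(), genome_id = character(),
                      gene_id = character(), replicon_id = character(),
                      rank = integer()))
  do.call(rbind, rows)
}

#' Pan-genome families by single-linkage clustering
#'
#' All-vs-all local alignment hits (e-value surrogate below
#' \code{evalue_max}) are thresholded at \code{identity_min} identity over an
#' aligned part covering more than \code{coverage_min} of the smallest
#' protein, then single-linkage clustered. Two standard settings are the
#' stringent (identity 0.8) and relaxed (identity 0.4) pan-genomes; stringent
#' families always refine relaxed ones. A family is persistent when present
#' in at least a third of the strains.
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param identity_min identity threshold (0.8 stringent, 0.4 relaxed).
#' @param coverage_min coverage-of-smallest threshold (strictly greater).
#' @param evalue_max e-value surrogate gate.
#' @param hits optional precomputed all-vs-all hit table to reuse across the
#'   two thresholds.
#' @return list: families (data.frame: family_id, genome_id, gene_id,
#'   strain_presence, persistent), hits (the hit table used).
#' @export
panFamilies <- function(gs, identity_min = 0.8, coverage_min = 0.8,
                        evalue_max = 1e-4, hits = NULL) {
  gt <- geneTable(gs)
  seqs <- setNames(gt$protein, gt$gene_id)
  if (anyDuplicated(names(seqs)))
    stop("gene ids must be unique across the GenomeSet")
  if (is.null(hits)) hits <- allVsAllHits(seqs, mode = "local")
  fam <- singleLinkageFamilies(hits, ids = names(seqs), identity_min,
                               coverage_min, evalue_max)
  fam$genome_id <- gt$genome_id[match(fam$member_id, gt$gene_id)]
  n_strains <- length(gs)
  pres <- tapply(fam$genome_id, fam$family_id,
                 function(g) length(unique(g)) / n_strains)
  fam$strain_presence <- as.numeric(pres[fam$family_id])
  fam$persistent <- fam$strain_presence >= 1 / 3
  names(fam)[names(fam) == "member_id"] <- "gene_id"
  list(families = fam[, c("family_id", "genome_id", "gene_id",
                          "strain_presence", "persistent")],
       hits = hits)
}

#' Classify pan-genome families by their R-M gene content
#'
#' Families are labeled \code{complete_only} (members only from complete
#' systems), \code{solitary_only}, \code{mixed} (both) or \code{none}. The
#' headline fractions are the share of complete-system-containing families
#' that also include a solitary gene from another genome, and the symmetric
#' share among solitary-containing families. When a core map is supplied,
#' core placement reports the fraction of complete systems whose component
#' genes are all core genes (positional core membership); without one it is
#' NA.
#'
#' @param pan result of \code{\link{panFamilies}}.
#' @param detection result of \code{\link{detectRMSystems}}.
#' @param core_map optional core map from \code{\link{coreGenome}}.
#' @return list: family_content, summary (fractions), per-family table.
#' @export
classifyRMFamilies <- function(pan, detection, core_map = NULL) {
  fam <- pan$families
  systems <- detection$systems[!detection$systems$mixed &
                                 detection$systems$complete, , drop = FALSE]
  comp_genes <- detection$components$gene_id[
    detection$components$system_id %in% systems$system_id]
  sol_genes <- detection$solitary$gene_id
  has_c <- tapply(fam$gene_id %in% comp_genes, fam$family_id, any)
  has_s <- tapply(fam$gene_id %in% sol_genes, fam$family_id, any)
  content <- ifelse(has_c & has_s, "mixed",
                    ifelse(has_c, "complete_only",
                           ifelse(has_s, "solitary_only", "none")))
  ftab <- data.frame(family_id = names(content), rm_content = as.character(content),
                     stringsAsFactors = FALSE)
  n_cfam <- sum(has_c); n_sfam <- sum(has_s)
  frac_c_mixed <- if (n_cfam) sum(has_c & has_s) / n_cfam else NA_real_
  frac_s_mixed <- if (n_sfam) sum(has_c & has_s) / n_sfam else NA_real_
  # core placement of complete systems (positional core membership)
  in_core <- if (is.null(core_map)) NA else vapply(
    systems$system_id, function(sid) {
      gids <- detection$components$gene_id[
        detection$components$system_id == sid]
      all(gids %in% core_map$gene_id)
    }, logical(1))
  list(family_content = ftab,
       summary = data.frame(
         n_families_with_complete = n_cfam,
         n_families_with_solitary = n_sfam,
         fraction_complete_families_mixed = frac_c_mixed,
         fraction_solitary_families_mixed = frac_s_mixed,
         fraction_systems_in_core =
           if (nrow(systems) && !anyNA(in_core)) mean(in_core) else NA_real_))
}

#' R-M elements (complete systems and solitary genes) for region analysis
#'
#' @param detection result of \code{\link{detectRMSystems}}.
#' @return data.frame: element_id, genome_id, replicon_id, min_rank,
#'   max_rank, class.
#' @export
rmElements <- function(detection) {
  sys <- detection$systems[!detection$systems$mixed &
                             detection$systems$complete, , drop = FALSE]
  sol <- detection$solitary
  rbind(
    data.frame(element_id = sys$system_id, genome_id = sys$genome_id,
               replicon_id = sys$replicon_id, min_rank = sys$min_rank,
               max_rank = sys$max_rank, class = "complete",
               stringsAsFactors = FALSE),
    data.frame(element_id = sol$gene_id, genome_id = sol$genome_id,
               replicon_id = sol$replicon_id, min_rank = sol$rank,
               max_rank = sol$rank, class = "solitary",
               stringsAsFactors = FALSE))
}

# Adjacency of two core genes in one genome's core order (per replicon,
# cyclic on circular replicons).
.core_adjacent <- function(core_map, gid, f1, f2, geo_map) {
  cm <- core_map[core_map$genome_id == gid, , drop = FALSE]
  r1 <- cm[cm$core_id == f1, , drop = FALSE]
  r2 <- cm[cm$core_id == f2, , drop = FALSE]
  if (!nrow(r1) || !nrow(r2)) return(NA)
  if (r1$replicon_id != r2$replicon_id) return(FALSE)
  on_rep <- cm[cm$replicon_id == r1$replicon_id, , drop = FALSE]
  ord <- on_rep$core_id[order(on_rep$rank)]
  i1 <- match(f1, ord); i2 <- match(f2, ord)
  k <- length(ord)
  circ <- geo_map[[r1$replicon_id]] %||% TRUE
  d <- abs(i1 - i2)
  if (circ) d <- min(d, k - d)
  d == 1
}

#' Integration regions of R-M elements between consecutive core genes
#'
#' For each element the flanking pair of consecutive core genes in its genome
#' is found; the region length L is the number of genes strictly between the
#' flanks. Regions whose flanking core genes are not consecutive core genes
#' in at least one other strain lie at rearrangement breakpoints: they are
#' flagged and excluded from size statistics. Elements not strictly between
#' two core genes (terminal on a linear replicon, overlapping a core gene, or
#' on a replicon with fewer than two core genes) are flagged with a reason
#' and excluded.
#'
#' @param elements element table (\code{\link{rmElements}} schema).
#' @param core_map core map from \code{\link{coreGenome}}.
#' @param gs \linkS4class{GenomeSet}.
#' @return data.frame: element_id, genome_id, replicon_id, class, flank_left,
#'   flank_right, length_genes, breakpoint, excluded, reason.
#' @export
integrationRegions <- function(elements, core_map, gs) {
  geo_map <- list()
  for (g in gs@genomes) for (r in replicons(g))
    geo_map[[repliconId(r)]] <- isCircular(r)
  rows <- list()
  genome_ids <- unique(core_map$genome_id)
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    res <- data.frame(element_id = el$element_id, genome_id = el$genome_id,
                      replicon_id = el$replicon_id, class = el$class,
                      flank_left = NA_character_, flank_right = NA_character_,
                      length_genes = NA_integer_, breakpoint = FALSE,
                      excluded = TRUE, reason = "", stringsAsFactors = FALSE)
    cm <- core_map[core_map$genome_id == el$genome_id &
                     core_map$replicon_id == el$replicon_id, , drop = FALSE]
    if (nrow(cm) < 2) {
      res$reason <- "fewer_than_two_core_genes"
      rows[[i]] <- res; next
    }
    cm <- cm[order(cm$rank), , drop = FALSE]
    rep <- getReplicon(gs, el$replicon_id)
    n <- nGenes(rep); circ <- isCircular(rep)
    if (any(cm$rank >= el$min_rank & cm$rank <= el$max_rank)) {
      res$reason <- "overlaps_core_gene"
      rows[[i]] <- res; next
    }
    below <- cm[cm$rank < el$min_rank, , drop = FALSE]
    above <- cm[cm$rank > el$max_rank, , drop = FALSE]
    if ((!nrow(below) || !nrow(above)) && !circ) {
      res$reason <- "terminal_on_linear_replicon"
      rows[[i]] <- res; next
    }
    left <- if (nrow(below)) below[nrow(below), ] else cm[nrow(cm), ]  # wrap
    right <- if (nrow(above)) above[1, ] else cm[1, ]
    L <- (right$rank - left$rank - 1L) %% n
    res$flank_left <- left$core_id; res$flank_right <- right$core_id
    res$length_genes <- as.integer(L)
    bp <- FALSE
    for (gid in setdiff(genome_ids, el$genome_id)) {
      adj <- .core_adjacent(core_map, gid, left$core_id, right$core_id, geo_map)
      if (isFALSE(adj)) { bp <- TRUE; break }
    }
    res$breakpoint <- bp
    res$excluded <- bp
    res$reason <- if (bp) "breakpoint_flanks" else "ok"
    rows[[i]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(), genome_id = character(),
               replicon_id = character(), class = character(),
               flank_left = character(), flank_right = character(),
               length_genes = integer(), breakpoint = logical(),
               excluded = logical(), reason = character())
  rownames(out) <- NULL
  out
}

#' Compare integration-region sizes of complete systems versus solitary genes
#'
#' Within each species, the median region length is computed separately for
#' complete systems and solitary genes (breakpoint and otherwise excluded
#' regions dropped); species where both classes occur are scored for the
#' direction median(complete) < median(solitary). A one-sided binomial test
#' against chance (p0 = 0.5) is applied to the number of agreeing species
#' (ties dropped).
#'
#' @param regions integration-region table carrying a \code{species} column
#'   (e.g. the clade label) in addition to the
#'   \code{\link{integrationRegions}} schema.
#' @return list: per_species (species, median_complete, median_solitary,
#'   direction), n_species, n_smaller_complete, test (binomial TestResult).
#' @export
compareRegionSizes <- function(regions) {
  ok <- regions[!regions$excluded & !regions$breakpoint &
                  !is.na(regions$length_genes), , drop = FALSE]
  if (!nrow(ok) || !"species" %in% names(regions)) {
    warning("no qualifying regions for size comparison")
    return(list(per_species = data.frame(), n_species = 0L,
                n_smaller_complete = 0L, test = NULL))
  }
  per <- do.call(rbind, lapply(split(ok, ok$species), function(d) {
    mc <- median(d$length_genes[d$class == "complete"])
    ms <- median(d$length_genes[d$class == "solitary"])
    data.frame(species = d$species[1], median_complete = mc,
               median_solitary = ms,
               direction = if (is.na(mc) || is.na(ms)) NA_character_
                           else if (mc < ms) "complete_smaller"
                           else if (mc > ms) "solitary_smaller" else "tie",
               stringsAsFactors = FALSE)
  }))
  per <- per[!is.na(per$direction), , drop = FALSE]
  informative <- per[per$direction != "tie", , drop = FALSE]
  k <- sum(informative$direction == "complete_smaller")
  n <- nrow(informative)
  test <- if (n > 0) binomialTest(k, n, 0.5, alternative = "greater") else NULL
  list(per_species = per, n_species = n, n_smaller_complete = k, test = test)
}
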