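#' Run the full R-M comparative-genomics pipeline on a dataset
#'
#' Role assignment, system and solitary detection, census, co-localization,
#' plasmid MOB typing, integron and competence detection, spacer matching and
#' MGE enrichment, returned as a named list of flat tables ready for
#' \code{\link{exportReport}}.
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param reference labeled reference library.
#' @param mges MGE span table (may be empty).
#' @param spacers named DNA vector of CRISPR spacers (may be NULL).
#' @param max_gap,solitary_gap,coloc_neighborhood thresholds.
#' @return named list of data.frames (plus \code{detection} with the raw
#'   detection lists, not exported as a table).
#' @export
runPipeline <- function(gs, reference, mges = NULL, spacers = NULL,
                        max_gap = 4, solitary_gap = 10,
                        coloc_neighborhood = 10) {
  roles <- assignRolesGenomeSet(gs, reference)
  roles <- roles[order(roles$genome_id, roles$replicon_id, roles$rank), ]
  rownames(roles) <- NULL
  detection <- detectRMSystems(gs, roles, max_gap, solitary_gap)
  census <- rmCensus(gs, detection)
  coloc <- colocalizationPairs(detection, gs, coloc_neighborhood)
  mob <- classifyMobGenomeSet(gs, roles)
  integrons <- list(); competence <- list()
  for (g in gs@genomes) for (r in replicons(g)) {
    rl <- roles[roles$genome_id == genomeId(g) &
                  roles$replicon_id == repliconId(r), , drop = FALSE]
    ig <- detectIntegrons(r, rl)
    if (nrow(ig)) {
      ig$genome_id <- genomeId(g)
      integrons[[length(integrons) + 1L]] <- ig
    }
    cl <- detectCompetenceLoci(r, rl, "positive")
    if (nrow(cl)) {
      cl$genome_id <- genomeId(g)
      competence[[length(competence) + 1L]] <- cl
    }
  }
  integrons <- if (length(integrons)) do.call(rbind, integrons) else
    data.frame(replicon_id = character(), gene_id = character(),
               rank = integer(), genome_id = character())
  competence <- if (length(competence)) do.call(rbind, competence) else
    data.frame(replicon_id = character(), locus_id = character(),
               start_rank = integer(), end_rank = integer(),
               n_genes = integer(), components = character(),
               complete_mandatory = logical(), genome_id = character())
  spacer_matches <- NULL
  if (!is.null(spacers) && length(spacers)) {
    rm_gene_ids <- unique(c(detection$components$gene_id,
                            detection$solitary$gene_id))
    gt <- geneTable(gs)
    targets <- setNames(gt$dna, gt$gene_id)[rm_gene_ids]
    targets <- targets[!is.na(targets)]
    spacer_matches <- matchSpacers(spacers, targets)
  }
  enrichment <- NULL
  if (!is.null(mges))
    enrichment <- mgeEnrichment(detection, gs, mges)
  tables <- list(
    roles = roles,
    systems = detection$systems,
    components = detection$components,
    solitary = detection$solitary,
    ambiguous = detection$ambiguous,
    census_per_genome = census$per_genome,
    census_per_clade = census$per_clade,
    census_per_replicon_kind = census$per_replicon_kind,
    census_solitary_tallies = census$solitary_tallies,
    census_totals = census$totals,
    colocalization_pairs = coloc$pairs,
    colocalization_summary = data.frame(
      neighborhood = coloc_neighborhood,
      fraction_colocalized = coloc$fraction_colocalized,
      fraction_colocalized_multi = coloc$fraction_colocalized_multi,
      n_systems = coloc$n_systems),
    mob = mob, integrons = integrons, competence = competence)
  if (!is.null(spacer_matches)) tables$spacer_matches <- spacer_matches
  if (!is.null(enrichment)) {
    tables$mge_enrichment <- enrichment$enrichment
    tables$mge_densities <- enrichment$densities
    tables$system_locations <- enrichment$locations
  }
  c(tables, list(detection = detection))
}

#' Export pipeline tables to a report directory
#'
#' @param results list from \code{\link{runPipeline}}.
#' @param out_dir output directory.
#' @param config configuration list recorded in the manifest.
#' @return invisibly, the manifest.
#' @export
exportPipelineReport <- function(results, out_dir, config = list()) {
  tables <- Filter(is.data.frame, results)
  exportReport(tables, out_dir, config)
}
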