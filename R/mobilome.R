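## Plasmid mobility typing, integron and competence locus detection, CRISPR
## spacer matching and R-M enrichment in mobile genetic elements.

#' Classify a plasmid as MOB+ or MOB-
#'
#' MOB+ plasmids encode at least a relaxase (mobilizable in trans) or a
#' complete conjugation gene set; all other plasmids are MOB-.
#'
#' @param plasmid a \linkS4class{Replicon} of kind \code{"plasmid"}.
#' @param roles role table covering this replicon's genes.
#' @param conjugation_set role labels that together form a complete
#'   conjugation machinery.
#' @return \code{"MOB_plus"} or \code{"MOB_minus"}.
#' @export
classifyPlasmidMob <- function(plasmid, roles,
                               conjugation_set = c("conjugation:T4CP",
                                                   "conjugation:MPF")) {
  if (repliconKind(plasmid) != "plasmid")
    stop("classifyPlasmidMob is defined for plasmids only, got ",
         repliconKind(plasmid))
  rl <- roles[roles$gene_id %in% plasmid@genes$gene_id, , drop = FALSE]
  has_relaxase <- any(rl$role == "relaxase")
  has_conj <- all(conjugation_set %in% rl$role)
  if (has_relaxase || has_conj) "MOB_plus" else "MOB_minus"
}

#' MOB classification for every plasmid of a GenomeSet
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param roles role table from \code{\link{assignRolesGenomeSet}}.
#' @param conjugation_set see \code{\link{classifyPlasmidMob}}.
#' @return data.frame: genome_id, replicon_id, size_mb, mob.
#' @export
classifyMobGenomeSet <- function(gs, roles,
                                 conjugation_set = c("conjugation:T4CP",
                                                     "conjugation:MPF")) {
  rows <- list()
  for (g in gs@genomes) for (r in replicons(g)) {
    if (repliconKind(r) != "plasmid") next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genomeId(g), replicon_id = repliconId(r),
      size_mb = r@lengthBp / 1e6,
      mob = classifyPlasmidMob(r, roles, conjugation_set),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), replicon_id = character(),
               size_mb = numeric(), mob = character())
}

#' Detect integron loci
#'
#' An integron integrase is called at genes that simultaneously pass the
#' tyrosine-recombinase references and the integron-specific signature
#' references; either signal alone is not enough.
#'
#' @param replicon a \linkS4class{Replicon}.
#' @param roles role table with \code{has_integrase_tyr} and
#'   \code{has_integron_signature} columns.
#' @return data.frame: replicon_id, gene_id, rank.
#' @export
detectIntegrons <- function(replicon, roles) {
  rl <- roles[roles$gene_id %in% replicon@genes$gene_id, , drop = FALSE]
  hit <- rl$has_integrase_tyr & rl$has_integron_signature
  data.frame(replicon_id = rep(repliconId(replicon), sum(hit)),
             gene_id = rl$gene_id[hit], rank = rl$rank[hit],
             stringsAsFactors = FALSE)
}

#' Competence machinery component sets
#'
#' Mandatory components are all listed components except the facultative ones
#' (PilU for Gram-negative, ComC for Gram-positive).
#'
#' @param gram \code{"positive"} or \code{"negative"}.
#' @return list with \code{components} and \code{facultative} role labels.
#' @export
competenceComponents <- function(gram = c("positive", "negative")) {
  gram <- match.arg(gram)
  if (gram == "positive")
    list(components = paste0("competence:", c("ComEA", "ComEC", "ComFA",
                                              "ComGA", "ComGB", "ComGC",
                                              "ComC", "DprA")),
         facultative = "competence:ComC")
  else
    list(components = paste0("competence:", c("PilA", "PilC", "PilD", "PilM",
                                              "PilN", "PilO", "PilP", "PilQ",
                                              "PilT", "PilU")),
         facultative = "competence:PilU")
}

#' Detect natural-transformation (competence) loci
#'
#' A locus is a maximal run of competence-component genes in which
#' consecutive members lie at most \code{max_gap} genes apart, carrying at
#' least \code{min_genes} members, and whose mandatory component set (all
#' components except the facultative ones) is complete.
#'
#' @param replicon a \linkS4class{Replicon}.
#' @param roles role table.
#' @param gram Gram stain of the configured component set.
#' @param max_gap maximum rank offset between consecutive locus genes.
#' @param min_genes minimum number of member genes.
#' @return data.frame: replicon_id, locus_id, start_rank, end_rank, n_genes,
#'   components, complete_mandatory.
#' @export
detectCompetenceLoci <- function(replicon, roles,
                                 gram = c("positive", "negative"),
                                 max_gap = 5, min_genes = 6) {
  cfg <- competenceComponents(gram)
  rl <- roles[roles$gene_id %in% replicon@genes$gene_id, , drop = FALSE]
  rl <- rl[rl$role %in% cfg$components, , drop = FALSE]
  rl <- rl[order(rl$rank), , drop = FALSE]
  out <- data.frame(replicon_id = character(), locus_id = character(),
                    start_rank = integer(), end_rank = integer(),
                    n_genes = integer(), components = character(),
                    complete_mandatory = logical(), stringsAsFactors = FALSE)
  if (!nrow(rl)) return(out)
  grp <- cumsum(c(1L, as.integer(diff(rl$rank) > max_gap)))
  mandatory <- setdiff(cfg$components, cfg$facultative)
  k <- 0L
  for (run in split(rl, grp)) {
    ok_n <- nrow(run) >= min_genes
    ok_mand <- all(mandatory %in% run$role)
    if (ok_n && ok_mand) {
      k <- k + 1L
      out <- rbind(out, data.frame(
        replicon_id = repliconId(replicon),
        locus_id = sprintf("%s|com%02d", repliconId(replicon), k),
        start_rank = min(run$rank), end_rank = max(run$rank),
        n_genes = nrow(run), components = paste(run$role, collapse = ","),
        complete_mandatory = TRUE, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Per-genome competence repertoire flag
#'
#' TRUE when the genome carries at least one detected competence locus.
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param roles role table.
#' @param gram,max_gap,min_genes see \code{\link{detectCompetenceLoci}}.
#' @return named logical vector keyed by genome_id.
#' @export
competenceFlags <- function(gs, roles, gram = "positive", max_gap = 5,
                            min_genes = 6) {
  vapply(gs@genomes, function(g) {
    any(vapply(replicons(g), function(r) {
      rl <- roles[roles$genome_id == genomeId(g) &
                    roles$replicon_id == repliconId(r), , drop = FALSE]
      nrow(detectCompetenceLoci(r, rl, gram, max_gap, min_genes)) > 0
    }, logical(1)))
  }, logical(1))
}

## ---- CRISPR spacer matching ------------------------------------------------

.dna_submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                         baseOnly = FALSE)
    m
  }
})

#' Match CRISPR spacers against R-M gene sequences
#'
#' Each spacer is compared to each target gene on both strands with ungapped
#' local alignment (gaps are effectively forbidden by an extreme gap
#' penalty). Identity is computed over the aligned span; the length
#' difference is the unaligned fraction of the spacer,
#' \code{(spacer length - span) / spacer length}. Matches with identity of at
#' least \code{min_identity} and length difference strictly below
#' \code{max_length_diff} are retained; exact (identity 1 over the full
#' spacer) matches are flagged separately since both tiers are reported.
#'
#' @param spacers named character vector of spacer DNA sequences.
#' @param targets named character vector of gene DNA sequences.
#' @param min_identity retention threshold on identity.
#' @param max_length_diff retention threshold on relative length difference.
#' @return data.frame: spacer_id, gene_id, strand, identity, length_diff,
#'   retained, exact.
#' @export
matchSpacers <- function(spacers, targets, min_identity = 0.9,
                         max_length_diff = 0.1) {
  stopifnot(length(spacers) > 0, length(targets) > 0)
  rows <- list()
  tset <- DNAStringSet(toupper(targets))
  for (si in seq_along(spacers)) {
    sp <- DNAString(toupper(spacers[[si]]))
    qlen <- length(sp)
    for (strand in c("+", "-")) {
      query <- if (strand == "+") sp else reverseComplement(sp)
      for (ti in seq_along(tset)) {
        al <- pairwiseAlignment(query, tset[[ti]], type = "local",
                                substitutionMatrix = .dna_submat(),
                                gapOpening = 1e6, gapExtension = 1e6)
        span <- Biostrings::width(Biostrings::pattern(al))
        if (span == 0) next
        ident <- Biostrings::nmatch(al) / span
        ldiff <- (qlen - span) / qlen
        rows[[length(rows) + 1L]] <- data.frame(
          spacer_id = names(spacers)[si], gene_id = names(targets)[ti],
          strand = strand, identity = ident, length_diff = ldiff,
          retained = ident >= min_identity & ldiff < max_length_diff,
          exact = ident == 1 & span == qlen, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  # keep the better strand per spacer x gene
  out <- out[order(out$spacer_id, out$gene_id, -out$identity * (1 - out$length_diff),
                   out$strand), , drop = FALSE]
  out <- out[!duplicated(out[c("spacer_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- MGE annotation and enrichment -----------------------------------------

#' Read a BED-like MGE annotation table
#'
#' Tab-separated with header: mge_id, replicon_id, start_rank, end_rank, kind
#' (prophage, ICE or IME). Spans are gene-rank intervals, inclusive.
#'
#' @param path TSV path.
#' @return data.frame of MGE spans.
#' @export
readMgeTable <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("mge_id", "replicon_id", "start_rank", "end_rank", "kind")
  if (!all(need %in% names(tab)))
    stop("MGE table must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(tab$kind %in% c("prophage", "ICE", "IME")))
  tab
}

# Category of a system/solitary location: smallest enclosing MGE span, else
# plasmid (replicon kind), else chromosome. A system straddling an MGE
# boundary counts as chromosomal (conservative) and is flagged.
.locate_element <- function(replicon_id, min_rank, max_rank, mges, kind_map) {
  m <- mges[mges$replicon_id == replicon_id, , drop = FALSE]
  inside <- m[m$start_rank <= min_rank & max_rank <= m$end_rank, , drop = FALSE]
  straddle <- FALSE
  if (!nrow(inside) && nrow(m)) {
    overlaps <- m[pmax(m$start_rank, min_rank) <= pmin(m$end_rank, max_rank), ,
                  drop = FALSE]
    straddle <- nrow(overlaps) > 0
  }
  if (nrow(inside)) {
    if (nrow(inside) > 1) {
      warning("overlapping MGE spans on ", replicon_id,
              "; assigning to smallest enclosing span")
      inside <- inside[order(inside$end_rank - inside$start_rank), , drop = FALSE]
    }
    cat_ <- if (inside$kind[1] == "prophage") "prophage" else "ICE_IME"
    return(list(category = cat_, mge_id = inside$mge_id[1], straddle = FALSE))
  }
  k <- kind_map[[replicon_id]] %||% "chromosome"
  cat_ <- if (k == "plasmid") "plasmid" else if (k == "phage") "phage" else "chromosome"
  list(category = cat_, mge_id = NA_character_, straddle = straddle)
}

#' Observed/expected enrichment from located systems
#'
#' Given one located system per row (R-M type and location category), the
#' expected count for a type x category cell is the type total multiplied by
#' the fraction of all systems falling in that category; O/E is their ratio.
#' A chi-square goodness-of-fit p-value is attached per category (observed
#' counts across types against the expected split).
#'
#' @param locations data.frame with columns \code{rm_type} and
#'   \code{category}.
#' @param categories category universe (defaults to those present).
#' @return list: enrichment (rm_type, category, observed, expected, oe_ratio,
#'   chi2_p), category_fractions.
#' @export
enrichmentFromLocations <- function(locations, categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(locations$category))
  total <- nrow(locations)
  frac <- vapply(categories,
                 function(cc) sum(locations$category == cc) / max(total, 1),
                 numeric(1))
  rows <- list()
  for (tt in unique(locations$rm_type)) {
    n_type <- sum(locations$rm_type == tt)
    for (cc in categories) {
      obs <- sum(locations$rm_type == tt & locations$category == cc)
      expct <- n_type * frac[[cc]]
      rows[[length(rows) + 1L]] <- data.frame(
        rm_type = tt, category = cc, observed = obs, expected = expct,
        oe_ratio = if (expct > 0) obs / expct else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  enr <- do.call(rbind, rows)
  if (is.null(enr))
    enr <- data.frame(rm_type = character(), category = character(),
                      observed = numeric(), expected = numeric(),
                      oe_ratio = numeric())
  enr$chi2_p <- NA_real_
  for (cc in unique(enr$category)) {
    sel <- enr$category == cc
    o <- enr$observed[sel]; e <- enr$expected[sel]
    keep <- e > 0
    if (sum(keep) >= 2 && sum(o[keep]) > 0) {
      tr <- chiSquareTest(o[keep], e[keep] * sum(o[keep]) / sum(e[keep]))
      enr$chi2_p[sel] <- tr$p_value
    }
  }
  list(enrichment = enr,
       category_fractions = data.frame(category = categories,
                                       fraction = as.numeric(frac),
                                       row.names = NULL))
}

#' R-M enrichment in mobile genetic elements
#'
#' Each system (and solitary gene) is located in one category: prophage or
#' ICE/IME when all its component ranks fall inside an annotated span,
#' plasmid or phage by replicon kind, chromosome otherwise. Expected counts
#' per R-M type and category follow the observed/expected construction:
#' expected = total systems of the type x fraction of all systems in the
#' category, so O/E measures over- or under-representation. A chi-square
#' goodness-of-fit p-value is reported per category (observed counts across
#' types against expected). Per-Mb densities by element class are included;
#' chromosomal solitary tallies exclude prophage-resident genes, which are
#' tallied with their prophage.
#'
#' @param detection result of \code{\link{detectRMSystems}}.
#' @param gs \linkS4class{GenomeSet}.
#' @param mges MGE span table (\code{\link{readMgeTable}} schema).
#' @return list: enrichment (rm_type x category with observed, expected,
#'   oe_ratio, chi2_p), locations (per system), solitary_locations,
#'   densities (per category), category_fractions.
#' @export
mgeEnrichment <- function(detection, gs, mges) {
  systems <- detection$systems[!detection$systems$mixed, , drop = FALSE]
  systems <- systems[systems$complete, , drop = FALSE]
  kind_map <- list(); mb_map <- list()
  coord_mb <- list()
  for (g in gs@genomes) for (r in replicons(g)) {
    kind_map[[repliconId(r)]] <- repliconKind(r)
    mb_map[[repliconId(r)]] <- r@lengthBp / 1e6
    coord_mb[[repliconId(r)]] <- r@genes[, c("rank", "start", "end")]
  }
  locate_df <- function(tab, min_col, max_col) {
    if (!nrow(tab)) return(cbind(tab, data.frame(category = character(),
                                                 mge_id = character(),
                                                 straddle = logical())))
    loc <- lapply(seq_len(nrow(tab)), function(i)
      .locate_element(tab$replicon_id[i], tab[[min_col]][i], tab[[max_col]][i],
                      mges, kind_map))
    tab$category <- vapply(loc, `[[`, character(1), "category")
    tab$mge_id <- vapply(loc, `[[`, character(1), "mge_id")
    tab$straddle <- vapply(loc, `[[`, logical(1), "straddle")
    tab
  }
  sys_loc <- locate_df(systems, "min_rank", "max_rank")
  sol <- detection$solitary
  sol$min_rank <- sol$rank; sol$max_rank <- sol$rank
  sol_loc <- locate_df(sol, "min_rank", "max_rank")

  categories <- c("chromosome", "plasmid", "prophage", "ICE_IME", "phage")
  eres <- enrichmentFromLocations(sys_loc, categories)
  enr <- eres$enrichment
  frac <- setNames(eres$category_fractions$fraction,
                   eres$category_fractions$category)
  # per-category Mb and densities
  mge_mb <- function(kinds) {
    tot <- 0
    for (i in seq_len(nrow(mges))) {
      if (!mges$kind[i] %in% kinds) next
      cm <- coord_mb[[mges$replicon_id[i]]]
      if (is.null(cm)) next
      lo <- cm$start[cm$rank == mges$start_rank[i]]
      hi <- cm$end[cm$rank == mges$end_rank[i]]
      if (length(lo) && length(hi)) tot <- tot + (hi - lo + 1) / 1e6
    }
    tot
  }
  kinds_v <- unlist(kind_map)
  chrom_reps <- names(kinds_v)[kinds_v == "chromosome"]
  mb <- c(chromosome = sum(unlist(mb_map[chrom_reps])) - mge_mb(c("prophage", "ICE", "IME")),
          plasmid = sum(unlist(mb_map[names(kinds_v)[kinds_v == "plasmid"]])),
          prophage = mge_mb("prophage"), ICE_IME = mge_mb(c("ICE", "IME")),
          phage = sum(unlist(mb_map[names(kinds_v)[kinds_v == "phage"]])))
  dens <- data.frame(
    category = categories,
    mb = as.numeric(mb[categories]),
    n_systems = vapply(categories, function(cc) sum(sys_loc$category == cc),
                       numeric(1)),
    n_solitary = vapply(categories, function(cc) sum(sol_loc$category == cc),
                        numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  dens$system_density <- ifelse(dens$mb > 0, dens$n_systems / dens$mb, NA)
  dens$solitary_density <- ifelse(dens$mb > 0, dens$n_solitary / dens$mb, NA)
  list(enrichment = enr, locations = sys_loc, solitary_locations = sol_loc,
       densities = dens,
       category_fractions = data.frame(category = categories,
                                       fraction = as.numeric(frac),
                                       row.names = NULL))
}
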