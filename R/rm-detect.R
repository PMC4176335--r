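## Assembly of restriction-modification systems from role-called genes.
##
## Types I, II and III systems are built by chaining cognate components
## (REase, MTase, S) lying less than `max_gap` genes apart in gene-rank space;
## a single gene carrying both REase and MTase functions is a complete Type
## IIC system; a Type IV REase forms a Type IV entry on its own. Components
## not in any system are solitary when their nearest cognate lies at least
## `solitary_gap` genes away, and "ambiguous" in the band in between.

RM_TYPES <- c("I", "II", "IIC", "III", "IV")

.rm_component_roles <- function(roles) {
  roles$role %in% c("REase", "MTase", "S") & roles$rm_type %in% c("I", "II", "III")
}

#' Assemble R-M systems on one replicon
#'
#' Greedy left-to-right agglomeration over genes role-called as REase, MTase
#' or S (Types I-III): consecutive components merge into one cluster while the
#' next component lies less than \code{max_gap} genes away. Clusters whose
#' components disagree on the R-M type are flagged \code{mixed} and excluded
#' from the census. Multiple specificity (S) genes are absorbed into the same
#' system. Each Type IIC gene forms one complete system; each Type IV REase
#' gene forms one Type IV entry. REase genes whose role call is ambiguous
#' between Type II and Type IV are resolved by genomic context: a compatible
#' MTase within range makes them Type II, otherwise Type IV. A system is
#' complete when it has both an REase and an MTase; Type IIC and Type IV
#' entries are complete by construction (they need no further component).
#'
#' @param replicon a \linkS4class{Replicon}.
#' @param roles role table for this replicon's genes (\code{\link{assignRoles}}
#'   output joined with ranks, as from \code{\link{assignRolesGenomeSet}}).
#' @param max_gap components must be less than this many genes apart
#'   (default 4: an offset of 3 passes, 4 does not).
#' @param genome_id genome label stamped into system ids.
#' @return list with \code{systems} (data.frame: system_id, genome_id,
#'   replicon_id, rm_type, complete, mixed, n_components, n_s_genes,
#'   component_genes, min_rank, max_rank), \code{components} (gene-level
#'   membership) and \code{unassigned} (REase/MTase/S genes in no system).
#' @export
assembleRMSystems <- function(replicon, roles, max_gap = 4,
                              genome_id = "genome") {
  stopifnot(all(c("gene_id", "role", "rm_type", "rank") %in% names(roles)))
  n <- nGenes(replicon); circ <- isCircular(replicon)
  rl <- roles[roles$gene_id %in% replicon@genes$gene_id, , drop = FALSE]
  rl <- rl[order(rl$rank), , drop = FALSE]

  # context resolution of II/IV ambiguous REases
  if (any(rl$ambiguous_ii_iv %||% FALSE)) {
    mt_ranks <- rl$rank[rl$role == "MTase" & rl$rm_type == "II"]
    amb <- which(rl$ambiguous_ii_iv)
    for (i in amb) {
      near <- length(mt_ranks) &&
        any(rankDistance(rl$rank[i], mt_ranks, n, circ) < max_gap)
      if (near) { rl$role[i] <- "REase"; rl$rm_type[i] <- "II" }
      else { rl$role[i] <- "TypeIV_REase"; rl$rm_type[i] <- "none" }
    }
  }

  comp <- rl[.rm_component_roles(rl), , drop = FALSE]
  clusters <- list()
  if (nrow(comp)) {
    ranks <- comp$rank
    gap_next <- if (nrow(comp) > 1) diff(ranks) else integer(0)
    brk <- which(gap_next >= max_gap)
    grp <- cumsum(c(1L, as.integer(seq_along(gap_next) %in% brk)))
    if (circ && nrow(comp) > 1 && max(grp) > 1) {
      wrap_gap <- (ranks[1] - ranks[length(ranks)]) %% n
      if (wrap_gap < max_gap) grp[grp == max(grp)] <- 1L  # merge around origin
    }
    clusters <- split(comp, grp)
  }

  sys_rows <- list(); comp_rows <- list(); unassigned <- list()
  add_system <- function(rm_type, members, complete, mixed = FALSE) {
    k <- length(sys_rows) + 1L
    sid <- sprintf("%s|%s|sys%03d", genome_id, repliconId(replicon), k)
    sys_rows[[k]] <<- data.frame(
      system_id = sid, genome_id = genome_id,
      replicon_id = repliconId(replicon), rm_type = rm_type,
      complete = complete, mixed = mixed,
      n_components = nrow(members), n_s_genes = sum(members$role == "S"),
      component_genes = paste(members$gene_id, collapse = ","),
      min_rank = min(members$rank), max_rank = max(members$rank),
      stringsAsFactors = FALSE)
    comp_rows[[k]] <<- data.frame(
      system_id = sid, gene_id = members$gene_id, role = members$role,
      rank = members$rank, stringsAsFactors = FALSE)
  }
  for (cl in clusters) {
    types <- unique(cl$rm_type)
    if (length(types) > 1) {
      warning("cluster with conflicting R-M types (", paste(types, collapse = "/"),
              ") on ", repliconId(replicon), ": flagged mixed, excluded from census")
      add_system(paste(sort(types), collapse = "/"), cl, complete = FALSE,
                 mixed = TRUE)
      next
    }
    has_r <- any(cl$role == "REase"); has_m <- any(cl$role == "MTase")
    if (nrow(cl) == 1L && !has_r && !has_m) { # lone S gene
      unassigned[[length(unassigned) + 1L]] <- cl
      next
    }
    if (nrow(cl) == 1L) {                      # lone REase or MTase
      unassigned[[length(unassigned) + 1L]] <- cl
      next
    }
    add_system(types, cl, complete = has_r && has_m)
  }
  # one-gene systems: IIC fusions and Type IV REases
  for (i in which(rl$role == "IIC"))
    add_system("IIC", rl[i, , drop = FALSE], complete = TRUE)
  for (i in which(rl$role == "TypeIV_REase"))
    add_system("IV", rl[i, , drop = FALSE], complete = TRUE)

  systems <- if (length(sys_rows)) do.call(rbind, sys_rows) else
    data.frame(system_id = character(), genome_id = character(),
               replicon_id = character(), rm_type = character(),
               complete = logical(), mixed = logical(),
               n_components = integer(), n_s_genes = integer(),
               component_genes = character(), min_rank = integer(),
               max_rank = integer(), stringsAsFactors = FALSE)
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(system_id = character(), gene_id = character(),
               role = character(), rank = integer(), stringsAsFactors = FALSE)
  un <- if (length(unassigned)) do.call(rbind, unassigned) else rl[0, ]
  list(systems = systems, components = components, unassigned = un)
}

#' Call solitary R-M components on one replicon
#'
#' Unassigned MTase/REase genes whose nearest cognate (a gene of the opposite
#' role among Type I-III components) lies at least \code{solitary_gap} genes
#' away are solitary. Components whose nearest cognate falls in the band
#' \code{[max_gap, solitary_gap)} are returned separately as ambiguous:
#' too far to form a system, too close to call solitary. Lone S genes are
#' reported in the ambiguous table (no solitary concept applies to them).
#'
#' @param replicon a \linkS4class{Replicon}.
#' @param roles role table (as in \code{\link{assembleRMSystems}}).
#' @param assembly result of \code{\link{assembleRMSystems}}.
#' @param solitary_gap minimum cognate distance for a solitary call.
#' @param max_gap system assembly distance (lower edge of the ambiguous band).
#' @param genome_id genome label.
#' @return list with \code{solitary} and \code{ambiguous} data.frames
#'   (gene_id, role, rm_type, replicon_id, rank, nearest_cognate_distance).
#' @export
callSolitary <- function(replicon, roles, assembly, solitary_gap = 10,
                         max_gap = 4, genome_id = "genome") {
  n <- nGenes(replicon); circ <- isCircular(replicon)
  rl <- roles[roles$gene_id %in% replicon@genes$gene_id, , drop = FALSE]
  comp <- rl[.rm_component_roles(rl), , drop = FALSE]
  un <- assembly$unassigned
  mk <- function() data.frame(gene_id = character(), role = character(),
                              rm_type = character(), replicon_id = character(),
                              rank = integer(),
                              nearest_cognate_distance = integer(),
                              stringsAsFactors = FALSE)
  sol <- mk(); amb <- mk()
  if (!nrow(un)) return(list(solitary = sol, ambiguous = amb))
  for (i in seq_len(nrow(un))) {
    g <- un[i, ]
    row <- data.frame(gene_id = g$gene_id, role = g$role, rm_type = g$rm_type,
                      replicon_id = repliconId(replicon), rank = g$rank,
                      nearest_cognate_distance = NA_integer_,
                      stringsAsFactors = FALSE)
    if (g$role == "S") { amb <- rbind(amb, row); next }
    cognate_role <- if (g$role == "MTase") "REase" else "MTase"
    cr <- comp$rank[comp$role == cognate_role]
    d <- if (length(cr)) min(rankDistance(g$rank, cr, n, circ)) else NA_integer_
    row$nearest_cognate_distance <- d
    if (is.na(d) || d >= solitary_gap) sol <- rbind(sol, row)
    else amb <- rbind(amb, row)
  }
  list(solitary = sol, ambiguous = amb)
}

#' Detect R-M systems and solitary components across a GenomeSet
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param roles role table from \code{\link{assignRolesGenomeSet}}.
#' @param max_gap,solitary_gap neighborhood thresholds.
#' @return list of data.frames: systems, components, solitary, ambiguous.
#' @export
detectRMSystems <- function(gs, roles, max_gap = 4, solitary_gap = 10) {
  sys <- list(); cmp <- list(); sol <- list(); amb <- list()
  for (g in gs@genomes) {
    for (rep in replicons(g)) {
      rl <- roles[roles$replicon_id == repliconId(rep) &
                    roles$genome_id == genomeId(g), , drop = FALSE]
      asm <- assembleRMSystems(rep, rl, max_gap, genomeId(g))
      so <- callSolitary(rep, rl, asm, solitary_gap, max_gap, genomeId(g))
      sys[[length(sys) + 1L]] <- asm$systems
      cmp[[length(cmp) + 1L]] <- asm$components
      add_gid <- function(d) if (nrow(d))
        cbind(data.frame(genome_id = genomeId(g), stringsAsFactors = FALSE), d)
        else cbind(data.frame(genome_id = character()), d)
      sol[[length(sol) + 1L]] <- add_gid(so$solitary)
      amb[[length(amb) + 1L]] <- add_gid(so$ambiguous)
    }
  }
  list(systems = do.call(rbind, sys), components = do.call(rbind, cmp),
       solitary = do.call(rbind, sol), ambiguous = do.call(rbind, amb))
}

#' Co-localization of R-M systems within a neighborhood
#'
#' Pairs of distinct systems on the same replicon whose nearest components lie
#' less than \code{neighborhood} genes apart. The co-localized fraction is the
#' share of systems appearing in at least one pair, reported for all genomes
#' and restricted to genomes encoding at least two systems.
#'
#' @param detection result of \code{\link{detectRMSystems}} (mixed systems are
#'   ignored).
#' @param gs the \linkS4class{GenomeSet} (for replicon geometry).
#' @param neighborhood rank-distance threshold (10 or 50 in the analyses).
#' @return list: pairs (data.frame: system_a, system_b, distance),
#'   fraction_colocalized, fraction_colocalized_multi, n_systems.
#' @export
colocalizationPairs <- function(detection, gs, neighborhood = 10) {
  systems <- detection$systems
  systems <- systems[!systems$mixed, , drop = FALSE]
  comp <- detection$components
  pairs <- list()
  for (gid in unique(systems$genome_id)) {
    gsys <- systems[systems$genome_id == gid, , drop = FALSE]
    for (rid in unique(gsys$replicon_id)) {
      rsys <- gsys[gsys$replicon_id == rid, , drop = FALSE]
      if (nrow(rsys) < 2) next
      rep <- getReplicon(gs, rid)
      n <- nGenes(rep); circ <- isCircular(rep)
      for (i in seq_len(nrow(rsys) - 1)) for (j in (i + 1):nrow(rsys)) {
        ri <- comp$rank[comp$system_id == rsys$system_id[i]]
        rj <- comp$rank[comp$system_id == rsys$system_id[j]]
        d <- min(outer(ri, rj, function(x, y) rankDistance(x, y, n, circ)))
        if (d < neighborhood)
          pairs[[length(pairs) + 1L]] <- data.frame(
            genome_id = gid, system_a = rsys$system_id[i],
            system_b = rsys$system_id[j], distance = d,
            stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(genome_id = character(), system_a = character(),
               system_b = character(), distance = integer())
  in_pair <- unique(c(pairs$system_a, pairs$system_b))
  multi_genomes <- names(which(table(systems$genome_id) >= 2))
  sys_multi <- systems$system_id[systems$genome_id %in% multi_genomes]
  list(pairs = pairs,
       fraction_colocalized =
         if (nrow(systems)) length(in_pair) / nrow(systems) else NA_real_,
       fraction_colocalized_multi =
         if (length(sys_multi)) sum(sys_multi %in% in_pair) / length(sys_multi)
         else NA_real_,
       n_systems = nrow(systems))
}

#' Census of R-M systems and solitary components
#'
#' Per-genome counts and densities (count per Mb) by R-M type, per-clade mean
#' densities restricted to clades with at least \code{min_clade_size} genomes,
#' per-replicon-kind densities, and solitary MTase/REase tallies per replicon
#' kind per Mb. Mixed-type clusters and incomplete systems are excluded from
#' the complete-system counts; both totals are reported.
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param detection result of \code{\link{detectRMSystems}}.
#' @param min_clade_size minimum genomes per clade for the clade summary.
#' @return list of data.frames: per_genome, per_clade, per_replicon_kind,
#'   solitary_tallies, totals.
#' @export
rmCensus <- function(gs, detection, min_clade_size = 10) {
  systems <- detection$systems[!detection$systems$mixed, , drop = FALSE]
  solitary <- detection$solitary
  gids <- names(gs@genomes)
  info <- data.frame(
    genome_id = gids,
    clade = vapply(gs@genomes, clade, character(1)),
    size_mb = vapply(gs@genomes, genomeSize, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  per_genome <- info
  for (tt in RM_TYPES)
    per_genome[[paste0("n_", tt)]] <- vapply(gids, function(g)
      sum(systems$genome_id == g & systems$rm_type == tt &
            (systems$complete | !systems$rm_type %in% c("I", "II", "III"))),
      numeric(1))
  per_genome$n_total <- rowSums(per_genome[paste0("n_", RM_TYPES)])
  per_genome$n_incomplete <- vapply(gids, function(g)
    sum(systems$genome_id == g & !systems$complete), numeric(1))
  per_genome$density <- per_genome$n_total / per_genome$size_mb
  per_genome$n_solitary <- vapply(gids, function(g)
    sum(solitary$genome_id == g), numeric(1))

  keep_clades <- names(which(table(info$clade) >= min_clade_size))
  pc <- per_genome[per_genome$clade %in% keep_clades, , drop = FALSE]
  per_clade <- do.call(rbind, lapply(split(pc, pc$clade), function(d)
    data.frame(clade = d$clade[1], n_genomes = nrow(d),
               mean_count = mean(d$n_total), mean_density = mean(d$density),
               stringsAsFactors = FALSE)))
  if (is.null(per_clade))
    per_clade <- data.frame(clade = character(), n_genomes = integer(),
                            mean_count = numeric(), mean_density = numeric())

  kind_of_replicon <- list(); mb_of_replicon <- list()
  for (g in gs@genomes) for (r in replicons(g)) {
    kind_of_replicon[[repliconId(r)]] <- repliconKind(r)
    mb_of_replicon[[repliconId(r)]] <- r@lengthBp / 1e6
  }
  kinds <- c("chromosome", "plasmid", "phage")
  per_kind <- do.call(rbind, lapply(kinds, function(k) {
    reps <- names(kind_of_replicon)[unlist(kind_of_replicon) == k]
    mb <- sum(unlist(mb_of_replicon[reps]))
    n_sys <- sum(systems$replicon_id %in% reps)
    n_sol <- sum(solitary$replicon_id %in% reps)
    data.frame(kind = k, total_mb = mb, n_systems = n_sys, n_solitary = n_sol,
               system_density = if (mb > 0) n_sys / mb else NA_real_,
               solitary_density = if (mb > 0) n_sol / mb else NA_real_,
               stringsAsFactors = FALSE)
  }))
  sol_tab <- do.call(rbind, lapply(kinds, function(k) {
    reps <- names(kind_of_replicon)[unlist(kind_of_replicon) == k]
    mb <- sum(unlist(mb_of_replicon[reps]))
    nm <- sum(solitary$replicon_id %in% reps & solitary$role == "MTase")
    nr <- sum(solitary$replicon_id %in% reps & solitary$role == "REase")
    data.frame(kind = k, n_solitary_mtase = nm, n_solitary_rease = nr,
               mtase_per_mb = if (mb > 0) nm / mb else NA_real_,
               rease_per_mb = if (mb > 0) nr / mb else NA_real_,
               stringsAsFactors = FALSE)
  }))
  totals <- data.frame(
    n_systems_complete = sum(per_genome$n_total),
    n_systems_incomplete = sum(per_genome$n_incomplete),
    n_solitary = nrow(solitary),
    fraction_genomes_with_rm = mean(per_genome$n_total > 0))
  list(per_genome = per_genome, per_clade = per_clade,
       per_replicon_kind = per_kind, solitary_tallies = sol_tab,
       totals = totals)
}

#' Scan Type IIC systems for fusions of split Type II systems
#'
#' Each single-gene Type IIC protein is aligned (locally) against the
#' individual REase and MTase proteins of every two-gene Type II system and
#' against their concatenation; the IIC system is flagged when any similarity
#' exceeds \code{threshold}.
#'
#' @param detection result of \code{\link{detectRMSystems}}.
#' @param gs \linkS4class{GenomeSet} (protein sequences).
#' @param threshold similarity fraction above which an IIC is flagged.
#' @return list: table (iic system_id, best_similarity, fused_with, flagged),
#'   fraction_flagged.
#' @export
iicFusionScan <- function(detection, gs, threshold = 0.5) {
  gt <- geneTable(gs)
  prot <- setNames(gt$protein, gt$gene_id)
  systems <- detection$systems
  iic <- systems[systems$rm_type == "IIC", , drop = FALSE]
  two_gene_ii <- systems[systems$rm_type == "II" & systems$complete &
                           systems$n_components == 2, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(iic))) {
    p <- prot[[strsplit(iic$component_genes[i], ",")[[1]][1]]]
    best <- 0; best_sys <- NA_character_
    for (j in seq_len(nrow(two_gene_ii))) {
      comps <- strsplit(two_gene_ii$component_genes[j], ",")[[1]]
      targets <- c(prot[comps], fused = paste(prot[comps], collapse = ""))
      st <- alignStats(setNames(p, "iic"), targets, mode = "local")
      s <- max(st$similarity)
      if (s > best) { best <- s; best_sys <- two_gene_ii$system_id[j] }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      system_id = iic$system_id[i], best_similarity = best,
      fused_with = best_sys, flagged = best > threshold,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(system_id = character(), best_similarity = numeric(),
               fused_with = character(), flagged = logical())
  list(table = tab,
       fraction_flagged = if (nrow(tab)) mean(tab$flagged) else NA_real_)
}
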