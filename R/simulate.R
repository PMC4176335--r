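## Deterministic synthetic-data generator.
##
## Every input the pipeline consumes can be generated here with a
## machine-readable truth table: a labeled reference protein library, single
## genomes with planted R-M systems / solitary genes / ambiguous-band decoys /
## MGE spans / integron, competence, antirestriction and cas genes / CRISPR
## spacers, clades with core/accessory structure and rearrangements, and
## codon pairs diverged under a known kappa/omega process. All randomness is
## driven by R's Mersenne-Twister stream seeded per call, so identical seed
## and configuration give byte-identical outputs.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

.random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                       collapse = "")

# Mutate a protein to (approximately) a target identity; mutated positions
# always change residue.
.mutate_protein <- function(prot, identity) {
  chars <- strsplit(prot, "")[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut == 0) return(prot)
  pos <- sample(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

.synonymous_codons <- function() {
  gc <- .gc_table()
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

# Reverse-translate a protein with uniformly random synonymous codons.
.reverse_translate <- function(prot) {
  syn <- .synonymous_codons()
  chars <- strsplit(prot, "")[[1]]
  paste(vapply(chars, function(a) {
    cands <- syn[[a]]
    cands[sample.int(length(cands), 1)]
  }, character(1)), collapse = "")
}

.random_codons <- function(n) {
  paste(sample(senseCodons(), n, replace = TRUE), collapse = "")
}

## ---- reference library -----------------------------------------------------

.reference_classes <- function() {
  # founder_key is the planting handle; role/rm_type are the header labels.
  rbind(
    data.frame(founder_key = "REase_I",    role = "REase", rm_type = "I",    len = 280),
    data.frame(founder_key = "MTase_I",    role = "MTase", rm_type = "I",    len = 300),
    data.frame(founder_key = "S_I",        role = "S",     rm_type = "I",    len = 200),
    data.frame(founder_key = "REase_II_a", role = "REase", rm_type = "II",   len = 250),
    data.frame(founder_key = "REase_II_b", role = "REase", rm_type = "II",   len = 240),
    data.frame(founder_key = "MTase_II_a", role = "MTase", rm_type = "II",   len = 260),
    data.frame(founder_key = "MTase_II_b", role = "MTase", rm_type = "II",   len = 270),
    data.frame(founder_key = "REase_III",  role = "REase", rm_type = "III",  len = 270),
    data.frame(founder_key = "MTase_III",  role = "MTase", rm_type = "III",  len = 290),
    data.frame(founder_key = "IIC_R",      role = "REase", rm_type = "IIC",  len = 180),
    data.frame(founder_key = "IIC_M",      role = "MTase", rm_type = "IIC",  len = 200),
    data.frame(founder_key = "TypeIV",     role = "TypeIV_REase", rm_type = "none", len = 260),
    data.frame(founder_key = "relaxase",   role = "relaxase", rm_type = "none", len = 300),
    data.frame(founder_key = "conj_T4CP",  role = "conjugation:T4CP", rm_type = "none", len = 250),
    data.frame(founder_key = "conj_MPF",   role = "conjugation:MPF", rm_type = "none", len = 350),
    data.frame(founder_key = "int_tyr",    role = "integrase_tyr", rm_type = "none", len = 300),
    data.frame(founder_key = "int_sig",    role = "integron_signature", rm_type = "none", len = 120),
    data.frame(founder_key = "ComEA",      role = "competence:ComEA", rm_type = "none", len = 150),
    data.frame(founder_key = "ComEC",      role = "competence:ComEC", rm_type = "none", len = 300),
    data.frame(founder_key = "ComFA",      role = "competence:ComFA", rm_type = "none", len = 250),
    data.frame(founder_key = "ComGA",      role = "competence:ComGA", rm_type = "none", len = 200),
    data.frame(founder_key = "ComGB",      role = "competence:ComGB", rm_type = "none", len = 180),
    data.frame(founder_key = "ComGC",      role = "competence:ComGC", rm_type = "none", len = 100),
    data.frame(founder_key = "ComC",       role = "competence:ComC", rm_type = "none", len = 120),
    data.frame(founder_key = "DprA",       role = "competence:DprA", rm_type = "none", len = 200),
    data.frame(founder_key = "argo",       role = "argo", rm_type = "none", len = 400),
    data.frame(founder_key = "cas",        role = "cas", rm_type = "none", len = 350))
}

#' Build a labeled reference protein library
#'
#' For every reference class (role x R-M type) an independent founder protein
#' is drawn and divergent copies are generated at controlled identity tiers,
#' emulating a curated library spanning close and remote homologs. Distinct
#' classes share no sequence, so cross-role hits are structurally impossible.
#'
#' @param seed RNG seed.
#' @param tiers identity tiers of the divergent copies.
#' @return list: seqs (named vector, founders and tier copies), info
#'   (ref_id, role, rm_type), founders (named by founder_key, used for
#'   planting genes), classes (the class table).
#' @export
buildReferenceLibrary <- function(seed = 101, tiers = c(0.95, 0.7, 0.4)) {
  .with_seed(seed, {
    cls <- .reference_classes()
    seqs <- character(); info <- list(); founders <- character()
    for (i in seq_len(nrow(cls))) {
      fk <- cls$founder_key[i]
      founder <- .random_protein(cls$len[i])
      founders[fk] <- founder
      ids <- c(sprintf("ref_%s_f", fk),
               sprintf("ref_%s_t%02d", fk, round(100 * tiers)))
      ss <- c(founder, vapply(tiers, function(tr) .mutate_protein(founder, tr),
                              character(1)))
      seqs[ids] <- ss
      info[[i]] <- data.frame(ref_id = ids, role = cls$role[i],
                              rm_type = cls$rm_type[i],
                              stringsAsFactors = FALSE)
    }
    list(seqs = seqs, info = do.call(rbind, info), founders = founders,
         classes = cls)
  })
}

#' Write a reference library as labeled FASTA
#' @param lib library from \code{\link{buildReferenceLibrary}}.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeReferenceFasta <- function(lib, path) {
  hdr <- sprintf("%s role=%s rm_type=%s", lib$info$ref_id, lib$info$role,
                 lib$info$rm_type)
  aa <- Biostrings::AAStringSet(setNames(lib$seqs[lib$info$ref_id], hdr))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

## ---- codon evolution -------------------------------------------------------

.codon_rate_matrix <- function(kappa, omega) {
  key <- sprintf("Q_%.6f_%.6f", kappa, omega)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  cods <- senseCodons()
  n <- length(cods)
  Q <- matrix(0, n, n, dimnames = list(cods, cods))
  for (c1 in cods) {
    nb <- .codon_neighbors(c1)
    nb <- nb[!nb$stop, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      rate <- (if (nb$ts[r]) kappa else 1) * (if (nb$syn[r]) 1 else omega)
      Q[c1, nb$target[r]] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -mean(diag(Q))           # uniform codon frequencies
  if (scale > 0) Q <- Q / scale
  .codon_env[[key]] <- Q
  Q
}

.codon_transition_matrix <- function(t, kappa, omega) {
  key <- sprintf("P_%.6f_%.6f_%.6f", t, kappa, omega)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  Q <- .codon_rate_matrix(kappa, omega)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  P[P < 0] <- 0
  P <- sweep(P, 1, rowSums(P), "/")
  dimnames(P) <- dimnames(Q)
  .codon_env[[key]] <- P
  P
}

#' Evolve a coding sequence under a codon Markov process
#'
#' Continuous-time Markov chain over the 61 sense codons with single
#' nucleotide changes only: synonymous changes at relative rate 1,
#' nonsynonymous scaled by omega, transitions by kappa; stop codons are
#' forbidden. The process is normalised so the expected number of
#' substitutions per codon over time \code{t} is \code{t} (Poisson counts).
#' With omega 0 the protein is exactly conserved; with t 0 the DNA is
#' unchanged.
#'
#' @param dna coding sequence (length divisible by 3, sense codons only).
#' @param t expected substitutions per codon.
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param seed optional RNG seed (the caller's RNG stream is restored).
#' @return the diverged coding sequence.
#' @export
evolveCodonSequence <- function(dna, t, kappa = 2, omega = 0.2, seed = NULL) {
  .with_seed(seed, {
    cods <- .split_codons(toupper(dna))
    if (any(!cods %in% senseCodons()))
      stop("input contains a stop or ambiguous codon")
    if (t == 0) return(paste(cods, collapse = ""))
    P <- .codon_transition_matrix(t, kappa, omega)
    idx <- match(cods, rownames(P))
    out <- vapply(idx, function(i)
      rownames(P)[sample.int(ncol(P), 1, prob = P[i, ])], character(1))
    paste(out, collapse = "")
  })
}

## ---- single-genome simulation ----------------------------------------------

.system_patterns <- list(
  I = c("MTase_I", "S_I", "REase_I", "S_I"),
  II = c("MTase_II_a", "REase_II_a"),
  III = c("REase_III", "MTase_III"),
  IIC = "IIC_FUSION",
  IV = "TypeIV")

.gene_record <- function(protein, dna, role = "background",
                         rm_type = "none", feature = NA_character_,
                         feature_kind = NA_character_) {
  list(protein = protein, dna = dna, role = role, rm_type = rm_type,
       feature = feature, feature_kind = feature_kind)
}

# Active reference library during generation: background genes are
# rejection-sampled against it so they cannot pass role-call thresholds.
.sim_env <- new.env(parent = emptyenv())

.set_active_library <- function(lib) {
  if (!identical(.sim_env$lib_seqs, lib$seqs)) {
    .sim_env$ref_idx <- NULL
    .sim_env$lib_seqs <- lib$seqs
  }
  .sim_env$lib <- lib
}

# kmer -> reference-index lookup, cached per active library
.ref_kmer_index <- function(lib) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  ks <- .kmer_sets(lib$seqs)
  for (i in seq_along(ks)) for (km in ks[[i]]) idx[[km]] <- c(idx[[km]], i)
  idx
}

.passes_role_call <- function(protein, lib, thresholds = roleThresholds()) {
  if (is.null(.sim_env$ref_idx)) .sim_env$ref_idx <- .ref_kmer_index(lib)
  n <- nchar(protein)
  if (n < 4) return(FALSE)
  kms <- unique(substring(protein, 1:(n - 3), 4:n))
  hits <- integer(0)
  for (km in kms) {
    v <- .sim_env$ref_idx[[km]]
    if (!is.null(v)) hits <- c(hits, v)
  }
  if (!length(hits)) return(FALSE)
  tab <- table(hits)
  cand <- as.integer(names(tab)[tab >= 2])
  if (!length(cand)) return(FALSE)
  st <- alignStats(setNames(protein, "q"), lib$seqs[cand], "local")
  st <- merge(st, lib$info, by.x = "subject_id", by.y = "ref_id")
  gated <- .coverage_gated(st$role, st$rm_type)
  any(st$evalue_proxy < thresholds$evalue_max &
        (!gated | st$subject_coverage >= thresholds$coverage_min))
}

.background_gene <- function(len = NULL, feature = NA_character_,
                             feature_kind = NA_character_) {
  if (is.null(len)) len <- sample(80:150, 1)
  for (try in 1:50) {
    dna <- .random_codons(len)
    prot <- .translate_cds(dna)
    if (is.null(.sim_env$lib) || !.passes_role_call(prot, .sim_env$lib)) break
  }
  .gene_record(prot, dna, feature = feature, feature_kind = feature_kind)
}

.planted_gene <- function(lib, founder_key, identity, role, rm_type,
                          feature, feature_kind) {
  prot <- if (founder_key == "IIC_FUSION")
    paste0(.mutate_protein(lib$founders[["IIC_R"]], identity),
           .mutate_protein(lib$founders[["IIC_M"]], identity))
  else if (founder_key == "INTEGRON_FUSION")
    paste0(.mutate_protein(lib$founders[["int_tyr"]], identity),
           .mutate_protein(lib$founders[["int_sig"]], identity))
  else .mutate_protein(lib$founders[[founder_key]], identity)
  .gene_record(prot, .reverse_translate(prot), role, rm_type, feature,
               feature_kind)
}

# Assemble a replicon from a list of blocks (each a list of gene records),
# separated by runs of background genes.
.assemble_blocks <- function(blocks, sep_range = c(12, 16), lead = 3) {
  genes <- replicate(lead, .background_gene(), simplify = FALSE)
  for (b in blocks) {
    genes <- c(genes, b)
    nsep <- sample(sep_range[1]:sep_range[2], 1)
    genes <- c(genes, replicate(nsep, .background_gene(), simplify = FALSE))
  }
  genes
}

.system_block <- function(lib, rm_type, gaps, identity, feature) {
  pat <- .system_patterns[[rm_type]]
  role_of <- function(fk) switch(fk,
    IIC_FUSION = "IIC", TypeIV = "TypeIV_REase",
    sub("_.*$", "", fk))  # MTase_II_a -> MTase etc.
  genes <- list()
  for (i in seq_along(pat)) {
    fk <- pat[i]
    rt <- if (rm_type %in% c("IIC", "IV")) "none" else rm_type
    genes[[length(genes) + 1L]] <-
      .planted_gene(lib, fk, identity, role_of(fk), rt, feature, "system")
    if (i < length(pat)) {
      g <- gaps[min(i, length(gaps))]
      if (g > 1)
        genes <- c(genes, replicate(g - 1, .background_gene(), simplify = FALSE))
    }
  }
  genes
}

#' Default single-genome simulation plan
#'
#' @param genome_id,clade labels.
#' @return a configuration list understood by \code{\link{simulateGenome}};
#'   fields can be overridden selectively.
#' @export
genomePlan <- function(genome_id = "g01", clade = "cladeA") {
  list(
    genome_id = genome_id, clade = clade, identity = 0.9,
    systems = list(list(rm_type = "II", gaps = 1),
                   list(rm_type = "II", gaps = 3),
                   list(rm_type = "I", gaps = c(1, 1, 1)),
                   list(rm_type = "III", gaps = 2),
                   list(rm_type = "IIC", gaps = 1),
                   list(rm_type = "IV", gaps = 1)),
    solitary = list(list(role = "MTase", founder = "MTase_II_b"),
                    list(role = "REase", founder = "REase_II_b")),
    ambiguous_pair_gap = 5,
    prophage = TRUE, ice = TRUE,
    integron = TRUE, competence = TRUE, argo = TRUE, cas = TRUE,
    plasmids = c("plus", "minus"),
    sep_range = c(12, 16))
}

#' Simulate one annotated genome with planted features and ground truth
#'
#' The chromosome is a circular molecule of background genes (random-codon
#' ORFs, structurally unable to hit the reference library) interleaved with
#' planted feature blocks separated by at least \code{sep_range[1]} background
#' genes: R-M systems of the requested types with component offsets below the
#' assembly threshold, solitary MTase/REase genes (nearest cognate at least 10
#' genes away, from founders distinct from the system founders), an
#' ambiguous-band cognate pair, a prophage span harboring a solitary MTase, an
#' ICE span harboring a complete Type II system, an integron integrase
#' (tyrosine recombinase fused to the integron signature), a Gram-positive
#' competence locus, antirestriction (argo) and cas marker genes. Optional
#' plasmids carry a relaxase plus conjugation genes (MOB+) or neither (MOB-).
#' The generator self-validates every planted spacing constraint.
#'
#' @param lib reference library (\code{\link{buildReferenceLibrary}}).
#' @param plan configuration (\code{\link{genomePlan}}).
#' @param seed RNG seed.
#' @return list: genome (\linkS4class{Genome}), truth (list of tables:
#'   genes, systems, solitary, ambiguous, mges, mob, markers).
#' @export
simulateGenome <- function(lib, plan = genomePlan(), seed = 1) {
  .with_seed(seed, .simulate_genome_inner(lib, plan))
}

.simulate_genome_inner <- function(lib, plan) {
  .set_active_library(lib)
  idf <- plan$identity
  blocks <- list(); block_meta <- list()
  add_block <- function(b, meta) {
    blocks[[length(blocks) + 1L]] <<- b
    block_meta[[length(block_meta) + 1L]] <<- meta
  }
  k_sys <- 0L
  for (s in plan$systems) {
    k_sys <- k_sys + 1L
    fid <- sprintf("%s_sys%02d", plan$genome_id, k_sys)
    add_block(.system_block(lib, s$rm_type, s$gaps, idf, fid),
              list(kind = "system", rm_type = s$rm_type, feature = fid))
  }
  k_sol <- 0L
  for (s in plan$solitary) {
    k_sol <- k_sol + 1L
    fid <- sprintf("%s_sol%02d", plan$genome_id, k_sol)
    add_block(list(.planted_gene(lib, s$founder, idf, s$role, "II", fid,
                                 "solitary")),
              list(kind = "solitary", feature = fid))
  }
  if (!is.null(plan$ambiguous_pair_gap)) {
    fid <- sprintf("%s_amb01", plan$genome_id)
    g <- plan$ambiguous_pair_gap
    b <- c(list(.planted_gene(lib, "MTase_II_a", idf, "MTase", "II", fid,
                              "ambiguous")),
           replicate(g - 1, .background_gene(), simplify = FALSE),
           list(.planted_gene(lib, "REase_II_a", idf, "REase", "II", fid,
                              "ambiguous")))
    add_block(b, list(kind = "ambiguous", feature = fid, gap = g))
  }
  if (isTRUE(plan$prophage)) {
    fid <- sprintf("%s_pro01", plan$genome_id)
    b <- c(replicate(3, .background_gene(feature = fid, feature_kind = "mge_bg"),
                     simplify = FALSE),
           list(.planted_gene(lib, "MTase_II_b", idf, "MTase", "II",
                              paste0(fid, ".sol"), "solitary")),
           replicate(3, .background_gene(feature = fid, feature_kind = "mge_bg"),
                     simplify = FALSE))
    add_block(b, list(kind = "prophage", feature = fid))
  }
  if (isTRUE(plan$ice)) {
    fid <- sprintf("%s_ice01", plan$genome_id)
    b <- c(replicate(2, .background_gene(feature = fid, feature_kind = "mge_bg"),
                     simplify = FALSE),
           .system_block(lib, "II", 1, idf, paste0(fid, ".sys")),
           replicate(2, .background_gene(feature = fid, feature_kind = "mge_bg"),
                     simplify = FALSE))
    add_block(b, list(kind = "ICE", feature = fid))
  }
  if (isTRUE(plan$integron))
    add_block(list(.planted_gene(lib, "INTEGRON_FUSION", idf, "integrase_tyr",
                                 "none", sprintf("%s_int01", plan$genome_id),
                                 "integron")),
              list(kind = "integron", feature = sprintf("%s_int01", plan$genome_id)))
  if (isTRUE(plan$competence)) {
    fid <- sprintf("%s_com01", plan$genome_id)
    comp <- c("ComEA", "ComEC", "ComFA", "ComGA", "ComGB", "ComGC", "DprA")
    b <- list()
    for (i in seq_along(comp)) {
      b[[length(b) + 1L]] <- .planted_gene(lib, comp[i], idf,
                                           paste0("competence:", comp[i]),
                                           "none", fid, "competence")
      if (i < length(comp) && i %% 2 == 0)  # occasional intervening genes
        b <- c(b, replicate(sample(1:3, 1), .background_gene(),
                            simplify = FALSE))
    }
    add_block(b, list(kind = "competence", feature = fid))
  }
  if (isTRUE(plan$argo))
    add_block(list(.planted_gene(lib, "argo", idf, "argo", "none",
                                 sprintf("%s_argo01", plan$genome_id), "argo")),
              list(kind = "argo", feature = sprintf("%s_argo01", plan$genome_id)))
  if (isTRUE(plan$cas))
    add_block(list(.planted_gene(lib, "cas", idf, "cas", "none",
                                 sprintf("%s_cas01", plan$genome_id), "cas")),
              list(kind = "cas", feature = sprintf("%s_cas01", plan$genome_id)))

  ord <- sample(length(blocks))   # shuffle feature order along the chromosome
  blocks <- blocks[ord]; block_meta <- block_meta[ord]
  genes <- .assemble_blocks(blocks, plan$sep_range)
  chrom <- .materialize_replicon(genes, sprintf("%s_chr", plan$genome_id),
                                 "chromosome", circular = TRUE)
  reps <- list(chrom$replicon)
  truth_genes <- chrom$truth
  mges <- list(); mob_rows <- list()

  for (bm in block_meta) {
    if (bm$kind %in% c("prophage", "ICE")) {
      fid <- bm$feature
      in_block <- !is.na(truth_genes$feature) &
        startsWith(truth_genes$feature, fid)
      rks <- range(truth_genes$rank[in_block])
      mges[[length(mges) + 1L]] <- data.frame(
        mge_id = fid, replicon_id = repliconId(chrom$replicon),
        start_rank = rks[1], end_rank = rks[2],
        kind = if (bm$kind == "prophage") "prophage" else "ICE",
        stringsAsFactors = FALSE)
    }
  }

  if ("plus" %in% plan$plasmids) {
    pid <- sprintf("%s_pls1", plan$genome_id)
    b <- c(replicate(3, .background_gene(), simplify = FALSE),
           list(.planted_gene(lib, "relaxase", idf, "relaxase", "none",
                              paste0(pid, "_rel"), "relaxase"),
                .planted_gene(lib, "conj_T4CP", idf, "conjugation:T4CP",
                              "none", paste0(pid, "_conj"), "conjugation"),
                .planted_gene(lib, "conj_MPF", idf, "conjugation:MPF",
                              "none", paste0(pid, "_conj"), "conjugation")),
           replicate(3, .background_gene(), simplify = FALSE))
    pl <- .materialize_replicon(b, pid, "plasmid", circular = TRUE)
    reps[[length(reps) + 1L]] <- pl$replicon
    truth_genes <- rbind(truth_genes, pl$truth)
    mob_rows[[length(mob_rows) + 1L]] <-
      data.frame(replicon_id = pid, mob = "MOB_plus", stringsAsFactors = FALSE)
  }
  if ("minus" %in% plan$plasmids) {
    pid <- sprintf("%s_pls2", plan$genome_id)
    b <- replicate(8, .background_gene(), simplify = FALSE)
    pl <- .materialize_replicon(b, pid, "plasmid", circular = TRUE)
    reps[[length(reps) + 1L]] <- pl$replicon
    truth_genes <- rbind(truth_genes, pl$truth)
    mob_rows[[length(mob_rows) + 1L]] <-
      data.frame(replicon_id = pid, mob = "MOB_minus", stringsAsFactors = FALSE)
  }

  genome <- Genome(plan$genome_id, plan$clade, reps)
  truth_genes$genome_id <- plan$genome_id

  # feature-level truth tables
  sysr <- truth_genes[truth_genes$feature_kind %in% "system", , drop = FALSE]
  systems <- do.call(rbind, lapply(split(sysr, sysr$feature), function(d) {
    rt <- if (any(d$role == "IIC")) "IIC"
          else if (any(d$role == "TypeIV_REase")) "IV" else d$rm_type[1]
    data.frame(feature = d$feature[1], genome_id = plan$genome_id,
               replicon_id = d$replicon_id[1], rm_type = rt,
               component_genes = paste(sort(d$gene_id), collapse = ","),
               n_components = nrow(d),
               min_rank = min(d$rank), max_rank = max(d$rank),
               complete = TRUE, stringsAsFactors = FALSE)
  }))
  sol <- truth_genes[truth_genes$feature_kind %in% "solitary", , drop = FALSE]
  amb <- truth_genes[truth_genes$feature_kind %in% "ambiguous", , drop = FALSE]
  mges <- if (length(mges)) do.call(rbind, mges) else
    data.frame(mge_id = character(), replicon_id = character(),
               start_rank = integer(), end_rank = integer(), kind = character())
  mob <- if (length(mob_rows)) {
    m <- do.call(rbind, mob_rows); m$genome_id <- plan$genome_id; m
  } else data.frame(replicon_id = character(), mob = character(),
                    genome_id = character())
  truth <- list(genes = truth_genes, systems = systems, solitary = sol,
                ambiguous = amb, mges = mges, mob = mob)
  .validate_plant(genome, truth)
  list(genome = genome, truth = truth)
}

# Flatten gene records into a Replicon plus a per-gene truth table.
.materialize_replicon <- function(genes, replicon_id, kind, circular = TRUE) {
  n <- length(genes)
  pos <- 100L
  rows <- list()
  for (i in seq_len(n)) {
    g <- genes[[i]]
    len_bp <- 3L * (nchar(g$protein) + 1L)
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%04d", replicon_id, i), rank = i - 1L,
      start = pos, end = pos + len_bp - 1L,
      strand = sample(c("+", "-"), 1), protein = g$protein, dna = g$dna,
      role = g$role, rm_type = g$rm_type, feature = g$feature,
      feature_kind = g$feature_kind, block = NA_integer_,
      stringsAsFactors = FALSE)
    pos <- pos + len_bp + sample(20:80, 1)
  }
  tab <- do.call(rbind, rows)
  tab$replicon_id <- replicon_id
  rep <- Replicon(replicon_id, kind, pos + 200L, circular,
                  tab[, GENE_COLS, drop = FALSE])
  truth <- tab[, c("gene_id", "replicon_id", "rank", "role", "rm_type",
                   "feature", "feature_kind", "block"), drop = FALSE]
  list(replicon = rep, truth = truth)
}

# Generator self-check: planted spacings must satisfy the thresholds they are
# meant to exercise.
.validate_plant <- function(genome, truth, max_gap = 4, solitary_gap = 10) {
  tg <- truth$genes
  for (rep in replicons(genome)) {
    t_r <- tg[tg$replicon_id == repliconId(rep), , drop = FALSE]
    n <- nGenes(rep)
    rm_r <- t_r[t_r$role %in% c("REase", "MTase", "S") &
                  t_r$rm_type %in% c("I", "II", "III"), , drop = FALSE]
    # solitary genes: nearest cognate >= solitary_gap
    for (i in which(rm_r$feature_kind == "solitary")) {
      cog <- if (rm_r$role[i] == "MTase") "REase" else "MTase"
      other <- rm_r$rank[rm_r$role == cog]
      if (length(other) &&
          min(rankDistance(rm_r$rank[i], other, n, isCircular(rep))) < solitary_gap)
        stop("generator self-check failed: planted solitary too close to cognate")
    }
    # system components: consecutive offsets < max_gap
    for (f in unique(rm_r$feature[rm_r$feature_kind == "system"])) {
      rk <- sort(rm_r$rank[rm_r$feature == f & !is.na(rm_r$feature)])
      if (length(rk) > 1 && any(diff(rk) >= max_gap))
        stop("generator self-check failed: system components too far apart")
    }
  }
  invisible(TRUE)
}
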