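## Role assignment against a labeled reference protein library.

ROLE_LEVELS <- c("REase", "MTase", "S", "IIC", "TypeIV_REase", "relaxase",
                 "integrase_tyr", "integron_signature", "argo", "cas", "other")

#' Read a labeled reference protein library
#'
#' FASTA headers carry key-value tags, e.g.
#' \code{>refII_M_t95 role=MTase rm_type=II}. Recognised keys: \code{role}
#' (REase, MTase, S, TypeIV_REase, relaxase, conjugation:<comp>,
#' integrase_tyr, integron_signature, competence:<comp>, argo, cas) and
#' \code{rm_type} (I, II, IIC, III or none).
#'
#' @param path FASTA file.
#' @return list with \code{seqs} (named character) and \code{info}
#'   (data.frame: ref_id, role, rm_type).
#' @export
readReferenceLibrary <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("empty reference library: ", path)
  hdr <- names(aa)
  ref_id <- sub("\\s.*$", "", hdr)
  get_tag <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    v <- rep(NA_character_, length(hdr))
    v[regexpr(paste0(key, "=[^ ]+"), hdr) > 0] <- sub(paste0(key, "="), "", m)
    v
  }
  info <- data.frame(ref_id = ref_id, role = get_tag("role"),
                     rm_type = get_tag("rm_type"), stringsAsFactors = FALSE)
  info$rm_type[is.na(info$rm_type)] <- "none"
  if (anyNA(info$role)) stop("reference headers must carry role= tags")
  seqs <- setNames(as.character(aa), ref_id)
  list(seqs = seqs, info = info)
}

#' Default role-call thresholds
#'
#' Hits must pass the e-value surrogate threshold; for Type II REase, Type IIC
#' REase and Type IV REase references a minimum reference (subject) coverage
#' additionally applies, mirroring the BLAST-based search used for those
#' divergent families.
#'
#' Multi-signal rules (the Type IIC dual-function call and the integron
#' integrase flags) additionally require hit identity of at least
#' \code{aux_identity_min}: a faint chance similarity must never combine with
#' another faint one into a positive call. The floor equals the identity of
#' the most divergent members of the reference library itself.
#'
#' @param evalue_max maximum e-value surrogate.
#' @param coverage_min minimum subject coverage for the coverage-gated roles.
#' @param aux_identity_min minimum identity for hits feeding multi-signal
#'   rules.
#' @return list of thresholds.
#' @export
roleThresholds <- function(evalue_max = 1e-3, coverage_min = 0.5,
                           aux_identity_min = 0.4) {
  list(evalue_max = evalue_max, coverage_min = coverage_min,
       aux_identity_min = aux_identity_min)
}

.coverage_gated <- function(role, rm_type) {
  (role == "REase" & rm_type %in% c("II", "IIC")) | role == "TypeIV_REase"
}

#' Assign functional roles to genes from best hits against the reference
#'
#' Each gene receives the role of its best passing hit (by alignment score),
#' or \code{"other"}. A gene passing both the REase and the MTase references
#' of Type IIC is called \code{IIC} (a single polypeptide carrying both
#' functions). Genes called as Type II REase or Type IV REase that also pass
#' the other of those two reference classes with a comparable score (within a
#' factor of two) are marked \code{ambiguous_ii_iv}; system assembly resolves
#' them from genomic context. Boolean columns flag genes that pass the tyrosine
#' recombinase and integron-integrase signature references regardless of the
#' best-hit role, since integron integrases carry both signals on one gene.
#' Hits feeding these multi-signal rules must clear the auxiliary identity
#' floor (see \code{\link{roleThresholds}}).
#'
#' @param genes data.frame with columns \code{gene_id} and \code{protein}.
#' @param reference library from \code{\link{readReferenceLibrary}}, or a
#'   precomputed hit table (see \code{hits}).
#' @param thresholds from \code{\link{roleThresholds}}.
#' @param hits optional precomputed hit table in the \code{\link{alignStats}}
#'   schema (e.g. from \code{\link{readBlastTab}} with reference sequences as
#'   subjects); when supplied the built-in aligner is skipped.
#' @return data.frame: gene_id, role, rm_type, best_ref, score, identity,
#'   evalue_proxy, ambiguous_ii_iv, has_integrase_tyr, has_integron_signature.
#' @export
assignRoles <- function(genes, reference, thresholds = roleThresholds(),
                        hits = NULL) {
  if (is.null(reference$info) || !nrow(reference$info))
    stop("empty reference library")
  info <- reference$info
  if (is.null(hits)) {
    gene_seqs <- setNames(genes$protein, genes$gene_id)
    cand <- kmerCandidatePairs(gene_seqs, reference$seqs)
    hits <- alignStatsPairs(unname(gene_seqs[cand$query_id]),
                            unname(reference$seqs[cand$subject_id]), "local",
                            query_ids = cand$query_id,
                            subject_ids = cand$subject_id)
  }
  hits <- merge(hits, info, by.x = "subject_id", by.y = "ref_id")
  gated <- .coverage_gated(hits$role, hits$rm_type)
  pass <- hits$evalue_proxy < thresholds$evalue_max &
    (!gated | hits$subject_coverage >= thresholds$coverage_min)
  hits <- hits[pass, , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id, role = "other",
                    rm_type = "none", best_ref = NA_character_,
                    score = NA_real_, identity = NA_real_,
                    evalue_proxy = NA_real_,
                    ambiguous_ii_iv = FALSE, has_integrase_tyr = FALSE,
                    has_integron_signature = FALSE, stringsAsFactors = FALSE)
  if (!nrow(hits)) return(out)
  hits <- hits[order(hits$query_id, -hits$score, hits$subject_id), , drop = FALSE]
  by_gene <- split(hits, hits$query_id)
  for (gid in names(by_gene)) {
    h <- by_gene[[gid]]
    i <- match(gid, out$gene_id)
    if (is.na(i)) next
    ha <- h[h$identity >= thresholds$aux_identity_min, , drop = FALSE]
    iic_m <- any(ha$role == "MTase" & ha$rm_type == "IIC")
    iic_r <- any(ha$role == "REase" & ha$rm_type == "IIC")
    best <- h[1, ]
    if (iic_m && iic_r) {
      out$role[i] <- "IIC"; out$rm_type[i] <- "none"
      best <- ha[ha$rm_type == "IIC", ][1, ]
    } else {
      out$role[i] <- best$role
      out$rm_type[i] <- if (best$role %in% c("REase", "MTase", "S") &&
                            best$rm_type %in% c("I", "II", "III"))
        best$rm_type else "none"
    }
    out$best_ref[i] <- best$subject_id
    out$score[i] <- best$score
    out$identity[i] <- best$identity
    out$evalue_proxy[i] <- best$evalue_proxy
    # II/IV ambiguity: only when the gene is actually called as one of the
    # two REase classes and the competing class scores comparably (weak
    # incidental cross-hits must not overturn a confident call)
    s_re2 <- suppressWarnings(max(h$score[h$role == "REase" &
                                            h$rm_type == "II"], -Inf))
    s_iv <- suppressWarnings(max(h$score[h$role == "TypeIV_REase"], -Inf))
    out$ambiguous_ii_iv[i] <-
      out$role[i] %in% c("REase", "TypeIV_REase") &&
      (out$role[i] != "REase" || out$rm_type[i] == "II") &&
      is.finite(s_re2) && is.finite(s_iv) &&
      min(s_re2, s_iv) >= 0.5 * max(s_re2, s_iv)
    out$has_integrase_tyr[i] <- any(ha$role == "integrase_tyr")
    out$has_integron_signature[i] <- any(ha$role == "integron_signature")
  }
  out
}

#' Role calls for every gene of a GenomeSet
#'
#' @param gs \linkS4class{GenomeSet}.
#' @param reference labeled library (\code{\link{readReferenceLibrary}}).
#' @param thresholds role-call thresholds.
#' @return role table with genome_id/replicon_id/rank columns joined in.
#' @export
assignRolesGenomeSet <- function(gs, reference, thresholds = roleThresholds()) {
  gt <- geneTable(gs)
  roles <- assignRoles(gt[, c("gene_id", "protein")], reference, thresholds)
  merge(gt[, c("genome_id", "replicon_id", "gene_id", "rank")], roles,
        by = "gene_id", sort = FALSE)
}
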