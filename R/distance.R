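#' Rank distance between two genes on one replicon
#'
#' Distance is measured in gene-order offsets: adjacent genes are 1 apart.
#' On circular replicons the shorter of the two arcs is used; linear replicons
#' use the plain absolute rank offset. Strand is ignored. All neighborhood
#' thresholds in the pipeline ("less than four genes apart", "less than 10
#' genes away") are applied to this quantity as printed, e.g. a cognate pair at
#' offset 3 satisfies "less than four".
#'
#' @param rank_a,rank_b 0-based gene ranks (vectors recycle).
#' @param n_genes number of genes on the replicon.
#' @param circular logical; wrap around the origin when TRUE.
#' @return integer vector of non-negative offsets.
#' @export
rankDistance <- function(rank_a, rank_b, n_genes, circular = TRUE) {
  d <- abs(as.integer(rank_a) - as.integer(rank_b))
  if (circular) d <- pmin(d, n_genes - d)
  as.integer(d)
}

#' Rank distance between two genes, checking they share a replicon
#'
#' @param a,b single-row gene records (as in \code{geneTable}) carrying
#'   \code{rank} and \code{replicon_id}.
#' @param replicon the \linkS4class{Replicon} both genes lie on.
#' @return non-negative integer offset.
#' @export
geneDistance <- function(a, b, replicon) {
  if (!identical(a$replicon_id, b$replicon_id) ||
      !identical(a$replicon_id, repliconId(replicon)))
    stop("geneDistance is undefined for genes on different replicons")
  rankDistance(a$rank, b$rank, nGenes(replicon), isCircular(replicon))
}

#' Ranks within a rank-offset neighborhood
#'
#' @param rank focal 0-based rank
#' @param k half-width (offsets 1..k on each side)
#' @param n_genes,circular replicon geometry
#' @return integer vector of neighbor ranks (focal excluded)
#' @export
neighborRanks <- function(rank, k, n_genes, circular = TRUE) {
  off <- setdiff(seq.int(-k, k), 0L)
  r <- rank + off
  if (circular) r <- r %% n_genes else r <- r[r >= 0 & r < n_genes]
  unique(r[r != rank])
}
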