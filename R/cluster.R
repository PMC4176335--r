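## Protein family clustering: Markov clustering (MCL) over a similarity graph
## and single-linkage at identity/coverage thresholds.

#' Markov clustering of a weighted similarity graph
#'
#' Classic MCL iteration: self-loops are added with weight equal to the
#' maximum incident edge weight, columns are normalised to stochastic, then
#' expansion (matrix squaring) and inflation (elementwise power I followed by
#' renormalisation) alternate until the matrix change drops below \code{tol}.
#' Attractor rows (positive diagonal) define clusters; overlapping attractor
#' sets are merged.
#'
#' @param edges data.frame with columns \code{from, to, weight} (symmetrised
#'   by maximum weight if both orientations are present).
#' @param ids universe of node ids (isolated nodes become singletons).
#' @param inflation inflation parameter I (>= 1).
#' @param tol convergence tolerance on the max absolute matrix change.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return data.frame(member_id, family_id).
#' @export
mclCluster <- function(edges, ids = NULL, inflation = 1.4, tol = 1e-6,
                       max_iter = 200) {
  stopifnot(inflation >= 1)
  ids <- sort(unique(c(ids, edges$from, edges$to)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    i <- match(edges$from, ids); j <- match(edges$to, ids)
    w <- abs(edges$weight)
    for (k in seq_along(i)) {
      M[i[k], j[k]] <- max(M[i[k], j[k]], w[k])
      M[j[k], i[k]] <- max(M[j[k], i[k]], w[k])
    }
  }
  loop <- apply(M, 1, max); loop[loop == 0] <- 1
  diag(M) <- loop
  normalize <- function(A) sweep(A, 2, colSums(A), "/")
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    M2 <- normalize((M %*% M)^inflation)
    M2[M2 < 1e-12] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
    if (it == max_iter)
      stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                   max_iter, delta))
  }
  attractors <- which(diag(M) > tol)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  for (a in attractors) {
    members <- which(M[a, ] > tol)
    if (length(members) > 1)
      g <- igraph::add_edges(g, as.vector(rbind(members[1], members[-1])))
  }
  comp <- igraph::components(g)$membership
  .family_table(ids, comp)
}

#' Single-linkage families from thresholded alignment hits
#'
#' Edges are hits passing the identity threshold and, when present, the
#' coverage-of-smallest threshold; families are connected components, so
#' membership is transitive (a chain A-B, B-C above threshold joins A and C
#' even when A-C falls below it).
#'
#' @param hits data.frame in the \code{\link{alignStats}} schema; the coverage
#'   of the smaller sequence is taken as
#'   \code{pmax(query_coverage, subject_coverage)}.
#' @param ids universe of sequence ids (singletons allowed).
#' @param identity_min minimum identity fraction.
#' @param coverage_min minimum coverage of the smallest protein (strictly
#'   greater than; set to 0 to disable).
#' @param evalue_max optional e-value gate applied before thresholding.
#' @return data.frame(member_id, family_id).
#' @export
singleLinkageFamilies <- function(hits, ids = NULL, identity_min = 0.8,
                                  coverage_min = 0.8, evalue_max = Inf) {
  ids <- sort(unique(c(ids, hits$query_id, hits$subject_id)))
  cov_small <- pmax(hits$query_coverage, hits$subject_coverage)
  pass <- hits$identity >= identity_min & hits$evalue_proxy < evalue_max &
    (coverage_min == 0 | cov_small > coverage_min)
  e <- hits[pass & hits$query_id != hits$subject_id, c("query_id", "subject_id")]
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  .family_table(ids, comp)
}

# Deterministic family ids: fam_0001.. ordered by each family's smallest member.
.family_table <- function(ids, membership) {
  reps <- tapply(ids, membership, min)
  ord <- rank(reps)
  fam <- sprintf("fam_%04d", ord[as.character(membership)])
  out <- data.frame(member_id = ids, family_id = fam, stringsAsFactors = FALSE)
  out[order(out$family_id, out$member_id), , drop = FALSE]
}

#' Cluster sequences into families
#'
#' Unified front end over the two clustering algorithms used in the pipeline:
#' \code{"mcl"} (Markov clustering of log-e-value weighted similarity graphs)
#' and \code{"single_linkage"} (identity/coverage thresholded connected
#' components).
#'
#' @param hits alignment hit table (\code{\link{alignStats}} schema).
#' @param method clustering method.
#' @param ids universe of sequence ids.
#' @param inflation MCL inflation parameter.
#' @param identity_min,coverage_min,evalue_max single-linkage thresholds.
#' @param weight_col column used as MCL edge weight; the default transforms
#'   the e-value surrogate as -log10(e), floored at 0.
#' @return data.frame(member_id, family_id).
#' @export
clusterFamilies <- function(hits, method = c("mcl", "single_linkage"),
                            ids = NULL, inflation = 1.4, identity_min = 0.8,
                            coverage_min = 0.8, evalue_max = Inf,
                            weight_col = NULL) {
  method <- match.arg(method)
  if (method == "single_linkage")
    return(singleLinkageFamilies(hits, ids, identity_min, coverage_min,
                                 evalue_max))
  w <- if (!is.null(weight_col)) hits[[weight_col]]
       else pmax(-log10(pmax(hits$evalue_proxy, 1e-300)), 0)
  edges <- data.frame(from = hits$query_id, to = hits$subject_id, weight = w)
  edges <- edges[edges$weight > 0 & edges$from != edges$to, , drop = FALSE]
  mclCluster(edges, ids, inflation)
}
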