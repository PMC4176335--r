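#' Bidirectional best hits between two proteomes
#'
#' Candidate pairs are seeded by shared k-mers, aligned with end-gap-free
#' global alignment, and filtered: hits with similarity below
#' \code{min_similarity} (fraction of aligned columns with a positive
#' substitution score) or relative length difference above
#' \code{max_length_diff} are discarded. A pair is kept when each member is
#' the other's best surviving hit by score. Score ties are broken by the
#' lexicographically lowest subject id and flagged in the \code{tie} column.
#'
#' @param proteome_a,proteome_b named character vectors of protein sequences.
#' @param min_similarity minimum similarity fraction (default 0.8: hits below
#'   80 percent similarity are discarded).
#' @param max_length_diff maximum relative protein length difference
#'   (default 0.2: more than 20 percent difference is discarded).
#' @param mode alignment mode (end-gap-free global by default).
#' @return data.frame: gene_a, gene_b, similarity, identity, length_diff,
#'   score, tie.
#' @export
bbhPairs <- function(proteome_a, proteome_b, min_similarity = 0.8,
                     max_length_diff = 0.2, mode = "global_endgapfree") {
  stopifnot(length(proteome_a) > 0, length(proteome_b) > 0)
  cand <- kmerCandidatePairs(proteome_a, proteome_b)
  if (!nrow(cand))
    return(data.frame(gene_a = character(), gene_b = character(),
                      similarity = numeric(), identity = numeric(),
                      length_diff = numeric(), score = numeric(),
                      tie = logical()))
  hits <- alignStatsPairs(unname(proteome_a[cand$query_id]),
                          unname(proteome_b[cand$subject_id]), mode,
                          query_ids = cand$query_id,
                          subject_ids = cand$subject_id)
  hits <- hits[hits$similarity >= min_similarity &
                 hits$length_diff <= max_length_diff, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene_a = character(), gene_b = character(),
                      similarity = numeric(), identity = numeric(),
                      length_diff = numeric(), score = numeric(),
                      tie = logical()))
  best_of <- function(h, key, other) {
    h <- h[order(h[[key]], -h$score, h[[other]]), , drop = FALSE]
    tie <- tapply(h$score, h[[key]], function(s) sum(s == max(s)) > 1)
    first <- h[!duplicated(h[[key]]), , drop = FALSE]
    first$tie <- as.logical(tie[first[[key]]])
    first
  }
  best_a <- best_of(hits, "query_id", "subject_id")   # best hit of each a
  best_b <- best_of(hits, "subject_id", "query_id")   # best hit of each b
  key_a <- paste(best_a$query_id, best_a$subject_id)
  key_b <- paste(best_b$query_id, best_b$subject_id)
  keep <- key_a %in% key_b
  res <- best_a[keep, , drop = FALSE]
  tie_b <- best_b$tie[match(key_a[keep], key_b)]
  data.frame(gene_a = res$query_id, gene_b = res$subject_id,
             similarity = res$similarity, identity = res$identity,
             length_diff = res$length_diff, score = res$score,
             tie = res$tie | tie_b,
             stringsAsFactors = FALSE, row.names = NULL)
}
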