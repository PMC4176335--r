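## Pairwise protein alignment and alignment statistics.
##
## All similarity searches in the pipeline go through these helpers, which
## wrap Biostrings dynamic programming under a fixed scoring scheme (BLOSUM62,
## affine gaps 10/0.5). Two modes are used: "local" (Smith-Waterman, the
## BLASTP-like search used for role calls and family clustering) and
## "global_endgapfree" (end-gap-free global, used for bidirectional best hits
## when building core genomes). Candidate pairs are aligned in one vectorised
## dynamic-programming call and statistics are extracted with vectorised
## accessors, so large all-vs-all searches stay fast.

ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXT <- 0.5

# Karlin-Altschul-style surrogate for BLAST e-values; constants fixed in
# config. Only ever compared against thresholds, so any monotone transform of
# the score with search-space scaling works.
KA_LAMBDA <- 0.267
KA_K <- 0.041

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

.align_type <- function(mode) {
  switch(mode, local = "local", global_endgapfree = "overlap",
         stop("unknown alignment mode: ", mode))
}

.clean_aa <- function(x) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x)
  if (any(bad)) {
    warning("unknown residues treated as wildcard X")
    x[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX*]", "X", x[bad])
  }
  x
}

#' Alignment statistics for paired sequence lists
#'
#' Aligns \code{queries[i]} to \code{subjects[i]} for every i in one
#' vectorised dynamic-programming call. Identity and similarity are fractions
#' of alignment columns (end gaps excluded; internal gap columns count in the
#' denominator); similarity counts columns whose BLOSUM62 score is positive.
#' Coverage is the aligned span over the full sequence length;
#' \code{length_diff} is the relative difference of the full sequence
#' lengths. \code{evalue_proxy} is a Karlin-Altschul-style transform of the
#' raw score scaled by the pair's search space.
#'
#' @param queries,subjects equal-length character vectors of amino-acid
#'   sequences.
#' @param mode \code{"local"} or \code{"global_endgapfree"}.
#' @param query_ids,subject_ids identifiers for the output table.
#' @return data.frame: query_id, subject_id, identity, similarity,
#'   query_coverage, subject_coverage, score, evalue_proxy, length_diff.
#' @export
alignStatsPairs <- function(queries, subjects,
                            mode = c("local", "global_endgapfree"),
                            query_ids = names(queries),
                            subject_ids = names(subjects)) {
  mode <- match.arg(mode)
  stopifnot(length(queries) == length(subjects))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), similarity = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      score = numeric(), evalue_proxy = numeric(),
                      length_diff = numeric(), stringsAsFactors = FALSE)
  if (!length(queries)) return(empty)
  if (any(!nzchar(queries)) || any(!nzchar(subjects))) stop("empty sequence")
  q <- .clean_aa(toupper(queries)); s <- .clean_aa(toupper(subjects))
  pa <- pairwiseAlignment(AAStringSet(q), AAStringSet(s),
                          substitutionMatrix = .blosum62(),
                          gapOpening = ALIGN_GAP_OPEN,
                          gapExtension = ALIGN_GAP_EXT,
                          type = .align_type(mode))
  ncols <- Biostrings::nchar(pa)
  nm <- Biostrings::nmatch(pa)
  pos_counts <- numeric(length(q))
  mt <- Biostrings::mismatchTable(pa)
  if (nrow(mt)) {
    bl <- .blosum62()
    pos <- bl[cbind(match(as.character(mt$PatternSubstring), rownames(bl)),
                    match(as.character(mt$SubjectSubstring), colnames(bl)))] > 0
    cnt <- tapply(pos, mt$PatternId, sum)
    pos_counts[as.integer(names(cnt))] <- as.numeric(cnt)
  }
  qlen <- nchar(q); slen <- nchar(s)
  sc <- as.numeric(BiocGenerics::score(pa))
  ident <- ifelse(ncols > 0, nm / ncols, 0)
  data.frame(
    query_id = query_ids %||% paste0("q", seq_along(q)),
    subject_id = subject_ids %||% paste0("s", seq_along(s)),
    identity = ident,
    similarity = pmax(ifelse(ncols > 0, (nm + pos_counts) / ncols, 0), ident),
    query_coverage = Biostrings::width(Biostrings::pattern(pa)) / qlen,
    subject_coverage = Biostrings::width(Biostrings::subject(pa)) / slen,
    score = sc,
    evalue_proxy = KA_K * qlen * slen * exp(-KA_LAMBDA * sc),
    length_diff = abs(qlen - slen) / pmax(qlen, slen),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Align one protein against a set of subjects
#'
#' @param query named length-1 character vector (amino-acid sequence).
#' @param subjects named character vector of subject sequences.
#' @param mode see \code{\link{alignStatsPairs}}.
#' @return data.frame of alignment statistics, one row per subject.
#' @export
alignStats <- function(query, subjects, mode = c("local", "global_endgapfree")) {
  mode <- match.arg(mode)
  stopifnot(length(query) == 1)
  alignStatsPairs(rep(unname(query), length(subjects)), unname(subjects), mode,
                  query_ids = rep(names(query) %||% "query", length(subjects)),
                  subject_ids = names(subjects) %||%
                    paste0("s", seq_along(subjects)))
}

#' Pairwise alignment statistics for a single sequence pair
#'
#' @param a,b amino-acid sequences (length-1 character, optionally named).
#' @param mode see \code{\link{alignStatsPairs}}.
#' @return one-row data.frame of alignment statistics.
#' @export
pairwiseAlign <- function(a, b, mode = c("local", "global_endgapfree")) {
  mode <- match.arg(mode)
  alignStatsPairs(as.character(a)[1], as.character(b)[1], mode,
                  query_ids = names(a) %||% "a",
                  subject_ids = names(b) %||% "b")
}

## ---- k-mer candidate prefilter ---------------------------------------------

.kmer_sets <- function(seqs, k = 4) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Candidate sequence pairs sharing at least a minimum number of k-mers
#'
#' Seed-style prefilter used before dynamic programming in all-vs-all
#' searches. Pairs of unrelated random proteins essentially never share two
#' 4-mers, while homologs above roughly 60 percent identity essentially
#' always do; the thresholds are config-visible.
#'
#' @param seqs_a,seqs_b named character vectors; if \code{seqs_b} is NULL,
#'   candidate pairs within \code{seqs_a} (i < j) are returned.
#' @param k k-mer length.
#' @param min_shared minimum number of distinct shared k-mers.
#' @return data.frame(query_id, subject_id).
#' @export
kmerCandidatePairs <- function(seqs_a, seqs_b = NULL, k = 4, min_shared = 2) {
  self <- is.null(seqs_b)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE)
  ka <- .kmer_sets(seqs_a, k)
  kb <- if (self) ka else .kmer_sets(seqs_b, k)
  buckets_a <- split(rep(seq_along(ka), lengths(ka)),
                     unlist(ka, use.names = FALSE))
  buckets_b <- if (self) buckets_a else
    split(rep(seq_along(kb), lengths(kb)), unlist(kb, use.names = FALSE))
  common <- intersect(names(buckets_a), names(buckets_b))
  if (self) common <- common[lengths(buckets_a[common]) >= 2]
  if (!length(common)) return(empty)
  # encode each candidate pair as i * 2^20 + j and count shared k-mers by rle
  keys <- unlist(lapply(common, function(km) {
    ia <- buckets_a[[km]]
    if (self) {
      m <- length(ia)
      i <- rep(seq_len(m - 1), (m - 1):1)
      j <- sequence((m - 1):1) + i
      ia[i] * 2^20 + ia[j]
    } else {
      ib <- buckets_b[[km]]
      rep(ia, each = length(ib)) * 2^20 + rep(ib, length(ia))
    }
  }), use.names = FALSE)
  if (!length(keys)) return(empty)
  keys <- sort(keys)
  r <- rle(keys)
  keep <- r$values[r$lengths >= min_shared]
  if (!length(keep)) return(empty)
  i <- keep %/% 2^20; j <- keep %% 2^20
  out <- data.frame(query_id = names(seqs_a)[i],
                    subject_id = names(if (self) seqs_a else seqs_b)[j],
                    stringsAsFactors = FALSE)
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' All-vs-all alignment hits with k-mer prefiltering
#'
#' @param seqs named character vector of protein sequences.
#' @param mode alignment mode, see \code{\link{alignStatsPairs}}.
#' @param k,min_shared prefilter parameters (\code{\link{kmerCandidatePairs}}).
#' @param symmetric if TRUE each unordered pair is aligned once and mirrored.
#' @return data.frame of alignment statistics for candidate pairs.
#' @export
allVsAllHits <- function(seqs, mode = "local", k = 4, min_shared = 2,
                         symmetric = TRUE) {
  cand <- kmerCandidatePairs(seqs, NULL, k = k, min_shared = min_shared)
  hits <- alignStatsPairs(unname(seqs[cand$query_id]),
                          unname(seqs[cand$subject_id]), mode,
                          query_ids = cand$query_id,
                          subject_ids = cand$subject_id)
  if (symmetric && nrow(hits)) {
    rev <- hits
    rev$query_id <- hits$subject_id; rev$subject_id <- hits$query_id
    rev$query_coverage <- hits$subject_coverage
    rev$subject_coverage <- hits$query_coverage
    hits <- rbind(hits, rev)
  }
  hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
}

#' Read similarity hits in BLAST tabular (outfmt 6) dialect
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Percent identity is rescaled to a fraction and the
#' file's e-value is used directly as \code{evalue_proxy}. Coverages are
#' computed when sequence lengths are supplied.
#'
#' @param path tabular file path.
#' @param query_lengths,subject_lengths optional named integer vectors.
#' @return data.frame in the \code{\link{alignStatsPairs}} schema (similarity
#'   is set equal to identity, the closest available surrogate).
#' @export
readBlastTab <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                    stringsAsFactors = FALSE)
  qcov <- scov <- rep(NA_real_, nrow(tab))
  if (!is.null(query_lengths))
    qcov <- abs(tab$qend - tab$qstart + 1) / query_lengths[tab$query_id]
  if (!is.null(subject_lengths))
    scov <- abs(tab$send - tab$sstart + 1) / subject_lengths[tab$subject_id]
  ld <- rep(NA_real_, nrow(tab))
  if (!is.null(query_lengths) && !is.null(subject_lengths)) {
    ql <- query_lengths[tab$query_id]; sl <- subject_lengths[tab$subject_id]
    ld <- abs(ql - sl) / pmax(ql, sl)
  }
  data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
             identity = tab$pident / 100, similarity = tab$pident / 100,
             query_coverage = qcov, subject_coverage = scov,
             score = tab$bitscore, evalue_proxy = tab$evalue,
             length_diff = ld, stringsAsFactors = FALSE)
}
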