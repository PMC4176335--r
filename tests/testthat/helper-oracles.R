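# Independent oracles and shared fixtures. Oracles are deliberately written
# as plain, slow reference code, sharing no internals with the package paths
# they check.

## ---- shared fixtures (memoized across test files) --------------------------

.fixtures <- new.env(parent = emptyenv())

shared_lib <- function() {
  if (is.null(.fixtures$lib)) .fixtures$lib <- buildReferenceLibrary(101)
  .fixtures$lib
}

shared_dataset <- function() {
  if (is.null(.fixtures$dataset))
    .fixtures$dataset <- simulateDataset(shared_lib(), n_genomes = 20, seed = 1)
  .fixtures$dataset
}

shared_roles <- function() {
  if (is.null(.fixtures$roles)) {
    ds <- shared_dataset()
    .fixtures$roles <- assignRolesGenomeSet(ds$gs, ds$lib)
  }
  .fixtures$roles
}

shared_detection <- function() {
  if (is.null(.fixtures$detection))
    .fixtures$detection <- detectRMSystems(shared_dataset()$gs, shared_roles())
  .fixtures$detection
}

shared_clade <- function() {
  if (is.null(.fixtures$clade))
    .fixtures$clade <- simulateClade(shared_lib(), cladePlan(), seed = 7)
  .fixtures$clade
}

## ---- alignment oracle: plain Gotoh affine-gap DP ---------------------------

# Returns the optimal local alignment score under BLOSUM62 with gap open 10 /
# extend 0.5, charging open+extend for the first gap position (Biostrings
# convention).
oracle_local_score <- function(a, b, go = 10, ge = 0.5) {
  bl <- rmscape:::.blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in match state
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- bl[a[i - 1], b[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    best <- max(best, M[i, j])
  }
  best
}

## ---- NG86 oracle: recursive pathway enumeration ----------------------------

oracle_ng86 <- function(dna1, dna2) {
  gc <- Biostrings::GENETIC_CODE
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(toupper(dna1)); c2 <- split3(toupper(dna2))
  stopifnot(length(c1) == length(c2))
  nuc <- c("A", "C", "G", "T")
  sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(nuc, ch[p])
      ok <- 0; syn <- 0
      for (x in alts) {
        t <- ch; t[p] <- x; t <- paste(t, collapse = "")
        if (gc[[t]] == "*") next
        ok <- ok + 1
        if (gc[[t]] == gc[[codon]]) syn <- syn + 1
      }
      if (ok > 0) s <- s + syn / ok
    }
    s
  }
  # all pathways between codons by recursion
  paths <- function(from, to) {
    dp <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dp)) return(list(list(sd = 0, nd = 0, valid = TRUE)))
    out <- list()
    for (p in dp) {
      ch <- strsplit(from, "")[[1]]
      ch[p] <- strsplit(to, "")[[1]][p]
      mid <- paste(ch, collapse = "")
      step_valid <- gc[[mid]] != "*"
      step_syn <- step_valid && gc[[mid]] == gc[[from]]
      for (rest in paths(mid, to)) {
        out[[length(out) + 1L]] <- list(
          sd = rest$sd + as.numeric(step_syn),
          nd = rest$nd + as.numeric(!step_syn),
          valid = rest$valid && step_valid)
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    S <- S + (sites(c1[i]) + sites(c2[i])) / 2
    pp <- paths(c1[i], c2[i])
    ok <- Filter(function(p) p$valid, pp)
    if (!length(ok)) ok <- pp
    Sd <- Sd + mean(vapply(ok, `[[`, numeric(1), "sd"))
    Nd <- Nd + mean(vapply(ok, `[[`, numeric(1), "nd"))
  }
  N <- 3 * length(c1) - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) Inf else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(pS), dN = jc(pN))
}

## ---- MCL oracle: plain dense iteration -------------------------------------

oracle_mcl <- function(adj, inflation, iters = 300) {
  # adj: symmetric weighted adjacency matrix with named dims
  diag(adj) <- apply(adj, 1, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-14] <- 0
    M <- sweep(M, 2, colSums(M), "/")
  }
  # cluster: nodes supported by the same attractor set
  memb <- apply(M > 1e-6, 2, function(col) paste(which(col), collapse = ","))
  split(colnames(adj), memb)
}

## ---- union-find oracle for single linkage ----------------------------------

oracle_union_find <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$from[k]); rb <- find(edges$to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, find, character(1))
}

## ---- misc helpers ----------------------------------------------------------

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, TRUE),
        collapse = "")
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n_codons, TRUE), collapse = "")
}

# a tiny hand-built replicon: proteins/dna need not be biologically paired
toy_replicon <- function(n = 20, id = "chr", circular = TRUE, kind = "chromosome") {
  genes <- data.frame(
    gene_id = sprintf("%s_g%02d", id, seq_len(n)),
    rank = seq_len(n) - 1L,
    start = seq(100, by = 500, length.out = n),
    end = seq(100, by = 500, length.out = n) + 299L,
    strand = rep(c("+", "-"), length.out = n),
    protein = vapply(seq_len(n), function(i) random_protein(99, seed = i), ""),
    dna = NA_character_, stringsAsFactors = FALSE)
  Replicon(id, kind, 500 * n + 1000, circular, genes)
}

# role table for a toy replicon with planted roles at given ranks
toy_roles <- function(replicon, role_at = list()) {
  g <- replicon@genes
  out <- data.frame(gene_id = g$gene_id, rank = g$rank, role = "other",
                    rm_type = "none", ambiguous_ii_iv = FALSE,
                    has_integrase_tyr = FALSE, has_integron_signature = FALSE,
                    stringsAsFactors = FALSE)
  for (spec in role_at) {
    i <- which(out$rank == spec$rank)
    out$role[i] <- spec$role
    out$rm_type[i] <- spec$rm_type %||% "none"
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
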