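# Alignment statistics, role assignment, BBH and clustering.

test_that("alignment statistics match their definitions on constructed pairs", {
  p <- random_protein(50, seed = 1)
  st <- pairwiseAlign(setNames(p, "a"), setNames(p, "b"))
  expect_equal(st$identity, 1)
  expect_equal(st$similarity, 1)
  expect_equal(st$query_coverage, 1)
  expect_equal(st$subject_coverage, 1)
  # C-terminal extension, end-gap-free: identity 1 over the aligned core
  q <- random_protein(50, seed = 2)
  st2 <- pairwiseAlign(setNames(q, "a"),
                       setNames(paste0(q, random_protein(10, seed = 3)), "b"),
                       mode = "global_endgapfree")
  expect_equal(st2$identity, 1)
  expect_equal(st2$length_diff, 10 / 60)
  expect_error(pairwiseAlign("", "AAA"), "empty")
  expect_warning(pairwiseAlign("MKVB", "MKVA"), "wildcard")
})

test_that("local alignment score equals an independent Gotoh DP oracle", {
  set.seed(11)
  for (i in 1:12) {
    a <- random_protein(30)
    b <- if (i %% 3 == 0) {
      # related pair: mutate a few positions so alignments are non-trivial
      ch <- strsplit(a, "")[[1]]
      ch[sample(30, 6)] <- sample(c("A", "G", "W", "P"), 6, TRUE)
      paste(ch, collapse = "")
    } else random_protein(30)
    got <- pairwiseAlign(setNames(a, "a"), setNames(b, "b"), "local")$score
    expect_equal(got, oracle_local_score(a, b), tolerance = 1e-9)
  }
})

test_that("alignment score and identity are symmetric in sequence order", {
  set.seed(21)
  for (i in 1:8) {
    a <- random_protein(40); b <- random_protein(40)
    s1 <- pairwiseAlign(setNames(a, "a"), setNames(b, "b"))
    s2 <- pairwiseAlign(setNames(b, "b"), setNames(a, "a"))
    expect_equal(s1$score, s2$score)
    expect_equal(s1$identity, s2$identity)
  }
})

test_that("role assignment follows best passing hit with coverage gating", {
  lib <- shared_lib()
  mt <- lib$seqs[["ref_MTase_II_a_f"]]
  re <- lib$seqs[["ref_REase_II_a_f"]]
  iic <- paste0(lib$seqs[["ref_IIC_R_f"]], lib$seqs[["ref_IIC_M_f"]])
  # a gene that is only a 40%-length fragment of a Type II REase: fails the
  # 50% reference-coverage gate, so no REase call
  frag <- substr(re, 1, round(nchar(re) * 0.4))
  genes <- data.frame(
    gene_id = c("gm", "gr", "gfrag", "giic", "gbg"),
    protein = c(mt, re, frag, iic, random_protein(120, seed = 5)),
    stringsAsFactors = FALSE)
  rc <- assignRoles(genes, lib)
  rc <- rc[match(genes$gene_id, rc$gene_id), ]
  expect_equal(rc$role, c("MTase", "REase", "other", "IIC", "other"))
  expect_equal(rc$rm_type, c("II", "II", "none", "none", "none"))
  expect_error(assignRoles(genes, list(info = NULL)), "empty reference")
})

test_that("bidirectional best hits pass the similarity and length filters", {
  set.seed(31)
  prots <- setNames(vapply(1:6, function(i) random_protein(100), ""),
                    sprintf("p%d", 1:6))
  # identical proteomes: everything pairs with itself
  bb <- bbhPairs(prots, prots)
  expect_equal(nrow(bb), 6L)
  expect_true(all(bb$gene_a == bb$gene_b))
  expect_true(all(bb$similarity == 1))
  # length filter: 30 extra residues on 100 -> length_diff 0.23 > 0.2
  long <- setNames(paste0(prots[["p1"]], random_protein(30)), "p1L")
  bb2 <- bbhPairs(prots["p1"], long)
  expect_equal(nrow(bb2), 0L)
})

test_that("bbh pairs equal a brute-force all-vs-all best-hit oracle", {
  set.seed(41)
  base <- vapply(1:5, function(i) random_protein(90), "")
  mutate <- function(p, k) {
    ch <- strsplit(p, "")[[1]]
    pos <- sample(length(ch), k)
    for (j in pos) ch[j] <- sample(setdiff(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]], ch[j]), 1)
    paste(ch, collapse = "")
  }
  pa <- setNames(base, sprintf("a%d", 1:5))
  pb <- setNames(vapply(base, mutate, "", k = 6), sprintf("b%d", 1:5))
  got <- bbhPairs(pa, pb)
  # oracle: align every pair with no prefilter, apply filters, reciprocal best
  stats <- do.call(rbind, lapply(names(pa), function(i)
    do.call(rbind, lapply(names(pb), function(j)
      cbind(pairwiseAlign(setNames(pa[[i]], i), setNames(pb[[j]], j),
                          "global_endgapfree"))))))
  stats <- stats[stats$similarity >= 0.8 & stats$length_diff <= 0.2, ]
  keep <- list()
  for (i in names(pa)) {
    si <- stats[stats$query_id == i, ]
    if (!nrow(si)) next
    best_j <- si$subject_id[order(-si$score, si$subject_id)][1]
    sj <- stats[stats$subject_id == best_j, ]
    best_i <- sj$query_id[order(-sj$score, sj$query_id)][1]
    if (identical(best_i, i)) keep[[i]] <- c(i, best_j)
  }
  oracle_pairs <- unname(sort(vapply(keep, paste, "", collapse = "|")))
  expect_equal(sort(paste(got$gene_a, got$gene_b, sep = "|")), oracle_pairs)
  # symmetry in argument order
  rev <- bbhPairs(pb, pa)
  expect_equal(sort(paste(got$gene_a, got$gene_b)),
               sort(paste(rev$gene_b, rev$gene_a)))
})

test_that("single-linkage families are transitive and refine across thresholds", {
  mk_hit <- function(a, b, id) data.frame(
    query_id = a, subject_id = b, identity = id, similarity = id,
    query_coverage = 1, subject_coverage = 1, score = 100,
    evalue_proxy = 1e-10, length_diff = 0)
  hits <- rbind(mk_hit("A", "B", 0.85), mk_hit("B", "C", 0.82),
                mk_hit("A", "C", 0.45))
  fam <- singleLinkageFamilies(hits, ids = c("A", "B", "C"),
                               identity_min = 0.8, coverage_min = 0)
  expect_equal(length(unique(fam$family_id)), 1L)
  # two 3-cliques with no cross edges -> 2 families under both methods
  cl1 <- rbind(mk_hit("A", "B", .9), mk_hit("B", "C", .9), mk_hit("A", "C", .9))
  cl2 <- rbind(mk_hit("X", "Y", .9), mk_hit("Y", "Z", .9), mk_hit("X", "Z", .9))
  hits2 <- rbind(cl1, cl2)
  f_sl <- clusterFamilies(hits2, "single_linkage",
                          ids = c("A","B","C","X","Y","Z"), coverage_min = 0)
  expect_equal(length(unique(f_sl$family_id)), 2L)
  f_mcl <- clusterFamilies(hits2, "mcl", ids = c("A","B","C","X","Y","Z"))
  expect_equal(length(unique(f_mcl$family_id)), 2L)
  expect_equal(unname(table(f_mcl$family_id)[f_mcl$family_id[f_mcl$member_id == "A"]]), 3L)
  # random graphs: stringent families refine relaxed families
  set.seed(17)
  for (rep in 1:10) {
    ids <- sprintf("n%02d", 1:12)
    pairs <- t(combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.25
    h <- do.call(rbind, lapply(which(sel), function(k)
      mk_hit(pairs[k, 1], pairs[k, 2], runif(1, 0.3, 1))))
    if (is.null(h)) next
    f80 <- singleLinkageFamilies(h, ids, 0.8, coverage_min = 0)
    f40 <- singleLinkageFamilies(h, ids, 0.4, coverage_min = 0)
    m80 <- setNames(f80$family_id, f80$member_id)
    m40 <- setNames(f40$family_id, f40$member_id)
    per80 <- tapply(m40[names(m80)], m80, function(v) length(unique(v)))
    expect_true(all(per80 == 1))
  }
})

test_that("single-linkage partition equals an independent union-find oracle", {
  set.seed(23)
  for (rep in 1:5) {
    ids <- sprintf("n%02d", 1:15)
    pairs <- t(combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.2
    h <- do.call(rbind, lapply(which(sel), function(k) data.frame(
      query_id = pairs[k, 1], subject_id = pairs[k, 2],
      identity = runif(1, 0.5, 1), similarity = 1, query_coverage = 1,
      subject_coverage = 1, score = 10, evalue_proxy = 1e-9, length_diff = 0)))
    got <- singleLinkageFamilies(h, ids, 0.8, coverage_min = 0)
    edges <- h[h$identity >= 0.8, c("query_id", "subject_id")]
    names(edges) <- c("from", "to")
    roots <- oracle_union_find(ids, edges)
    got_m <- setNames(got$family_id, got$member_id)[ids]
    # same partition: pairs agree on same/different family
    for (k in seq_len(nrow(pairs))) {
      same_got <- got_m[pairs[k, 1]] == got_m[pairs[k, 2]]
      same_or <- roots[pairs[k, 1]] == roots[pairs[k, 2]]
      expect_identical(unname(same_got), unname(same_or))
    }
  }
})

test_that("MCL partition matches a reference iteration on a random graph", {
  set.seed(5)
  ids <- sprintf("v%02d", 1:12)
  adj <- matrix(0, 12, 12, dimnames = list(ids, ids))
  # two noisy communities plus sparse cross edges
  for (grp in list(1:6, 7:12))
    for (i in grp) for (j in grp) if (i < j && runif(1) < 0.7)
      adj[i, j] <- adj[j, i] <- runif(1, 0.5, 1)
  adj[3, 9] <- adj[9, 3] <- 0.05
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edf <- data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                    weight = adj[edges])
  got <- mclCluster(edf, ids = ids, inflation = 1.4)
  oracle <- oracle_mcl(adj, 1.4)
  got_m <- setNames(got$family_id, got$member_id)
  or_m <- rep(names(oracle), lengths(oracle))
  names(or_m) <- unlist(oracle)
  for (k in t(combn(ids, 2))) {
    expect_identical(unname(got_m[k[1]] == got_m[k[2]]),
                     unname(or_m[k[1]] == or_m[k[2]]))
  }
})

test_that("MCL at very high inflation reduces clusters to exact-tie groups", {
  # self-loops carry the maximum incident weight, so at extreme inflation a
  # node stays only with neighbors it ties exactly; the weak b-c bridge
  # breaks while the strong pairs persist as two-node tie groups
  ids <- c("a", "b", "c", "d", "e")
  edf <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                    weight = c(0.9, 0.4, 0.8))
  fam <- mclCluster(edf, ids = ids, inflation = 20)
  m <- setNames(fam$family_id, fam$member_id)
  expect_identical(unname(m["a"] == m["b"]), TRUE)
  expect_identical(unname(m["c"] == m["d"]), TRUE)
  expect_identical(unname(m["b"] == m["c"]), FALSE)
  # an isolated node is always its own family
  expect_equal(sum(m == m["e"]), 1L)
  # high inflation never merges clusters that a lower inflation separates
  lo <- mclCluster(edf, ids = ids, inflation = 1.4)
  expect_gte(length(unique(fam$family_id)), length(unique(lo$family_id)))
})

test_that("BLAST tabular ingestion maps columns onto the hit schema", {
  tf <- tempfile()
  writeLines(c("q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t180",
               "q2\ts2\t40.0\t80\t48\t2\t1\t80\t11\t90\t0.5\t30"), tf)
  hits <- readBlastTab(tf, query_lengths = c(q1 = 100, q2 = 100),
                       subject_lengths = c(s1 = 100, s2 = 200))
  expect_equal(hits$identity, c(0.95, 0.40))
  expect_equal(hits$evalue_proxy, c(1e-50, 0.5))
  expect_equal(hits$query_coverage, c(1, 0.8))
  expect_equal(hits$subject_coverage, c(1, 0.4))
  expect_equal(hits$length_diff, c(0, 0.5))
})
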