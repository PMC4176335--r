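## Pairwise dN/dS estimation on codon alignments.
##
## Two counting estimators are provided: classical Nei-Gojobori counting
## (equal pathway weighting, Jukes-Cantor correction) and the Yang-Nielsen
## approximate method (transition/transversion and codon-usage weighted
## counting with K80-style distance correction and iterative omega updates).
## Universal genetic code only.

.codon_env <- new.env(parent = emptyenv())

.gc_table <- function() {
  if (is.null(.codon_env$gc)) .codon_env$gc <- Biostrings::GENETIC_CODE
  .codon_env$gc
}

#' Sense codons of the universal genetic code
#' @return character vector of the 61 non-stop codons.
#' @export
senseCodons <- function() {
  gc <- .gc_table()
  names(gc)[gc != "*"]
}

NUC <- c("A", "C", "G", "T")

.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

.codon_aa <- function(codon) unname(.gc_table()[codon])

# Single-nucleotide neighbors of a codon: data.frame(pos, from, to, target,
# syn, ts, stop)
.codon_neighbors <- function(codon) {
  key <- paste0("nb_", codon)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  gc <- .gc_table()
  aa <- gc[[codon]]
  chars <- strsplit(codon, "")[[1]]
  rows <- list()
  for (pos in 1:3) for (nt in setdiff(NUC, chars[pos])) {
    tgt <- chars; tgt[pos] <- nt
    tgt <- paste(tgt, collapse = "")
    rows[[length(rows) + 1L]] <- data.frame(
      pos = pos, from = chars[pos], to = nt, target = tgt,
      syn = gc[[tgt]] == aa, ts = .is_transition(chars[pos], nt),
      stop = gc[[tgt]] == "*", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .codon_env[[key]] <- out
  out
}

# NG86 site counts for one codon (stop-producing changes excluded from the
# opportunity count at each position; total sites kept at 3).
.ng86_sites <- function(codon) {
  key <- paste0("s_", codon)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  nb <- .codon_neighbors(codon)
  s <- 0
  for (pos in 1:3) {
    at <- nb[nb$pos == pos & !nb$stop, , drop = FALSE]
    if (nrow(at)) s <- s + sum(at$syn) / nrow(at)
  }
  out <- c(S = s, N = 3 - s)
  .codon_env[[key]] <- out
  out
}

# All substitution pathways between two codons; each pathway is a sequence of
# single-nucleotide steps. Returns per-pathway syn/nonsyn (and ts/tv) step
# counts and validity (no stop codon visited).
.codon_pathways <- function(c1, c2) {
  key <- paste0("p_", c1, "_", c2)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  gc <- .gc_table()
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  k <- length(diff_pos)
  if (k == 0) {
    out <- list()
  } else {
    orders <- .permutations(k)
    out <- vector("list", nrow(orders))
    for (r in seq_len(nrow(orders))) {
      seq_pos <- diff_pos[orders[r, ]]
      cur <- ch1
      steps <- list(); valid <- TRUE
      for (p in seq_pos) {
        nxt <- cur; nxt[p] <- ch2[p]
        from_c <- paste(cur, collapse = ""); to_c <- paste(nxt, collapse = "")
        if (gc[[to_c]] == "*") valid <- FALSE
        steps[[length(steps) + 1L]] <- data.frame(
          from = from_c, to = to_c, pos = p,
          syn = gc[[from_c]] == gc[[to_c]] & gc[[to_c]] != "*",
          ts = .is_transition(cur[p], ch2[p]),
          to_nt = ch2[p], stringsAsFactors = FALSE)
        cur <- nxt
      }
      out[[r]] <- list(steps = do.call(rbind, steps), valid = valid)
    }
  }
  .codon_env[[key]] <- out
  out
}

#' Back-thread a protein alignment onto coding sequences
#'
#' Every aligned protein column becomes a codon column; protein gaps become
#' triplet gaps. Coding sequences must be exactly three times the ungapped
#' protein length (a terminal stop codon, if present, is stripped) and must
#' translate to the corresponding protein, codon by codon.
#'
#' @param prot_aln_a,prot_aln_b aligned protein strings (with \code{-} gaps)
#'   of equal length.
#' @param dna_a,dna_b coding sequences.
#' @return list with codon-aligned strings \code{codon_a}, \code{codon_b}.
#' @export
backtranslateAlignment <- function(prot_aln_a, prot_aln_b, dna_a, dna_b) {
  stopifnot(nchar(prot_aln_a) == nchar(prot_aln_b))
  thread <- function(aln, dna, label) {
    dna <- toupper(dna)
    if (nchar(dna) %% 3 != 0)
      stop(label, ": DNA length not a multiple of 3")
    last <- substr(dna, nchar(dna) - 2, nchar(dna))
    if (last %in% STOP_CODONS) dna <- substr(dna, 1, nchar(dna) - 3)
    prot <- gsub("-", "", aln)
    if (nchar(dna) != 3 * nchar(prot))
      stop(label, ": DNA length does not match ungapped protein length")
    gc <- .gc_table()
    cols <- strsplit(aln, "")[[1]]
    out <- character(length(cols))
    ci <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") { out[i] <- "---"; next }
      ci <- ci + 1L
      codon <- substr(dna, 3 * ci - 2, 3 * ci)
      aa <- gc[[codon]]
      if (aa == "*")
        stop(label, ": internal stop codon at codon ", ci)
      if (aa != cols[i])
        stop(label, ": translation mismatch at codon ", ci, " (", codon,
             " -> ", aa, ", expected ", cols[i], ")")
      out[i] <- codon
    }
    paste(out, collapse = "")
  }
  list(codon_a = thread(prot_aln_a, dna_a, "sequence a"),
       codon_b = thread(prot_aln_b, dna_b, "sequence b"))
}

.split_codons <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

# Pairwise complete deletion of gap-bearing codon columns.
.gapless_codon_pairs <- function(codon_a, codon_b) {
  ca <- .split_codons(toupper(codon_a)); cb <- .split_codons(toupper(codon_b))
  stopifnot(length(ca) == length(cb))
  keep <- !grepl("-", ca) & !grepl("-", cb)
  list(a = ca[keep], b = cb[keep])
}

.jc_correct <- function(p) {
  if (p >= 0.749999) return(Inf)
  -3 / 4 * log(1 - 4 / 3 * p)
}

.k80_correct <- function(P, Q) {
  t1 <- 1 - 2 * P - Q; t2 <- 1 - 2 * Q
  if (t1 <= 0 || t2 <= 0) return(Inf)
  -0.5 * log(t1) - 0.25 * log(t2)
}

.ng86_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("d_", c1, "_", c2)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  paths <- .codon_pathways(c1, c2)
  valid <- Filter(function(p) p$valid, paths)
  use <- if (length(valid)) valid else paths
  sd <- mean(vapply(use, function(p) sum(p$steps$syn), numeric(1)))
  nd <- mean(vapply(use, function(p) sum(!p$steps$syn), numeric(1)))
  out <- c(sd = sd, nd = nd)
  .codon_env[[key]] <- out
  out
}

.estimate_ng86 <- function(ca, cb) {
  Sa <- sum(vapply(ca, function(c) .ng86_sites(c)[["S"]], numeric(1)))
  Sb <- sum(vapply(cb, function(c) .ng86_sites(c)[["S"]], numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  dsum <- rowSums(vapply(seq_along(ca),
                         function(i) .ng86_pair_diffs(ca[i], cb[i]),
                         numeric(2)))
  Sd <- dsum[["sd"]]; Nd <- dsum[["nd"]]
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  list(method = "ng86", S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, kappa = NA_real_,
       omega = if (is.finite(dS) && dS > 0 && is.finite(dN)) dN / dS else NA_real_,
       saturated = !is.finite(dS) || dS > 1,
       saturated_overflow = !is.finite(dS) || !is.finite(dN))
}

# F3x4 position-specific nucleotide frequencies from both sequences.
.f3x4 <- function(ca, cb) {
  m <- matrix(1e-9, 3, 4, dimnames = list(NULL, NUC))  # tiny pseudo-mass
  for (codons in list(ca, cb)) {
    ch <- do.call(rbind, strsplit(codons, ""))
    for (k in 1:3) {
      tb <- table(factor(ch[, k], levels = NUC))
      m[k, ] <- m[k, ] + as.numeric(tb)
    }
  }
  sweep(m, 1, rowSums(m), "/")
}

# kappa from fourfold-degenerate and nondegenerate sites (K80 corrected,
# weighted by site counts); conservative fallback when the correction leaves
# its domain.
.yn_kappa <- function(ca, cb) {
  gc <- .gc_table()
  four_fold <- function(codon, pos) {
    nb <- .codon_neighbors(codon)
    at <- nb[nb$pos == pos, , drop = FALSE]
    all(at$syn & !at$stop)
  }
  zero_fold <- function(codon, pos) {
    nb <- .codon_neighbors(codon)
    at <- nb[nb$pos == pos, , drop = FALSE]
    all(!at$syn)
  }
  cls <- list(four = c(ts = 0, tv = 0, n = 0), zero = c(ts = 0, tv = 0, n = 0))
  for (i in seq_along(ca)) {
    ch1 <- strsplit(ca[i], "")[[1]]; ch2 <- strsplit(cb[i], "")[[1]]
    for (pos in 1:3) {
      f1 <- four_fold(ca[i], pos); f2 <- four_fold(cb[i], pos)
      z1 <- zero_fold(ca[i], pos); z2 <- zero_fold(cb[i], pos)
      cl <- if (f1 && f2) "four" else if (z1 && z2) "zero" else next
      cls[[cl]]["n"] <- cls[[cl]]["n"] + 1
      if (ch1[pos] != ch2[pos]) {
        if (.is_transition(ch1[pos], ch2[pos]))
          cls[[cl]]["ts"] <- cls[[cl]]["ts"] + 1
        else cls[[cl]]["tv"] <- cls[[cl]]["tv"] + 1
      }
    }
  }
  kap <- c(); wt <- c()
  for (cl in names(cls)) {
    n <- cls[[cl]]["n"]
    if (n < 4) next
    P <- cls[[cl]]["ts"] / n; Q <- cls[[cl]]["tv"] / n
    t1 <- 1 - 2 * P - Q; t2 <- 1 - 2 * Q
    if (t1 <= 0 || t2 <= 0) next
    a <- -0.5 * log(t1) + 0.25 * log(t2)
    b <- -0.25 * log(t2)
    if (b < 1e-9) { kap <- c(kap, 20); wt <- c(wt, n); next }
    kap <- c(kap, min(max(a / b, 0.1), 99))
    wt <- c(wt, n)
  }
  if (!length(kap)) return(2)
  sum(kap * wt) / sum(wt)
}

# Mutation-opportunity site counting with kappa and F3x4 weighting.
.yn_sites <- function(codons, kappa, f3) {
  S <- 0
  for (codon in codons) {
    nb <- .codon_neighbors(codon)
    nb <- nb[!nb$stop, , drop = FALSE]
    w <- f3[cbind(nb$pos, match(nb$to, NUC))] * ifelse(nb$ts, kappa, 1)
    tot <- sum(w)
    if (tot > 0) S <- S + 3 * sum(w[nb$syn]) / tot
  }
  c(S = S, N = 3 * length(codons) - S)
}

# Pathway-weighted difference counting, split by transition/transversion.
# Averaged over both orientations for symmetry in sequence order.
.yn_diffs_one <- function(c1, c2, kappa, omega, f3) {
  if (c1 == c2) return(c(s_ts = 0, s_tv = 0, n_ts = 0, n_tv = 0))
  paths <- .codon_pathways(c1, c2)
  valid <- Filter(function(p) p$valid, paths)
  use <- if (length(valid)) valid else paths
  wts <- vapply(use, function(p) {
    st <- p$steps
    prod(f3[cbind(st$pos, match(st$to_nt, NUC))] *
           ifelse(st$ts, kappa, 1) * ifelse(st$syn, 1, omega))
  }, numeric(1))
  if (sum(wts) <= 0) wts <- rep(1, length(use))
  wts <- wts / sum(wts)
  acc <- c(s_ts = 0, s_tv = 0, n_ts = 0, n_tv = 0)
  for (r in seq_along(use)) {
    st <- use[[r]]$steps
    acc <- acc + wts[r] * c(
      s_ts = sum(st$syn & st$ts), s_tv = sum(st$syn & !st$ts),
      n_ts = sum(!st$syn & st$ts), n_tv = sum(!st$syn & !st$ts))
  }
  acc
}

.estimate_yn00 <- function(ca, cb, tol = 1e-8, max_iter = 100) {
  f3 <- .f3x4(ca, cb)
  kappa <- .yn_kappa(ca, cb)
  sa <- .yn_sites(ca, kappa, f3); sb <- .yn_sites(cb, kappa, f3)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  omega <- 1
  dS <- dN <- NA_real_
  Sd <- Nd <- NA_real_
  for (it in seq_len(max_iter)) {
    acc <- c(s_ts = 0, s_tv = 0, n_ts = 0, n_tv = 0)
    for (i in seq_along(ca))
      acc <- acc + 0.5 * (.yn_diffs_one(ca[i], cb[i], kappa, omega, f3) +
                            .yn_diffs_one(cb[i], ca[i], kappa, omega, f3))
    Sd <- acc[["s_ts"]] + acc[["s_tv"]]; Nd <- acc[["n_ts"]] + acc[["n_tv"]]
    dS <- if (S > 0) .k80_correct(acc[["s_ts"]] / S, acc[["s_tv"]] / S) else 0
    dN <- if (N > 0) .k80_correct(acc[["n_ts"]] / N, acc[["n_tv"]] / N) else 0
    new_omega <- if (is.finite(dS) && dS > 0 && is.finite(dN)) dN / dS else NA
    if (is.na(new_omega)) { omega <- NA_real_; break }
    if (abs(new_omega - omega) < tol) { omega <- new_omega; break }
    omega <- new_omega
  }
  list(method = "yn00", S = S, N = N, Sd = Sd, Nd = Nd,
       pS = if (S > 0) Sd / S else 0, pN = if (N > 0) Nd / N else 0,
       dS = dS, dN = dN, kappa = kappa, omega = omega,
       saturated = !is.finite(dS) || dS > 1,
       saturated_overflow = !is.finite(dS) || !is.finite(dN))
}

#' Pairwise dN/dS on a codon alignment
#'
#' Gap-bearing codon columns are removed pairwise (complete deletion), then
#' synonymous and nonsynonymous sites and differences are counted.
#' \code{"ng86"}: Nei-Gojobori counting with equal pathway weighting and
#' Jukes-Cantor correction. \code{"yn00"}: Yang-Nielsen approximate method -
#' transition/transversion ratio estimated from fourfold-degenerate and
#' nondegenerate sites, F3x4 codon-usage weighted site and pathway counting,
#' K80-style correction applied separately to the synonymous and
#' nonsynonymous classes, and omega updated iteratively. Estimates with
#' dS > 1 are flagged saturated; proportions outside the distance-correction
#' domain are flagged \code{saturated_overflow} (infinite distance).
#' Omega is NA (undefined) when dS is 0.
#'
#' @param codon_a,codon_b codon-aligned DNA strings (gaps as \code{---}).
#' @param method \code{"yn00"} or \code{"ng86"}.
#' @return list: method, S, N, Sd, Nd, pS, pN, dS, dN, kappa, omega,
#'   saturated, saturated_overflow, n_codons.
#' @export
estimateDnds <- function(codon_a, codon_b, method = c("yn00", "ng86")) {
  method <- match.arg(method)
  pair <- .gapless_codon_pairs(codon_a, codon_b)
  if (!length(pair$a)) stop("no alignable codons after gap removal")
  bad <- c(pair$a, pair$b)[!(c(pair$a, pair$b) %in% senseCodons())]
  if (length(bad)) stop("non-sense codon in alignment: ", bad[1])
  est <- if (method == "ng86") .estimate_ng86(pair$a, pair$b)
         else .estimate_yn00(pair$a, pair$b)
  est$n_codons <- length(pair$a)
  est
}

#' Selection summary per role group with saturation filtering
#'
#' Estimates with dS > 1 (saturation) are discarded; dS exactly 1 is kept.
#' Estimates with undefined omega (dS = 0) are excluded from the summaries.
#' Group means and SDs of omega are reported per role x R-M type, with
#' two-sided Mann-Whitney comparisons of REase versus MTase omega within each
#' R-M type (groups under 2 estimates are reported without a test).
#'
#' @param estimates data.frame with columns role, rm_type, dS, omega,
#'   saturated.
#' @return list: groups (role, rm_type, n, mean_omega, sd_omega),
#'   comparisons (rm_type, n_rease, n_mtase, statistic, p_value),
#'   n_discarded_saturated.
#' @export
summarizeSelection <- function(estimates) {
  n_sat <- sum(estimates$dS > 1 | !is.finite(estimates$dS))
  keep <- estimates[is.finite(estimates$dS) & estimates$dS <= 1 &
                      !is.na(estimates$omega), , drop = FALSE]
  if (!nrow(keep))
    return(list(groups = data.frame(), comparisons = data.frame(),
                n_discarded_saturated = n_sat))
  grp <- do.call(rbind, lapply(
    split(keep, paste(keep$role, keep$rm_type, sep = "|")),
    function(d) data.frame(role = d$role[1], rm_type = d$rm_type[1],
                           n = nrow(d), mean_omega = mean(d$omega),
                           sd_omega = if (nrow(d) > 1) sd(d$omega) else NA_real_,
                           stringsAsFactors = FALSE)))
  rownames(grp) <- NULL
  cmps <- list()
  for (tt in unique(keep$rm_type)) {
    a <- keep$omega[keep$role == "REase" & keep$rm_type == tt]
    b <- keep$omega[keep$role == "MTase" & keep$rm_type == tt]
    if (length(a) >= 2 && length(b) >= 2) {
      tr <- mannWhitneyU(a, b, "two")
      cmps[[tt]] <- data.frame(rm_type = tt, n_rease = length(a),
                               n_mtase = length(b), statistic = tr$statistic,
                               p_value = tr$p_value, stringsAsFactors = FALSE)
    } else {
      cmps[[tt]] <- data.frame(rm_type = tt, n_rease = length(a),
                               n_mtase = length(b), statistic = NA_real_,
                               p_value = NA_real_, stringsAsFactors = FALSE)
    }
  }
  list(groups = grp, comparisons = do.call(rbind, c(cmps, list(make.row.names = FALSE))),
       n_discarded_saturated = n_sat)
}
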