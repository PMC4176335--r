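## Nonparametric tests used throughout the analyses. Small samples are
## handled by exact enumeration (all permutations / label assignments /
## binomial tail sums); larger samples use the standard approximations.
## Two-sided alternatives are the default everywhere except the directional
## binomial test on species counts.

.test_result <- function(method, statistic, p_value, n, sidedness) {
  list(method = method, statistic = unname(statistic),
       p_value = unname(min(max(p_value, 0), 1)), n = n, sidedness = sidedness)
}

EXACT_MAX_N <- 8L  # full enumeration bound for the exact modes

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho uses average ranks for ties. For n up to \code{EXACT_MAX_N} the
#' p-value is computed by full enumeration of all permutations of one vector;
#' above that a t-approximation is used.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param sidedness \code{"two"} or \code{"one"} (one-sided: positive
#'   association).
#' @return list: method, statistic (rho), p_value, n, sidedness.
#' @export
rankCorrelation <- function(x, y, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(x) == length(y), length(x) >= 3)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: rho undefined")
    return(.test_result("spearman", NA_real_, NA_real_, n, sidedness))
  }
  rho_of <- function(a, b) cor(rank(a), rank(b))
  rho <- rho_of(x, y)
  if (n <= EXACT_MAX_N) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) rho_of(x, y[p]))
    eps <- 1e-12
    p <- if (sidedness == "two") mean(abs(rhos) >= abs(rho) - eps)
         else mean(rhos >= rho - eps)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (sidedness == "two") 2 * pt(-abs(tstat), n - 2)
         else pt(tstat, n - 2, lower.tail = FALSE)
  }
  .test_result("spearman", rho, p, n, sidedness)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Mann-Whitney U test with exact small-sample p-value
#'
#' U counts pairs where a exceeds b (ties 1/2). Groups of at most
#' \code{EXACT_MAX_N} each are tested by enumerating all label assignments of
#' the pooled sample; larger groups use the tie-corrected normal
#' approximation.
#'
#' @param a,b numeric samples.
#' @param sidedness \code{"two"} or \code{"one"} (one-sided: a tends larger).
#' @return list: method, statistic (U of sample a), p_value, n, sidedness.
#' @export
mannWhitneyU <- function(a, b, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b)
  u_of <- function(a, b) {
    cmp <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
    sum(cmp)
  }
  U <- u_of(a, b)
  mu <- n1 * n2 / 2
  if (n1 <= EXACT_MAX_N && n2 <= EXACT_MAX_N) {
    pool <- c(a, b)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
    eps <- 1e-9
    p <- if (sidedness == "two") mean(abs(us - mu) >= abs(U - mu) - eps)
         else mean(us >= U - eps)
  } else {
    ties <- table(c(a, b))
    N <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- if (sidedness == "two") 2 * pnorm(-abs(z))
         else pnorm(z, lower.tail = FALSE)
  }
  .test_result("mann_whitney", U, p, c(n1 = n1, n2 = n2), sidedness)
}

#' Pearson chi-square test (goodness of fit or independence)
#'
#' Goodness of fit: \code{observed} and \code{expected} vectors (expected may
#' be rescaled to the observed total). Independence: \code{observed} a matrix
#' with expected counts from the margins.
#'
#' @param observed counts (vector or matrix).
#' @param expected expected counts for the goodness-of-fit mode.
#' @return list: method, statistic, p_value, n (df), sidedness ("upper").
#' @export
chiSquareTest <- function(observed, expected = NULL) {
  if (is.matrix(observed)) {
    if (!is.null(expected)) stop("expected is ignored for matrix input")
    rs <- rowSums(observed); cs <- colSums(observed); N <- sum(observed)
    expected <- outer(rs, cs) / N
    df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  } else {
    stopifnot(!is.null(expected), length(expected) == length(observed))
    df <- length(observed) - 1
  }
  if (any(expected <= 0))
    stop("zero expected cell; merge categories before testing")
  stat <- sum((observed - expected)^2 / expected)
  .test_result("chi_square", stat, pchisq(stat, df, lower.tail = FALSE),
               c(df = df), "upper")
}

#' Exact binomial test
#'
#' Tail sums of the binomial probability mass function. The two-sided
#' p-value sums all outcomes at most as probable as the observed one.
#'
#' @param k successes, \code{0 <= k <= n}.
#' @param n trials.
#' @param p0 null success probability, in (0, 1).
#' @param alternative \code{"two.sided"}, \code{"greater"} or \code{"less"}.
#' @return list: method, statistic (k), p_value, n, sidedness.
#' @export
binomialTest <- function(k, n, p0 = 0.5,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  stopifnot(k >= 0, k <= n)
  pmf <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    greater = sum(pmf[(k + 1):(n + 1)]),
    less = sum(pmf[1:(k + 1)]),
    two.sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
  .test_result("binomial", k, p, n,
               if (alternative == "two.sided") "two" else "one")
}

#' Co-occurrence of a genome feature with R-M counts, stratified by size
#'
#' Genomes are split into small (below \code{boundary_mb}) and large (at
#' least \code{boundary_mb}); within each stratum the R-M counts of genomes
#' with and without the feature are compared by a two-sided Mann-Whitney
#' test. Used for competence, CRISPR-Cas, antirestriction and MGE-presence
#' associations.
#'
#' @param counts named numeric vector of per-genome R-M counts.
#' @param flag named logical vector (same genomes) marking the feature.
#' @param size_mb named numeric vector of genome sizes in Mb.
#' @param boundary_mb stratum boundary (a genome of exactly this size is
#'   assigned to the large stratum).
#' @return data.frame with one row per stratum: stratum, n_flagged,
#'   n_unflagged, statistic, p_value (NA when a group is empty).
#' @export
coOccurrenceTest <- function(counts, flag, size_mb, boundary_mb = 2) {
  ids <- names(counts)
  stopifnot(!is.null(ids), setequal(ids, names(flag)),
            setequal(ids, names(size_mb)))
  flag <- flag[ids]; size_mb <- size_mb[ids]
  stratum <- ifelse(size_mb < boundary_mb, "small", "large")
  out <- list()
  for (s in c("small", "large")) {
    sel <- stratum == s
    a <- counts[sel & flag]; b <- counts[sel & !flag]
    if (!length(a) || !length(b)) {
      out[[s]] <- data.frame(stratum = s, n_flagged = length(a),
                             n_unflagged = length(b), statistic = NA_real_,
                             p_value = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tr <- mannWhitneyU(a, b, "two")
    out[[s]] <- data.frame(stratum = s, n_flagged = length(a),
                           n_unflagged = length(b), statistic = tr$statistic,
                           p_value = tr$p_value, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Benjamini-Hochberg adjusted p-values for a results table
#'
#' Emitted alongside raw p-values for transparency; never used to gate any
#' result in the pipeline.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")
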