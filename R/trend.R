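# Case-control association statistics: Cochran-Armitage trend test and its
# stratum-combined (Cochran-Mantel-Haenszel style) version.

#' Genotype count table for one SNP
#'
#' Counts of affected and unaffected subjects per genotype class
#' (0, 1, 2 minor alleles), optionally labelled with a stratum.
#'
#' @param affected,unaffected integer vectors of length 3,
#'   `c(n0, n1, n2)` by minor-allele count.
#' @param stratum optional label.
#' @return Object of class `genotype_counts`.
#' @export
genotype_counts <- function(affected, unaffected, stratum = NULL) {
  stopifnot(length(affected) == 3L, length(unaffected) == 3L,
            all(affected >= 0), all(unaffected >= 0))
  structure(list(affected = as.numeric(affected),
                 unaffected = as.numeric(unaffected),
                 stratum = stratum),
            class = "genotype_counts")
}

# Tabulate affected/unaffected x genotype for one set of subjects.
count_genotypes <- function(calls, phenotype) {
  keep <- !is.na(calls) & !is.na(phenotype)
  g <- calls[keep]; y <- phenotype[keep]
  genotype_counts(affected = tabulate(g[y == 1L] + 1L, nbins = 3L),
                  unaffected = tabulate(g[y == 0L] + 1L, nbins = 3L))
}

#' Cochran-Armitage test for trend
#'
#' Score test for a linear trend in disease proportion across genotype
#' classes under additive scores (0, 1, 2).  With `a_j`/`u_j` affected and
#' unaffected counts, `n_j = a_j + u_j`, `A = sum a_j`, `N = sum n_j`:
#' \deqn{U = \sum_j s_j (a_j - n_j A / N),\qquad
#'       V = \frac{A(N-A)}{N^2}\Big(\sum_j s_j^2 n_j -
#'           \big(\sum_j s_j n_j\big)^2 / N\Big)}
#' and `Z = U / sqrt(V)` is compared with a standard normal (two-sided).
#' The unconditional (binomial, `N^2`) variance denominator is used;
#' `hypergeometric = TRUE` applies the `N^2(N-1)/N` finite-sample
#' correction instead.  No continuity correction.
#'
#' A degenerate table (no genotype variation or a single phenotype class,
#' `V = 0`) yields an untestable result with missing `Z` and `p` rather than
#' an error.
#'
#' @param table a [genotype_counts()].
#' @param scores genotype scores, default additive `c(0, 1, 2)`.
#' @param hypergeometric use the conditional variance denominator.
#' @return List of class `trend_test` with `U`, `V`, `Z`, `p`, `n`,
#'   `untestable`.
#' @export
trend_test <- function(table, scores = c(0, 1, 2), hypergeometric = FALSE) {
  a <- table$affected; u <- table$unaffected
  n <- a + u; N <- sum(n); A <- sum(a)
  if (N < 2) stop("trend test needs at least 2 subjects")
  U <- sum(scores * (a - n * A / N))
  V <- A * (N - A) / N^2 * (sum(scores^2 * n) - sum(scores * n)^2 / N)
  if (hypergeometric) V <- V * N / (N - 1)
  if (V <= 0) {
    res <- list(U = U, V = 0, Z = NA_real_, p = NA_real_, n = N,
                untestable = TRUE)
  } else {
    Z <- U / sqrt(V)
    res <- list(U = U, V = V, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n = N,
                untestable = FALSE)
  }
  class(res) <- "trend_test"
  res
}

#' @export
print.trend_test <- function(x, ...) {
  if (x$untestable) cat("Cochran-Armitage trend test: untestable (V = 0)\n")
  else cat(sprintf("Cochran-Armitage trend test: Z = %.4f, p = %.4g (n = %d)\n",
                   x$Z, x$p, x$n))
  invisible(x)
}

#' Stratum-combined trend test
#'
#' Combines per-stratum trend numerators and variances in the
#' Cochran-Mantel-Haenszel manner: `Z = sum(U_k) / sqrt(sum(V_k))`.
#' Degenerate strata (`V_k = 0`) contribute nothing; if all strata are
#' degenerate the result is untestable.  The result is invariant to the
#' order of the strata.
#'
#' @param tables list of [genotype_counts()], one per stratum.
#' @param scores genotype scores.
#' @return List of class `trend_test` (with `n` = total subjects over
#'   contributing strata).
#' @export
cmh_trend <- function(tables, scores = c(0, 1, 2)) {
  U <- 0; V <- 0; N <- 0L
  for (tab in tables) {
    a <- tab$affected; u <- tab$unaffected
    n <- a + u; Nk <- sum(n); Ak <- sum(a)
    if (Nk < 2) next
    Vk <- Ak * (Nk - Ak) / Nk^2 * (sum(scores^2 * n) - sum(scores * n)^2 / Nk)
    if (Vk <= 0) next
    U <- U + sum(scores * (a - n * Ak / Nk))
    V <- V + Vk
    N <- N + Nk
  }
  if (V <= 0) {
    res <- list(U = U, V = 0, Z = NA_real_, p = NA_real_, n = N,
                untestable = TRUE)
  } else {
    Z <- U / sqrt(V)
    res <- list(U = U, V = V, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n = N,
                untestable = FALSE)
  }
  class(res) <- "trend_test"
  res
}

# Vectorised trend test over SNPs: A and Un are M x 3 matrices of affected /
# unaffected genotype counts.  Returns data.frame(U, V, Z, p).
trend_test_matrix <- function(A, Un, scores = c(0, 1, 2)) {
  Nmat <- A + Un
  N <- rowSums(Nmat); Atot <- rowSums(A)
  s1 <- Nmat %*% scores; s2 <- Nmat %*% scores^2
  U <- as.vector(A %*% scores) - as.vector(s1) * Atot / N
  V <- Atot * (N - Atot) / N^2 * (as.vector(s2) - as.vector(s1)^2 / N)
  Z <- ifelse(V > 0, U / sqrt(V), NA_real_)
  data.frame(U = U, V = V, Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

# Per-stratum genotype count matrices for a subject subset.
# Returns list of list(A, U) per stratum (M x 3 matrices).
stratified_counts <- function(genotypes, subject_idx, phenotype, strata) {
  g <- unclass(genotypes)[, subject_idx, drop = FALSE]
  out <- list()
  for (st in unique(strata)) {
    sel <- which(strata == st)
    A <- matrix(0, nrow(g), 3L); Un <- matrix(0, nrow(g), 3L)
    for (j in 0:2) {
      gj <- g[, sel, drop = FALSE] == j
      yj <- phenotype[sel]
      A[, j + 1L] <- rowSums(gj[, yj == 1L, drop = FALSE], na.rm = TRUE)
      Un[, j + 1L] <- rowSums(gj[, yj == 0L, drop = FALSE], na.rm = TRUE)
    }
    out[[st]] <- list(A = A, U = Un)
  }
  out
}

#' Per-SNP case-control association scan
#'
#' Runs the stratum-combined trend test for every SNP over the unrelated
#' subset.  Strata are the cartesian product of the pedigree `stratum` label
#' (e.g. recruitment centre) and sex, so a single pass both adjusts for sex
#' and stratifies by centre.  In `"pooled_with_probands"` mode the trio
#' offspring (with their phenotypes) are added to the unrelated subjects,
#' replicating the common single-step case-control strategy.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pedigree the matching [pedigree_table()].
#' @param subset `"singletons_only"` or `"pooled_with_probands"`.
#' @param trios `trio_set`, required for the pooled mode and to identify
#'   singletons.
#' @return Data frame: `snp_id`, `z_trend`, `p_trend`, `n`.
#' @export
singleton_association <- function(genotypes, pedigree,
                                  subset = c("singletons_only",
                                             "pooled_with_probands"),
                                  trios = NULL) {
  subset <- match.arg(subset)
  if (is.null(trios)) trios <- build_trios(pedigree, genotypes)
  ids <- attr(trios, "singletons")
  if (subset == "pooled_with_probands")
    ids <- c(ids, trios$offspring_id)
  idx <- match(ids, colnames(genotypes))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("empty subject subset")
  prow <- match(colnames(genotypes)[idx], pedigree$individual_id)
  y <- pedigree$phenotype[prow]
  strata <- paste(pedigree$stratum[prow], pedigree$sex[prow], sep = ":")
  keep <- !is.na(y)
  idx <- idx[keep]; y <- y[keep]; strata <- strata[keep]

  per_stratum <- stratified_counts(genotypes, idx, y, strata)
  m <- nrow(genotypes)
  Usum <- numeric(m); Vsum <- numeric(m)
  for (st in per_stratum) {
    r <- trend_test_matrix(st$A, st$U)
    ok <- r$V > 0
    Usum[ok] <- Usum[ok] + r$U[ok]
    Vsum[ok] <- Vsum[ok] + r$V[ok]
  }
  Z <- ifelse(Vsum > 0, Usum / sqrt(Vsum), NA_real_)
  data.frame(snp_id = snp_map(genotypes)$snp_id,
             z_trend = Z, p_trend = 2 * stats::pnorm(-abs(Z)),
             n = length(idx), stringsAsFactors = FALSE)
}
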