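# Marker screening statistically independent of the subsequent tests:
# conditional-power screening from parental genotypes and offspring
# phenotypes (trios), and contingency-table partitioning (cases/controls).

#' Conditional-power screening of SNPs from trio data
#'
#' Ranks SNPs by the predicted power of the upcoming family-based test using
#' only parental genotypes and offspring phenotypes; offspring genotypes are
#' never read, which keeps the ranking statistically independent of the FBAT
#' testing step.
#'
#' Per SNP: (1) the offspring genotype proxy is its Mendelian expectation
#' `g_i = E(X_i|S_i)` from the parents; (2) ordinary least squares of `Y_i`
#' on `g_i` gives a slope estimate `b` and residual variance `s2`;
#' (3) with `V = sum_i (Y_i - offset)^2 Var(X_i|S_i)` the noncentrality of
#' the FBAT Z under a small additive effect is approximated by
#' `delta = b * sqrt(V) / s2`; (4) the screening score is the two-sided
#' power `Phi(delta - z_{alpha/2}) + Phi(-delta - z_{alpha/2})`.  Power is
#' strictly increasing in `|delta|`, so the ranking does not depend on
#' `alpha`.  SNPs with no proxy variance get the null power `alpha` and
#' rank last among ties.
#'
#' @param trios `trio_set` with index columns (see [build_trios()]).
#' @param genotypes a [genotype_matrix()]; only the parental columns are
#'   accessed.
#' @param offset phenotypic offset, default 0.3.
#' @param alpha nominal level of the planned test, default 0.05.
#' @return Data frame: `snp_id`, `screen_power`, `b_hat`, `delta`, `rank`
#'   (1 = most promising; ties broken by smaller bp, then snp_id).
#' @export
conditional_power_screen <- function(trios, genotypes, offset = 0.3,
                                     alpha = 0.05) {
  if (is.null(trios) || nrow(trios) == 0L) stop("no trios available")
  g <- unclass(genotypes)
  f <- g[, trios$father_idx, drop = FALSE]
  m <- g[, trios$mother_idx, drop = FALSE]
  y <- trios$phenotype
  ok <- !is.na(f) & !is.na(m)
  ex <- (f + m) / 2
  vx <- f / 2 * (1 - f / 2) + m / 2 * (1 - m / 2)
  ex[!ok] <- NA; vx[!ok] <- 0

  # rowwise OLS of y on ex over complete trios
  n_i <- rowSums(ok)
  Ymat <- matrix(y, nrow(ex), length(y), byrow = TRUE)
  Yobs <- Ymat; Yobs[!ok] <- NA
  Sg <- rowSums(ex, na.rm = TRUE)
  Sy <- rowSums(Yobs, na.rm = TRUE)
  Sgg <- rowSums(ex^2, na.rm = TRUE)
  Sgy <- rowSums(ex * Yobs, na.rm = TRUE)
  Syy <- rowSums(Yobs^2, na.rm = TRUE)
  ssg <- Sgg - Sg^2 / n_i
  ssy <- Syy - Sy^2 / n_i
  sgy <- Sgy - Sg * Sy / n_i
  b <- ifelse(ssg > 0, sgy / ssg, 0)
  dfree <- pmax(n_i - 2, 1)
  s2 <- pmax((ssy - b * sgy) / dfree, 1e-12)

  tw2 <- (y - offset)^2
  V <- as.vector(vx %*% tw2)
  delta <- ifelse(ssg > 0, b * sqrt(V) / s2, 0)
  zc <- stats::qnorm(1 - alpha / 2)
  power <- stats::pnorm(delta - zc) + stats::pnorm(-delta - zc)

  map <- snp_map(genotypes)
  out <- data.frame(snp_id = map$snp_id, screen_power = power,
                    b_hat = b, delta = delta, stringsAsFactors = FALSE)
  out$rank <- screen_rank(power, map)
  out
}

# Descending-score ranks with deterministic tie-breaking:
# higher score first, then smaller genomic position, then snp_id.
screen_rank <- function(score, map) {
  ord <- order(-score, map$bp, map$snp_id)
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

#' Partition a case-control contingency table for C2BAT screening
#'
#' Splits the subjects behind one SNP's affection-by-genotype table into a
#' testing table and a non-informative screening table.  Independently per
#' genotype class, `round(fraction_j * n_j)` subjects (drawn from the pooled
#' affected + unaffected subjects of that class, ignoring phenotype) go to
#' the testing table; the rest form the screening table.  The default
#' fractions preferentially select minor homozygotes:
#' 75% of minor homozygotes, 50% of heterozygotes and 25% of major
#' homozygotes.  Rounding is half-away-from-zero.
#'
#' @param table a [genotype_counts()] for the full case-control sample.
#' @param fractions length-3 numeric, testing fraction for
#'   (minor homozygote, heterozygote, major homozygote), i.e. genotype
#'   classes (2, 1, 0).
#' @return List of class `contingency_split`: `screening_table`,
#'   `testing_table` (both [genotype_counts()]), and `testing_margins`
#'   (`affected`, `unaffected`, `genotype_totals`).
#' @export
c2bat_split <- function(table, fractions = c(0.75, 0.50, 0.25)) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0), all(fractions <= 1))
  a <- table$affected; u <- table$unaffected
  n <- a + u
  # fractions are given minor-hom first; genotype class order here is 0,1,2
  frac_by_class <- rev(fractions)
  t_n <- round_half_up(frac_by_class * n)
  if (sum(t_n) == 0) stop("empty testing table (all fractions select 0)")
  # simple random sample of t_n[j] subjects per class ignoring phenotype:
  # affected count in the testing cell is hypergeometric
  t_a <- numeric(3L)
  for (j in 1:3) t_a[j] <- stats::rhyper(1L, m = a[j], n = u[j], k = t_n[j])
  t_u <- t_n - t_a
  testing <- genotype_counts(t_a, t_u)
  screening <- genotype_counts(a - t_a, u - t_u)
  structure(list(screening_table = screening,
                 testing_table = testing,
                 testing_margins = list(affected = sum(t_a),
                                        unaffected = sum(t_u),
                                        genotype_totals = t_n)),
            class = "contingency_split")
}

round_half_up <- function(x) floor(x + 0.5)

#' C2BAT screening score for one SNP
#'
#' Uses only the screening table and the margins of the testing table: the
#' testing-table cells are imputed under the null given those margins
#' (sequential hypergeometric draws, so that all margins hold exactly),
#' added to the screening table, and the absolute trend-test Z of the summed
#' table is the screening score.  Because the actual testing cell counts are
#' never touched, the score is independent of [c2bat_test()].
#'
#' @param split a `contingency_split` from [c2bat_split()].
#' @param expected use deterministic expected counts instead of random
#'   draws (for testing).
#' @return List: `score` (absolute Z; 0 when the summed table is
#'   degenerate), `imputed_table` ([genotype_counts()]).
#' @export
c2bat_screen <- function(split, expected = FALSE) {
  marg <- split$testing_margins
  t_n <- marg$genotype_totals
  A <- marg$affected
  if (expected) {
    imp_a <- t_n * A / max(sum(t_n), 1)
  } else {
    imp_a <- numeric(3L)
    left <- A
    rest <- sum(t_n)
    for (j in 1:3) {
      rest <- rest - t_n[j]
      imp_a[j] <- if (j < 3L)
        stats::rhyper(1L, m = t_n[j], n = rest, k = left)
      else left
      left <- left - imp_a[j]
    }
  }
  imputed <- genotype_counts(imp_a, t_n - imp_a)
  sumtab <- genotype_counts(split$screening_table$affected + imp_a,
                            split$screening_table$unaffected + (t_n - imp_a))
  tt <- trend_test(sumtab)
  list(score = if (tt$untestable) 0 else abs(tt$Z), imputed_table = imputed)
}

#' C2BAT association test for one SNP
#'
#' Two-sided trend test on the testing table alone.  With testing fractions
#' all equal to 1 this reduces to the full-sample trend test.
#'
#' @param split a `contingency_split` from [c2bat_split()].
#' @return A `trend_test` result (untestable flag when degenerate).
#' @export
c2bat_test <- function(split) trend_test(split$testing_table)

#' C2BAT screen-and-test scan across all SNPs
#'
#' Applies [c2bat_split()], [c2bat_screen()] and [c2bat_test()] to every SNP
#' of the unrelated case-control subset.  Reproducibility: each SNP uses its
#' own RNG stream derived from `seed` and the SNP index, so results do not
#' depend on the number or order of other SNPs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param subject_idx column indices of the unrelated subjects.
#' @param phenotype 0/1 phenotype aligned with `subject_idx`.
#' @param fractions testing fractions as in [c2bat_split()].
#' @param seed master seed for the per-SNP streams.
#' @return Data frame: `snp_id`, `screen_score`, `rank`, `z_c2bat`,
#'   `p_c2bat`, `untestable`.
#' @export
c2bat_scan <- function(genotypes, subject_idx, phenotype,
                       fractions = c(0.75, 0.50, 0.25), seed = 1L) {
  g <- unclass(genotypes)[, subject_idx, drop = FALSE]
  map <- snp_map(genotypes)
  m <- nrow(g)
  keep <- !is.na(phenotype)
  g <- g[, keep, drop = FALSE]; phenotype <- phenotype[keep]
  # precompute affected/unaffected genotype counts for all SNPs at once
  A <- matrix(0, m, 3L); U <- matrix(0, m, 3L)
  for (j in 0:2) {
    gj <- !is.na(g) & g == j
    A[, j + 1L] <- rowSums(gj[, phenotype == 1L, drop = FALSE])
    U[, j + 1L] <- rowSums(gj[, phenotype == 0L, drop = FALSE])
  }
  score <- numeric(m); z <- rep(NA_real_, m); p <- rep(NA_real_, m)
  # per-SNP RNG streams from the master seed; caller's RNG state untouched
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed",
                                               envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (i in seq_len(m)) {
    set.seed((as.integer(seed) + 7919L * (i %% 270000L)) %% 2147483647L)
    split <- c2bat_split(genotype_counts(A[i, ], U[i, ]), fractions)
    score[i] <- c2bat_screen(split)$score
    tt <- c2bat_test(split)
    if (!tt$untestable) { z[i] <- tt$Z; p[i] <- tt$p }
  }
  data.frame(snp_id = map$snp_id, screen_score = score,
             rank = screen_rank(score, map),
             z_c2bat = z, p_c2bat = p, untestable = is.na(p),
             stringsAsFactors = FALSE)
}
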