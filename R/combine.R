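# Combining evidence across the family-based and population-based subsets.

#' Fisher's combined probability test
#'
#' Aggregates k independent p-values via `X = -2 sum(log(p_i))`, referred to
#' a chi-square distribution with `2k` degrees of freedom (upper tail).
#' Independence is the caller's responsibility; in the two-step pipeline it
#' is guaranteed by testing in disjoint subsets.
#'
#' @param p_values numeric vector, each in `(0, 1]`.  Exact zeros are
#'   rejected; callers must floor (see `p_floor` in [two_step_decision()]).
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (!length(p_values)) stop("no p-values to combine")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p_values))
  stats::pchisq(X, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Sample-size weighted Z meta-analysis
#'
#' Each study's p-value is converted to a signed Z-score,
#' `Z_i = qnorm(1 - p_i/2) * direction_i`, weighted by the square root of
#' its sample size, and combined:
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))` with `w_i = sqrt(N_i)`;
#' the result is referred two-sided to a standard normal.  A study with
#' `p = 1` (undefined direction) contributes `Z_i = 0`.
#'
#' @param p_values two-sided p-values in `(0, 1]`.
#' @param directions effect directions, `+1` or `-1` per study.
#' @param sample_sizes positive study sizes.
#' @return List: `Z`, `p`.
#' @export
weighted_z_combine <- function(p_values, directions, sample_sizes) {
  stopifnot(length(p_values) == length(directions),
            length(p_values) == length(sample_sizes),
            all(sample_sizes > 0))
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  dirs <- ifelse(p_values >= 1, 0, sign(directions))
  if (any(dirs == 0 & p_values < 1)) stop("directions must be +1 or -1")
  Zi <- stats::qnorm(1 - p_values / 2) * dirs
  w <- sqrt(sample_sizes)
  Z <- sum(w * Zi) / sqrt(sum(w^2))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Aggregate screening ranks from the two subsets
#'
#' The aggregate score of a SNP is the mean of the log-transformed subset
#' ranks, `(log r_family + log r_cc) / 2`; ordering by this score is
#' identical to ordering by the rank product.  SNPs missing a rank in one
#' subset receive the worst rank `M` there and are flagged.  Ties are broken
#' by the smaller family rank, then by snp_id.
#'
#' @param rank_family,rank_cc integer rank vectors (1 = best) aligned with
#'   `snp_id`; `NA` = not ranked in that subset.
#' @param snp_id SNP identifiers.
#' @return Data frame: `snp_id`, `rank_family`, `rank_cc`,
#'   `aggregate_score`, `aggregate_rank`, `partial` (missing-rank flag).
#' @export
aggregate_ranks <- function(rank_family, rank_cc, snp_id = NULL) {
  m <- length(rank_family)
  stopifnot(length(rank_cc) == m)
  if (is.null(snp_id)) snp_id <- as.character(seq_len(m))
  partial <- is.na(rank_family) | is.na(rank_cc)
  rf <- ifelse(is.na(rank_family), m, rank_family)
  rc <- ifelse(is.na(rank_cc), m, rank_cc)
  score <- (log(rf) + log(rc)) / 2
  # sort on the exact integer rank product (same ordering as the mean
  # log-rank, but immune to floating-point ties in the log scale)
  ord <- order(rf * rc, rf, snp_id)
  arank <- integer(m)
  arank[ord] <- seq_len(m)
  data.frame(snp_id = snp_id, rank_family = rf, rank_cc = rc,
             aggregate_score = score, aggregate_rank = arank,
             partial = partial, stringsAsFactors = FALSE)
}

#' Two-step top-K decision rule
#'
#' Selects the `K` SNPs with the best aggregate screening rank and tests
#' each with Fisher's combined probability of the two testing p-values -
#' the FBAT p (full trio data; valid because the family screen never reads
#' offspring genotypes) and the C2BAT testing-table p (valid because the
#' case-control screen used only disjoint subjects plus margins).  A
#' selected SNP is significant when its combined p falls below `alpha / K`;
#' with `K = 10` and `alpha = 0.05` the per-SNP threshold is 0.005.
#' Statistics for all SNPs are reported, not just the selected ones.
#'
#' @param aggregated output of [aggregate_ranks()].
#' @param p_family FBAT p-values aligned with `aggregated$snp_id`.
#' @param p_cc C2BAT testing-table p-values, same alignment.  Using the
#'   full-sample trend p here would break independence and is deliberately
#'   not supported.
#' @param K number of SNPs carried to testing, default 10.
#' @param alpha familywise level, default 0.05.
#' @param p_floor lower clamp applied before combination, default 1e-300.
#' @return Data frame of class `combined_result`: aggregation columns plus
#'   `p_fisher`, `selected_top_k`, `significant`; attribute `threshold`
#'   (`alpha / K`).
#' @export
two_step_decision <- function(aggregated, p_family, p_cc, K = 10L,
                              alpha = 0.05, p_floor = 1e-300) {
  m <- nrow(aggregated)
  if (K < 1L || K > m) stop("K must lie in [1, number of SNPs]")
  stopifnot(length(p_family) == m, length(p_cc) == m)
  sel <- aggregated$aggregate_rank <= K
  pf <- pmax(p_family, p_floor)
  pc <- pmax(p_cc, p_floor)
  p_fisher <- rep(NA_real_, m)
  ok <- !is.na(pf) & !is.na(pc)
  p_fisher[ok] <- vapply(which(ok),
                         function(i) fisher_combine(c(pf[i], pc[i])),
                         numeric(1))
  out <- aggregated
  out$p_family <- p_family
  out$p_cc <- p_cc
  out$p_fisher <- p_fisher
  out$selected_top_k <- sel
  out$significant <- sel & !is.na(p_fisher) & p_fisher < alpha / K
  attr(out, "threshold") <- alpha / K
  class(out) <- c("combined_result", "data.frame")
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, optionally rounded to a number of significant figures for
#' reporting (e.g. `0.05 / 357887` prints as `1.4e-07` at two significant
#' figures).
#'
#' @param alpha familywise level.
#' @param m number of tests.
#' @param sigfigs significant figures for reporting; `NULL` = full
#'   precision.
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m, sigfigs = NULL) {
  x <- alpha / m
  if (!is.null(sigfigs)) x <- signif(x, sigfigs)
  x
}
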