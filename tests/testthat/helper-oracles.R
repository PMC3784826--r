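# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package code.

# Cochran-Armitage trend chi-square via stats::prop.trend.test (weighted
# least-squares route, unconditional variance).  Returns the 1-df statistic.
oracle_trend_chisq <- function(affected, unaffected, scores = 0:2) {
  suppressWarnings(
    unname(stats::prop.trend.test(affected, affected + unaffected,
                                  score = scores)$statistic))
}

# All 2x3 genotype count tables with total N: rows of a data frame with
# columns a0 a1 a2 u0 u1 u2.
enumerate_tables <- function(N) {
  cuts <- utils::combn(N + 5L, 5L)
  # stars and bars: compositions of N into 6 non-negative cells
  comp <- apply(cuts, 2L, function(cc) diff(c(0L, cc, N + 6L)) - 1L)
  t(comp)
}

# Subject-level route: the additive trend chi-square with unconditional
# variance equals N times the squared Pearson correlation between the
# genotype score and the affection indicator.
oracle_trend_chisq_cor <- function(affected, unaffected, scores = 0:2) {
  g <- rep(rep(scores, 2L), c(affected, unaffected))
  y <- rep(c(1L, 0L), c(sum(affected), sum(unaffected)))
  N <- length(g)
  # population (1/N) moments
  r <- (mean(g * y) - mean(g) * mean(y)) /
    sqrt((mean(g^2) - mean(g)^2) * (mean(y^2) - mean(y)^2))
  N * r^2
}

# Monte-Carlo permutation p-value for the trend test: permute affection
# labels over subjects, two-sided on |U|.  `mid = TRUE` returns the mid-p
# (half the tie mass), the right comparison point for a continuous
# approximation to a lattice statistic.
oracle_permutation_p <- function(affected, unaffected, n_perm = 1e5,
                                 scores = 0:2, mid = FALSE) {
  g <- rep(rep(scores, 2L), c(affected, unaffected))
  A <- sum(affected); N <- length(g)
  s1 <- sum(g)
  U_obs <- sum(g[seq_len(A)]) - A * s1 / N
  U_perm <- vapply(seq_len(n_perm), function(i)
    sum(g[sample.int(N, A)]) - A * s1 / N, numeric(1))
  over <- mean(abs(U_perm) > abs(U_obs) + 1e-9)
  ties <- mean(abs(abs(U_perm) - abs(U_obs)) < 1e-9)
  if (mid) over + ties / 2 else over + ties
}

# Offspring minor-allele-count distribution by direct enumeration of the
# four equally likely parental allele transmissions (no package code).
oracle_transmission <- function(f, m) {
  fa <- c(rep(1L, f), rep(0L, 2L - f))
  ma <- c(rep(1L, m), rep(0L, 2L - m))
  x <- as.vector(outer(fa, ma, `+`))
  prob <- c(mean(x == 0L), mean(x == 1L), mean(x == 2L))
  list(prob = prob, mean = mean(x), var = mean(x^2) - mean(x)^2)
}

# Null conditional moments of the FBAT numerator sum(T_i * X_i) by
# enumerating all 3^n offspring genotype configurations.
oracle_fbat_moments <- function(f, m, y, offset) {
  n <- length(f)
  tw <- y - offset
  dists <- lapply(seq_len(n), function(i) oracle_transmission(f[i], m[i]))
  configs <- expand.grid(rep(list(0:2), n))
  pr <- rep(1, nrow(configs))
  for (i in seq_len(n)) pr <- pr * dists[[i]]$prob[configs[[i]] + 1L]
  S <- as.vector(as.matrix(configs) %*% tw)
  mu <- sum(pr * S)
  list(mean = mu, var = sum(pr * (S - mu)^2))
}

# Small literal genotype matrix builder (SNPs x subjects).
make_geno <- function(calls, subject_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(subject_ids))
    subject_ids <- sprintf("I%03d", seq_len(ncol(calls)))
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(nrow(calls))),
                    chr = "1", bp = seq_len(nrow(calls)) * 1000)
  genotype_matrix(calls, map, subject_ids)
}

# Trio set referencing columns (f1, m1, o1, f2, m2, o2, ...) of a matrix
# built with make_geno; phenotypes per offspring.
make_trios <- function(phenotype) {
  n <- length(phenotype)
  data.frame(family_id = sprintf("F%02d", seq_len(n)),
             father_id = sprintf("I%03d", 3 * seq_len(n) - 2),
             mother_id = sprintf("I%03d", 3 * seq_len(n) - 1),
             offspring_id = sprintf("I%03d", 3 * seq_len(n)),
             phenotype = phenotype,
             father_idx = 3L * seq_len(n) - 2L,
             mother_idx = 3L * seq_len(n) - 1L,
             offspring_idx = 3L * seq_len(n),
             stringsAsFactors = FALSE)
}

# Quick PED/MAP scratch writer for parser tests.
write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
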