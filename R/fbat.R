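# Mendelian transmission model and the generalized (offset) FBAT statistic.

#' Offspring genotype distribution given parental genotypes
#'
#' Under Mendelian transmission each parent passes the counted (minor)
#' allele independently with probability `score/2`, so the offspring
#' minor-allele count is the sum of two independent Bernoulli draws.
#' Conditional moments: `E(X|S) = (f + m) / 2` and
#' `Var(X|S) = f/2 (1 - f/2) + m/2 (1 - m/2)`.
#'
#' @param father_score,mother_score parental minor-allele counts in
#'   `{0, 1, 2}`.
#' @return List of class `transmission_dist` with `prob` (named vector over
#'   offspring scores 0, 1, 2), `mean`, `var`.
#' @export
offspring_distribution <- function(father_score, mother_score) {
  if (is.na(father_score) || is.na(mother_score))
    stop("missing parental score; caller must skip this trio")
  stopifnot(father_score %in% 0:2, mother_score %in% 0:2)
  pf <- father_score / 2; pm <- mother_score / 2
  prob <- c(`0` = (1 - pf) * (1 - pm),
            `1` = pf * (1 - pm) + (1 - pf) * pm,
            `2` = pf * pm)
  structure(list(prob = prob,
                 mean = pf + pm,
                 var = pf * (1 - pf) + pm * (1 - pm)),
            class = "transmission_dist")
}

#' Generalized FBAT with phenotypic offset for one SNP
#'
#' Family-based association test comparing observed offspring minor-allele
#' counts with their Mendelian expectation given the parents.  With the
#' offset `mu` (the trait prevalence; 0.3 for diabetic nephropathy within
#' type 1 diabetes) and `T_i = Y_i - mu`:
#' \deqn{U = \sum_i T_i (X_i - E(X_i|S_i)),\qquad
#'       V = \sum_i T_i^2 \,\mathrm{Var}(X_i|S_i),\qquad Z = U/\sqrt{V}.}
#' Unaffected offspring enter with weight `-mu`; with `offset = 0` the test
#' reduces to the traditional affecteds-only TDT.  Trios with a missing call
#' in any member are skipped; `V = 0` yields an untestable result.  Results
#' with fewer than `min_informative` informative trios (positive conditional
#' variance, non-zero weight) are flagged `low_info`.
#'
#' @param snp SNP id or row index.
#' @param trios `trio_set` with index columns (see [build_trios()]).
#' @param genotypes a [genotype_matrix()].
#' @param offset phenotypic offset `mu`, default 0.3.
#' @param min_informative low-information flag threshold, default 10.
#' @return List of class `fbat_result`: `U`, `V`, `Z`, `p`, `n_informative`,
#'   `untestable`, `low_info`.
#' @export
fbat_test <- function(snp, trios, genotypes, offset = 0.3,
                      min_informative = 10L) {
  g <- unclass(genotypes)
  if (is.character(snp)) snp <- match(snp, rownames(g))
  f <- g[snp, trios$father_idx]
  m <- g[snp, trios$mother_idx]
  o <- g[snp, trios$offspring_idx]
  y <- trios$phenotype
  keep <- !is.na(f) & !is.na(m) & !is.na(o)
  f <- f[keep]; m <- m[keep]; o <- o[keep]; y <- y[keep]
  if (!length(f)) return(fbat_result(0, 0, 0L, min_informative))
  ex <- (f + m) / 2
  vx <- f / 2 * (1 - f / 2) + m / 2 * (1 - m / 2)
  tw <- y - offset
  U <- sum(tw * (o - ex))
  V <- sum(tw^2 * vx)
  fbat_result(U, V, sum(vx > 0 & tw != 0), min_informative)
}

fbat_result <- function(U, V, n_informative, min_informative) {
  if (V <= 0) {
    res <- list(U = U, V = 0, Z = NA_real_, p = NA_real_,
                n_informative = as.integer(n_informative),
                untestable = TRUE, low_info = TRUE)
  } else {
    Z <- U / sqrt(V)
    res <- list(U = U, V = V, Z = Z, p = 2 * stats::pnorm(-abs(Z)),
                n_informative = as.integer(n_informative),
                untestable = FALSE,
                low_info = n_informative < min_informative)
  }
  class(res) <- "fbat_result"
  res
}

#' @export
print.fbat_result <- function(x, ...) {
  if (x$untestable) cat("FBAT: untestable (V = 0)\n")
  else cat(sprintf("FBAT: Z = %.4f, p = %.4g (%d informative trios%s)\n",
                   x$Z, x$p, x$n_informative,
                   if (x$low_info) ", low information" else ""))
  invisible(x)
}

#' FBAT scan across all SNPs
#'
#' Vectorised application of [fbat_test()] to every SNP.  Untestable SNPs
#' are reported with missing `z_fbat`/`p_fbat` rather than dropped.
#'
#' @inheritParams fbat_test
#' @return Data frame: `snp_id`, `u_fbat`, `v_fbat`, `z_fbat`, `p_fbat`,
#'   `n_informative`, `low_info`.
#' @export
fbat_scan <- function(trios, genotypes, offset = 0.3, min_informative = 10L) {
  if (is.null(trios) || nrow(trios) == 0L) stop("no trios available")
  g <- unclass(genotypes)
  f <- g[, trios$father_idx, drop = FALSE]
  m <- g[, trios$mother_idx, drop = FALSE]
  o <- g[, trios$offspring_idx, drop = FALSE]
  ok <- !is.na(f) & !is.na(m) & !is.na(o)
  ex <- (f + m) / 2
  vx <- f / 2 * (1 - f / 2) + m / 2 * (1 - m / 2)
  dev <- o - ex
  dev[!ok] <- 0; vx[!ok] <- 0
  tw <- trios$phenotype - offset
  U <- as.vector(dev %*% tw)
  V <- as.vector(vx %*% tw^2)
  ninf <- as.integer(rowSums(sweep(vx > 0, 2L, tw != 0, `&`)))
  Z <- ifelse(V > 0, U / sqrt(V), NA_real_)
  data.frame(snp_id = snp_map(genotypes)$snp_id,
             u_fbat = U, v_fbat = V, z_fbat = Z,
             p_fbat = 2 * stats::pnorm(-abs(Z)),
             n_informative = ninf,
             low_info = V <= 0 | ninf < min_informative,
             stringsAsFactors = FALSE)
}
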