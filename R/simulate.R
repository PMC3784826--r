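# Synthetic cohort generator: unrelated cases/controls plus case/control
# proband trios, Mendelian transmission, logistic disease model, optional
# two-subpopulation stratification.  SNPs are simulated independently
# (no linkage disequilibrium).

#' Simulation configuration
#'
#' Describes a synthetic mixed-design cohort: unrelated singleton cases and
#' controls plus mother-father-offspring trios ascertained on the proband
#' phenotype.  Disease follows a logistic model
#' `logit P(Y=1 | X) = b0 + sum(log(OR_c) * X_c)` over the causal SNPs,
#' with `b0` calibrated so the marginal prevalence matches `prevalence`
#' (default 0.3, the prevalence of diabetic nephropathy within type 1
#' diabetes).  Optional stratification draws each family or singleton from
#' one of two subpopulations that shift both the minor-allele frequencies
#' and the baseline prevalence.
#'
#' @param n_snps number of SNPs.
#' @param n_trios number of trios; case probands are
#'   `round(n_trios * trio_case_fraction)`.
#' @param n_cases,n_controls singleton counts.
#' @param causal data frame with columns `index` (SNP row) and `or`
#'   (allelic odds ratio), optionally `maf` to pin those SNPs' minor-allele
#'   frequency; `NULL` = global null.
#' @param maf_range minor-allele frequency range, default `c(0.05, 0.5)`.
#' @param prevalence baseline disease prevalence, default 0.3.
#' @param trio_case_fraction fraction of trios with an affected proband,
#'   default 0.5.
#' @param stratification `NULL`, or a list with `maf_delta` (allele
#'   frequency difference between the two subpopulations),
#'   `prevalence_delta` and `mixing` (probability of subpopulation 2,
#'   default 0.5).
#' @param seed mandatory integer seed; the generator draws no implicit
#'   entropy.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_snps, n_trios, n_cases, n_controls,
                              causal = NULL, maf_range = c(0.05, 0.5),
                              prevalence = 0.3, trio_case_fraction = 0.5,
                              stratification = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_snps >= 1, prevalence > 0, prevalence < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(causal)) {
    stopifnot(all(causal$index >= 1), all(causal$index <= n_snps),
              all(causal$or > 0), nrow(causal) <= 10L)
  }
  if (!is.null(stratification)) {
    stratification <- utils::modifyList(
      list(maf_delta = 0.2, prevalence_delta = 0.2, mixing = 0.5),
      stratification)
  }
  structure(list(n_snps = as.integer(n_snps), n_trios = as.integer(n_trios),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal = causal, maf_range = maf_range,
                 prevalence = prevalence,
                 trio_case_fraction = trio_case_fraction,
                 stratification = stratification,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

expit <- function(x) 1 / (1 + exp(-x))

# Calibrate the logistic intercept so that the marginal prevalence over the
# causal-genotype distribution equals `prev`.  Enumerates the joint causal
# genotype distribution (independent SNPs, HWE at `maf`).
calibrate_intercept <- function(prev, causal, maf, tol = 1e-8) {
  if (is.null(causal) || nrow(causal) == 0L)
    return(stats::qlogis(prev))
  combos <- expand.grid(rep(list(0:2), nrow(causal)))
  logor <- log(causal$or)
  lin <- as.vector(as.matrix(combos) %*% logor)
  w <- rep(1, nrow(combos))
  for (k in seq_len(nrow(causal))) {
    p <- maf[causal$index[k]]
    w <- w * stats::dbinom(combos[[k]], 2L, p)
  }
  f <- function(b0) sum(w * expit(b0 + lin)) - prev
  stats::uniroot(f, c(-50, 50), tol = tol)$root
}

# Draw causal genotypes + phenotype for a batch of independent subjects
# of one subpopulation; returns list(xc = matrix batch x n_causal, y).
draw_subjects <- function(batch, causal, maf, b0) {
  if (is.null(causal) || nrow(causal) == 0L) {
    xc <- matrix(0L, batch, 0L)
    y <- stats::rbinom(batch, 1L, expit(b0))
  } else {
    nc <- nrow(causal)
    xc <- matrix(stats::rbinom(batch * nc, 2L,
                               rep(maf[causal$index], each = batch)),
                 nrow = batch, ncol = nc)
    y <- stats::rbinom(batch, 1L,
                       expit(b0 + as.vector(xc %*% log(causal$or))))
  }
  list(xc = xc, y = y)
}

#' Simulate a mixed-design cohort
#'
#' Parents and singletons are drawn in Hardy-Weinberg equilibrium at the
#' (sub)population allele frequency; offspring genotypes arise by Mendelian
#' transmission; phenotypes follow the logistic model of
#' [simulation_config()].  Singletons and probands are ascertained by
#' phenotype (rejection sampling, capped at 1e6 candidate draws per pool)
#' to hit the requested case/control counts.  Parent phenotypes are
#' missing, mirroring proband-based recruitment.
#'
#' @param config a [simulation_config()].
#' @return List of class `simulated_study`: `pedigree`
#'   ([pedigree_table()]), `genotypes` ([genotype_matrix()]), `truth`
#'   (per-SNP `snp_id`, `maf`, `causal`, `or`), `subpop` (per-subject
#'   subpopulation, 1 or 2), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  if (!is.null(config$causal) && !is.null(config$causal$maf))
    maf[config$causal$index] <- config$causal$maf
  strat <- config$stratification
  if (is.null(strat)) {
    mafs <- list(maf)
    prevs <- config$prevalence
    mixing <- 0
  } else {
    mafs <- list(pmin(pmax(maf - strat$maf_delta / 2, 0.005), 0.995),
                 pmin(pmax(maf + strat$maf_delta / 2, 0.005), 0.995))
    prevs <- config$prevalence + c(-1, 1) * strat$prevalence_delta / 2
    stopifnot(all(prevs > 0), all(prevs < 1))
    mixing <- strat$mixing
  }
  b0 <- vapply(seq_along(mafs), function(z)
    calibrate_intercept(prevs[z], config$causal, mafs[[z]]), numeric(1))

  n_case_tr <- round_half_up(config$n_trios * config$trio_case_fraction)
  n_ctrl_tr <- config$n_trios - n_case_tr

  # --- singleton ascertainment on causal genotypes only -------------------
  sg <- ascertain(config$n_cases, config$n_controls, mixing, function(z, b) {
    d <- draw_subjects(b, config$causal, mafs[[z]], b0[z])
    list(y = d$y, payload = d$xc)
  })
  # --- trio ascertainment on proband phenotype ----------------------------
  tr <- ascertain(n_case_tr, n_ctrl_tr, mixing, function(z, b) {
    if (is.null(config$causal) || nrow(config$causal) == 0L) {
      fa <- matrix(0L, b, 0L); mo <- fa; off <- fa
      y <- stats::rbinom(b, 1L, expit(b0[z]))
    } else {
      p <- mafs[[z]][config$causal$index]
      nc <- length(p)
      fa <- matrix(stats::rbinom(b * nc, 2L, rep(p, each = b)), b, nc)
      mo <- matrix(stats::rbinom(b * nc, 2L, rep(p, each = b)), b, nc)
      off <- matrix(stats::rbinom(b * nc, 1L, fa / 2) +
                      stats::rbinom(b * nc, 1L, mo / 2), b, nc)
      y <- stats::rbinom(b, 1L,
                         expit(b0[z] + as.vector(off %*% log(config$causal$or))))
    }
    list(y = y, payload = list(fa = fa, mo = mo, off = off))
  }, payload_bind = function(ps, rows) {
    list(fa = do.call(rbind, lapply(ps, `[[`, "fa"))[rows, , drop = FALSE],
         mo = do.call(rbind, lapply(ps, `[[`, "mo"))[rows, , drop = FALSE],
         off = do.call(rbind, lapply(ps, `[[`, "off"))[rows, , drop = FALSE])
  })

  # --- fill full genotype matrices ----------------------------------------
  causal_idx <- if (is.null(config$causal)) integer(0) else config$causal$index
  n_tr <- config$n_trios
  n_sg <- config$n_cases + config$n_controls

  hwe_draw <- function(subpop) {
    # columns: subjects; per-subject MAF vector by subpopulation
    n <- length(subpop)
    if (n == 0L) return(matrix(integer(0), m, 0L))
    if (length(mafs) == 1L)   # homogeneous population: recycle per column
      return(matrix(stats::rbinom(m * n, 2L, mafs[[1L]]), m, n))
    pm <- vapply(subpop, function(z) mafs[[z]], numeric(m))
    matrix(stats::rbinom(m * n, 2L, c(pm)), m, n)
  }
  fa_g <- hwe_draw(tr$subpop)
  mo_g <- hwe_draw(tr$subpop)
  off_g <- matrix(stats::rbinom(m * n_tr, 1L, fa_g / 2) +
                    stats::rbinom(m * n_tr, 1L, mo_g / 2), m, n_tr)
  sg_g <- hwe_draw(sg$subpop)
  if (length(causal_idx)) {
    if (n_tr > 0L) {
      fa_g[causal_idx, ] <- t(tr$payload$fa)
      mo_g[causal_idx, ] <- t(tr$payload$mo)
      off_g[causal_idx, ] <- t(tr$payload$off)
    }
    if (n_sg > 0L) sg_g[causal_idx, ] <- t(sg$payload)
  }

  # --- assemble pedigree + matrix (trios first, then singletons) ----------
  # per-family member order father, mother, offspring
  trio_fam <- sprintf("F%05d", seq_len(n_tr))
  fam3 <- rep(trio_fam, each = 3L)
  member <- rep(c("_F", "_M", "_O"), n_tr)
  id3 <- paste0(fam3, member)
  is_off <- member == "_O"
  father3 <- ifelse(is_off, paste0(fam3, "_F"), MISSING_MARKER)
  mother3 <- ifelse(is_off, paste0(fam3, "_M"), MISSING_MARKER)
  sex3 <- rep(c("male", "female", ""), n_tr)
  sex3[is_off] <- sample(c("male", "female"), n_tr, replace = TRUE)
  phen3 <- rep(NA_integer_, 3L * n_tr)
  phen3[is_off] <- tr$y
  sg_id <- sprintf("S%05d", seq_len(n_sg))

  ped <- pedigree_table(
    family_id = c(fam3, sg_id),
    individual_id = c(id3, sg_id),
    father_id = c(father3, rep(MISSING_MARKER, n_sg)),
    mother_id = c(mother3, rep(MISSING_MARKER, n_sg)),
    sex = c(sex3, sample(c("male", "female"), n_sg, replace = TRUE)),
    phenotype = c(phen3, sg$y),
    stratum = "C1")

  calls <- matrix(NA_integer_, m, nrow(ped))
  trio_cols <- function(member) seq_len(n_tr) * 3L - (3L - member)
  if (n_tr > 0L) {
    calls[, trio_cols(1L)] <- fa_g
    calls[, trio_cols(2L)] <- mo_g
    calls[, trio_cols(3L)] <- off_g
  }
  if (n_sg > 0L) calls[, 3L * n_tr + seq_len(n_sg)] <- sg_g

  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chr = "1", bp = 10000 * seq_len(m))
  genotypes <- genotype_matrix(calls, map, ped$individual_id)

  truth <- data.frame(snp_id = map$snp_id, maf = maf,
                      causal = seq_len(m) %in% causal_idx,
                      or = 1, stringsAsFactors = FALSE)
  if (length(causal_idx)) truth$or[causal_idx] <- config$causal$or
  subpop <- c(rep(tr$subpop, each = 3L), sg$subpop)

  structure(list(pedigree = ped, genotypes = genotypes, truth = truth,
                 subpop = subpop, config = config),
            class = "simulated_study")
}

# Rejection-sample subjects until n1 affected and n0 unaffected are
# collected.  `draw(z, batch)` returns list(y, payload) for `batch`
# candidates of subpopulation z.  Returns y, subpop and payload in final
# order (affected first).
ascertain <- function(n1, n0, mixing, draw, payload_bind = NULL,
                      max_draws = 1e6) {
  got1 <- 0L; got0 <- 0L; total <- 0L
  ys <- list(); zs <- list(); ps <- list(); keeps <- list()
  while (got1 < n1 || got0 < n0) {
    if (total >= max_draws)
      stop("ascertainment failed: case/control quotas unattainable")
    batch <- min(max(2L * (n1 + n0), 200L), max_draws - total)
    z <- 1L + stats::rbinom(batch, 1L, mixing)
    d1 <- draw(1L, sum(z == 1L))
    d2 <- if (any(z == 2L)) draw(2L, sum(z == 2L)) else NULL
    y <- integer(batch)
    y[z == 1L] <- d1$y
    if (!is.null(d2)) y[z == 2L] <- d2$y
    # payload rows aligned with candidate order within the batch
    pl <- list(d1$payload, d2$payload)
    ord <- c(which(z == 1L), which(z == 2L))
    keep <- logical(batch)
    need1 <- which(y == 1L); need0 <- which(y == 0L)
    take1 <- need1[seq_len(min(length(need1), n1 - got1))]
    take0 <- need0[seq_len(min(length(need0), n0 - got0))]
    keep[c(take1, take0)] <- TRUE
    got1 <- got1 + length(take1); got0 <- got0 + length(take0)
    total <- total + batch
    ys[[length(ys) + 1L]] <- y[keep]
    zs[[length(zs) + 1L]] <- z[keep]
    # reorder payload back to candidate order, then subset kept rows
    if (is.null(payload_bind)) {
      pay <- rbind(d1$payload,
                   if (!is.null(d2)) d2$payload else NULL)
      pay <- pay[order(ord), , drop = FALSE][keep, , drop = FALSE]
      ps[[length(ps) + 1L]] <- pay
    } else {
      both <- list(d1$payload, if (!is.null(d2)) d2$payload else
        list(fa = d1$payload$fa[0, , drop = FALSE],
             mo = d1$payload$mo[0, , drop = FALSE],
             off = d1$payload$off[0, , drop = FALSE]))
      pay <- payload_bind(both, order(ord))
      ps[[length(ps) + 1L]] <- lapply(pay, function(x)
        x[keep, , drop = FALSE])
    }
  }
  y <- as.integer(unlist(ys)); z <- as.integer(unlist(zs))
  # affected first, preserving draw order within class
  final <- c(which(y == 1L), which(y == 0L))
  if (is.null(payload_bind)) {
    payload <- do.call(rbind, ps)[final, , drop = FALSE]
  } else {
    payload <- list(
      fa = do.call(rbind, lapply(ps, `[[`, "fa"))[final, , drop = FALSE],
      mo = do.call(rbind, lapply(ps, `[[`, "mo"))[final, , drop = FALSE],
      off = do.call(rbind, lapply(ps, `[[`, "off"))[final, , drop = FALSE])
  }
  list(y = y[final], subpop = z[final], payload = payload)
}

#' Write a simulated study as PED/MAP plus truth TSV
#'
#' Produces `<prefix>.ped`, `<prefix>.map` and `<prefix>.truth.tsv`; the
#' PED/MAP pair round-trips through [read_ped()].
#'
#' @param study a `simulated_study`.
#' @param out_prefix output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_fixture <- function(study, out_prefix) {
  paths <- write_ped(study$pedigree, study$genotypes, out_prefix)
  truth_path <- paste0(out_prefix, ".truth.tsv")
  utils::write.table(study$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, truth = truth_path))
}
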