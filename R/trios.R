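# Trio assembly and per-SNP quality control.

#' Assemble complete mother-father-offspring trios
#'
#' Scans the pedigree for offspring whose father and mother both resolve to
#' genotyped subjects.  Only complete trios are returned: offspring with
#' exactly one recorded parent are excluded from the trio set and from the
#' singleton set (they carry partial family information and fit neither
#' subset).  When several offspring share the same parents, the one with the
#' lowest `individual_id` is kept.  Offspring with missing phenotype are
#' dropped.
#'
#' Singletons - subjects with no recorded parents that are not themselves a
#' parent of any retained trio - are exposed through `attr(x, "singletons")`
#' (individual ids) so population-based analyses can select them.
#'
#' @param pedigree a [pedigree_table()].
#' @param genotypes optional [genotype_matrix()]; when given, trio member
#'   indices into the subject order are attached and subjects missing from
#'   the matrix disqualify their trio.
#' @return Data frame of class `trio_set` with columns `family_id`,
#'   `father_id`, `mother_id`, `offspring_id`, `phenotype`, and (when
#'   `genotypes` is given) `father_idx`, `mother_idx`, `offspring_idx`.
#' @export
build_trios <- function(pedigree, genotypes = NULL) {
  has_both <- pedigree$father_id != MISSING_MARKER &
    pedigree$mother_id != MISSING_MARKER
  known <- function(id) id %in% pedigree$individual_id
  if (!is.null(genotypes)) {
    typed <- function(id) id %in% colnames(genotypes)
  } else typed <- function(id) rep(TRUE, length(id))

  cand <- pedigree[has_both, , drop = FALSE]
  resolved <- known(cand$father_id) & known(cand$mother_id)
  if (any(!resolved)) {
    warning("excluding ", sum(!resolved),
            " famil(y/ies) with unresolved parent ids")
    cand <- cand[resolved, , drop = FALSE]
  }
  ok <- typed(cand$father_id) & typed(cand$mother_id) &
    typed(cand$individual_id) & !is.na(cand$phenotype)
  cand <- cand[ok, , drop = FALSE]

  # one offspring per parent couple: lowest individual_id
  couple <- paste(cand$father_id, cand$mother_id, sep = "\r")
  ord <- order(couple, cand$individual_id)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(couple[ord]), , drop = FALSE]
  cand <- cand[order(match(cand$individual_id, pedigree$individual_id)), ,
               drop = FALSE]

  trios <- data.frame(family_id = cand$family_id,
                      father_id = cand$father_id,
                      mother_id = cand$mother_id,
                      offspring_id = cand$individual_id,
                      phenotype = cand$phenotype,
                      stringsAsFactors = FALSE)
  members <- unique(c(trios$father_id, trios$mother_id, trios$offspring_id))
  if (length(members) < 3L * nrow(trios))
    stop("a subject appears in more than one trio")
  if (!is.null(genotypes)) {
    trios$father_idx <- match(trios$father_id, colnames(genotypes))
    trios$mother_idx <- match(trios$mother_id, colnames(genotypes))
    trios$offspring_idx <- match(trios$offspring_id, colnames(genotypes))
  }
  no_parents <- pedigree$father_id == MISSING_MARKER &
    pedigree$mother_id == MISSING_MARKER
  singletons <- pedigree$individual_id[no_parents &
                                         !(pedigree$individual_id %in% members)]
  structure(trios, singletons = singletons,
            class = c("trio_set", "data.frame"))
}

#' Count trios with a Mendelian error at one SNP
#'
#' A trio is inconsistent when the offspring call has probability zero under
#' Mendelian transmission from the parental calls (see
#' [offspring_distribution()]).  Trios with a missing call in any member are
#' skipped.
#'
#' @param snp SNP id or row index.
#' @param trios a `trio_set` with index columns (see [build_trios()]).
#' @param genotypes a [genotype_matrix()].
#' @return Integer count of inconsistent trios.
#' @export
mendel_error_trios <- function(snp, trios, genotypes) {
  g <- unclass(genotypes)
  if (is.character(snp)) snp <- match(snp, rownames(g))
  sum(mendel_error_flags(g[snp, trios$father_idx],
                         g[snp, trios$mother_idx],
                         g[snp, trios$offspring_idx]))
}

# Vectorised Mendelian-consistency check; NA in any member => FALSE (skipped).
mendel_error_flags <- function(f, m, o) {
  err <- (f == 0L & m == 0L & o > 0L) |
    (f == 2L & m == 2L & o < 2L) |
    ((f == 0L & m == 2L) | (f == 2L & m == 0L)) & o != 1L |
    ((f == 0L | m == 0L) & o == 2L) |
    ((f == 2L | m == 2L) & o == 0L)
  err & !is.na(err)
}

#' Per-SNP quality-control filter
#'
#' Removes SNPs with Mendelian errors in more than `max_mendel_trios` trios
#' (default 2, i.e. removal at 3 or more error trios), call rate below
#' `min_call_rate`, minor-allele frequency below `min_maf`, or no allelic
#' variation at all (monomorphic).  At retained SNPs, members of a trio
#' showing a Mendelian error are set to missing at that SNP only.
#' Surviving SNPs keep their original (MAP) order.
#'
#' @param genotypes a [genotype_matrix()].
#' @param trios optional `trio_set`; without it the Mendelian filter is
#'   skipped and `mendel_trios` is reported as 0.
#' @param max_mendel_trios largest tolerated number of Mendelian-error trios.
#' @param min_call_rate,min_maf inclusive lower thresholds.
#' @return List with `genotypes` (filtered matrix) and `report`, a data frame
#'   of class `qc_report` with per-SNP `snp_id`, `chr`, `bp`, `maf`,
#'   `call_rate`, `mendel_trios`, `removed`, `reason`
#'   (`mendel`/`call_rate`/`monomorphic`/`maf` or `""`).
#' @export
filter_snps <- function(genotypes, trios = NULL, max_mendel_trios = 2L,
                        min_call_rate = 0.95, min_maf = 0.01) {
  g <- unclass(genotypes)
  map <- snp_map(genotypes)
  m <- nrow(g)

  mendel <- integer(m)
  if (!is.null(trios) && nrow(trios) > 0L) {
    f <- g[, trios$father_idx, drop = FALSE]
    mo <- g[, trios$mother_idx, drop = FALSE]
    o <- g[, trios$offspring_idx, drop = FALSE]
    err <- matrix(mendel_error_flags(f, mo, o), nrow = m)
    mendel <- as.integer(rowSums(err))
  }
  call_rate <- rowMeans(!is.na(g))
  maf <- rowMeans(g, na.rm = TRUE) / 2
  maf[is.nan(maf)] <- 0
  mono <- apply(g, 1L, function(x) length(unique(x[!is.na(x)])) <= 1L)

  reason <- character(m)
  reason[maf < min_maf] <- "maf"
  reason[mono] <- "monomorphic"
  reason[call_rate < min_call_rate] <- "call_rate"
  reason[mendel > max_mendel_trios] <- "mendel"
  removed <- reason != ""

  report <- data.frame(snp_id = map$snp_id, chr = map$chr, bp = map$bp,
                       maf = maf, call_rate = call_rate,
                       mendel_trios = mendel, removed = removed,
                       reason = reason, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  if (all(removed)) stop("no SNPs pass QC")

  keep <- which(!removed)
  out <- subset_genotypes(genotypes, snps = keep)
  # per-SNP zeroing of Mendelian-error trios at retained SNPs
  if (!is.null(trios) && nrow(trios) > 0L && any(mendel[keep] > 0L)) {
    x <- unclass(out)
    errk <- err[keep, , drop = FALSE]
    idx <- which(errk, arr.ind = TRUE)
    for (col in c("father_idx", "mother_idx", "offspring_idx"))
      x[cbind(idx[, 1L], trios[[col]][idx[, 2L]])] <- NA_integer_
    out <- genotype_matrix(x, snp_map(out), colnames(out))
  }
  list(genotypes = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [filter_snps()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
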