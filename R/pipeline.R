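# End-to-end orchestration: QC, the single-step strategies, screening,
# rank aggregation and the top-K two-step decision.

#' Pipeline run configuration
#'
#' All defaults are the values used throughout the package's reference
#' analysis: phenotypic offset 0.3, top-K of 10 at familywise alpha 0.05
#' (per-SNP threshold 0.005), C2BAT testing fractions 0.75/0.50/0.25 for
#' minor homozygote/heterozygote/major homozygote.
#'
#' @param ped_path,map_path input PED/MAP files (omit when `run_all()` is
#'   given an in-memory study).
#' @param phenotype_path optional phenotype/stratum TSV (see [read_ped()]).
#' @param offset FBAT phenotypic offset.
#' @param K number of top-ranked SNPs carried to testing.
#' @param alpha familywise significance level.
#' @param fractions C2BAT testing fractions.
#' @param max_mendel_trios,min_call_rate,min_maf QC thresholds (see
#'   [filter_snps()]).
#' @param seed master seed for all randomised steps.
#' @param out_dir output directory; created if absent.
#' @return List of class `run_config`.
#' @export
run_config <- function(ped_path = NULL, map_path = NULL,
                       phenotype_path = NULL, offset = 0.3, K = 10L,
                       alpha = 0.05, fractions = c(0.75, 0.50, 0.25),
                       max_mendel_trios = 2L, min_call_rate = 0.95,
                       min_maf = 0.01, seed = 1L, out_dir = NULL) {
  structure(list(ped_path = ped_path, map_path = map_path,
                 phenotype_path = phenotype_path, offset = offset,
                 K = as.integer(K), alpha = alpha, fractions = fractions,
                 max_mendel_trios = as.integer(max_mendel_trios),
                 min_call_rate = min_call_rate, min_maf = min_maf,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_result_tsv <- function(df, path, alpha, m) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_snps: %d", m),
               sprintf("# bonferroni_threshold: %.17g", alpha / m),
               sprintf("# bonferroni_threshold_2sf: %g",
                       signif(alpha / m, 2))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full combined-design analysis
#'
#' Executes, in order: trio assembly; per-subset QC (population subset:
#' call rate and MAF over the unrelated subjects; family subset: the same
#' plus the Mendelian-error trio filter); the four single-strategy analyses
#' (singletons-only trend, pooled trend, FBAT, all-SNP Fisher combination
#' and weighted-Z meta-analysis on the subset p-values); the two
#' independent screens (conditional power from parents + phenotypes, C2BAT
#' partitioning); log-rank aggregation over the SNPs passing QC in both
#' subsets; and the top-K Fisher decision.  With a dataset containing no
#' trios the family-dependent outputs are skipped with a notice and the
#' population outputs are still produced.
#'
#' Identical configuration and seed yield byte-identical output files.
#'
#' @param config a [run_config()].
#' @param study optional in-memory study (list with `pedigree` and
#'   `genotypes`, e.g. a `simulated_study`); bypasses file input.
#' @return Invisibly, a list with every intermediate table: `qc_population`,
#'   `qc_family`, `singletons_only`, `pooled`, `fbat`, `fisher_all`,
#'   `weighted_z`, `screen_family`, `screen_cc`, `two_step`, `notices`.
#' @export
run_all <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  notices <- character(0)
  if (is.null(study)) {
    if (is.null(config$ped_path)) stop("no input: ped_path or study required")
    study <- read_ped(config$ped_path, config$map_path,
                      config$phenotype_path)
  }
  pedigree <- study$pedigree
  genotypes <- study$genotypes
  out <- list()

  trios <- build_trios(pedigree, genotypes)
  singleton_ids <- attr(trios, "singletons")
  have_trios <- nrow(trios) > 0L
  if (!have_trios)
    notices <- c(notices, "no complete trios: family-based outputs skipped")

  # ---- per-subset QC ------------------------------------------------------
  sg_idx <- match(singleton_ids, colnames(genotypes))
  sg_idx <- sg_idx[!is.na(sg_idx)]
  pheno <- pedigree$phenotype[match(colnames(genotypes),
                                    pedigree$individual_id)]
  pop_subjects <- sg_idx[!is.na(pheno[sg_idx])]
  if (!length(pop_subjects)) stop("stage qc: no phenotyped singletons")
  qc_pop <- filter_snps(subset_genotypes(genotypes, subjects = pop_subjects),
                        trios = NULL,
                        max_mendel_trios = config$max_mendel_trios,
                        min_call_rate = config$min_call_rate,
                        min_maf = config$min_maf)
  out$qc_population <- qc_pop$report
  pop_snps <- qc_pop$report$snp_id[!qc_pop$report$removed]

  if (have_trios) {
    fam_cols <- c(rbind(trios$father_idx, trios$mother_idx,
                        trios$offspring_idx))
    fam_geno_all <- subset_genotypes(genotypes, subjects = fam_cols)
    fam_trios <- trios
    fam_trios$father_idx <- seq(1L, by = 3L, length.out = nrow(trios))
    fam_trios$mother_idx <- seq(2L, by = 3L, length.out = nrow(trios))
    fam_trios$offspring_idx <- seq(3L, by = 3L, length.out = nrow(trios))
    qc_fam <- filter_snps(fam_geno_all, fam_trios,
                          max_mendel_trios = config$max_mendel_trios,
                          min_call_rate = config$min_call_rate,
                          min_maf = config$min_maf)
    out$qc_family <- qc_fam$report
    fam_snps <- qc_fam$report$snp_id[!qc_fam$report$removed]
    fam_geno <- qc_fam$genotypes
  }

  # ---- single-step strategies --------------------------------------------
  pop_geno <- subset_genotypes(genotypes, snps = match(pop_snps,
                                                       rownames(genotypes)))
  out$singletons_only <- singleton_association(pop_geno, pedigree,
                                               "singletons_only", trios)
  out$pooled <- singleton_association(pop_geno, pedigree,
                                      "pooled_with_probands", trios)

  if (have_trios) {
    out$fbat <- fbat_scan(fam_trios, fam_geno, offset = config$offset)

    # all-SNP Fisher / weighted-Z on the intersection universe
    common <- intersect(pop_snps, fam_snps)
    i_pop <- match(common, out$singletons_only$snp_id)
    i_fam <- match(common, out$fbat$snp_id)
    p_pop <- out$singletons_only$p_trend[i_pop]
    z_pop <- out$singletons_only$z_trend[i_pop]
    p_fam <- out$fbat$p_fbat[i_fam]
    z_fam <- out$fbat$z_fbat[i_fam]
    n_pop <- out$singletons_only$n[1L]
    n_fam <- nrow(trios)
    comb <- function(i) {
      if (is.na(p_pop[i]) || is.na(p_fam[i]))
        return(c(NA_real_, NA_real_))
      pf <- fisher_combine(pmax(c(p_pop[i], p_fam[i]), 1e-300))
      wz <- weighted_z_combine(pmax(pmin(c(p_pop[i], p_fam[i]),
                                         1), 1e-300),
                               directions = sign(c(z_pop[i], z_fam[i]) +
                                                   1e-300),
                               sample_sizes = c(n_pop, n_fam))
      c(pf, wz$p)
    }
    both <- vapply(seq_along(common), comb, numeric(2))
    out$fisher_all <- data.frame(snp_id = common, p_fisher = both[1L, ],
                                 stringsAsFactors = FALSE)
    out$weighted_z <- data.frame(snp_id = common, p_weighted_z = both[2L, ],
                                 stringsAsFactors = FALSE)

    # ---- screening + two-step decision -----------------------------------
    scr_fam <- conditional_power_screen(fam_trios, fam_geno,
                                        offset = config$offset,
                                        alpha = config$alpha)
    out$screen_family <- scr_fam
    pop_pheno <- pheno[pop_subjects]
    scr_cc <- c2bat_scan(pop_geno, match(colnames(genotypes)[pop_subjects],
                                         colnames(pop_geno)),
                         pop_pheno, fractions = config$fractions,
                         seed = config$seed)
    out$screen_cc <- scr_cc

    # aggregate over the intersection universe; re-rank within it
    a_fam <- scr_fam[match(common, scr_fam$snp_id), ]
    a_cc <- scr_cc[match(common, scr_cc$snp_id), ]
    map_common <- snp_map(genotypes)
    map_common <- map_common[match(common, map_common$snp_id), ]
    rk_fam <- screen_rank(a_fam$screen_power, map_common)
    rk_cc <- screen_rank(a_cc$screen_score, map_common)
    agg <- aggregate_ranks(rk_fam, rk_cc, snp_id = common)
    out$two_step <- two_step_decision(agg,
                                      p_family = out$fbat$p_fbat[i_fam],
                                      p_cc = a_cc$p_c2bat,
                                      K = min(config$K, length(common)),
                                      alpha = config$alpha)
  }
  out$notices <- notices

  # ---- write outputs ------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(name, df, m_snps) {
      write_result_tsv(df, file.path(config$out_dir,
                                     paste0(name, ".tsv")),
                       config$alpha, m_snps)
    }
    write_qc_report(out$qc_population,
                    file.path(config$out_dir, "qc_population.tsv"))
    w("singletons_only", out$singletons_only, length(pop_snps))
    w("pooled", out$pooled, length(pop_snps))
    if (have_trios) {
      write_qc_report(out$qc_family,
                      file.path(config$out_dir, "qc_family.tsv"))
      w("fbat", out$fbat, length(fam_snps))
      w("fisher_all", out$fisher_all, nrow(out$fisher_all))
      w("weighted_z", out$weighted_z, nrow(out$weighted_z))
      two <- as.data.frame(out$two_step)
      con <- file(file.path(config$out_dir, "two_step.tsv"), "w")
      writeLines(c(sprintf("# n_snps: %d", nrow(two)),
                   sprintf("# K: %d", config$K),
                   sprintf("# threshold: %.17g",
                           attr(out$two_step, "threshold"))), con)
      utils::write.table(two, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    manifest <- c(sprintf("trioscreen_version: %s",
                          as.character(utils::packageVersion("trioscreen"))),
                  sprintf("r_version: %s", R.version.string),
                  sprintf("seed: %d", config$seed),
                  sprintf("offset: %g", config$offset),
                  sprintf("K: %d", config$K),
                  sprintf("alpha: %g", config$alpha),
                  sprintf("fractions: %s",
                          paste(config$fractions, collapse = ",")),
                  sprintf("max_mendel_trios: %d", config$max_mendel_trios),
                  sprintf("min_call_rate: %g", config$min_call_rate),
                  sprintf("min_maf: %g", config$min_maf),
                  notices)
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  }
  invisible(out)
}
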