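# Synthetic cohort generator.

test_that("config validation", {
  expect_error(simulation_config(10, 5, 5, 5), "seed")
  expect_error(simulation_config(10, 5, 5, 5, maf_range = c(0, 0.5),
                                 seed = 1))
  expect_error(simulation_config(10, 5, 5, 5, prevalence = 0, seed = 1))
  expect_error(simulation_config(10, 5, 5, 5,
                                 causal = data.frame(index = 11, or = 2),
                                 seed = 1))
})

test_that("requested counts, Mendelian consistency and determinism", {
  cfg <- simulation_config(n_snps = 30, n_trios = 20, n_cases = 25,
                           n_controls = 35, seed = 61)
  st <- simulate_cohort(cfg)
  ped <- st$pedigree
  expect_equal(nrow(ped), 3 * 20 + 60)
  sg <- ped[ped$father_id == "0" & !startsWith(ped$family_id, "F"), ]
  expect_equal(sum(sg$phenotype == 1), 25)
  expect_equal(sum(sg$phenotype == 0), 35)
  off <- ped[ped$father_id != "0", ]
  expect_equal(sum(off$phenotype == 1), 10)  # trio_case_fraction 0.5
  trios <- build_trios(ped, st$genotypes)
  expect_equal(nrow(trios), 20)
  errs <- vapply(1:30, mendel_error_trios, integer(1), trios = trios,
                 genotypes = st$genotypes)
  expect_true(all(errs == 0L))

  # same seed: identical; different seed: different
  st2 <- simulate_cohort(cfg)
  expect_identical(unclass(st2$genotypes), unclass(st$genotypes))
  st3 <- simulate_cohort(simulation_config(n_snps = 30, n_trios = 20,
                                           n_cases = 25, n_controls = 35,
                                           seed = 62))
  expect_false(identical(unclass(st3$genotypes), unclass(st$genotypes)))
})

test_that("parental allele frequencies recover the configured MAF", {
  cfg <- simulation_config(n_snps = 12, n_trios = 2000, n_cases = 0,
                           n_controls = 0, maf_range = c(0.1, 0.45),
                           seed = 63)
  st <- simulate_cohort(cfg)
  trios <- build_trios(st$pedigree, st$genotypes)
  par_idx <- c(trios$father_idx, trios$mother_idx)
  g <- unclass(st$genotypes)[, par_idx]
  emp <- rowMeans(g) / 2
  se <- sqrt(st$truth$maf * (1 - st$truth$maf) / (2 * length(par_idx)))
  expect_true(all(abs(emp - st$truth$maf) < 3 * se))
})

test_that("null model: no case/control allele-frequency difference in bulk", {
  cfg <- simulation_config(n_snps = 400, n_trios = 0, n_cases = 300,
                           n_controls = 300, seed = 64)
  st <- simulate_cohort(cfg)
  y <- st$pedigree$phenotype
  g <- unclass(st$genotypes)
  diff <- rowMeans(g[, y == 1, drop = FALSE]) / 2 -
    rowMeans(g[, y == 0, drop = FALSE]) / 2
  se_mean <- sd(diff) / sqrt(length(diff))
  expect_lt(abs(mean(diff)), 3 * se_mean)
})

test_that("causal SNP shifts case allele frequency in the right direction", {
  cfg <- simulation_config(n_snps = 20, n_trios = 0, n_cases = 500,
                           n_controls = 500,
                           causal = data.frame(index = 3, or = 2, maf = 0.3),
                           seed = 65)
  st <- simulate_cohort(cfg)
  y <- st$pedigree$phenotype
  g <- unclass(st$genotypes)
  expect_gt(mean(g[3, y == 1]), mean(g[3, y == 0]))
})

test_that("write_fixture round-trips and is byte-deterministic", {
  cfg <- simulation_config(n_snps = 15, n_trios = 8, n_cases = 10,
                           n_controls = 10, seed = 66)
  st <- simulate_cohort(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_fixture(st, p1)
  write_fixture(simulate_cohort(cfg), p2)
  expect_identical(readLines(paste0(p1, ".ped")),
                   readLines(paste0(p2, ".ped")))
  expect_identical(readLines(paste0(p1, ".map")),
                   readLines(paste0(p2, ".map")))
  back <- read_ped(paste0(p1, ".ped"), paste0(p1, ".map"))
  expect_identical(back$pedigree$individual_id, st$pedigree$individual_id)
  truth <- read.delim(paste0(p1, ".truth.tsv"))
  expect_equal(nrow(truth), 15)
})

test_that("stratification shifts subpopulation allele frequencies", {
  cfg <- simulation_config(n_snps = 50, n_trios = 0, n_cases = 400,
                           n_controls = 400,
                           maf_range = c(0.3, 0.4),
                           stratification = list(maf_delta = 0.3,
                                                 prevalence_delta = 0,
                                                 mixing = 0.5),
                           seed = 67)
  st <- simulate_cohort(cfg)
  g <- unclass(st$genotypes)
  f1 <- rowMeans(g[, st$subpop == 1, drop = FALSE]) / 2
  f2 <- rowMeans(g[, st$subpop == 2, drop = FALSE]) / 2
  expect_gt(mean(f2 - f1), 0.2)
})
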