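# PED/MAP parsing, trio assembly and QC filters.

map1 <- "1\trs1\t0\t1000"

test_that("read_ped orients calls to the minor allele and handles missing codes", {
  # single subject, monomorphic A: counted allele is the absent one -> 0
  ped <- write_lines_tmp("F1 I1 0 0 1 2 A A", ".ped")
  map <- write_lines_tmp(map1, ".map")
  x <- read_ped(ped, map)
  expect_equal(unname(unclass(x$genotypes)[1, 1]), 0L)
  expect_equal(x$pedigree$phenotype, 1L)
  expect_equal(x$pedigree$sex, "male")

  # allele pair containing the missing code "0" -> missing call
  ped <- write_lines_tmp(c("F1 I1 0 0 1 2 0 A", "F2 I2 0 0 2 1 A C"), ".ped")
  x <- read_ped(ped, map)
  expect_true(is.na(unclass(x$genotypes)[1, 1]))
  expect_equal(x$pedigree$phenotype, c(1L, 0L))

  # orientation: C is rarer, so calls count C
  ped <- write_lines_tmp(c("F1 I1 0 0 1 2 A A",
                           "F2 I2 0 0 2 1 A C",
                           "F3 I3 0 0 0 0 A A"), ".ped")
  x <- read_ped(ped, map)
  expect_equal(unname(unclass(x$genotypes)[1, ]), c(0L, 1L, 0L))
  expect_true(is.na(x$pedigree$phenotype[3]))
  map_df <- snp_map(x$genotypes)
  expect_equal(map_df$snp_id, "rs1")
  expect_equal(map_df$bp, 1000)
})

test_that("phenotype/stratum TSV overrides PED column 6", {
  ped <- write_lines_tmp(c("F1 I1 0 0 1 2 A C", "F2 I2 0 0 2 1 A A"), ".ped")
  map <- write_lines_tmp(map1, ".map")
  tsv <- write_lines_tmp(c("subject_id\tphenotype\tstratum",
                           "I1\t0\tJDC", "I2\t1\tGWU"), ".tsv")
  x <- read_ped(ped, map, phenotype_path = tsv)
  expect_equal(x$pedigree$phenotype, c(0L, 1L))  # PED said 1, 0
  expect_equal(x$pedigree$stratum, c("JDC", "GWU"))
})

test_that("read_ped rejects malformed input", {
  map4 <- write_lines_tmp(sprintf("1\trs%d\t0\t%d", 1:4, 1:4 * 100), ".map")
  ped5 <- write_lines_tmp(paste("F1 I1 0 0 1 2",
                                paste(rep("A A", 5), collapse = " ")), ".ped")
  expect_error(read_ped(ped5, map4), "fields")

  map <- write_lines_tmp(map1, ".map")
  dup <- write_lines_tmp(c("F1 I1 0 0 1 2 A A", "F2 I1 0 0 1 2 A A"), ".ped")
  expect_error(read_ped(dup, map), "duplicate")
})

test_that("write_ped/read_ped round-trips a simulated study", {
  st <- simulate_cohort(simulation_config(n_snps = 25, n_trios = 15,
                                          n_cases = 20, n_controls = 20,
                                          seed = 11))
  prefix <- tempfile()
  write_ped(st$pedigree, st$genotypes, prefix)
  back <- read_ped(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  # orientation on re-read may flip SNPs whose empirical frequency is > 0.5;
  # a second write/read cycle must then be a fixed point (idempotence)
  prefix2 <- tempfile()
  write_ped(back$pedigree, back$genotypes, prefix2)
  back2 <- read_ped(paste0(prefix2, ".ped"), paste0(prefix2, ".map"))
  expect_identical(back2$pedigree, back$pedigree)
  expect_identical(unclass(back2$genotypes), unclass(back$genotypes))
  expect_identical(back$pedigree$individual_id, st$pedigree$individual_id)
  expect_identical(back$pedigree$phenotype, st$pedigree$phenotype)
  # calls agree up to a per-SNP orientation flip
  a <- unclass(st$genotypes); b <- unclass(back$genotypes)
  flip_ok <- vapply(seq_len(nrow(a)), function(i)
    identical(a[i, ], b[i, ]) || identical(a[i, ], 2L - b[i, ]),
    logical(1))
  expect_true(all(flip_ok))
})

test_that("build_trios keeps only complete trios and exposes singletons", {
  expect_warning(
    ped <- pedigree_table(
      family_id = c("F1", "F1", "F1", "F2", "F3", "F1"),
      individual_id = c("dad", "mom", "kid", "solo", "halfkid", "kid2"),
      father_id = c("0", "0", "dad", "0", "0", "dad"),
      mother_id = c("0", "0", "mom", "0", "momx", "mom"),
      sex = c("male", "female", "male", "female", "male", "female"),
      phenotype = c(NA, NA, 1L, 0L, 1L, 1L)),
    "do not resolve")
  trios <- suppressWarnings(build_trios(ped))
  expect_equal(nrow(trios), 1L)
  expect_equal(trios$offspring_id, "kid")   # lowest id among kid/kid2
  # halfkid has partial family data: neither trio member nor singleton
  expect_identical(attr(trios, "singletons"), "solo")
})

test_that("build_trios requires genotyped members when a matrix is given", {
  ped <- pedigree_table(family_id = c("F1", "F1", "F1"),
                        individual_id = c("dad", "mom", "kid"),
                        father_id = c("0", "0", "dad"),
                        mother_id = c("0", "0", "mom"),
                        phenotype = c(NA, NA, 1L))
  g <- make_geno(matrix(c(1L, 1L), 1, 2), c("dad", "mom"))  # kid untyped
  expect_equal(nrow(build_trios(ped, g)), 0L)
})

test_that("mendel_error_trios matches the transmission model", {
  trios <- make_trios(c(1L, 1L, 1L))
  # families: (0,0)->1 error; (2,0)->0 error; (1,1)->2 fine
  g <- make_geno(matrix(c(0L, 0L, 1L,  2L, 0L, 0L,  1L, 1L, 2L), nrow = 1))
  expect_equal(mendel_error_trios(1, trios, g), 2L)
  g2 <- make_geno(matrix(c(0L, 0L, 0L,  2L, 0L, 1L,  1L, 1L, 0L), nrow = 1))
  expect_equal(mendel_error_trios(1, trios, g2), 0L)
  # missing member -> trio skipped
  g3 <- make_geno(matrix(c(0L, NA, 1L,  2L, 0L, 0L,  1L, 1L, 1L), nrow = 1))
  expect_equal(mendel_error_trios(1, trios, g3), 1L)
})

test_that("filter_snps applies the 3-or-more Mendelian-error rule", {
  trios <- make_trios(c(1L, 0L, 1L))
  calls <- rbind(c(0L, 0L, 1L,  0L, 0L, 2L,  2L, 2L, 0L),   # 3 error trios
                 c(0L, 0L, 1L,  0L, 0L, 2L,  1L, 1L, 1L),   # 2 error trios
                 c(1L, 1L, 1L,  1L, 0L, 1L,  0L, 1L, 0L),   # clean
                 c(0L, 0L, 0L,  0L, 0L, 0L,  0L, 0L, 0L))   # monomorphic
  g <- make_geno(calls)
  res <- filter_snps(g, trios, min_call_rate = 0, min_maf = 0)
  expect_equal(res$report$reason, c("mendel", "", "", "monomorphic"))
  expect_equal(res$report$mendel_trios, c(3L, 2L, 0L, 0L))
  expect_equal(rownames(res$genotypes), c("s002", "s003"))
  # retained SNP: the two offending trios are zeroed at that SNP only
  kept <- unclass(res$genotypes)
  expect_true(all(is.na(kept[1, 1:6])))    # trios 1-2 zeroed at s002
  expect_false(anyNA(kept[1, 7:9]))        # clean trio untouched
  expect_false(anyNA(kept[2, ]))           # clean SNP untouched
})

test_that("filter_snps errors when nothing survives", {
  g <- make_geno(matrix(0L, 2, 4))
  expect_error(filter_snps(g, NULL, min_call_rate = 0, min_maf = 0),
               "no SNPs pass QC")
})

test_that("zero-genotyping-error simulation has zero Mendelian errors", {
  st <- simulate_cohort(simulation_config(n_snps = 40, n_trios = 30,
                                          n_cases = 10, n_controls = 10,
                                          seed = 5))
  trios <- build_trios(st$pedigree, st$genotypes)
  errs <- vapply(seq_len(40), mendel_error_trios, integer(1),
                 trios = trios, genotypes = st$genotypes)
  expect_true(all(errs == 0L))
})
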