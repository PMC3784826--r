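# Conditional-power screening (trios) and C2BAT partitioning (case-control).

test_that("conditional power is alpha at zero slope and monotone in |delta|", {
  # phenotype orthogonal to the proxy genotype by construction: b_hat = 0
  trios <- make_trios(c(1L, 0L, 1L, 0L))
  calls <- matrix(c(1L, 1L, 1L,  1L, 1L, 1L,  1L, 1L, 1L,  1L, 1L, 1L),
                  nrow = 1)
  scr <- conditional_power_screen(make_trios(c(1L, 0L, 1L, 0L)),
                                  make_geno(calls), alpha = 0.05)
  expect_equal(scr$b_hat, 0)
  expect_equal(scr$screen_power, 0.05, tolerance = 1e-12)

  # power bounds and monotonicity in |delta|
  zc <- qnorm(0.975)
  pw <- function(d) pnorm(d - zc) + pnorm(-d - zc)
  ds <- seq(0, 6, by = 0.25)
  expect_true(all(diff(pw(ds)) > 0))
  expect_true(all(pw(ds) >= 0.05 - 1e-12 & pw(ds) < 1))
  expect_equal(pw(0), 0.05)
})

test_that("alpha does not change conditional-power ranks", {
  st <- simulate_cohort(simulation_config(n_snps = 60, n_trios = 80,
                                          n_cases = 5, n_controls = 5,
                                          seed = 41))
  trios <- build_trios(st$pedigree, st$genotypes)
  r1 <- conditional_power_screen(trios, st$genotypes, alpha = 0.05)
  r2 <- conditional_power_screen(trios, st$genotypes, alpha = 0.005)
  expect_equal(r1$rank, r2$rank)
  expect_true(all(sort(r1$rank) == seq_len(60)))
})

test_that("conditional power never reads offspring genotypes", {
  st <- simulate_cohort(simulation_config(n_snps = 40, n_trios = 50,
                                          n_cases = 5, n_controls = 5,
                                          seed = 43))
  trios <- build_trios(st$pedigree, st$genotypes)
  base <- conditional_power_screen(trios, st$genotypes)
  # scramble every offspring column; the screen must not notice
  g <- unclass(st$genotypes)
  set.seed(99)
  for (i in trios$offspring_idx) g[, i] <- sample(0:2, nrow(g), replace = TRUE)
  scrambled <- genotype_matrix(g, snp_map(st$genotypes), colnames(g))
  expect_identical(base, conditional_power_screen(trios, scrambled))
})

test_that("screen ranks break ties by position then id", {
  map <- data.frame(snp_id = c("b", "a", "c"), chr = "1",
                    bp = c(500, 500, 100))
  # equal scores: order by bp (c first), then snp_id (a before b)
  expect_equal(trioscreen:::screen_rank(c(1, 1, 1), map), c(3L, 2L, 1L))
})

test_that("c2bat_split honours fractions and margins", {
  tab <- genotype_counts(affected = c(60, 50, 40), unaffected = c(40, 50, 60))
  # 100 subjects per genotype class: testing totals 25, 50, 75
  set.seed(1)
  sp <- c2bat_split(tab)
  expect_equal(unname(sp$testing_margins$genotype_totals), c(25, 50, 75))
  full_a <- sp$screening_table$affected + sp$testing_table$affected
  full_u <- sp$screening_table$unaffected + sp$testing_table$unaffected
  expect_equal(full_a, tab$affected)
  expect_equal(full_u, tab$unaffected)

  expect_error(c2bat_split(tab, fractions = c(0, 0, 0)), "empty testing")

  sp1 <- c2bat_split(tab, fractions = c(1, 1, 1))
  expect_equal(sp1$testing_table$affected, tab$affected)
  expect_equal(sp1$screening_table$affected +
                 sp1$screening_table$unaffected, c(0, 0, 0))
  # fractions (1,1,1): the testing table IS the full table
  expect_equal(c2bat_test(sp1)$Z, trend_test(tab)$Z)
})

test_that("c2bat imputation preserves the testing margins exactly", {
  tab <- genotype_counts(c(30, 25, 12), c(20, 35, 18))
  set.seed(2)
  sp <- c2bat_split(tab)
  marg <- sp$testing_margins
  for (i in 1:1000) {
    imp <- c2bat_screen(sp)$imputed_table
    expect_true(sum(imp$affected) == marg$affected &&
                  all(imp$affected + imp$unaffected ==
                        marg$genotype_totals))
  }
  # expected-count mode is deterministic and margin-exact too
  imp <- c2bat_screen(sp, expected = TRUE)$imputed_table
  expect_equal(sum(imp$affected), marg$affected)
})

test_that("degenerate summed table gives screening score 0", {
  # every subject affected: trend on the imputed+screening sum has V = 0
  tab <- genotype_counts(c(10, 10, 10), c(0, 0, 0))
  set.seed(3)
  sp <- c2bat_split(tab)
  expect_equal(c2bat_screen(sp)$score, 0)
  expect_true(c2bat_test(sp)$untestable)
})

test_that("c2bat_test on identical case/control distributions gives p = 1", {
  sp <- list(screening_table = genotype_counts(c(0, 0, 0), c(0, 0, 0)),
             testing_table = genotype_counts(c(10, 20, 10), c(10, 20, 10)),
             testing_margins = list(affected = 40, unaffected = 40,
                                    genotype_totals = c(20, 40, 20)))
  class(sp) <- "contingency_split"
  expect_equal(c2bat_test(sp)$p, 1)
})

test_that("c2bat_scan is reproducible and independent of SNP order", {
  st <- simulate_cohort(simulation_config(n_snps = 30, n_trios = 0,
                                          n_cases = 60, n_controls = 60,
                                          seed = 47))
  idx <- seq_len(ncol(st$genotypes))
  y <- st$pedigree$phenotype
  r1 <- c2bat_scan(st$genotypes, idx, y, seed = 5)
  r2 <- c2bat_scan(st$genotypes, idx, y, seed = 5)
  expect_identical(r1, r2)
  r3 <- c2bat_scan(st$genotypes, idx, y, seed = 6)
  expect_false(identical(r1$screen_score, r3$screen_score))
  # per-SNP streams: restricting to a subset leaves per-SNP results intact
  sub <- subset_geno <- trioscreen:::subset_genotypes(st$genotypes,
                                                      snps = 1:10)
  r_sub <- c2bat_scan(sub, idx, y, seed = 5)
  expect_equal(r_sub$p_c2bat, r1$p_c2bat[1:10])
  expect_equal(r_sub$screen_score, r1$screen_score[1:10])
})

test_that("causal SNP is ranked highly by conditional power", {
  # 1 causal SNP (OR 2, MAF 0.3) among nulls, 500 trios; the screen reads
  # only parents + phenotypes yet should place the causal SNP near the top.
  ranks <- vapply(1:20, function(r) {
    st <- simulate_cohort(simulation_config(
      n_snps = 200, n_trios = 500, n_cases = 5, n_controls = 5,
      causal = data.frame(index = 100, or = 2, maf = 0.3), seed = 400 + r))
    trios <- build_trios(st$pedigree, st$genotypes)
    conditional_power_screen(trios, st$genotypes)$rank[100]
  }, numeric(1))
  expect_lte(median(ranks), 10)
})
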