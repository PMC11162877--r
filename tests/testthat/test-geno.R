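test_that("EIGENSTRAT round trip is the identity, '9' is missing", {
  g <- matrix(c(0L, 2L, NA, 1L, 0L,
                2L, NA, 1L, 0L, 2L,
                1L, 1L, 2L, NA, 0L), nrow = 3, byrow = TRUE)
  panel <- tiny_panel(g, pops = c("P1", "P1", "P2"))
  prefix <- file.path(tempdir(), "rt_fixture")
  write_eigenstrat(panel, prefix)
  back <- read_eigenstrat(prefix)
  expect_identical(back$geno, panel$geno)
  expect_identical(back$variants$pos, panel$variants$pos)
  expect_identical(back$individuals$population, panel$individuals$population)
})

test_that("a raw .geno line parses positionally", {
  prefix <- file.path(tempdir(), "raw_fixture")
  writeLines("029", paste0(prefix, ".geno"))
  writeLines(c("s1\t1\t0\t100\tC\tA"), paste0(prefix, ".snp"))
  writeLines(c("a\tU\tP", "b\tU\tP", "c\tU\tQ"), paste0(prefix, ".ind"))
  panel <- read_eigenstrat(prefix)
  expect_identical(as.integer(panel$geno[, 1]), c(0L, 2L, NA))
  # dimension mismatch and bad characters are rejected
  writeLines("02", paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "mismatch")
  writeLines("0x9", paste0(prefix, ".geno"))
  expect_error(read_eigenstrat(prefix), "invalid genotype")
})

test_that("round trip holds on a simulated 1000-site panel", {
  fr <- simulate_frequencies(demo_tree(), 1100, seed = 20)
  panel <- sample_diploids(fr, c(A = 4, X = 3, Out = 2), seed = 21)
  panel$geno[sample(length(panel$geno), 50)] <- NA  # sprinkle missingness
  prefix <- file.path(tempdir(), "sim_rt")
  write_eigenstrat(panel, prefix)
  back <- read_eigenstrat(prefix)
  expect_identical(back$geno, panel$geno)
})

test_that("PLINK text panels load with per-site allele coding", {
  map <- file.path(tempdir(), "t.map"); ped <- file.path(tempdir(), "t.ped")
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200"), map)
  writeLines(c("F1 a 0 0 0 -9 A A A G",
               "F1 b 0 0 0 -9 A C G G",
               "F2 c 0 0 0 -9 C C 0 0"), ped)
  panel <- read_plink_ped(ped, map)
  expect_identical(as.integer(panel$geno[, 1]), c(0L, 1L, 2L))
  expect_identical(as.integer(panel$geno[, 2]), c(1L, 2L, NA))
  expect_identical(panel$individuals$population, c("F1", "F1", "F2"))
})

test_that("pileup pseudo-haploidization follows the read draw", {
  v <- tiny_variants(3)
  pu <- data.frame(individual = "a", chrom = "1",
                   pos = c(10000, 20000, 30000),
                   count0 = c(0L, 5L, 0L), count1 = c(0L, 0L, 4L))
  h <- pseudo_haploidize_pileup(pu, v, seed = 30)
  expect_identical(as.integer(h$geno[1, ]), c(NA, 0L, 1L))
  # a balanced (1,1) pileup draws each allele about half the time
  n <- 10000
  vb <- tiny_variants(n)
  pub <- data.frame(individual = "a", chrom = "1", pos = vb$pos,
                    count0 = 1L, count1 = 1L)
  hb <- pseudo_haploidize_pileup(pub, vb, seed = 31)
  expect_lt(abs(mean(hb$geno[1, ]) - 0.5), 3 * sqrt(0.25 / n))
  # unknown site rejected
  bad <- data.frame(individual = "a", chrom = "2", pos = 1,
                    count0 = 1L, count1 = 0L)
  expect_error(pseudo_haploidize_pileup(bad, v, seed = 1), "absent")
})

test_that("diploid pseudo-haploidization is deterministic on homozygotes", {
  g <- matrix(c(0L, 2L, NA, 1L), 1)
  p <- tiny_panel(g)
  h1 <- pseudo_haploidize_diploid(p, seed = 1)
  expect_identical(as.integer(h1$geno[1, 1:3]), c(0L, 1L, NA))
  draws <- vapply(1:600, function(s)
    pseudo_haploidize_diploid(p, seed = s)$geno[1, 4], integer(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("transition masking flags exactly the A/G and C/T pairs", {
  v <- variant_table(rep("1", 4), 1:4 * 100,
                     c("C", "A", "G", "T"), c("T", "C", "A", "G"))
  expect_identical(mask_transitions(v), c(TRUE, FALSE, TRUE, FALSE))
  bad <- variant_table("1", 1, "I", "D")
  expect_error(mask_transitions(bad), "base")
})

test_that("site filtering matches a per-site counting oracle", {
  set.seed(40)
  n <- 400
  g <- matrix(rbinom(20 * n, 2, runif(n)[col(matrix(0, 20, n))]), 20, n)
  g[runif(length(g)) < 0.03] <- NA
  panel <- tiny_panel(g)
  out <- filter_sites(panel, max_missing = 0.05, min_maf = 0.1)
  # independent per-site loop
  keep <- logical(n)
  for (j in seq_len(n)) {
    x <- g[, j]
    miss <- mean(is.na(x))
    f <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
    keep[j] <- miss <= 0.05 && min(f, 1 - f) >= 0.1
  }
  expect_identical(out$variants$pos, panel$variants$pos[keep])
  # monomorphic site always dropped under min_maf > 0
  mono <- tiny_panel(matrix(0L, 5, 1))
  expect_warning(filter_sites(mono, 1, 0.01), "all sites removed")
})

test_that("merging harmonizes flipped alleles and drops triallelic sites", {
  v_a <- variant_table(rep("1", 3), c(100, 200, 300),
                       c("A", "A", "A"), c("C", "C", "C"))
  v_b <- variant_table(rep("1", 3), c(100, 200, 300),
                       c("A", "C", "A"), c("C", "A", "G"))
  a <- gt_panel(matrix(c(0L, 1L, 2L), 1), v_a,
                data.frame(id = "a1", population = "P"), "diploid")
  b <- gt_panel(matrix(c(2L, 2L, 0L), 1), v_b,
                data.frame(id = "b1", population = "Q"), "diploid")
  m <- merge_datasets(a, b)
  expect_identical(m$variants$pos, c(100L, 200L))  # (A,G) site dropped
  expect_identical(as.integer(m$geno["b1", ]), c(2L, 0L))  # flip 2 -> 0
  expect_identical(attr(m, "n_triallelic_dropped"), 1L)
  # identity merge keeps every site
  a2 <- gt_panel(matrix(c(0L, 1L, 2L), 1), v_a,
                 data.frame(id = "a2", population = "P"), "diploid")
  m2 <- merge_datasets(a, a2)
  expect_identical(m2$variants$pos, v_a$pos)
})

test_that("LD pruning removes duplicates greedily", {
  set.seed(41)
  base <- rbinom(40, 2, 0.5)
  g <- cbind(base, base, base, rbinom(40, 2, 0.5))
  panel <- tiny_panel(g)
  keep <- ld_prune(panel, window_snps = 4, step = 1, r2_max = 0.4)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE))
  # independent sites are essentially untouched
  g2 <- matrix(rbinom(200 * 60, 2, 0.5), 60)
  panel2 <- tiny_panel(g2)
  keep2 <- ld_prune(panel2, window_snps = 50, step = 10, r2_max = 0.4)
  expect_gt(mean(keep2), 0.95)
})

test_that("outgroup polarization requires a homozygous matching allele", {
  v <- tiny_variants(4, allele0 = "A", allele1 = "C")
  calls <- data.frame(chrom = "1", pos = c(10000, 20000, 30000),
                      allele_a = c("A", "A", "G"),
                      allele_b = c("A", "C", "G"))
  out <- polarize_by_outgroup(v, calls)
  expect_identical(out$ancestral, c("A", NA, NA, NA))
})

test_that("pseudo-haploid calls are unbiased for the allele frequency", {
  freqs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  panel <- hwe_panel(freqs, 400, seed = 42)
  h <- pseudo_haploidize_diploid(panel, seed = 43)
  dip_f <- colMeans(panel$geno) / 2
  hap_f <- colMeans(h$geno)
  se <- sqrt(dip_f * (1 - dip_f) / nrow(h$geno))
  expect_true(all(abs(hap_f - dip_f) < 4 * se))
})

test_that("transition masking commutes with site filtering", {
  fr <- simulate_frequencies(demo_tree(), 800, seed = 44)
  panel <- sample_diploids(fr, c(A = 8, X = 8), seed = 45)
  tv_first <- filter_sites(subset_panel(panel,
                                        sites = !mask_transitions(panel$variants)),
                           max_missing = 1, min_maf = 0.05)
  filt <- filter_sites(panel, max_missing = 1, min_maf = 0.05)
  tv_last <- subset_panel(filt, sites = !mask_transitions(filt$variants))
  expect_identical(tv_first$variants$pos, tv_last$variants$pos)
  expect_identical(tv_first$geno, tv_last$geno)
})
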