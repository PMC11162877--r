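test_that("zero-drift branches copy parent frequencies exactly", {
  tree <- population_tree(data.frame(parent = c("r", "r", "a", "a"),
                                     child = c("Out", "a", "P1", "P2"),
                                     f = c(0, 0, 0, 0)), "Out")
  fr <- simulate_frequencies(tree, 500, seed = 1, ascertain = FALSE)
  expect_identical(fr[, "P1"], fr[, "P2"])
  expect_identical(fr[, "P1"], fr[, "Out"])
})

test_that("Balding-Nichols drift variance matches F p (1 - p)", {
  tree <- population_tree(
    data.frame(parent = c("r", "r"), child = c("Out", "A"), f = c(0, 0.1)),
    "Out", root_freq = c(0.5, 0.5))
  fr <- simulate_frequencies(tree, 50000, seed = 2, ascertain = FALSE)
  expect_equal(mean(fr[, "A"]), 0.5, tolerance = 0.01)
  expect_equal(var(fr[, "A"]), 0.1 * 0.25, tolerance = 0.05)
})

test_that("full-replacement admixture copies the source population", {
  adm <- data.frame(source = "A", target = "B", alpha = 1.0)
  tree <- population_tree(data.frame(parent = c("r", "r", "r"),
                                     child = c("Out", "A", "B"),
                                     f = c(0, 0.1, 0.1)), "Out",
                          admixture = adm)
  fr <- simulate_frequencies(tree, 300, seed = 3, ascertain = FALSE)
  expect_identical(fr[, "A"], fr[, "B"])
})

test_that("tree validation rejects bad drift and admixture", {
  expect_error(population_tree(data.frame(parent = "r", child = "A", f = 1),
                               "A"), "drift")
  expect_error(population_tree(data.frame(parent = "r", child = "A", f = 0.1),
                               "B"), "outgroup")
  expect_error(population_tree(
    data.frame(parent = c("r", "r", "a", "a"),
               child = c("Out", "a", "A", "B"), f = rep(0.1, 4)), "Out",
    admixture = data.frame(source = "A", target = "a", alpha = 0.5)),
    "ancestor")
})

test_that("simulation is deterministic given seed", {
  tree <- demo_tree()
  f1 <- simulate_frequencies(tree, 400, seed = 9)
  f2 <- simulate_frequencies(tree, 400, seed = 9)
  expect_identical(f1, f2)
  p1 <- sample_diploids(f1, c(A = 3, X = 2), seed = 4)
  p2 <- sample_diploids(f2, c(A = 3, X = 2), seed = 4)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$variants, p2$variants)
})

test_that("diploid sampling respects fixed and intermediate frequencies", {
  fr <- cbind(P = c(0, 1, 0.5))
  attr(fr, "n_drawn") <- 3
  panel <- sample_diploids(fr, c(P = 10000), seed = 5,
                           chrom_lengths = c("1" = 1e6))
  expect_true(all(panel$geno[, 1] == 0L))
  expect_true(all(panel$geno[, 2] == 2L))
  het <- mean(panel$geno[, 3] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("pileup reads are faithful without damage or error", {
  v <- tiny_variants(50, allele0 = "A", allele1 = "C")
  panel <- tiny_panel(matrix(2L, 1, 50), variants = v)
  pu <- simulate_ancient_pileup(panel, ancient_spec(mean_depth = 3), seed = 6)
  expect_true(all(pu$count0 == 0L))
  expect_true(all(pu$count1 >= 1L))
})

test_that("Poisson depth gives the expected covered-site fraction", {
  n <- 30000
  v <- tiny_variants(n)
  panel <- tiny_panel(matrix(0L, 1, n), variants = v)
  pu <- simulate_ancient_pileup(panel, ancient_spec(mean_depth = 0.07),
                                seed = 7)
  frac <- nrow(pu) / n
  expected <- 1 - exp(-0.07)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("deamination flips the stated fraction of C reads at C/T sites", {
  n <- 10000
  v <- tiny_variants(n, allele0 = "C", allele1 = "T")
  panel <- tiny_panel(matrix(0L, 1, n), variants = v)  # homozygous C
  pu <- simulate_ancient_pileup(panel,
                                ancient_spec(mean_depth = 1, damage_rate = 0.2),
                                seed = 8)
  t_frac <- sum(pu$count1) / sum(pu$count0 + pu$count1)
  expect_lt(abs(t_frac - 0.2), 3 * sqrt(0.2 * 0.8 / sum(pu$count0 + pu$count1)))
})

test_that("damage never touches transversion-pair sites", {
  n <- 2000
  v <- tiny_variants(n, allele0 = "A", allele1 = "C")
  panel <- tiny_panel(matrix(0L, 1, n), variants = v)
  pu <- simulate_ancient_pileup(panel,
                                ancient_spec(mean_depth = 2, damage_rate = 0.5),
                                seed = 9)
  expect_true(all(pu$count1 == 0L))
})

test_that("planted tracts are homozygous with frequency-drawn alleles", {
  n <- 2000
  v <- tiny_variants(n, spacing = 1000)  # 2 Mb of sites
  fr <- matrix(0.5, n, 1, dimnames = list(NULL, "P"))
  panel <- hwe_panel(rep(0.5, n), 1, seed = 10, spacing = 1000)
  none <- plant_roh(panel, panel_segments <- data.frame(
    individual = character(0), chrom = character(0),
    start = integer(0), end = integer(0)), fr, seed = 1)
  expect_identical(none$panel$geno, panel$geno)
  seg <- data.frame(individual = "i01", chrom = "1",
                    start = 1, end = 1000000)
  pl <- plant_roh(panel, seg, fr, seed = 11)
  inside <- pl$panel$variants$pos <= 1000000
  expect_true(all(pl$panel$geno[1, inside] %in% c(0L, 2L)))
  hom_derived <- mean(pl$panel$geno[1, inside] == 2L)
  expect_lt(abs(hom_derived - 0.5), 3 * sqrt(0.25 / sum(inside)))
  expect_identical(pl$panel$geno[1, !inside], panel$geno[1, !inside])
  expect_error(plant_roh(panel, rbind(seg, seg), fr, seed = 1), "overlap")
})

test_that("coverage profiles encode sex in the X/autosome ratio", {
  f <- simulate_coverage_profile("female", 1.0, seed = 12)
  m <- simulate_coverage_profile("male", 1.0, seed = 13)
  expect_equal(sex_from_coverage(f)$ratio, 1.0, tolerance = 0.1)
  expect_equal(sex_from_coverage(m)$ratio, 0.5, tolerance = 0.1)
  hi <- simulate_coverage_profile("female", 6.7, cv = 0.02, seed = 14)
  auto <- hi[hi$class == "autosome", ]
  expect_equal(weighted.mean(auto$mean_depth, auto$length), 6.7,
               tolerance = 0.02)
  expect_error(simulate_coverage_profile("unknown", 1), "sex")
})

test_that("insertion read geometry distinguishes carrier states", {
  rd <- simulate_insertion_reads(FALSE, 50, read_length = 60,
                                 breakpoint = 1000, seed = 15)
  absent <- rd[rd$reference_version == "insertion_absent", ]
  present <- rd[rd$reference_version == "insertion_present", ]
  # true haplotype spans cleanly on the matching reference only
  expect_true(all(absent$mismatches == 0L))
  expect_true(all(pmin(present$overhang_left, present$overhang_right) <= 5))
  # centered reads overlap the breakpoint by >= 20 bp on the matching side
  centered <- absent$overhang_left >= 20 & absent$overhang_right >= 20
  expect_gt(sum(centered), 0)
  # carrier: no clean spanning reads on the insertion-absent reference
  rd2 <- simulate_insertion_reads(TRUE, 50, seed = 16)
  wrong <- rd2[rd2$reference_version == "insertion_absent", ]
  expect_true(all(pmin(wrong$overhang_left, wrong$overhang_right) > 10 |
                    wrong$mismatches > 0 |
                    pmin(wrong$overhang_left, wrong$overhang_right) <= 5))
  expect_equal(nrow(simulate_insertion_reads(TRUE, 0)), 0)
})
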