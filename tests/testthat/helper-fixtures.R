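# small programmatic fixtures shared across test files

# variant table on one chromosome with evenly spaced sites
tiny_variants <- function(n, spacing = 10000, chrom = "1",
                          allele0 = "A", allele1 = "C") {
  variant_table(rep(chrom, n), seq(spacing, by = spacing, length.out = n),
                rep(allele0, n), rep(allele1, n))
}

# diploid panel with explicit dosage matrix
tiny_panel <- function(geno, pops = NULL, variants = NULL,
                       ploidy = "diploid") {
  geno <- as.matrix(geno)
  if (is.null(variants)) variants <- tiny_variants(ncol(geno))
  if (is.null(pops)) pops <- rep("P", nrow(geno))
  ind <- data.frame(id = sprintf("i%02d", seq_len(nrow(geno))),
                    population = pops, stringsAsFactors = FALSE)
  gt_panel(geno, variants, ind, ploidy)
}

# HWE diploid panel at given per-site frequencies
hwe_panel <- function(freqs, n_ind, seed, pops = "P", spacing = 10000) {
  set.seed(seed)
  g <- t(vapply(seq_len(n_ind),
                function(i) stats::rbinom(length(freqs), 2L, freqs),
                integer(length(freqs))))
  tiny_panel(g, pops = rep_len(pops, n_ind),
             variants = tiny_variants(length(freqs), spacing = spacing))
}

# four-populations-plus-outgroup tree used by several tests
demo_tree <- function(f_shared = 0.05) {
  population_tree(data.frame(
    parent = c("root", "root", "n1", "n1", "n2", "n2", "n3", "n3"),
    child = c("Out", "n1", "n2", "Y", "n3", "Z", "A", "X"),
    f = c(0.2, 0.03, 0.03, 0.08, f_shared, 0.08, 0.06, 0.06)),
    outgroup = "Out")
}
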