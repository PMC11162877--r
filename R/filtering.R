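#' Filter sites on missingness and minor-allele frequency
#'
#' Drops sites whose missing-call fraction exceeds `max_missing` or whose
#' minor-allele frequency (computed on non-missing calls) is below
#' `min_maf`, preserving site order. Defaults mirror the common strict
#' panel filter (`--geno 0.01 --maf 0.01`).
#'
#' @param panel a [gt_panel()].
#' @param max_missing maximum tolerated missing fraction per site.
#' @param min_maf minimum minor-allele frequency.
#' @return The filtered panel, with attribute `n_dropped`.
#' @export
filter_sites <- function(panel, max_missing = 0.01, min_maf = 0.01) {
  stopifnot(inherits(panel, "gt_panel"),
            max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  s <- site_summary(panel)
  keep <- s$missing_frac <= max_missing &
    !is.na(s$maf) & s$maf >= min_maf
  if (!any(keep)) warning("all sites removed by filtering")
  out <- subset_panel(panel, sites = keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Merge two genotype datasets on shared sites
#'
#' Intersects on (chrom, pos); where the two allele sets match with
#' reversed labels, dosages in `b` are flipped to `a`'s orientation; sites
#' whose allele sets differ (effectively triallelic across datasets) are
#' dropped, as are duplicated positions and duplicated individual ids
#' (first occurrence kept). Strand-ambiguous A/T and C/G sites are
#' retained but flagged in the returned attribute `ambiguous_sites`, since
#' label matching cannot detect strand flips there.
#'
#' @param a,b [gt_panel()]s of equal ploidy.
#' @return Merged [gt_panel()] over the shared harmonized sites, rows of
#'   `a` first.
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "gt_panel"), inherits(b, "gt_panel"),
            a$ploidy == b$ploidy)
  dedup <- function(p) {
    keyv <- paste(p$variants$chrom, p$variants$pos)
    p <- subset_panel(p, sites = !duplicated(keyv))
    subset_panel(p, inds = !duplicated(p$individuals$id))
  }
  a <- dedup(a); b <- dedup(b)
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) stop("no shared sites between datasets")
  ia <- match(common, key_a); ib <- match(common, key_b)
  va <- a$variants[ia, , drop = FALSE]
  vb <- b$variants[ib, , drop = FALSE]
  same <- va$allele0 == vb$allele0 & va$allele1 == vb$allele1
  flipped <- va$allele0 == vb$allele1 & va$allele1 == vb$allele0
  keep <- same | flipped
  if (!any(keep)) stop("no shared sites with compatible alleles")
  ia <- ia[keep]; ib <- ib[keep]
  flipped <- flipped[keep]
  va <- a$variants[ia, , drop = FALSE]
  ga <- a$geno[, ia, drop = FALSE]
  gb <- b$geno[, ib, drop = FALSE]
  maxdose <- if (a$ploidy == "diploid") 2L else 1L
  if (any(flipped))
    gb[, flipped] <- maxdose - gb[, flipped, drop = FALSE]
  dup_ind <- b$individuals$id %in% a$individuals$id
  if (any(dup_ind)) {
    warning("dropping ", sum(dup_ind), " duplicated individual id(s) from b")
    gb <- gb[!dup_ind, , drop = FALSE]
  }
  inds <- rbind(a$individuals[, c("id", "population")],
                b$individuals[!dup_ind, c("id", "population")])
  rownames(va) <- NULL; rownames(inds) <- NULL
  out <- gt_panel(rbind(ga, gb), va, inds, a$ploidy)
  pair <- paste(pmin(va$allele0, va$allele1), pmax(va$allele0, va$allele1))
  attr(out, "ambiguous_sites") <- which(pair %in% c("A T", "C G"))
  attr(out, "n_triallelic_dropped") <- sum(!keep)
  out
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window_snps` sites (advanced by `step`),
#' site pairs are visited in position order and the later member of any
#' pair with genotype correlation r^2 greater than `r2_max` is removed.
#' Defaults reproduce the common `--indep-pairwise 200 25 0.4` setting.
#' Correlations use pairwise-complete observations; windows never span
#' chromosomes.
#'
#' @param panel a [gt_panel()].
#' @param window_snps window size in SNPs.
#' @param step window step in SNPs.
#' @param r2_max maximum tolerated pairwise r^2.
#' @return Logical keep mask over sites.
#' @export
ld_prune <- function(panel, window_snps = 200, step = 25, r2_max = 0.4) {
  stopifnot(inherits(panel, "gt_panel"), window_snps >= 2, step >= 1,
            r2_max > 0)
  v <- panel$variants
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    n <- length(idx)
    start <- 1
    repeat {
      win <- idx[start:min(start + window_snps - 1, n)]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        gw <- panel$geno[, win, drop = FALSE]
        r2 <- suppressWarnings(
          stats::cor(gw, use = "pairwise.complete.obs"))^2
        for (i in seq_len(length(win) - 1)) {
          if (!keep[win[i]]) next
          for (j in (i + 1):length(win)) {
            if (!keep[win[j]]) next
            if (!is.na(r2[i, j]) && r2[i, j] > r2_max)
              keep[win[j]] <- FALSE
          }
        }
      }
      if (start + window_snps - 1 >= n) break
      start <- start + step
    }
  }
  keep
}
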