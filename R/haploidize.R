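#' Pseudo-haploidize ancient samples from a read pileup
#'
#' At each covered site one read is drawn uniformly at random and the
#' individual is coded for that read's allele; zero-depth sites are
#' missing. This is the standard random-read genotyping used for
#' low-coverage ancient DNA.
#'
#' @param pileup pileup data.frame (`individual`, `chrom`, `pos`, `count0`,
#'   `count1`), e.g. from [simulate_ancient_pileup()] or
#'   [read_pileup_tsv()].
#' @param variants variant table defining the site set of the output panel;
#'   every pileup site must be present in it.
#' @param seed integer seed; the random draw is deterministic given seed.
#' @return A haploid [gt_panel()] over `variants`' sites, one row per
#'   individual present in `pileup`.
#' @export
pseudo_haploidize_pileup <- function(pileup, variants, seed) {
  validate_variants(variants)
  set.seed(seed)
  site_key <- paste(variants$chrom, variants$pos)
  idx <- match(paste(pileup$chrom, pileup$pos), site_key)
  if (anyNA(idx))
    stop("pileup contains sites absent from the variant table")
  inds <- unique(pileup$individual)
  g <- matrix(NA_integer_, length(inds), nrow(variants))
  depth <- pileup$count0 + pileup$count1
  covered <- depth > 0L
  call <- rep(NA_integer_, nrow(pileup))
  call[covered] <- stats::rbinom(sum(covered), 1L,
                                 pileup$count1[covered] / depth[covered])
  g[cbind(match(pileup$individual, inds), idx)] <- call
  gt_panel(g, variants,
           data.frame(id = inds, population = inds, stringsAsFactors = FALSE),
           "haploid")
}

#' Pseudo-haploidize diploid genotypes
#'
#' One of the two alleles is chosen at random per individual and site:
#' dosage 0 maps to call 0 and dosage 2 to call 1 deterministically;
#' heterozygotes are Bernoulli(0.5); missing stays missing.
#'
#' @param panel diploid [gt_panel()].
#' @param seed integer seed.
#' @return A haploid [gt_panel()] with the same individuals and sites.
#' @export
pseudo_haploidize_diploid <- function(panel, seed) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "diploid")
  set.seed(seed)
  g <- panel$geno
  out <- g
  out[g == 2L] <- 1L
  het <- which(g == 1L)
  out[het] <- stats::rbinom(length(het), 1L, 0.5)
  gt_panel(out, panel$variants, panel$individuals, "haploid")
}

#' Mask transition SNPs
#'
#' Returns `TRUE` for sites whose allele pair is \{A,G\} or \{C,T\} -- the
#' pairs that postmortem cytosine deamination can mimic. Downstream
#' analyses drop or ignore masked sites ("transversions only").
#'
#' @param variants variant table with base alleles.
#' @return Logical vector, `TRUE` = transition site (to be masked).
#' @export
mask_transitions <- function(variants) {
  validate_variants(variants)
  ok <- c("A", "C", "G", "T")
  if (!all(variants$allele0 %in% ok) || !all(variants$allele1 %in% ok))
    stop("transition masking requires single-base alleles")
  pair <- paste(pmin(variants$allele0, variants$allele1),
                pmax(variants$allele0, variants$allele1))
  pair %in% c("A G", "C T")
}

#' Assign ancestral states from an outgroup individual
#'
#' A site's ancestral state is set to the outgroup's allele when the
#' outgroup is homozygous for one of the site's two alleles; sites where
#' the outgroup is heterozygous, carries a third allele, or is unobserved
#' remain unpolarized (and are excluded from polarized analyses).
#'
#' @param variants variant table.
#' @param outgroup_calls data.frame with columns `chrom`, `pos`,
#'   `allele_a`, `allele_b`: the two alleles observed in the outgroup
#'   (equal when homozygous).
#' @return The variant table with `ancestral` filled where determined.
#' @export
polarize_by_outgroup <- function(variants, outgroup_calls) {
  validate_variants(variants)
  stopifnot(all(c("chrom", "pos", "allele_a", "allele_b") %in%
                  names(outgroup_calls)))
  idx <- match(paste(variants$chrom, variants$pos),
               paste(outgroup_calls$chrom, outgroup_calls$pos))
  variants$ancestral <- NA_character_
  have <- which(!is.na(idx))
  if (length(have)) {
    oa <- outgroup_calls$allele_a[idx[have]]
    ob <- outgroup_calls$allele_b[idx[have]]
    homo <- oa == ob
    matches <- oa == variants$allele0[have] | oa == variants$allele1[have]
    setit <- homo & matches
    variants$ancestral[have[setit]] <- oa[setit]
  }
  variants
}
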