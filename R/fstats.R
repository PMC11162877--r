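#' Per-site per-group allele frequencies and observation counts
#'
#' The allele-1 frequency among non-missing calls and the number of allele
#' observations (2 x called individuals for diploid panels, 1 x for
#' pseudo-haploid panels), per site and population group.
#'
#' @param panel a [gt_panel()].
#' @param groups grouping vector over individuals (default: the panel's
#'   population tags).
#' @return list with matrices `freq` and `n_obs` (sites x groups); `freq`
#'   is `NA` where a group has no observations.
#' @export
group_allele_freqs <- function(panel, groups = NULL) {
  stopifnot(inherits(panel, "gt_panel"))
  if (is.null(groups)) groups <- panel$individuals$population
  stopifnot(length(groups) == nrow(panel$geno))
  ploidy <- if (panel$ploidy == "diploid") 2L else 1L
  glev <- unique(groups)
  n_sites <- ncol(panel$geno)
  freq <- matrix(NA_real_, n_sites, length(glev),
                 dimnames = list(NULL, glev))
  n_obs <- matrix(0L, n_sites, length(glev), dimnames = list(NULL, glev))
  for (g in glev) {
    rows <- panel$geno[groups == g, , drop = FALSE]
    called <- unname(colSums(!is.na(rows)))
    n_obs[, g] <- as.integer(ploidy * called)
    f <- unname(colSums(rows, na.rm = TRUE)) / (ploidy * pmax(called, 1L))
    f[called == 0L] <- NA_real_
    freq[, g] <- f
  }
  storage.mode(n_obs) <- "integer"
  list(freq = freq, n_obs = n_obs)
}

#' Assign sites to contiguous physical blocks
#'
#' Contiguous blocks of `block_size_bp` per chromosome (the last block on a
#' chromosome may be shorter); every site gets exactly one block. Blocks
#' are the resampling unit of the weighted block jackknife.
#'
#' @param variants variant table, sorted by chromosome then position.
#' @param block_size_bp physical block length (default 5 Mb).
#' @return integer vector of block indices (1-based, consecutive), with the
#'   block table (`chrom`, `start`, `end`) as attribute `blocks`.
#' @export
make_blocks <- function(variants, block_size_bp = 5e6) {
  validate_variants(variants)
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (!identical(ord, seq_len(nrow(variants))))
    stop("variants must be sorted by chromosome and position")
  within <- (variants$pos - 1) %/% block_size_bp
  key <- paste(variants$chrom, within)
  idx <- match(key, unique(key))
  ublocks <- !duplicated(key)
  attr(idx, "blocks") <- data.frame(
    chrom = variants$chrom[ublocks],
    start = within[ublocks] * block_size_bp + 1,
    end = (within[ublocks] + 1) * block_size_bp)
  idx
}

#' Weighted block-jackknife value and standard error
#'
#' For a ratio-of-sums statistic theta = sum(num) / sum(wt) over blocks,
#' computes the leave-one-block-out estimates from the running totals and
#' the weighted delete-m_j jackknife standard error with block weights
#' proportional to their SNP (weight) content. With equal block weights
#' this reduces exactly to the classical unweighted delete-one jackknife.
#'
#' @param num per-block numerator sums.
#' @param wt per-block weights (e.g. per-block SNP counts), positive.
#' @return list with `value`, `se`, `loo` (leave-one-out estimates) and
#'   `n_blocks`. `se` is `NA` with a warning when fewer than 2 blocks have
#'   positive weight.
#' @export
weighted_block_jackknife <- function(num, wt) {
  stopifnot(length(num) == length(wt), all(wt >= 0))
  use <- wt > 0
  num <- num[use]; wt <- wt[use]
  g <- length(wt)
  n <- sum(wt)
  theta <- sum(num) / n
  if (g < 2) {
    warning("fewer than 2 non-empty blocks: SE undefined")
    return(list(value = theta, se = NA_real_, loo = rep(theta, g),
                n_blocks = g))
  }
  loo <- (sum(num) - num) / (n - wt)
  jackknife_se_from_loo(theta, loo, wt)
}

# Weighted delete-m_j jackknife (Busing, Meijer & van der Leeden 1999)
# from an overall estimate, leave-one-block-out estimates and block
# weights. Shared by every jackknifed statistic in the package.
jackknife_se_from_loo <- function(theta, loo, wt) {
  g <- length(loo)
  n <- sum(wt)
  h <- n / wt
  theta_j <- g * theta - sum((1 - wt / n) * loo)
  pseudo <- h * theta - (h - 1) * loo
  var_j <- sum((pseudo - theta_j)^2 / (h - 1)) / g
  list(value = theta, se = sqrt(var_j), loo = loo, n_blocks = g)
}

new_jackknifed_estimate <- function(value, se, n_snps, n_blocks,
                                    statistic, label = NULL) {
  z <- if (!is.na(se) && se > 0) value / se else NA_real_
  structure(list(statistic = statistic, label = label, value = value,
                 se = se, z = z, n_snps = n_snps, n_blocks = n_blocks),
            class = "jackknifed_estimate")
}

#' @export
print.jackknifed_estimate <- function(x, ...) {
  cat(sprintf("%s%s: %.6g  (SE %.3g, Z %.2f, %d SNPs, %d blocks)\n",
              x$statistic,
              if (!is.null(x$label)) paste0("[", x$label, "]") else "",
              x$value, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' @export
as.data.frame.jackknifed_estimate <- function(x, ...) {
  data.frame(statistic = x$statistic,
             label = if (is.null(x$label)) NA_character_ else x$label,
             value = x$value, se = x$se, z = x$z,
             n_snps = x$n_snps, n_blocks = x$n_blocks,
             stringsAsFactors = FALSE)
}

#' Outgroup f3 shared-drift statistic
#'
#' f3(O; A, B) = mean over sites of (o - a)(o - b), where o, a, b are the
#' allele frequencies of the outgroup and the two test groups. It measures
#' the shared genetic drift of A and B since their divergence from the
#' outgroup and is symmetric in (A, B). Only sites with at least one
#' observation in all three groups are used; the standard error comes from
#' the weighted block jackknife.
#'
#' @param gf output of [group_allele_freqs()] (list with `freq`, `n_obs`).
#' @param outgroup,a,b group names.
#' @param blocks per-site block assignment from [make_blocks()].
#' @param bias_correct subtract the finite-sample heterozygosity correction
#'   h_o / n_o at each site (default `FALSE`: the uncorrected estimator
#'   generally used for shared-drift ranking).
#' @return A `jackknifed_estimate`.
#' @export
f3_outgroup <- function(gf, outgroup, a, b, blocks, bias_correct = FALSE) {
  stopifnot(all(c(outgroup, a, b) %in% colnames(gf$freq)),
            length(blocks) == nrow(gf$freq))
  o <- gf$freq[, outgroup]; fa <- gf$freq[, a]; fb <- gf$freq[, b]
  no <- gf$n_obs[, outgroup]
  use <- no >= 1 & gf$n_obs[, a] >= 1 & gf$n_obs[, b] >= 1 &
    !is.na(o) & !is.na(fa) & !is.na(fb)
  term <- (o - fa) * (o - fb)
  if (bias_correct) {
    corr <- o * (1 - o) / pmax(no - 1, 1)
    corr[no < 2] <- 0
    term <- term - corr
  }
  term <- term[use]
  bl <- blocks[use]
  num <- tapply_sum(term, bl)
  wt <- tapply_sum(rep(1, length(bl)), bl)
  jk <- weighted_block_jackknife(num, wt)
  new_jackknifed_estimate(jk$value, jk$se, n_snps = sum(use),
                          n_blocks = jk$n_blocks, statistic = "f3",
                          label = sprintf("%s;%s,%s", outgroup, a, b))
}

# sum of x within integer groups, dense over observed groups
tapply_sum <- function(x, grp) {
  u <- sort(unique(grp))
  as.numeric(rowsum(x, factor(grp, levels = u)))
}
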