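#' Pairwise-mismatch (conditional nucleotide) diversity of a group
#'
#' For each pair of individuals in the group, the mismatch rate is the
#' fraction of jointly non-missing sites at which their single-allele calls
#' differ; the group value is the mean over pairs. On pseudo-haploid data
#' at sites ascertained as polymorphic this estimates conditional
#' nucleotide diversity, a heterozygosity proxy robust to low coverage.
#' Diploid panels are pseudo-haploidized first (one random allele per
#' individual and site). Restricting to transversions removes the
#' inflation caused by postmortem deamination damage. Standard errors come
#' from the weighted block jackknife over sites.
#'
#' @param panel a [gt_panel()] (haploid, or diploid -- then haploidized
#'   with `seed`).
#' @param group population name; needs >= 2 members.
#' @param blocks per-site block assignment from [make_blocks()].
#' @param transversions_only drop transition (A/G, C/T) sites first.
#' @param site_mask optional logical vector of sites to use (e.g. a
#'   polymorphism-ascertainment mask); combined with the transversion
#'   filter.
#' @param pair_policy `"all"` (every within-group pair) or `"random"`
#'   (`n_pairs` pairs sampled without replacement).
#' @param n_pairs number of pairs when `pair_policy = "random"`.
#' @param seed integer seed (pair sampling and haploidization).
#' @return A `jackknifed_estimate`.
#' @export
pairwise_mismatch <- function(panel, group, blocks,
                              transversions_only = FALSE, site_mask = NULL,
                              pair_policy = c("all", "random"),
                              n_pairs = NULL, seed = 1) {
  pair_policy <- match.arg(pair_policy)
  stopifnot(inherits(panel, "gt_panel"))
  set.seed(seed)
  if (panel$ploidy == "diploid")
    panel <- pseudo_haploidize_diploid(panel, seed = seed)
  use_site <- rep(TRUE, ncol(panel$geno))
  if (transversions_only) use_site <- use_site & !mask_transitions(panel$variants)
  if (!is.null(site_mask)) use_site <- use_site & site_mask
  members <- which(panel$individuals$population == group)
  if (length(members) < 2) stop("group must have at least 2 individuals")
  calls <- panel$geno[members, use_site, drop = FALSE]
  bl <- blocks[use_site]
  pairs <- utils::combn(length(members), 2)
  if (pair_policy == "random") {
    if (is.null(n_pairs)) n_pairs <- min(ncol(pairs), length(members))
    pairs <- pairs[, sample.int(ncol(pairs), min(n_pairs, ncol(pairs))),
                   drop = FALSE]
  }
  ub <- sort(unique(bl))
  blf <- factor(bl, levels = ub)
  n_pr <- ncol(pairs)
  diffs <- matrix(0, n_pr, length(ub))
  joint <- matrix(0, n_pr, length(ub))
  for (p in seq_len(n_pr)) {
    x <- calls[pairs[1, p], ]; y <- calls[pairs[2, p], ]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) stop("no jointly called sites for a pair in group ", group)
    diffs[p, ] <- as.numeric(rowsum((x != y & ok) + 0, blf))
    joint[p, ] <- as.numeric(rowsum(ok + 0, blf))
  }
  D <- rowSums(diffs); N <- rowSums(joint)
  theta <- mean(D / N)
  # leave-one-block-out group mean, blocks weighted by total joint calls
  loo <- vapply(seq_along(ub), function(j) {
    mean((D - diffs[, j]) / (N - joint[, j]))
  }, numeric(1))
  wt <- colSums(joint)
  if (length(ub) < 2) {
    warning("fewer than 2 blocks: SE undefined")
    se <- NA_real_
  } else {
    se <- jackknife_se_from_loo(theta, loo, wt)$se
  }
  new_jackknifed_estimate(theta, se, n_snps = sum(use_site),
                          n_blocks = length(ub),
                          statistic = "pairwise_mismatch", label = group)
}
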