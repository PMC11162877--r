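#' Specify a population tree for frequency simulation
#'
#' The tree drives a Balding-Nichols drift model: each branch transforms the
#' parent allele frequency p into a child frequency drawn from a Beta
#' distribution with mean p and variance F p(1-p), where F in [0, 1) is the
#' per-branch drift. Admixture edges mix node frequencies linearly after the
#' tree traversal. Exactly one leaf is designated the outgroup; by default
#' only sites still polymorphic in the outgroup are retained
#' (outgroup-ascertained SNP panel).
#'
#' @param edges data.frame with columns `parent`, `child`, `f` (drift per
#'   branch, in `[0, 1)`). Leaves are children that are never parents; the
#'   root is the unique parent that is never a child.
#' @param outgroup name of the outgroup leaf.
#' @param admixture optional data.frame with columns `source`, `target`,
#'   `alpha`: after drift, `target` frequencies become
#'   `alpha * source + (1 - alpha) * target`, with `alpha` in (0, 1]. The
#'   target must not be an ancestor of the source.
#' @param root_freq lower/upper bound of the uniform ancestral allele
#'   frequency distribution (default `c(0.05, 0.95)`).
#' @return An object of class `pop_tree`.
#' @export
population_tree <- function(edges, outgroup, admixture = NULL,
                            root_freq = c(0.05, 0.95)) {
  stopifnot(is.data.frame(edges), all(c("parent", "child", "f") %in% names(edges)),
            nrow(edges) >= 1)
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(edges$f < 0 | edges$f >= 1))
    stop("branch drift F must be in [0, 1)")
  if (anyDuplicated(edges$child)) stop("each node may have only one parent")
  roots <- setdiff(edges$parent, edges$child)
  if (length(unique(roots)) != 1) stop("tree must have exactly one root")
  leaves <- setdiff(edges$child, edges$parent)
  if (!outgroup %in% leaves) stop("outgroup must be a leaf of the tree")
  if (!is.null(admixture)) {
    stopifnot(all(c("source", "target", "alpha") %in% names(admixture)))
    if (any(admixture$alpha <= 0 | admixture$alpha > 1))
      stop("admixture proportions must be in (0, 1]")
    nodes <- union(edges$parent, edges$child)
    if (!all(admixture$source %in% nodes) || !all(admixture$target %in% nodes))
      stop("admixture edges must connect tree nodes")
    for (i in seq_len(nrow(admixture))) {
      anc <- tree_ancestors(edges, admixture$source[i])
      if (admixture$target[i] %in% anc)
        stop("admixture target must not be an ancestor of its source")
    }
  }
  stopifnot(length(root_freq) == 2, root_freq[1] > 0, root_freq[2] < 1,
            root_freq[1] <= root_freq[2])
  structure(list(edges = edges, root = roots, leaves = leaves,
                 outgroup = outgroup, admixture = admixture,
                 root_freq = root_freq),
            class = "pop_tree")
}

tree_ancestors <- function(edges, node) {
  anc <- character(0)
  repeat {
    p <- edges$parent[match(node, edges$child)]
    if (is.na(p)) break
    anc <- c(anc, p); node <- p
  }
  anc
}

# One Balding-Nichols drift step: child ~ Beta with mean p, var F p(1-p).
# Frequencies already fixed at 0/1 stay fixed; draws within machine
# tolerance of the boundary are clamped to exact 0/1.
drift_step <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  if (any(inner)) {
    nu <- (1 - f) / f
    out[inner] <- stats::rbeta(sum(inner), p[inner] * nu, (1 - p[inner]) * nu)
  }
  out[out < 1e-12] <- 0
  out[out > 1 - 1e-12] <- 1
  out
}

#' Simulate population allele frequencies along a drift tree
#'
#' Draws ancestral frequencies at the root, applies Balding-Nichols drift
#' down every branch, applies admixture edges, and (by default) retains only
#' sites that remain polymorphic in the outgroup -- mimicking an
#' outgroup-ascertained SNP panel.
#'
#' @param tree a [population_tree()].
#' @param n_snps number of sites to draw before ascertainment.
#' @param seed integer seed; output is deterministic given seed and tree.
#' @param ascertain retain only sites with outgroup frequency strictly
#'   inside (0, 1) (default `TRUE`).
#' @return Numeric matrix, retained sites x leaf populations, with the
#'   number of pre-ascertainment draws in attribute `n_drawn`.
#' @export
simulate_frequencies <- function(tree, n_snps, seed, ascertain = TRUE) {
  stopifnot(inherits(tree, "pop_tree"), n_snps >= 1)
  set.seed(seed)
  freqs <- list()
  freqs[[tree$root]] <- stats::runif(n_snps, tree$root_freq[1], tree$root_freq[2])
  todo <- tree$edges
  while (nrow(todo) > 0) {
    ready <- todo$parent %in% names(freqs)
    if (!any(ready)) stop("tree edges do not form a rooted tree")
    for (i in which(ready))
      freqs[[todo$child[i]]] <- drift_step(freqs[[todo$parent[i]]], todo$f[i])
    todo <- todo[!ready, , drop = FALSE]
  }
  if (!is.null(tree$admixture)) {
    for (i in seq_len(nrow(tree$admixture))) {
      s <- tree$admixture$source[i]; t <- tree$admixture$target[i]
      a <- tree$admixture$alpha[i]
      freqs[[t]] <- a * freqs[[s]] + (1 - a) * freqs[[t]]
    }
  }
  m <- do.call(cbind, freqs[tree$leaves])
  colnames(m) <- tree$leaves
  if (ascertain) {
    keep <- m[, tree$outgroup] > 0 & m[, tree$outgroup] < 1
    m <- m[keep, , drop = FALSE]
  }
  attr(m, "n_drawn") <- n_snps
  m
}

#' Default chromosome lengths for simulated panels
#'
#' Twenty-six autosomes with lengths declining from 280 Mb to 45 Mb plus a
#' 135 Mb X chromosome, loosely shaped like the sheep karyotype.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
default_chrom_lengths <- function() {
  auto <- round(seq(280e6, 45e6, length.out = 26))
  stats::setNames(c(auto, 135e6), c(as.character(1:26), "X"))
}

# Random variant metadata: sites spread over chromosomes proportionally to
# length, unique sorted positions, allele pairs drawn uniformly from the 6
# unordered base pairs (4 transversion pairs, 2 transition pairs).
random_variants <- function(n_snps, chrom_lengths) {
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  assign <- sample(chroms, n_snps, replace = TRUE, prob = pr)
  chrom <- character(n_snps); pos <- integer(n_snps)
  k <- 0
  for (ch in chroms) {
    n_ch <- sum(assign == ch)
    if (n_ch == 0) next
    p <- sort(sample.int(as.integer(chrom_lengths[[ch]]), n_ch))
    chrom[(k + 1):(k + n_ch)] <- ch
    pos[(k + 1):(k + n_ch)] <- p
    k <- k + n_ch
  }
  pairs <- rbind(c("A", "C"), c("A", "G"), c("A", "T"),
                 c("C", "G"), c("C", "T"), c("G", "T"))
  pick <- pairs[sample.int(6, n_snps, replace = TRUE), , drop = FALSE]
  swap <- stats::runif(n_snps) < 0.5
  a0 <- ifelse(swap, pick[, 2], pick[, 1])
  a1 <- ifelse(swap, pick[, 1], pick[, 2])
  variant_table(chrom, pos, a0, a1)
}

#' Sample diploid individuals from population frequencies
#'
#' Genotypes are Binomial(2, p) derived-allele dosages: Hardy-Weinberg
#' equilibrium within each population by construction. Variant metadata
#' (positions along configurable chromosomes, random allele pairs) is drawn
#' alongside so the panel can feed transversion masking and block-jackknife
#' machinery.
#'
#' @param freqs site x population frequency matrix (allele-1 frequency),
#'   e.g. from [simulate_frequencies()].
#' @param n_per_pop named integer vector: individuals per population; names
#'   must be columns of `freqs`.
#' @param seed integer seed.
#' @param chrom_lengths named chromosome-length vector used for variant
#'   positions (default [default_chrom_lengths()]).
#' @return A diploid [gt_panel()].
#' @export
sample_diploids <- function(freqs, n_per_pop, seed,
                            chrom_lengths = default_chrom_lengths()) {
  stopifnot(is.matrix(freqs), !is.null(names(n_per_pop)),
            all(names(n_per_pop) %in% colnames(freqs)),
            all(freqs >= 0 & freqs <= 1))
  set.seed(seed)
  n_snps <- nrow(freqs)
  variants <- random_variants(n_snps, chrom_lengths)
  pops <- rep(names(n_per_pop), times = n_per_pop)
  ids <- unlist(lapply(names(n_per_pop), function(p)
    sprintf("%s_%03d", p, seq_len(n_per_pop[[p]]))), use.names = FALSE)
  g <- matrix(NA_integer_, nrow = length(pops), ncol = n_snps)
  for (i in seq_along(pops))
    g[i, ] <- stats::rbinom(n_snps, 2L, freqs[, pops[i]])
  gt_panel(g, variants,
           data.frame(id = ids, population = pops, stringsAsFactors = FALSE),
           "diploid")
}
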