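#' Fit a PCA model on a modern genotype panel
#'
#' Dosages are centered by the per-site mean and scaled by
#' sqrt(p(1-p)) with p the dosage-based allele frequency (the usual
#' genotype standardization); missing dosages are mean-imputed at fit time.
#' Components come from the singular value decomposition of the
#' standardized matrix; each component's sign is fixed so its
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param panel diploid [gt_panel()], ideally filtered and LD-pruned; sites
#'   with no called individuals or zero variance are rejected.
#' @param k number of components, at most the matrix rank.
#' @return A `pca_model`: site `means` and `scales`, `loadings` (sites x
#'   k, orthonormal columns), `eigenvalues` (non-increasing),
#'   `pct_variance`, fit-time `scores` (individuals x k) and the
#'   individual table.
#' @export
fit_pca <- function(panel, k = 10) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "diploid", k >= 1)
  X <- panel$geno
  n <- nrow(X); m <- ncol(X)
  called <- colSums(!is.na(X))
  if (any(called == 0)) stop("all-missing sites present: filter first")
  mu <- colSums(X, na.rm = TRUE) / called
  p <- mu / 2
  sc <- sqrt(p * (1 - p))
  if (any(sc == 0)) stop("monomorphic sites present: filter first")
  Z <- sweep(X, 2, mu, "-")
  Z[is.na(Z)] <- 0  # mean imputation after centering
  Z <- sweep(Z, 2, sc, "/")
  rk <- min(n - 1, m)
  if (k > rk) stop("k exceeds the rank of the panel (", rk, ")")
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  V <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  U <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, "*")
  d <- sv$d[seq_len(k)]
  scores <- sweep(U, 2, d, "*")
  rownames(scores) <- panel$individuals$id
  eig <- sv$d^2 / (n - 1)
  total <- sum(eig)
  structure(list(means = mu, scales = sc, loadings = V,
                 eigenvalues = eig[seq_len(k)],
                 pct_variance = 100 * eig[seq_len(k)] / total,
                 scores = scores, individuals = panel$individuals,
                 variants = panel$variants, shrink_factors = NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d sites, %d components\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat("  pct variance:",
      paste(sprintf("%.2f", x$pct_variance), collapse = " "), "\n")
  invisible(x)
}

#' Least-squares projection of samples onto a fitted PCA
#'
#' Solves the restricted-loading normal equations over each sample's
#' non-missing sites only, the standard way to place low-coverage
#' (pseudo-haploid, heavily missing) samples onto components fitted on a
#' complete modern panel. A complete-data individual from the fit panel
#' projects exactly onto its fit-time scores. With `shrink = TRUE` the
#' scores are rescaled by per-component factors from
#' [estimate_shrinkage()], compensating the shrinkage of out-of-sample
#' projections toward the origin.
#'
#' @param calls haploid calls (0/1/NA) or diploid dosages (0/1/2/NA) over
#'   the model's sites: a vector or an individuals x sites matrix. Haploid
#'   calls are scaled to dosages (0/2).
#' @param model a `pca_model`.
#' @param ploidy `"haploid"` or `"diploid"`, how to read `calls`.
#' @param shrink apply the model's shrinkage factors (requires
#'   [estimate_shrinkage()] to have been run).
#' @return Matrix of projected scores (samples x k).
#' @export
project_lsq <- function(calls, model, ploidy = c("haploid", "diploid"),
                        shrink = FALSE) {
  ploidy <- match.arg(ploidy)
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != nrow(model$loadings))
    stop("calls must cover the model's site set")
  if (ploidy == "haploid") calls <- calls * 2
  k <- ncol(model$loadings)
  out <- matrix(NA_real_, nrow(calls), k)
  for (i in seq_len(nrow(calls))) {
    obs <- which(!is.na(calls[i, ]))
    if (length(obs) == 0) stop("sample ", i, ": all sites missing")
    z <- (calls[i, obs] - model$means[obs]) / model$scales[obs]
    V <- model$loadings[obs, , drop = FALSE]
    out[i, ] <- solve(crossprod(V), crossprod(V, z))
  }
  if (shrink) {
    if (is.null(model$shrink_factors))
      stop("model has no shrinkage factors: run estimate_shrinkage() first")
    out <- sweep(out, 2, model$shrink_factors, "*")
  }
  rownames(out) <- rownames(calls)
  colnames(out) <- paste0("PC", seq_len(k))
  out
}

#' Estimate per-component projection shrinkage factors
#'
#' Out-of-sample projections are shrunk toward the origin relative to
#' fit-time scores. The factor per component is calibrated by
#' leave-one-out refits: each probe individual is removed from the panel,
#' the PCA refit, the individual projected, and components matched to the
#' full-fit model by loading correlation. The factor is the median ratio
#' of full-fit score magnitude to leave-one-out projected magnitude.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param panel the diploid panel the model was fitted on.
#' @param n_probe number of individuals to probe (default 20, capped at
#'   panel size).
#' @param seed integer seed for probe selection.
#' @return The model with `shrink_factors` (length k, each >= 1) filled.
#' @export
estimate_shrinkage <- function(model, panel, n_probe = 20, seed = 1) {
  stopifnot(inherits(model, "pca_model"), inherits(panel, "gt_panel"))
  set.seed(seed)
  n <- nrow(panel$geno)
  k <- ncol(model$loadings)
  probes <- sample.int(n, min(n_probe, n))
  ratios <- matrix(NA_real_, length(probes), k)
  for (pi in seq_along(probes)) {
    i <- probes[pi]
    sub <- subset_panel(panel, inds = setdiff(seq_len(n), i))
    fit_i <- tryCatch(fit_pca(sub, k), error = function(e) NULL)
    if (is.null(fit_i)) next
    # match leave-one-out components to full-fit components by loadings
    cc <- crossprod(model$loadings, fit_i$loadings)
    proj <- project_lsq(panel$geno[i, ], fit_i, ploidy = "diploid")
    for (j in seq_len(k)) {
      jj <- which.max(abs(cc[j, ]))
      pr <- proj[1, jj] * sign(cc[j, jj])
      if (abs(pr) > 1e-9)
        ratios[pi, j] <- model$scores[i, j] / pr
    }
  }
  fac <- apply(ratios, 2, stats::median, na.rm = TRUE)
  fac[!is.finite(fac) | fac < 1] <- 1
  model$shrink_factors <- fac
  model
}
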