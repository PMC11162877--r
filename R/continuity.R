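#' @title Drift likelihood-ratio test of population continuity
#' @description Internal machinery plus user-facing fitting functions for
#' testing whether an ancient sample set can lie directly on the ancestral
#' lineage of a later (modern) population. Per site the data are derived
#' allele counts: `d` of `n` sampled modern chromosomes and `a` of `m`
#' pseudo-haploid ancient chromosomes. The latent ancestral frequency at
#' the split is uniform a priori; the modern population drifts from it for
#' a variance-scaled time `t1` and the ancient one for `t2`. Under
#' continuity the ancient samples sit on the modern lineage itself, i.e.
#' `t2 = 0`.
#'
#' The drift transition is the mean/variance-matched Balding-Nichols Beta
#' (mean p, variance p(1-p)(1 - e^-t)); its boundary mass supplies the
#' fixation classes. Both binomial sampling layers integrate against the
#' Beta in closed form (beta-binomial), leaving only the ancestral
#' frequency to Gauss-Legendre quadrature. The likelihood conditions on
#' the modern counts, so modern-panel ascertainment (polymorphism filters
#' on `d`) does not bias the test.
#' @name continuity
NULL

# P(k | size, x, t) for k = 0..size at each latent frequency x:
# beta-binomial under Balding-Nichols drift; binomial in the t -> 0 limit.
# Returns a (size+1) x length(x) matrix.
drift_sampling_matrix <- function(size, x, t) {
  k <- 0:size
  if (t < 1e-9)
    return(outer(k, x, function(kk, xx) stats::dbinom(kk, size, xx)))
  nu <- exp(-t) / (1 - exp(-t))
  alpha <- x * nu
  beta <- (1 - x) * nu
  lc <- lchoose(size, k)
  A <- outer(k, alpha, "+")          # k + alpha
  B <- outer(size - k, beta, "+")    # size - k + beta
  lp <- lc + lbeta(A, B) - rep(lbeta(alpha, beta), each = size + 1)
  matrix(exp(lp), nrow = size + 1)
}

gl_nodes <- function(order) {
  q <- pracma::gaussLegendre(order, 0, 1)
  list(x = q$x, w = q$w)
}

# Joint and marginal log-likelihood pieces for one (n, m) configuration:
# returns list(joint = log P(d, a) matrix (n+1) x (m+1),
#              marg = log P(d) vector (n+1)) under uniform prior on x.
continuity_tables <- function(n, m, t1, t2, quad) {
  Pd <- drift_sampling_matrix(n, quad$x, t1)
  Pa <- drift_sampling_matrix(m, quad$x, t2)
  joint <- Pd %*% (quad$w * t(Pa))
  marg <- as.numeric(Pd %*% quad$w)
  list(joint = log(pmax(joint, 1e-300)), marg = log(pmax(marg, 1e-300)))
}

#' Per-site log-likelihood of the two-branch drift model
#'
#' log P(a | m, d, n, t1, t2): the probability of the ancient derived
#' count conditional on the modern count, marginalizing the latent
#' ancestral and population frequencies under Balding-Nichols drift. At
#' `t1 = t2 = 0` this reduces to the pooled (hypergeometric-style)
#' posterior-predictive sampling probability of `a` given `d`.
#'
#' @param t1,t2 drift times (>= 0) of the modern and ancient branch.
#' @param site data.frame (or list) with fields `a`, `m`, `d`, `n`;
#'   vectorized over rows.
#' @param quad_order Gauss-Legendre order for the ancestral-frequency
#'   integral (default 64).
#' @return Numeric vector of per-site log-likelihoods (finite for all
#'   valid inputs).
#' @export
site_loglik <- function(t1, t2, site, quad_order = 64) {
  if (t1 < 0 || t2 < 0) stop("drift times must be non-negative")
  quad <- gl_nodes(quad_order)
  out <- numeric(length(site$a))
  for (cfg in unique(paste(site$n, site$m))) {
    rows <- which(paste(site$n, site$m) == cfg)
    n <- site$n[rows[1]]; m <- site$m[rows[1]]
    tb <- continuity_tables(n, m, t1, t2, quad)
    out[rows] <- tb$joint[cbind(site$d[rows] + 1L, site$a[rows] + 1L)] -
      tb$marg[site$d[rows] + 1L]
  }
  out
}

# pattern-compressed negative log-likelihood over a dataset
continuity_negll <- function(t1, t2, patterns, quad) {
  ll <- 0
  for (p in patterns) {
    tb <- continuity_tables(p$n, p$m, t1, t2, quad)
    ll <- ll + sum(p$count *
                     (tb$joint[cbind(p$d + 1L, p$a + 1L)] - tb$marg[p$d + 1L]))
  }
  -ll
}

compress_patterns <- function(data) {
  lapply(split(seq_len(nrow(data)), paste(data$n, data$m)), function(rows) {
    tab <- stats::aggregate(list(count = rows),
                            by = list(d = data$d[rows], a = data$a[rows]),
                            FUN = length)
    list(n = data$n[rows[1]], m = data$m[rows[1]],
         d = tab$d, a = tab$a, count = tab$count)
  })
}

#' Fit the continuity and independent-drift models and test continuity
#'
#' Maximizes the summed site log-likelihoods under two nested models: the
#' null of direct continuity (`t2 = 0`, only the modern branch drifts) and
#' the alternative of independent populations (`t1, t2` free). Reports the
#' likelihood-ratio statistic `2 (loglik_alt - loglik_null)` and a p-value
#' from the boundary mixture 0.5 chi2_0 + 0.5 chi2_1, appropriate because
#' the null pins `t2` to the edge of its parameter space.
#'
#' @param data continuity input: data.frame with per-site columns `a`,
#'   `m` (ancient derived/total chromosomes) and `d`, `n` (modern), e.g.
#'   from [build_continuity_input()].
#' @param quad_order Gauss-Legendre order (default 64).
#' @param t_max upper optimization bound on both drift times (default 10).
#' @return An object of class `continuity_fit`: `null` and `alt` fits
#'   (`t1`, `t2`, `loglik`, `converged`), `lrt`, `p`, `n_sites`.
#' @export
fit_continuity <- function(data, quad_order = 64, t_max = 10) {
  stopifnot(all(c("a", "m", "d", "n") %in% names(data)))
  stopifnot(all(data$a >= 0 & data$a <= data$m),
            all(data$d >= 0 & data$d <= data$n))
  if (nrow(data) < 100)
    warning("fewer than 100 informative sites: the test will be weak")
  quad <- gl_nodes(quad_order)
  patterns <- compress_patterns(data)
  null_opt <- stats::optim(
    par = 0.1,
    fn = function(t1) continuity_negll(t1, 0, patterns, quad),
    method = "Brent", lower = 0, upper = t_max,
    control = list(reltol = 1e-10))
  starts <- list(c(0.02, 0.02), c(0.1, 0.1), c(0.5, 0.5))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(
      par = s,
      fn = function(p) continuity_negll(p[1], p[2], patterns, quad),
      method = "L-BFGS-B", lower = c(0, 0), upper = c(t_max, t_max),
      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ll_null <- -null_opt$value
  ll_alt <- -best$value
  lrt <- max(0, 2 * (ll_alt - ll_null))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE) +
    if (lrt <= 0) 0.5 else 0
  structure(list(
    null = list(t1 = null_opt$par, t2 = 0, loglik = ll_null,
                converged = null_opt$convergence == 0),
    alt = list(t1 = best$par[1], t2 = best$par[2], loglik = ll_alt,
               converged = best$convergence == 0),
    lrt = lrt, p = p, n_sites = nrow(data)), class = "continuity_fit")
}

#' @export
print.continuity_fit <- function(x, ...) {
  cat("Population-continuity likelihood-ratio test\n")
  cat(sprintf("  null (continuity):   t1 = %.4f, t2 = 0,    loglik = %.2f\n",
              x$null$t1, x$null$loglik))
  cat(sprintf("  alt  (independent):  t1 = %.4f, t2 = %.4f, loglik = %.2f\n",
              x$alt$t1, x$alt$t2, x$alt$loglik))
  cat(sprintf("  LRT = %.3f, p = %.4g (0.5*chi2_0 + 0.5*chi2_1), %d sites\n",
              x$lrt, x$p, x$n_sites))
  invisible(x)
}

#' Build continuity-test input from genotype panels
#'
#' Orients per-site counts to the derived allele using the variant table's
#' ancestral states (e.g. from [polarize_by_outgroup()]); unpolarized
#' sites are dropped. Optional coverage-style filters restrict the number
#' of called ancient chromosomes per site.
#'
#' @param modern diploid [gt_panel()].
#' @param ancient haploid [gt_panel()] (pseudo-haploid calls) over the same
#'   variant coordinates.
#' @param variants polarized variant table governing both panels.
#' @param min_m,max_m per-site bounds on called ancient chromosomes
#'   (defaults 1 and Inf).
#' @param min_n per-site minimum modern chromosomes (default 2).
#' @param polymorphic_modern keep only sites polymorphic in the modern
#'   panel (`1 <= d <= n-1`); the default, matching the usual
#'   known-polymorphic ascertainment. Harmless for the test, which
#'   conditions on the modern counts.
#' @return data.frame with columns `a`, `m`, `d`, `n`, one row per site.
#' @export
build_continuity_input <- function(modern, ancient, variants,
                                   min_m = 1, max_m = Inf, min_n = 2,
                                   polymorphic_modern = TRUE) {
  stopifnot(inherits(modern, "gt_panel"), modern$ploidy == "diploid",
            inherits(ancient, "gt_panel"), ancient$ploidy == "haploid")
  validate_variants(variants)
  key <- paste(variants$chrom, variants$pos)
  im <- match(key, paste(modern$variants$chrom, modern$variants$pos))
  ia <- match(key, paste(ancient$variants$chrom, ancient$variants$pos))
  use <- !is.na(im) & !is.na(ia) & !is.na(variants$ancestral)
  if (!any(use)) stop("no polarized sites shared by both panels")
  im <- im[use]; ia <- ia[use]
  derived_is_1 <- variants$ancestral[use] == variants$allele0[use]
  gm <- modern$geno[, im, drop = FALSE]
  ga <- ancient$geno[, ia, drop = FALSE]
  n <- 2L * colSums(!is.na(gm))
  d <- colSums(gm, na.rm = TRUE)
  d[!derived_is_1] <- n[!derived_is_1] - d[!derived_is_1]
  m <- colSums(!is.na(ga))
  a <- colSums(ga, na.rm = TRUE)
  a[!derived_is_1] <- m[!derived_is_1] - a[!derived_is_1]
  out <- data.frame(a = as.integer(a), m = as.integer(m),
                    d = as.integer(d), n = as.integer(n))
  keep <- out$m >= min_m & out$m <= max_m & out$n >= min_n
  if (polymorphic_modern) keep <- keep & out$d >= 1 & out$d <= out$n - 1
  out[keep, , drop = FALSE]
}

#' Simulate derived-allele counts under the two-branch drift model
#'
#' Ground-truth generator for calibration and power studies of
#' [fit_continuity()]: ancestral frequencies are uniform, each branch
#' applies one Balding-Nichols drift step with `1 - e^-t` in the role of
#' F, and binomial sampling yields the counts. Sites fixed or lost in the
#' modern sample are dropped (polymorphism ascertainment), matching the
#' conditional likelihood.
#'
#' @param n_sites sites to retain after ascertainment.
#' @param n,m modern / ancient chromosomes sampled per site.
#' @param t1,t2 true drift times.
#' @param seed integer seed.
#' @return data.frame with columns `a`, `m`, `d`, `n`.
#' @export
simulate_drift_counts <- function(n_sites, n, m, t1, t2, seed) {
  set.seed(seed)
  out <- list(); got <- 0
  while (got < n_sites) {
    nb <- ceiling((n_sites - got) * 1.6) + 100
    x <- stats::runif(nb)
    z <- drift_step(x, 1 - exp(-t1))
    y <- if (t2 == 0) x else drift_step(x, 1 - exp(-t2))
    d <- stats::rbinom(nb, n, z)
    a <- stats::rbinom(nb, m, y)
    keep <- d >= 1 & d <= n - 1
    out[[length(out) + 1]] <- data.frame(a = a[keep], m = m,
                                         d = d[keep], n = n)
    got <- got + sum(keep)
  }
  out <- do.call(rbind, out)
  out[seq_len(n_sites), , drop = FALSE]
}
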