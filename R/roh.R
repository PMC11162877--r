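#' Parameters for window-based ROH calling
#'
#' Defaults reproduce the plink run of record for ancient-sample ROH:
#' `--homozyg-snp 100 --homozyg-kb 500 --homozyg-density 50 --homozyg-gap
#' 1000 --homozyg-window-snp 100 --homozyg-window-het 1
#' --homozyg-window-missing 10 --homozyg-window-threshold 0.02`.
#'
#' @param min_snps_in_segment minimum SNPs per reported segment.
#' @param min_length_kb minimum segment length in kb.
#' @param min_density_kb_per_snp maximum kb per SNP within a segment (a
#'   density requirement: length_kb / n_snps must not exceed it).
#' @param max_gap_kb split a candidate run when adjacent SNPs are farther
#'   apart than this.
#' @param window_snps sliding-window size in SNPs.
#' @param window_max_het maximum heterozygous calls per passing window.
#' @param window_max_missing maximum missing calls per passing window.
#' @param window_hit_threshold minimum fraction of passing windows covering
#'   a SNP for it to be a segment candidate.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(min_snps_in_segment = 100, min_length_kb = 500,
                       min_density_kb_per_snp = 50, max_gap_kb = 1000,
                       window_snps = 100, window_max_het = 1,
                       window_max_missing = 10,
                       window_hit_threshold = 0.02) {
  stopifnot(min_snps_in_segment > 0, min_length_kb > 0,
            min_density_kb_per_snp > 0, max_gap_kb > 0, window_snps > 0,
            window_max_het >= 0, window_max_missing >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1)
  structure(as.list(environment()), class = "roh_params")
}

# rolling sum of x over windows of width w (length(x) - w + 1 values)
roll_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Call runs of homozygosity for one individual
#'
#' Sliding windows of `window_snps` consecutive SNPs pass when they contain
#' at most `window_max_het` heterozygous and `window_max_missing` missing
#' calls. Each SNP's hit fraction is the share of passing windows among the
#' windows covering it (edge SNPs are covered by fewer windows and use the
#' reduced denominator; windows are only formed where `window_snps`
#' consecutive SNPs exist). SNPs at or above `window_hit_threshold` are
#' candidates; maximal candidate runs -- trimmed to homozygous end points
#' and split at gaps over `max_gap_kb` -- become segments when they meet
#' the SNP-count, length and density requirements.
#'
#' @param panel diploid [gt_panel()] with variants sorted by chromosome
#'   and position.
#' @param individual individual id.
#' @param params an [roh_params()].
#' @return data.frame of segments: `individual`, `chrom`, `start`, `end`,
#'   `n_snps`, `kb_length`.
#' @export
call_roh <- function(panel, individual, params = roh_params()) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "diploid",
            inherits(params, "roh_params"))
  row <- match(individual, panel$individuals$id)
  if (is.na(row)) stop("unknown individual: ", individual)
  v <- panel$variants
  ord <- order(match(v$chrom, unique(v$chrom)), v$pos)
  if (!identical(ord, seq_len(nrow(v))))
    stop("variants must be sorted by chromosome and position")
  g_all <- panel$geno[row, ]
  segs <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    g <- g_all[idx]; pos <- v$pos[idx]
    n <- length(g); w <- params$window_snps
    if (n < w) next
    het <- roll_sum(!is.na(g) & g == 1L, w)
    mis <- roll_sum(is.na(g), w)
    pass <- het <= params$window_max_het & mis <= params$window_max_missing
    nw <- length(pass)
    # windows covering SNP i: max(1, i-w+1) .. min(nw, i)
    lo <- pmax(seq_len(n) - w + 1L, 1L)
    hi <- pmin(seq_len(n), nw)
    cp <- c(0, cumsum(pass))
    n_pass <- cp[hi + 1L] - cp[lo]
    n_cov <- hi - lo + 1L
    cand <- n_pass / n_cov >= params$window_hit_threshold
    runs <- rle(cand)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      ii <- starts[r]:ends[r]
      # split at physical gaps larger than max_gap_kb
      gap_break <- which(diff(pos[ii]) > params$max_gap_kb * 1000)
      pieces <- split(ii, findInterval(seq_along(ii), gap_break + 1L))
      for (pc in pieces) {
        # trim ends to homozygous non-missing SNPs
        homo <- !is.na(g[pc]) & g[pc] != 1L
        if (!any(homo)) next
        pc <- pc[min(which(homo)):max(which(homo))]
        n_snps <- length(pc)
        kb <- (pos[max(pc)] - pos[min(pc)] + 1) / 1000
        if (n_snps < params$min_snps_in_segment) next
        if (kb < params$min_length_kb) next
        if (kb / n_snps > params$min_density_kb_per_snp) next
        segs[[length(segs) + 1]] <- data.frame(
          individual = individual, chrom = ch,
          start = pos[min(pc)], end = pos[max(pc)],
          n_snps = n_snps, kb_length = kb, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(individual = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), kb_length = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Summarize ROH segments per individual
#'
#' @param segments segment data.frame from [call_roh()] (may cover several
#'   individuals); overlapping segments within an individual are an error.
#' @param genome_length total genome length in bp for the f_roh fraction.
#' @return data.frame with one row per individual: `n_segments`,
#'   `total_kb`, `f_roh`.
#' @export
summarize_roh <- function(segments, genome_length) {
  stopifnot(genome_length > 0)
  if (nrow(segments) == 0)
    return(data.frame(individual = character(0), n_segments = integer(0),
                      total_kb = numeric(0), f_roh = numeric(0),
                      stringsAsFactors = FALSE))
  out <- lapply(split(segments, segments$individual), function(s) {
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$start), , drop = FALSE]
      if (nrow(sc) > 1 && any(sc$start[-1] <= sc$end[-nrow(sc)]))
        stop("overlapping segments for individual ", s$individual[1])
    }
    bp <- sum(s$end - s$start + 1)
    data.frame(individual = s$individual[1], n_segments = nrow(s),
               total_kb = bp / 1000, f_roh = bp / genome_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
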