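#' Sampling model for a low-coverage ancient individual
#'
#' @param mean_depth expected reads per site (Poisson lambda), > 0.
#' @param damage_rate probability that a read carrying a C (or G) allele at
#'   a C/T (G/A) site is observed as T (A) -- postmortem cytosine
#'   deamination. In `[0, 1)`.
#' @param error_rate per-read probability of flipping to the other allele,
#'   regardless of site type. In `[0, 1)`.
#' @param missing_rate per-site dropout probability. In `[0, 1)`.
#' @return An object of class `ancient_spec`.
#' @export
ancient_spec <- function(mean_depth, damage_rate = 0, error_rate = 0,
                         missing_rate = 0) {
  stopifnot(mean_depth > 0,
            damage_rate >= 0, damage_rate < 1,
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(mean_depth = mean_depth, damage_rate = damage_rate,
                 error_rate = error_rate, missing_rate = missing_rate),
            class = "ancient_spec")
}

#' Simulate an ancient-DNA read pileup from diploid genotypes
#'
#' Per site, read depth is Poisson(`mean_depth`) and each read draws one of
#' the individual's two chromosomes at random. At sites whose allele pair is
#' C/T or G/A, reads truly carrying the C (resp. G) allele are flipped to
#' the other allele with probability `damage_rate`, emulating deamination;
#' transversion-pair sites are never touched by damage. Every read is then
#' flipped with probability `error_rate`, and whole sites are dropped with
#' probability `missing_rate`. Sites with missing genotype yield no reads.
#'
#' @param panel diploid [gt_panel()] holding the individuals to sample.
#' @param spec an [ancient_spec()].
#' @param seed integer seed.
#' @param inds optional subset of individual ids (default: all).
#' @return A pileup data.frame with columns `individual`, `chrom`, `pos`,
#'   `count0`, `count1` (reads carrying allele0/allele1), containing only
#'   sites with at least one read.
#' @export
simulate_ancient_pileup <- function(panel, spec, seed, inds = NULL) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "diploid",
            inherits(spec, "ancient_spec"))
  set.seed(seed)
  if (is.null(inds)) inds <- panel$individuals$id
  v <- panel$variants
  pair <- paste(pmin(v$allele0, v$allele1), pmax(v$allele0, v$allele1))
  damageable <- pair %in% c("C T", "A G")
  # within a damageable pair the deaminating base is C (of C/T) or G (of G/A)
  dam_is_allele0 <- v$allele0 %in% c("C", "G") & damageable
  out <- vector("list", length(inds))
  for (j in seq_along(inds)) {
    g <- panel$geno[match(inds[j], panel$individuals$id), ]
    n <- length(g)
    depth <- stats::rpois(n, spec$mean_depth)
    depth[stats::runif(n) < spec$missing_rate] <- 0L
    depth[is.na(g)] <- 0L
    # reads truly carrying allele1
    c1 <- stats::rbinom(n, depth, ifelse(is.na(g), 0, g / 2))
    c1[depth == 0L] <- 0L
    c0 <- depth - c1
    if (spec$damage_rate > 0) {
      flip0 <- stats::rbinom(n, ifelse(damageable & dam_is_allele0, c0, 0L),
                             spec$damage_rate)
      flip1 <- stats::rbinom(n, ifelse(damageable & !dam_is_allele0, c1, 0L),
                             spec$damage_rate)
      c0 <- c0 - flip0 + flip1
      c1 <- c1 - flip1 + flip0
    }
    if (spec$error_rate > 0) {
      e0 <- stats::rbinom(n, c0, spec$error_rate)
      e1 <- stats::rbinom(n, c1, spec$error_rate)
      c0 <- c0 - e0 + e1
      c1 <- c1 - e1 + e0
    }
    keep <- depth > 0L
    out[[j]] <- data.frame(individual = inds[j],
                           chrom = v$chrom[keep], pos = v$pos[keep],
                           count0 = c0[keep], count1 = c1[keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant homozygous tracts (ROH) into a diploid panel
#'
#' Inside each planted segment the individual becomes homozygous at every
#' site, with the allele drawn once per site from its population's
#' frequency; genotypes outside the segments are unchanged. Returns the
#' modified panel plus the segments as ground truth.
#'
#' @param panel diploid [gt_panel()].
#' @param segments data.frame with columns `individual`, `chrom`, `start`,
#'   `end` (1-based, inclusive). Segments must not overlap within an
#'   individual.
#' @param freqs site x population frequency matrix aligned with
#'   `panel$variants` rows.
#' @param seed integer seed.
#' @return list with elements `panel` (modified) and `segments` (the truth).
#' @export
plant_roh <- function(panel, segments, freqs, seed) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "diploid",
            all(c("individual", "chrom", "start", "end") %in% names(segments)),
            nrow(freqs) == nrow(panel$variants))
  set.seed(seed)
  for (id in unique(segments$individual)) {
    s <- segments[segments$individual == id, , drop = FALSE]
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$start), , drop = FALSE]
      if (nrow(sc) > 1 && any(sc$start[-1] <= sc$end[-nrow(sc)]))
        stop("overlapping planted segments for individual ", id)
    }
  }
  g <- panel$geno
  v <- panel$variants
  for (i in seq_len(nrow(segments))) {
    id <- segments$individual[i]
    row <- match(id, panel$individuals$id)
    if (is.na(row)) stop("unknown individual in segments: ", id)
    pop <- panel$individuals$population[row]
    in_seg <- v$chrom == segments$chrom[i] &
      v$pos >= segments$start[i] & v$pos <= segments$end[i]
    if (!any(in_seg)) next
    allele <- stats::rbinom(sum(in_seg), 1L, freqs[in_seg, pop])
    g[row, in_seg] <- 2L * allele
  }
  list(panel = gt_panel(g, v, panel$individuals, "diploid"),
       segments = segments)
}

#' Simulate a per-chromosome coverage profile for a sexed individual
#'
#' Autosomal coverages are drawn Normal(d, cv * d); the X chromosome has
#' mean d for a female and d/2 for a male (one X in males).
#'
#' @param sex `"female"` or `"male"`.
#' @param autosomal_depth mean autosomal depth d, > 0.
#' @param chrom_lengths named lengths including an `"X"` entry (default
#'   [default_chrom_lengths()]).
#' @param cv coefficient of variation of per-chromosome depth (default
#'   0.05).
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `length`, `mean_depth`,
#'   `class` (`"autosome"`/`"X"`).
#' @export
simulate_coverage_profile <- function(sex, autosomal_depth,
                                      chrom_lengths = default_chrom_lengths(),
                                      cv = 0.05, seed = 1) {
  if (!sex %in% c("female", "male")) stop("unknown sex label: ", sex)
  stopifnot(autosomal_depth > 0, "X" %in% names(chrom_lengths))
  set.seed(seed)
  chroms <- names(chrom_lengths)
  cls <- ifelse(chroms == "X", "X", "autosome")
  mu <- ifelse(cls == "X" & sex == "male",
               autosomal_depth / 2, autosomal_depth)
  depth <- pmax(stats::rnorm(length(mu), mu, cv * mu), 0)
  data.frame(chrom = chroms, length = as.numeric(chrom_lengths),
             mean_depth = depth, class = cls, stringsAsFactors = FALSE)
}

#' Simulate breakpoint-spanning reads against two reference versions
#'
#' Emulates mapping the reads of an insertion carrier / non-carrier to two
#' modified references, one containing the insertion and one lacking it.
#' Reads from the matching haplotype align contiguously across the
#' breakpoint with zero overhang mismatches; on the non-matching reference
#' the same read aligns on one side only, with a short spurious overhang
#' (0-5 bp) across the breakpoint carrying random mismatches.
#'
#' @param carrier `TRUE` if the individual carries the insertion.
#' @param n_reads number of reads overlapping the breakpoint region.
#' @param read_length read length in bp (default 60).
#' @param breakpoint breakpoint coordinate: the insertion sits between
#'   `breakpoint` and `breakpoint + 1` (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `read_id`, `reference_version`
#'   (`"insertion_present"` / `"insertion_absent"`), `start`, `end`,
#'   `overhang_left`, `overhang_right`, `mismatches`.
#' @export
simulate_insertion_reads <- function(carrier, n_reads, read_length = 60,
                                     breakpoint = 1000, seed = 1) {
  stopifnot(n_reads >= 0, read_length >= 2)
  set.seed(seed)
  if (n_reads == 0)
    return(data.frame(read_id = character(0), reference_version = character(0),
                      start = integer(0), end = integer(0),
                      overhang_left = integer(0), overhang_right = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  start <- breakpoint - sample.int(read_length, n_reads, replace = TRUE) + 1L
  end <- start + read_length - 1L
  left <- pmax(breakpoint - start + 1L, 0L)
  right <- pmax(end - breakpoint, 0L)
  match_ref <- if (carrier) "insertion_present" else "insertion_absent"
  other_ref <- if (carrier) "insertion_absent" else "insertion_present"
  # on the mismatching reference only the larger true side aligns, plus a
  # short noisy overhang across the breakpoint
  spill <- sample(0:5, n_reads, replace = TRUE)
  mm <- stats::rbinom(n_reads, spill, 0.5)
  left_side <- left >= right
  o_left <- ifelse(left_side, left, spill)
  o_right <- ifelse(left_side, spill, right)
  o_start <- ifelse(left_side, start, breakpoint + 1L - spill)
  o_end <- ifelse(left_side, breakpoint + spill, end)
  ids <- sprintf("read_%04d", seq_len(n_reads))
  rbind(
    data.frame(read_id = ids, reference_version = match_ref,
               start = start, end = end,
               overhang_left = left, overhang_right = right,
               mismatches = 0L, stringsAsFactors = FALSE),
    data.frame(read_id = ids, reference_version = other_ref,
               start = as.integer(o_start), end = as.integer(o_end),
               overhang_left = as.integer(o_left),
               overhang_right = as.integer(o_right),
               mismatches = mm, stringsAsFactors = FALSE)
  )
}
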