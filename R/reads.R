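#' Molecular sex determination from X/autosome coverage
#'
#' The ratio of mean X-chromosome depth to length-weighted mean autosomal
#' depth is close to 1 in females (two X copies) and close to 0.5 in males
#' (one X). Thresholds formalize "similar" and "around half": at or above
#' `female_min_ratio` the call is female, at or below `male_max_ratio`
#' male, in between indeterminate.
#'
#' @param profile coverage data.frame with columns `chrom`, `length`,
#'   `mean_depth` and `class` (`"autosome"`/`"X"`), e.g. from
#'   [simulate_coverage_profile()] or [read_coverage_tsv()].
#' @param female_min_ratio minimum X/autosome ratio for a female call
#'   (default 0.8).
#' @param male_max_ratio maximum ratio for a male call (default 0.6).
#' @return list with `ratio`, `call` (`"female"`, `"male"`,
#'   `"indeterminate"`), `autosomal_depth`, `x_depth`.
#' @export
sex_from_coverage <- function(profile, female_min_ratio = 0.8,
                              male_max_ratio = 0.6) {
  stopifnot(all(c("chrom", "length", "mean_depth", "class") %in%
                  names(profile)),
            male_max_ratio < female_min_ratio)
  auto <- profile[profile$class == "autosome", , drop = FALSE]
  xchr <- profile[profile$class == "X", , drop = FALSE]
  if (nrow(auto) < 1 || nrow(xchr) < 1)
    stop("profile needs at least one autosome and the X chromosome")
  a_depth <- sum(auto$mean_depth * auto$length) / sum(auto$length)
  if (a_depth <= 0) stop("zero autosomal coverage")
  x_depth <- sum(xchr$mean_depth * xchr$length) / sum(xchr$length)
  ratio <- x_depth / a_depth
  call <- if (ratio >= female_min_ratio) "female"
  else if (ratio <= male_max_ratio) "male"
  else "indeterminate"
  list(ratio = ratio, call = call, autosomal_depth = a_depth,
       x_depth = x_depth)
}

#' Genotype an insertion from breakpoint-spanning reads
#'
#' Reads aligned to two reference versions (with and without the
#' insertion) vote for the version they span cleanly: a read supports its
#' reference iff it crosses the breakpoint by at least `min_overhang` bp
#' on both sides with at most `max_overhang_mismatches` mismatches in the
#' overhang. Short, mismatch-rich overhangs -- e.g. a 3 bp overhang with 2
#' mismatches -- are not treated as evidence. The call is `present` or
#' `absent` when one reference has qualified support and the other none,
#' `ambiguous` when both do, `no_data` when neither.
#'
#' @param reads read-interval data.frame (columns `reference_version`,
#'   `overhang_left`, `overhang_right`, `mismatches`), e.g. from
#'   [simulate_insertion_reads()] or [read_intervals_tsv()], covering both
#'   reference versions of one locus.
#' @param min_overhang minimum breakpoint overhang on each side (default
#'   10 bp).
#' @param max_overhang_mismatches maximum mismatches in the overhang
#'   (default 1).
#' @return list with `support_present`, `support_absent`, `call` and
#'   `low_confidence` (`TRUE` when the winning side has fewer than 3
#'   qualified reads).
#' @export
genotype_insertion <- function(reads, min_overhang = 10,
                               max_overhang_mismatches = 1) {
  stopifnot(all(c("reference_version", "overhang_left", "overhang_right",
                  "mismatches") %in% names(reads)))
  qual <- pmin(reads$overhang_left, reads$overhang_right) >= min_overhang &
    reads$mismatches <= max_overhang_mismatches
  sp <- sum(qual & reads$reference_version == "insertion_present")
  sa <- sum(qual & reads$reference_version == "insertion_absent")
  call <- if (sp == 0 && sa == 0) "no_data"
  else if (sp >= 1 && sa == 0) "present"
  else if (sa >= 1 && sp == 0) "absent"
  else "ambiguous"
  list(support_present = sp, support_absent = sa, call = call,
       low_confidence = call %in% c("present", "absent") && max(sp, sa) < 3)
}

#' Convert SAM text alignments to breakpoint read intervals
#'
#' A thin convenience parser: takes plain-text SAM lines mapped to one
#' reference version, computes each read's aligned reference span from
#' POS and CIGAR (M/D/N/=/X consume reference), derives the breakpoint
#' overhangs, and takes mismatches from the NM tag (an upper bound on
#' overhang mismatches, since NM counts the whole alignment). Unmapped
#' reads are skipped.
#'
#' @param sam_path path to a SAM text file.
#' @param breakpoint breakpoint coordinate (insertion between `breakpoint`
#'   and `breakpoint + 1`).
#' @param reference_version `"insertion_present"` or `"insertion_absent"`.
#' @return read-interval data.frame as accepted by
#'   [genotype_insertion()].
#' @export
read_sam_intervals <- function(sam_path, breakpoint,
                               reference_version = c("insertion_absent",
                                                     "insertion_present")) {
  reference_version <- match.arg(reference_version)
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) return(NULL)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) return(NULL)  # unmapped
    pos <- as.integer(f[4])
    ops <- gregexpr("\\d+[MIDNSHP=X]", f[6])[[1]]
    cig <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", cig))
    type <- sub("^\\d+", "", cig)
    ref_len <- sum(lens[type %in% c("M", "D", "N", "=", "X")])
    if (ref_len == 0) return(NULL)
    nm <- regmatches(l, regexpr("NM:i:\\d+", l))
    mm <- if (length(nm)) as.integer(sub("NM:i:", "", nm)) else 0L
    end <- pos + ref_len - 1L
    data.frame(read_id = f[1], reference_version = reference_version,
               start = pos, end = end,
               overhang_left = as.integer(max(breakpoint - pos + 1, 0)),
               overhang_right = as.integer(max(end - breakpoint, 0)),
               mismatches = mm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read_id = character(0),
                      reference_version = character(0),
                      start = integer(0), end = integer(0),
                      overhang_left = integer(0),
                      overhang_right = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  out
}
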