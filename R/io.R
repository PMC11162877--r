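#' Read an EIGENSTRAT genotype dataset
#'
#' Parses the `.geno` / `.snp` / `.ind` triple. Each `.geno` line holds one
#' site as one character per individual: `0`, `1`, `2` allele-1 dosages or
#' `9` for missing (translated to `NA`).
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind` must exist (or pass explicit paths).
#' @param geno,snp,ind optional explicit file paths overriding `prefix`.
#' @return A diploid [gt_panel()].
#' @export
read_eigenstrat <- function(prefix = NULL, geno = NULL, snp = NULL, ind = NULL) {
  if (!is.null(prefix)) {
    if (is.null(geno)) geno <- paste0(prefix, ".geno")
    if (is.null(snp)) snp <- paste0(prefix, ".snp")
    if (is.null(ind)) ind <- paste0(prefix, ".ind")
  }
  glines <- readLines(geno)
  sfields <- utils::read.table(snp, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(sfields) < 6) stop("malformed .snp file: expected 6 columns")
  ifields <- utils::read.table(ind, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ifields) < 3) stop("malformed .ind file: expected 3 columns")
  n_ind <- nrow(ifields); n_snp <- nrow(sfields)
  if (length(glines) != n_snp)
    stop("dimension mismatch: ", length(glines), " .geno lines vs ",
         n_snp, " .snp rows")
  if (any(nchar(glines) != n_ind))
    stop("dimension mismatch: .geno line width does not match .ind rows")
  chars <- strsplit(glines, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c("0", "1", "2", "9")),
              nrow = n_snp, byrow = TRUE)
  if (anyNA(m)) stop("invalid genotype character in .geno (allowed: 0 1 2 9)")
  m <- m - 1L
  m[m == 3L] <- NA_integer_
  variants <- variant_table(chrom = sfields[[2]], pos = sfields[[4]],
                            allele0 = sfields[[6]], allele1 = sfields[[5]],
                            snp_id = sfields[[1]])
  individuals <- data.frame(id = ifields[[1]], population = ifields[[3]],
                            stringsAsFactors = FALSE)
  gt_panel(t(m), variants, individuals, "diploid")
}

#' Write a genotype panel in EIGENSTRAT format
#'
#' Inverse of [read_eigenstrat()]: `write` then `read` reproduces the panel
#' exactly. Haploid panels are written with calls 0/1 and read back as
#' diploid dosages; use [pseudo_haploid_as_diploid()] if homozygous coding
#' is wanted instead.
#'
#' @param panel a [gt_panel()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_eigenstrat <- function(panel, prefix) {
  stopifnot(inherits(panel, "gt_panel"))
  g <- t(panel$geno)  # sites x individuals
  g[is.na(g)] <- 9L
  glines <- apply(g, 1, paste, collapse = "")
  writeLines(glines, paste0(prefix, ".geno"))
  v <- panel$variants
  utils::write.table(
    data.frame(v$snp_id, v$chrom, 0, v$pos, v$allele1, v$allele0),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  ind <- panel$individuals
  utils::write.table(
    data.frame(ind$id, "U", ind$population),
    paste0(prefix, ".ind"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Re-code a pseudo-haploid panel as homozygous diploid
#'
#' Pseudo-haploid calls 0/1 become dosages 0/2 (the individual is coded
#' homozygous for the drawn allele), the conventional representation when
#' merging pseudo-haploid samples into diploid panels.
#'
#' @param panel haploid [gt_panel()].
#' @return A diploid [gt_panel()].
#' @export
pseudo_haploid_as_diploid <- function(panel) {
  stopifnot(inherits(panel, "gt_panel"), panel$ploidy == "haploid")
  gt_panel(panel$geno * 2L, panel$variants, panel$individuals, "diploid")
}

#' Read a PLINK text dataset (.ped/.map)
#'
#' Alleles observed per site define the dosage coding: allele0/allele1 are
#' taken in order of first appearance; `0` denotes missing. Sites showing
#' more than two alleles are rejected.
#'
#' @param ped,map file paths.
#' @return A diploid [gt_panel()].
#' @export
read_plink_ped <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("malformed .map: expected 4 columns")
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  n_snp <- nrow(mp)
  if (ncol(pd) != 6 + 2 * n_snp)
    stop("dimension mismatch between .ped and .map")
  n_ind <- nrow(pd)
  a1 <- as.matrix(pd[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  a2 <- as.matrix(pd[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  g <- matrix(NA_integer_, n_ind, n_snp)
  allele0 <- character(n_snp); allele1 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(a1[, j], a2[, j])
    lev <- unique(obs[obs != "0"])
    if (length(lev) > 2) stop("more than two alleles at site ", mp[[2]][j])
    if (length(lev) == 0) lev <- c("N1", "N2")
    if (length(lev) == 1) lev <- c(lev, setdiff(c("A", "C", "G", "T"), lev)[1])
    d <- (a1[, j] == lev[2]) + (a2[, j] == lev[2])
    d[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    g[, j] <- as.integer(d)
    allele0[j] <- lev[1]; allele1[j] <- lev[2]
  }
  variants <- variant_table(chrom = mp[[1]], pos = mp[[4]],
                            allele0 = allele0, allele1 = allele1,
                            snp_id = mp[[2]])
  individuals <- data.frame(id = pd[[2]], population = pd[[1]],
                            stringsAsFactors = FALSE)
  gt_panel(g, variants, individuals, "diploid")
}

#' Read / write per-site allele-count pileup tables
#'
#' Tab-separated with header columns `individual`, `chrom`, `pos`,
#' `count0`, `count1`.
#'
#' @param path file path.
#' @return data.frame (read) or invisible path (write).
#' @export
read_pileup_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("individual", "chrom", "pos", "count0", "count1")
  if (!all(need %in% names(d)))
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  d$chrom <- as.character(d$chrom)
  d
}

#' @rdname read_pileup_tsv
#' @param pileup pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read / write per-chromosome coverage tables
#'
#' Tab-separated with header columns `chrom`, `length`, `mean_depth` and
#' optionally `class`; a missing `class` column is inferred (`"X"` for
#' chromosome `X`, autosome otherwise).
#'
#' @param path file path.
#' @return data.frame (read) or invisible path (write).
#' @export
read_coverage_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "length", "mean_depth")
  if (!all(need %in% names(d)))
    stop("coverage TSV must have columns: ", paste(need, collapse = ", "))
  d$chrom <- as.character(d$chrom)
  if (!"class" %in% names(d))
    d$class <- ifelse(d$chrom %in% c("X", "chrX"), "X", "autosome")
  d
}

#' @rdname read_coverage_tsv
#' @param coverage coverage data.frame.
#' @export
write_coverage_tsv <- function(coverage, path) {
  utils::write.table(coverage, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read / write breakpoint read-interval tables
#'
#' Tab-separated with header columns `read_id`, `reference_version`,
#' `start`, `end`, `overhang_left`, `overhang_right`, `mismatches`.
#'
#' @param path file path.
#' @return data.frame (read) or invisible path (write).
#' @export
read_intervals_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("read_id", "reference_version", "start", "end",
            "overhang_left", "overhang_right", "mismatches")
  if (!all(need %in% names(d)))
    stop("interval TSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_intervals_tsv
#' @param intervals interval data.frame.
#' @export
write_intervals_tsv <- function(intervals, path) {
  utils::write.table(intervals, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
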