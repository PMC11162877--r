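#' Construct a variant table
#'
#' A variant table holds per-SNP metadata: chromosome, 1-based physical
#' position, the two alleles, an optional ancestral state and an identifier.
#' It is the site-level companion of every genotype panel in the package.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param allele0,allele1 single-character allele labels (usually bases);
#'   `allele0` and `allele1` must differ at every site.
#' @param snp_id optional SNP identifiers; generated as `chrom_pos` when
#'   missing.
#' @param ancestral optional ancestral allele per site; must be `NA` or one
#'   of the two alleles.
#' @return A `data.frame` with columns `chrom`, `pos`, `snp_id`, `allele0`,
#'   `allele1`, `ancestral`.
#' @export
variant_table <- function(chrom, pos, allele0, allele1, snp_id = NULL,
                          ancestral = NA_character_) {
  n <- length(pos)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == n, length(allele0) == n, length(allele1) == n)
  if (is.null(snp_id)) snp_id <- paste(chrom, pos, sep = "_")
  ancestral <- rep_len(as.character(ancestral), n)
  v <- data.frame(chrom = chrom, pos = pos, snp_id = as.character(snp_id),
                  allele0 = as.character(allele0),
                  allele1 = as.character(allele1),
                  ancestral = ancestral, stringsAsFactors = FALSE)
  validate_variants(v)
  v
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("chrom", "pos", "allele0", "allele1") %in% names(v)))
  if (anyNA(v$pos) || any(v$pos < 1))
    stop("positions must be 1-based positive integers")
  if (any(v$allele0 == v$allele1))
    stop("allele0 and allele1 must differ at every site")
  key <- paste(v$chrom, v$pos)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos) in variant table")
  if ("ancestral" %in% names(v)) {
    bad <- !is.na(v$ancestral) &
      v$ancestral != v$allele0 & v$ancestral != v$allele1
    if (any(bad)) stop("ancestral state must be one of the two alleles")
  }
  invisible(v)
}

#' Construct a genotype panel
#'
#' The central container of the package: a matrix of allele-1 dosages over
#' individuals (rows) and sites (columns), together with the variant table
#' and per-individual metadata. Diploid panels carry dosages in
#' \{0, 1, 2, NA\}; pseudo-haploid panels carry single-allele calls in
#' \{0, 1, NA\}. Missing data is always `NA` internally; file parsers
#' translate format-specific codes ('9', '0', './.') on the way in and out.
#'
#' @param geno integer matrix, individuals x sites.
#' @param variants variant table with one row per column of `geno`.
#' @param individuals data.frame with columns `id` and `population` (one row
#'   per row of `geno`), or a character vector of ids.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return An object of class `gt_panel`.
#' @export
gt_panel <- function(geno, variants, individuals, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.character(individuals))
    individuals <- data.frame(id = individuals,
                              population = individuals,
                              stringsAsFactors = FALSE)
  stopifnot(is.data.frame(individuals),
            all(c("id", "population") %in% names(individuals)))
  validate_variants(variants)
  if (nrow(geno) != nrow(individuals))
    stop("geno rows must match individuals")
  if (ncol(geno) != nrow(variants))
    stop("geno columns must match variant table")
  maxdose <- if (ploidy == "diploid") 2L else 1L
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0L || max(vals) > maxdose))
    stop("dosages out of range for ", ploidy, " panel")
  rownames(geno) <- individuals$id
  colnames(geno) <- variants$snp_id
  structure(list(geno = geno, variants = variants,
                 individuals = individuals, ploidy = ploidy),
            class = "gt_panel")
}

#' @export
print.gt_panel <- function(x, ...) {
  cat(sprintf("gt_panel: %d %s individuals x %d sites\n",
              nrow(x$geno), x$ploidy, ncol(x$geno)))
  cat(sprintf("  populations: %s\n",
              paste(unique(x$individuals$population), collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.gt_panel <- function(x) dim(x$geno)

#' Subset a genotype panel by sites and/or individuals
#'
#' @param panel a `gt_panel`.
#' @param sites logical or integer index over sites (columns).
#' @param inds logical or integer index over individuals (rows), or a
#'   character vector of individual ids.
#' @return The subset `gt_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, inds = NULL) {
  stopifnot(inherits(panel, "gt_panel"))
  g <- panel$geno; v <- panel$variants; ind <- panel$individuals
  if (!is.null(inds)) {
    if (is.character(inds)) inds <- match(inds, ind$id)
    g <- g[inds, , drop = FALSE]
    ind <- ind[inds, , drop = FALSE]
  }
  if (!is.null(sites)) {
    g <- g[, sites, drop = FALSE]
    v <- v[sites, , drop = FALSE]
  }
  rownames(v) <- NULL; rownames(ind) <- NULL
  gt_panel(g, v, ind, panel$ploidy)
}

#' Per-site missingness and minor-allele frequency
#'
#' Frequencies are computed on non-missing calls only, respecting ploidy.
#'
#' @param panel a `gt_panel`.
#' @return data.frame with columns `missing_frac`, `freq1` (allele-1
#'   frequency) and `maf`.
#' @export
site_summary <- function(panel) {
  g <- panel$geno
  ploidy <- if (panel$ploidy == "diploid") 2L else 1L
  n_called <- colSums(!is.na(g))
  miss <- colSums(is.na(g)) / nrow(g)
  freq1 <- colSums(g, na.rm = TRUE) / (ploidy * pmax(n_called, 1L))
  freq1[n_called == 0L] <- NA_real_
  data.frame(missing_frac = miss, freq1 = freq1,
             maf = pmin(freq1, 1 - freq1))
}
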