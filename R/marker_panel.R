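#' Ordered panel of biallelic markers
#'
#' A `marker_panel` is the site-level backbone of the analysis: an ordered
#' set of biallelic sites on one chromosome with physical positions,
#' ref/alt alleles, optional population alternate-allele frequencies and
#' optional genetic-map coordinates.
#'
#' @param chrom Chromosome label (single value).
#' @param pos 1-based physical positions, bp, strictly increasing.
#' @param ref,alt Reference and alternate alleles per site.
#' @param pop_af Population alternate-allele frequency per site, in
#'   \eqn{[0, 1]}; `NA` where unknown.
#' @param cm Genetic-map coordinate per site, centiMorgans, non-decreasing;
#'   `NA` until a map is attached (see [attach_annotations()]).
#' @return An object of class `marker_panel` (a validated data.frame).
#' @export
marker_panel <- function(chrom, pos, ref, alt, pop_af = NA_real_, cm = NA_real_) {
  n <- length(pos)
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  panel <- data.frame(
    chrom = chrom,
    pos = as.numeric(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    pop_af = rep_len(as.numeric(pop_af), n),
    cm = rep_len(as.numeric(cm), n),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("marker_panel", "data.frame")
  validate_marker_panel(panel)
}

validate_marker_panel <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  if (nrow(panel) == 0L) stop("marker panel is empty")
  if (length(unique(panel$chrom)) != 1L)
    stop("marker panel must be on a single chromosome")
  if (any(diff(panel$pos) <= 0))
    stop("marker panel positions must be strictly increasing")
  af <- panel$pop_af
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("pop_af must lie in [0, 1]")
  cmv <- panel$cm[!is.na(panel$cm)]
  if (length(cmv) > 1L && any(diff(cmv) < 0))
    stop("cm must be non-decreasing along the panel")
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d sites on %s, %s-%s bp (%d with AF, %d with cM)\n",
              nrow(x), x$chrom[1],
              format(min(x$pos), big.mark = ","),
              format(max(x$pos), big.mark = ","),
              sum(!is.na(x$pop_af)), sum(!is.na(x$cm))))
  invisible(x)
}

#' Genotype matrix over a marker panel
#'
#' Per-individual genotype calls at every site of a [marker_panel()],
#' centred on a focal variant.  Genotypes are coded as alternate-allele
#' counts: `0` hom-ref, `1` het, `2` hom-alt, `NA` missing — the coding
#' used throughout the scan, delineation and ROH modules.
#'
#' @param panel A `marker_panel`.
#' @param samples Character vector of individual identifiers.
#' @param gt Integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param focal_index Column index (1-based) of the focal variant in `panel`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(panel, samples, gt, focal_index) {
  panel <- validate_marker_panel(panel)
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != length(samples) || ncol(gt) != nrow(panel))
    stop("gt must be |samples| x |panel| (got ", nrow(gt), "x", ncol(gt), ")")
  bad <- gt[!is.na(gt)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("genotype codes must be 0 (hom-ref), 1 (het), 2 (hom-alt) or NA")
  focal_index <- as.integer(focal_index)
  if (length(focal_index) != 1L || is.na(focal_index) ||
      focal_index < 1L || focal_index > nrow(panel))
    stop("focal_index out of range")
  rownames(gt) <- samples
  structure(list(panel = panel, samples = as.character(samples),
                 gt = gt, focal_index = focal_index),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  f <- x$panel[x$focal_index, ]
  cat(sprintf("genotype_matrix: %d samples x %d sites; focal %s:%s %s>%s (site %d)\n",
              length(x$samples), nrow(x$panel), f$chrom,
              format(f$pos, big.mark = ","), f$ref, f$alt, x$focal_index))
  invisible(x)
}

#' Keep only individuals homozygous for the focal alternate allele
#'
#' The haplotype scan and block delineation are defined over carriers that
#' are hom-alt at the focal variant; this filter enforces that contract
#' rather than assuming it.
#'
#' @param G A `genotype_matrix`.
#' @return `G` restricted to samples with genotype code 2 at the focal site.
#' @export
filter_focal_homozygotes <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- !is.na(G$gt[, G$focal_index]) & G$gt[, G$focal_index] == 2L
  if (!any(keep))
    stop("no individual is homozygous for the focal alternate allele")
  genotype_matrix(G$panel, G$samples[keep], G$gt[keep, , drop = FALSE],
                  G$focal_index)
}
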