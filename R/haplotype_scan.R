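#' Informative-site mask
#'
#' Sites retained by the scan and delineation: population AF present,
#' minor allele frequency at least `maf_min`, and per-site missingness in
#' the cohort at most `max_missing`.
#'
#' @param G A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01, i.e. the
#'   common ">1% MAF" variant-quality cut).
#' @param max_missing Maximum tolerated fraction of missing calls per site
#'   before the site is excluded globally (default 0.2).
#' @return Logical vector over panel sites.
#' @keywords internal
informative_sites <- function(G, maf_min = 0.01, max_missing = 0.2) {
  af <- G$panel$pop_af
  maf <- pmin(af, 1 - af)
  miss_frac <- colMeans(is.na(G$gt))
  !is.na(af) & maf >= maf_min & miss_frac <= max_missing
}

# Cohort consensus homozygous allele per site: the modal allele among
# homozygous calls (code 0 or 2); NA when no homozygous call or tied.
consensus_hom_allele <- function(G) {
  n0 <- colSums(G$gt == 0L, na.rm = TRUE)
  n2 <- colSums(G$gt == 2L, na.rm = TRUE)
  out <- rep(NA_integer_, ncol(G$gt))
  out[n0 > n2] <- 0L
  out[n2 > n0] <- 2L
  out
}

#' Scan for markers shared homozygous across all carriers
#'
#' For every informative site (see `maf_min`, `max_missing`), reports
#' whether all carriers with a genotype call are homozygous for the same
#' allele, and the information content of the shared allele — the
#' reciprocal of its population frequency, so rare shared alleles score
#' high.  This is the computation behind an information-content versus
#' position founder-haplotype plot.
#'
#' @param G A `genotype_matrix`; every individual must be homozygous for
#'   the focal alternate allele (use [filter_focal_homozygotes()]).
#' @param maf_min Minimum minor allele frequency for a site to be scanned.
#' @param max_missing Per-site missingness cap; see [informative_sites].
#' @param informative_af_max Shared sites whose shared-allele population
#'   frequency is below this are flagged `highly_informative` — the rare
#'   shared alleles that carry most of the evidence for common descent.
#'   Reporting only; no filtering depends on it.
#' @return A data.frame with one row per scanned site: `site` (panel
#'   index), `chrom`, `pos`, `pop_af`, `n_hom`, `n_total` (non-missing
#'   calls), `shared`, `shared_allele` (`"ref"`/`"alt"`/`NA`),
#'   `info_content` (reciprocal of the shared-allele population frequency,
#'   `NA` where undefined) and `highly_informative`.
#' @export
scan_shared_homozygosity <- function(G, maf_min = 0.01, max_missing = 0.2,
                                     informative_af_max = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(G$samples) == 0L) stop("genotype matrix has zero individuals")
  check_focal_homozygous(G)
  keep <- which(informative_sites(G, maf_min, max_missing))
  if (length(keep) == 0L) {
    warning("no sites pass the MAF/missingness filter")
    return(empty_scan_report())
  }
  gt <- G$gt[, keep, drop = FALSE]
  n_total <- colSums(!is.na(gt))
  n_hom <- colSums(gt == 0L | gt == 2L, na.rm = TRUE)
  all0 <- colSums(gt != 0L, na.rm = TRUE) == 0L
  all2 <- colSums(gt != 2L, na.rm = TRUE) == 0L
  shared <- n_total > 0L & (all0 | all2)
  shared_allele <- ifelse(shared, ifelse(all2, "alt", "ref"), NA_character_)
  af <- G$panel$pop_af[keep]
  shared_af <- ifelse(shared_allele == "alt", af, 1 - af)
  info <- ifelse(shared & !is.na(shared_af) & shared_af > 0,
                 1 / shared_af, NA_real_)
  data.frame(site = keep,
             chrom = G$panel$chrom[keep],
             pos = G$panel$pos[keep],
             pop_af = af,
             n_hom = n_hom,
             n_total = n_total,
             shared = shared,
             shared_allele = shared_allele,
             info_content = info,
             highly_informative = shared & !is.na(shared_af) &
               shared_af < informative_af_max,
             stringsAsFactors = FALSE)
}

empty_scan_report <- function() {
  data.frame(site = integer(), chrom = character(), pos = numeric(),
             pop_af = numeric(), n_hom = integer(), n_total = integer(),
             shared = logical(), shared_allele = character(),
             info_content = numeric(), highly_informative = logical(),
             stringsAsFactors = FALSE)
}

check_focal_homozygous <- function(G, sample = NULL) {
  g <- G$gt[, G$focal_index]
  if (is.null(sample)) {
    bad <- G$samples[is.na(g) | g != 2L]
    if (length(bad))
      stop("individuals not homozygous for the focal alternate allele: ",
           paste(bad, collapse = ", "))
  } else {
    gi <- g[match(sample, G$samples)]
    if (is.na(gi) || gi != 2L)
      stop("sample '", sample, "' is not homozygous at the focal variant")
  }
  invisible(TRUE)
}

#' Delineate per-individual ancestral haplotype blocks
#'
#' Walks outward from the focal variant in both directions over
#' informative sites, carrying all individuals simultaneously.  Because
#' the delineated individuals are homozygous carriers, a heterozygous
#' call at an informative site is direct evidence that the ancestral
#' segment has ended on at least one of the two copies, and always
#' terminates the block.  A homozygous call is compared against the
#' ancestral allele, estimated at each site as the modal allele among
#' homozygous calls of the individuals whose blocks are still active:
#' concordant calls extend the block, discordant ones terminate it.
#' Terminated individuals stop contributing to the consensus, so the
#' ancestral haplotype can be followed beyond the region shared by all
#' carriers, as long as at least one carrier still retains it.
#'
#' Sites below the MAF threshold (private/rare variants that arise on a
#' subset of founder haplotypes) and missing calls are transparent: they
#' never terminate a block.  Where the active homozygous calls tie (no
#' consensus), homozygous calls are transparent too; heterozygous calls
#' still terminate.
#'
#' Two boundary conventions are available: `"concordant"` (default)
#' reports the last concordant informative marker — a conservative inner
#' bound — while `"midpoint"` reports the midpoint between that marker and
#' the first discordant one.
#'
#' @param G A `genotype_matrix`; every individual must be hom-alt at the
#'   focal variant.
#' @param samples Samples to delineate (default all; the consensus is
#'   always built from the full cohort in `G`).
#' @param maf_min,max_missing Informative-site filter; see
#'   [scan_shared_homozygosity()].
#' @param boundary Boundary convention, `"concordant"` or `"midpoint"`.
#' @return A data.frame with one row per sample: `sample`, `left_bp`,
#'   `right_bp`, `span_bp`, one-sided genetic lengths
#'   `left_morgans`/`right_morgans` (from the panel `cm` column, `NA` if no
#'   map was attached), `left_censored`/`right_censored` flags set when the
#'   walk ran off the loaded region instead of hitting a discordant
#'   marker, and `focal_pos`.
#' @export
delineate_blocks <- function(G, samples = G$samples, maf_min = 0.01,
                             max_missing = 0.2,
                             boundary = c("concordant", "midpoint")) {
  stopifnot(inherits(G, "genotype_matrix"))
  boundary <- match.arg(boundary)
  check_focal_homozygous(G)
  info <- which(informative_sites(G, maf_min, max_missing))
  pos <- G$panel$pos
  cmv <- G$panel$cm
  focal_pos <- pos[G$focal_index]
  n <- length(G$samples)

  # One direction for the whole cohort: returns per-sample last concordant
  # site and terminating discordant site (NA = ran off the region).
  walk <- function(idx) {
    last_ok <- rep(NA_integer_, n)
    stop_at <- rep(NA_integer_, n)
    active <- rep(TRUE, n)
    for (i in idx) {
      g <- G$gt[, i]
      het <- active & !is.na(g) & g == 1L     # segment over: copies differ
      hom <- active & !is.na(g) & (g == 0L | g == 2L)
      n0 <- sum(g[hom] == 0L); n2 <- sum(g[hom] == 2L)
      if (n0 != n2) {
        cons <- if (n2 > n0) 2L else 0L
        ok <- hom & g == cons
        ko <- het | (hom & g != cons)
      } else {
        ok <- rep(FALSE, n)                   # tied/absent consensus:
        ko <- het                             # hom calls are transparent
      }
      last_ok[ok] <- i
      stop_at[ko] <- i
      active[ko] <- FALSE
      if (!any(active)) break
    }
    list(last_ok = last_ok, stop_at = stop_at)
  }
  left <- walk(rev(info[pos[info] < focal_pos]))
  right <- walk(info[pos[info] > focal_pos])

  bound <- function(w) {
    anchor <- ifelse(is.na(w$last_ok), focal_pos, pos[w$last_ok])
    censored <- is.na(w$stop_at)
    bp <- anchor
    if (boundary == "midpoint") {
      mid <- (anchor + pos[ifelse(is.na(w$stop_at), 1L, w$stop_at)]) / 2
      bp <- ifelse(censored, anchor, mid)
    }
    list(bp = bp, censored = censored)
  }
  lb <- bound(left); rb <- bound(right)

  side_morgans <- function(bp) {
    if (all(is.na(cmv))) return(rep(NA_real_, n))
    cm_at <- stats::approx(pos, cmv, xout = bp, rule = 2, ties = "ordered")$y
    cm_f <- stats::approx(pos, cmv, xout = focal_pos, rule = 2,
                          ties = "ordered")$y
    abs(cm_f - cm_at) / 100
  }
  out <- data.frame(sample = G$samples,
                    left_bp = lb$bp, right_bp = rb$bp,
                    span_bp = rb$bp - lb$bp,
                    left_morgans = side_morgans(lb$bp),
                    right_morgans = side_morgans(rb$bp),
                    left_censored = lb$censored,
                    right_censored = rb$censored,
                    focal_pos = focal_pos,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[match(samples, G$samples), , drop = FALSE]
}

#' Delineate one individual's ancestral haplotype block
#'
#' Convenience wrapper around [delineate_blocks()] returning the single
#' row for `sample`.  The cohort-wide progressive consensus is identical
#' to a full [delineate_blocks()] run, so per-sample and cohort calls
#' always agree.
#'
#' @inheritParams delineate_blocks
#' @param sample Sample identifier; must be hom-alt at the focal variant.
#' @return A one-row data.frame; see [delineate_blocks()].
#' @export
delineate_block <- function(G, sample, maf_min = 0.01, max_missing = 0.2,
                            boundary = c("concordant", "midpoint")) {
  check_focal_homozygous(G, sample)
  out <- delineate_blocks(G, samples = sample, maf_min = maf_min,
                          max_missing = max_missing, boundary = boundary)
  rownames(out) <- NULL
  out
}

#' Shared core of a set of haplotype blocks
#'
#' The intersection of all per-individual ancestral blocks: the segment of
#' the founder chromosome still intact in every present-day carrier.
#'
#' @param blocks Data.frame of blocks from [delineate_blocks()] (or any
#'   data.frame with `left_bp`/`right_bp` columns), all containing the
#'   focal position.
#' @return A list with `start_bp`, `end_bp`, `span_bp` and `length_kb`
#'   (`span_bp / 1000`).
#' @export
shared_core <- function(blocks) {
  if (NROW(blocks) < 1L) stop("need at least one haplotype block")
  start_bp <- max(blocks$left_bp)
  end_bp <- min(blocks$right_bp)
  if (start_bp > end_bp)
    stop("haplotype blocks have an empty intersection")
  list(start_bp = start_bp, end_bp = end_bp,
       span_bp = end_bp - start_bp,
       length_kb = (end_bp - start_bp) / 1000)
}
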