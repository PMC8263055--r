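#' Shared runs of homozygosity across individuals
#'
#' Scans a genotype matrix for maximal runs of consecutive sites at which
#' every listed individual is homozygous — the autozygosity signal used to
#' map recessive variants in consanguineous pedigrees.  In `"strict"`
#' homogeneity mode all individuals must be homozygous for the same
#' allele at each site (genetic homogeneity across affected relatives);
#' `"loose"` mode requires homozygosity only.
#'
#' Per-site classification: `hom` (run site), `het` (interrupts; up to
#' `max_het` tolerated inside a run), `bad` (strict-mode allele
#' disagreement; always breaks a run).  Sites with a missing call in any
#' listed individual are transparent: they neither extend nor break a run
#' and do not count towards `n_sites`.  Region bounds are reported at the
#' outermost homozygous sites of each run.
#'
#' @param G A `genotype_matrix`.
#' @param samples Individuals to intersect (default all).
#' @param min_sites Minimum number of homozygous sites per reported run
#'   (`>= 1`).
#' @param max_het Heterozygous interruptions tolerated inside a run
#'   (default 0: strict runs).
#' @param homogeneity `"strict"` (same allele across individuals) or
#'   `"loose"`.
#' @param score `"n_sites"` (default: consecutive homozygous site count)
#'   or `"span_bp"`.
#' @return A data.frame of regions ranked by decreasing score, with
#'   columns `chrom`, `start_bp`, `end_bp`, `n_sites`, `span_bp`, `score`,
#'   `rank` (dense; tied scores share a rank) and `shared_by`.
#' @export
find_shared_roh <- function(G, samples = G$samples, min_sites = 5L,
                            max_het = 0L,
                            homogeneity = c("strict", "loose"),
                            score = c("n_sites", "span_bp")) {
  stopifnot(inherits(G, "genotype_matrix"))
  homogeneity <- match.arg(homogeneity)
  score <- match.arg(score)
  if (min_sites < 1L) stop("min_sites must be at least 1")
  if (length(samples) < 1L) stop("need at least one sample")
  idx <- match(samples, G$samples)
  if (anyNA(idx)) stop("unknown samples: ",
                       paste(samples[is.na(idx)], collapse = ", "))
  gt <- G$gt[idx, , drop = FALSE]
  state <- classify_roh_sites(gt, homogeneity)
  regions <- enumerate_roh_runs(state, max_het)
  if (length(regions) == 0L) return(empty_roh_table())
  pos <- G$panel$pos
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = G$panel$chrom[1],
               start_bp = pos[r$first_hom], end_bp = pos[r$last_hom],
               n_sites = r$n_hom,
               span_bp = pos[r$last_hom] - pos[r$first_hom],
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_roh_table())
  out$score <- if (score == "n_sites") out$n_sites else out$span_bp
  out <- out[order(-out$score, out$start_bp), , drop = FALSE]
  out$rank <- match(out$score, sort(unique(out$score), decreasing = TRUE))
  out$shared_by <- paste(samples, collapse = ",")
  rownames(out) <- NULL
  out
}

# Per-site run state over the listed individuals:
#   "hom"  every individual homozygous (same allele in strict mode)
#   "het"  no missing call, at least one het, no strict disagreement
#   "bad"  strict-mode disagreement between homozygous individuals
#   "skip" any missing call (transparent)
classify_roh_sites <- function(gt, homogeneity) {
  n_sites <- ncol(gt)
  state <- character(n_sites)
  for (j in seq_len(n_sites)) {
    g <- gt[, j]
    if (anyNA(g)) { state[j] <- "skip"; next }
    hom <- g == 0L | g == 2L
    disagree <- homogeneity == "strict" && length(unique(g[hom])) > 1L
    if (all(hom)) {
      state[j] <- if (disagree) "bad" else "hom"
    } else {
      state[j] <- if (disagree) "bad" else "het"
    }
  }
  state
}

# Maximal windows with <= max_het het sites, no bad site, trimmed to
# outermost hom sites; skip sites are transparent.
enumerate_roh_runs <- function(state, max_het) {
  runs <- list()
  seg_bounds <- split(seq_along(state),
                      cumsum(state == "bad"))
  for (seg in seg_bounds) {
    seg <- seg[state[seg] != "bad"]
    if (length(seg) == 0L) next
    core <- seg[state[seg] %in% c("hom", "het")]
    if (length(core) == 0L) next
    hets <- which(state[core] == "het")
    m <- length(hets)
    n <- length(core)
    windows <- if (m <= max_het) {
      list(c(1L, n))
    } else {
      lo <- c(1L, hets[seq_len(m - max_het)] + 1L)
      hi <- c(hets[seq.int(max_het + 1L, m)] - 1L, n)
      Map(c, lo, hi)
    }
    for (w in windows) {
      if (w[1] > w[2]) next
      span <- core[w[1]:w[2]]
      homs <- span[state[span] == "hom"]
      if (length(homs) == 0L) next
      runs[[length(runs) + 1L]] <- list(first_hom = min(homs),
                                        last_hom = max(homs),
                                        n_hom = length(homs))
    }
  }
  # after trimming to hom endpoints, drop runs contained in another run
  # (maximality is defined on the trimmed regions)
  if (length(runs) > 1L) {
    key <- vapply(runs, function(r) paste(r$first_hom, r$last_hom), "")
    runs <- runs[!duplicated(key)]
    lo <- vapply(runs, `[[`, 0, "first_hom")
    hi <- vapply(runs, `[[`, 0, "last_hom")
    contained <- vapply(seq_along(runs), function(a)
      any(lo <= lo[a] & hi >= hi[a] & (lo < lo[a] | hi > hi[a])), TRUE)
    runs <- runs[!contained]
  }
  runs
}

empty_roh_table <- function() {
  data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric(),
             n_sites = integer(), span_bp = numeric(), score = numeric(),
             rank = integer(), shared_by = character(),
             stringsAsFactors = FALSE)
}

#' Region span in megabases
#'
#' @param start_bp,end_bp Region bounds, bp, with `end_bp >= start_bp`.
#' @param decimals Decimal places (default 1).
#' @return `(end_bp - start_bp) / 1e6`, rounded half-up.
#' @examples
#' region_span_mb(137825, 1646565)  # 1.5
#' @export
region_span_mb <- function(start_bp, end_bp, decimals = 1) {
  if (any(end_bp < start_bp)) stop("end_bp must be >= start_bp")
  round_half_up((end_bp - start_bp) / 1e6, decimals)
}
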