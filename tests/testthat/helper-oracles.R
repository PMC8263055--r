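# Independent brute-force oracles, deliberately written without reusing any
# package internals, plus small fixture builders shared across test files.

# Per-site exhaustive shared-homozygosity check: loops over sites and samples
# with no vectorisation shared with the scanner.
oracle_scan_shared <- function(gt, af, maf_min = 0.01, max_missing = 0.2) {
  n_sites <- ncol(gt)
  keep <- logical(n_sites); shared <- logical(n_sites)
  allele <- rep(NA_character_, n_sites)
  for (j in seq_len(n_sites)) {
    a <- af[j]
    if (is.na(a)) next
    if (min(a, 1 - a) < maf_min) next
    if (mean(is.na(gt[, j])) > max_missing) next
    keep[j] <- TRUE
    calls <- gt[!is.na(gt[, j]), j]
    if (length(calls) == 0) { shared[j] <- FALSE; next }
    if (all(calls == 2)) { shared[j] <- TRUE; allele[j] <- "alt" }
    else if (all(calls == 0)) { shared[j] <- TRUE; allele[j] <- "ref" }
  }
  data.frame(site = which(keep), shared = shared[keep],
             shared_allele = allele[keep], stringsAsFactors = FALSE)
}

# Exhaustive ROH run enumeration: classify every site, test every window for
# validity, keep windows maximal under containment.
oracle_shared_roh <- function(gt, max_het = 0, homogeneity = "strict") {
  n_sites <- ncol(gt)
  state <- character(n_sites)
  for (j in seq_len(n_sites)) {
    g <- gt[, j]
    if (anyNA(g)) { state[j] <- "skip"; next }
    if (all(g %in% c(0, 2))) {
      if (homogeneity == "strict" && length(unique(g)) > 1) state[j] <- "bad"
      else state[j] <- "hom"
    } else if (homogeneity == "strict" &&
               length(unique(g[g %in% c(0, 2)])) > 1) {
      state[j] <- "bad"
    } else state[j] <- "het"
  }
  valid <- list()
  for (i in seq_len(n_sites)) for (j in i:n_sites) {
    if (state[i] != "hom" || state[j] != "hom") next
    w <- state[i:j]
    if (any(w == "bad")) next
    if (sum(w == "het") > max_het) next
    valid[[length(valid) + 1L]] <- c(i, j, sum(w == "hom"))
  }
  if (length(valid) == 0) return(data.frame(first = integer(), last = integer(),
                                            n_hom = integer()))
  v <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(v)), function(a)
    !any(v[, 1] <= v[a, 1] & v[, 2] >= v[a, 2] &
           (v[, 1] < v[a, 1] | v[, 2] > v[a, 2])), TRUE)
  v <- v[maximal, , drop = FALSE]
  v <- v[order(v[, 1]), , drop = FALSE]
  data.frame(first = v[, 1], last = v[, 2], n_hom = v[, 3])
}

# Poisson upper tail by direct series summation of the density, independent
# of stats::ppois.
oracle_poisson_upper_tail <- function(lambda, observed) {
  if (observed == 0) return(1)
  k <- 0:(observed - 1)
  1 - sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

# A small hand-built genotype matrix: panel positions 100..n*100, focal in
# the middle, everything hom-alt unless overridden.
toy_matrix <- function(gt, af = NULL, pos = NULL, focal_index = NULL,
                       map = genetic_map_uniform(1)) {
  gt <- as.matrix(gt)
  n_sites <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100
  if (is.null(af)) af <- rep(0.3, n_sites)
  if (is.null(focal_index)) focal_index <- (n_sites + 1) %/% 2
  panel <- marker_panel("chr1", pos, rep("A", n_sites), rep("G", n_sites),
                        pop_af = af, cm = map_cm(map, pos))
  genotype_matrix(panel, sprintf("S%d", seq_len(nrow(gt))), gt, focal_index)
}

# Random small instance for oracle-equivalence trials.
random_matrix <- function(n_samples, n_sites, p_missing = 0.05) {
  gt <- matrix(sample(c(0L, 1L, 2L), n_samples * n_sites, replace = TRUE,
                      prob = c(0.35, 0.3, 0.35)), n_samples, n_sites)
  gt[matrix(stats::runif(n_samples * n_sites) < p_missing,
            n_samples, n_sites)] <- NA_integer_
  focal <- (n_sites + 1) %/% 2
  gt[, focal] <- 2L
  toy_matrix(gt, af = stats::runif(n_sites, 0.01, 0.5), focal_index = focal)
}
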