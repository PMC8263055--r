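#' Configuration for a synthetic founder cohort
#'
#' Describes a star-genealogy founder cohort: `n_carriers` unrelated
#' individuals carrying a focal allele inherited from a single founder
#' `generations` ago.  Around the focal variant each founder-descended
#' chromosome retains an ancestral segment whose one-sided genetic length
#' is Exponential(rate = generations) in Morgans, truncated at the region
#' edges; outside the retained segment (and on non-founder chromosomes)
#' alleles are drawn independently per site from the marker allele
#' frequencies (Hardy-Weinberg background, no linkage disequilibrium).
#'
#' @param n_carriers Number of carriers.
#' @param generations Founder age `g`, generations (`>= 0`; `g = 0` means
#'   no recombination has occurred — the full region is ancestral).
#' @param zygosity `"homozygote"` (two founder chromosomes per carrier,
#'   the situation for recessive cases) or `"carrier"` (one founder plus
#'   one background chromosome).
#' @param region_bp Region length, bp.
#' @param n_markers Number of background markers (`>= 2`).
#' @param af_range Population alternate-AF law for background markers:
#'   uniform on this interval (default `c(0.01, 0.5)`).
#' @param map A `genetic_map` (default uniform 1 cM/Mb).
#' @param genotyping_error Per-call probability of flipping a genotype to
#'   one of the other two codes (focal site exempt).
#' @param missing_rate Per-call missingness probability (focal exempt).
#' @param focal_af Population frequency recorded for the focal allele
#'   (default 0.001, a typical rare founder allele).
#' @param chrom Chromosome label for the emitted records.
#' @param seed Master seed; all randomness is derived from it through
#'   fixed per-stage substreams, so outputs are byte-reproducible and
#'   adding stages never perturbs earlier ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_carriers = 7, generations = 311,
                       zygosity = c("homozygote", "carrier"),
                       region_bp = 2e6, n_markers = 2000,
                       af_range = c(0.01, 0.5),
                       map = genetic_map_uniform(1),
                       genotyping_error = 0, missing_rate = 0,
                       focal_af = 0.001, chrom = "chr1", seed = 1) {
  zygosity <- match.arg(zygosity)
  stopifnot(n_carriers >= 1, generations >= 0, region_bp >= 10,
            n_markers >= 2, inherits(map, "genetic_map"))
  if (genotyping_error < 0 || genotyping_error > 1 ||
      missing_rate < 0 || missing_rate > 1 ||
      any(af_range < 0 | af_range > 1) || focal_af < 0 || focal_af > 1)
    stop("all rates and frequencies must lie in [0, 1]")
  if (n_markers > region_bp - 1) stop("more markers than available positions")
  structure(list(n_carriers = as.integer(n_carriers),
                 generations = generations, zygosity = zygosity,
                 region_bp = region_bp, n_markers = as.integer(n_markers),
                 af_range = af_range, map = map,
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate, focal_af = focal_af,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed per-stage substreams derived from the master seed: stage k uses
# seed (master * 7919 + k) mod 2^31-1, so stage order is frozen and new
# stages can only be appended.
substream <- function(seed, stage) {
  set.seed(as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647))
}

#' Simulate a founder cohort with recorded truth
#'
#' Generates the cohort described by a [sim_config()]: a genotype matrix
#' over a random marker panel with the focal variant at the region
#' centre, plus a truth log recording every chromosome's true retained
#' ancestral segment so block delineation and age recovery can be scored
#' against the generating process.  Optionally writes the standard file
#' set (VCF, AF table, genetic-map TSV, truth TSV) to a directory.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Optional directory; when given, `cohort.vcf`, `af.tsv`,
#'   `map.tsv` and `truth.tsv` are written there and their paths returned.
#' @return A list: `genotypes` (a [genotype_matrix()] annotated with AF
#'   and cM), `truth` (data.frame, one row per sample/copy/side with the
#'   true breakpoint bp, retained genetic length in Morgans and a
#'   censored-at-edge flag), `founder` (founder haplotype allele per
#'   marker, 0 = ref, 1 = alt), `af_table`, `config`, and `paths` when
#'   written.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$generations
  focal_pos <- floor(cfg$region_bp / 2)

  substream(cfg$seed, 1)  # marker panel
  pos <- sort(sample.int(cfg$region_bp, min(cfg$region_bp, cfg$n_markers + 10L)))
  pos <- setdiff(pos, focal_pos)
  if (length(pos) < cfg$n_markers) stop("region too small for requested markers")
  pos <- pos[seq_len(cfg$n_markers)]
  af <- stats::runif(cfg$n_markers, cfg$af_range[1], cfg$af_range[2])

  substream(cfg$seed, 2)  # founder haplotype
  founder <- stats::rbinom(cfg$n_markers, 1, af)

  ord <- order(c(pos, focal_pos))
  all_pos <- c(pos, focal_pos)[ord]
  fidx <- which(all_pos == focal_pos)
  all_af <- c(af, cfg$focal_af)[ord]
  all_founder <- c(founder, 1L)[ord]
  ref <- rep("A", length(all_pos)); alt <- rep("G", length(all_pos))
  ref[fidx] <- "G"; alt[fidx] <- "GGCGCGGAGC"

  n_copies <- if (cfg$zygosity == "homozygote") 2L else 1L
  n <- cfg$n_carriers
  samples <- sprintf("S%02d", seq_len(n))

  substream(cfg$seed, 3)  # breakpoints
  draw_len <- function(k) if (g == 0) rep(Inf, k) else stats::rexp(k, rate = g)
  truth <- expand.grid(copy = seq_len(n_copies), sample = samples,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- truth[, c("sample", "copy")]
  nrowt <- nrow(truth)
  len_l <- draw_len(nrowt)   # Morgans
  len_r <- draw_len(nrowt)
  cm_focal <- map_cm(cfg$map, focal_pos)
  cm_max <- map_cm(cfg$map, cfg$region_bp)
  bp_left <- map_bp(cfg$map, pmax(cm_focal - 100 * len_l, 0))
  bp_right <- map_bp(cfg$map, pmin(cm_focal + 100 * len_r, cm_max))
  cens_l <- cm_focal - 100 * len_l <= 0
  cens_r <- cm_focal + 100 * len_r >= cm_max
  truth <- rbind(
    data.frame(truth, side = "left", breakpoint_bp = bp_left,
               length_morgans = pmin(len_l, cm_focal / 100),
               censored = cens_l, stringsAsFactors = FALSE),
    data.frame(truth, side = "right", breakpoint_bp = bp_right,
               length_morgans = pmin(len_r, (cm_max - cm_focal) / 100),
               censored = cens_r, stringsAsFactors = FALSE))
  truth <- truth[order(truth$sample, truth$copy, truth$side), ]
  rownames(truth) <- NULL

  substream(cfg$seed, 4)  # background genotypes
  n_sites <- length(all_pos)
  gt <- matrix(0L, n, n_sites)
  for (i in seq_len(n)) {
    alleles <- matrix(0L, 2L, n_sites)
    for (cp in seq_len(2L)) {
      if (cp <= n_copies) {
        tl <- truth[truth$sample == samples[i] & truth$copy == cp, ]
        lb <- tl$breakpoint_bp[tl$side == "left"]
        rb <- tl$breakpoint_bp[tl$side == "right"]
        on_seg <- all_pos >= lb & all_pos <= rb
      } else {
        on_seg <- rep(FALSE, n_sites)
      }
      bg <- stats::rbinom(n_sites, 1, all_af)
      alleles[cp, ] <- ifelse(on_seg, all_founder, bg)
    }
    gt[i, ] <- alleles[1, ] + alleles[2, ]
  }

  substream(cfg$seed, 5)  # genotyping error
  if (cfg$genotyping_error > 0) {
    flip <- matrix(stats::runif(n * n_sites) < cfg$genotyping_error, n, n_sites)
    flip[, fidx] <- FALSE
    pick <- matrix(stats::runif(n * n_sites), n, n_sites)
    w <- which(flip)
    if (length(w)) {
      others <- vapply(w, function(k) {
        alt_codes <- setdiff(0:2, gt[k])
        alt_codes[1L + (pick[k] > 0.5)]
      }, integer(1))
      gt[w] <- others
    }
  }

  substream(cfg$seed, 6)  # missingness
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * n_sites) < cfg$missing_rate, n, n_sites)
    miss[, fidx] <- FALSE
    gt[miss] <- NA_integer_
  }
  if (cfg$zygosity == "homozygote") gt[, fidx] <- 2L else gt[, fidx] <- 1L

  panel <- marker_panel(cfg$chrom, all_pos, ref, alt, pop_af = all_af,
                        cm = map_cm(cfg$map, all_pos))
  G <- genotype_matrix(panel, samples, gt, fidx)
  af_table <- data.frame(chrom = cfg$chrom, pos = all_pos, ref = ref,
                         alt = alt, af = all_af, stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                  af = file.path(out_dir, "af.tsv"),
                  map = file.path(out_dir, "map.tsv"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_genotype_vcf(G, paths$vcf)
    utils::write.table(af_table, paths$af, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    map_tab <- data.frame(bp = c(0, cfg$region_bp),
                          cm = map_cm(cfg$map, c(0, cfg$region_bp)))
    if (cfg$map$mode == "table")
      map_tab <- data.frame(bp = cfg$map$bp, cm = cfg$map$cm)
    utils::write.table(map_tab, paths$map, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(genotypes = G, truth = truth, founder = all_founder,
       af_table = af_table, config = cfg, paths = paths,
       focal = list(chrom = cfg$chrom, pos = focal_pos,
                    ref = ref[fidx], alt = alt[fidx]))
}

#' Write the canonical small test fixtures
#'
#' Emits the deterministic hand-built VCF/TSV fixtures used by the unit
#' tests — a basic 3-sample/5-site file, an all-missing site, a
#' multi-allelic site, a duplicate physical position, a single-sample ROH
#' run — plus an AF table and genetic-map table, and a manifest TSV with
#' MD5 checksums.
#'
#' @param out_dir Writable output directory (created if absent).
#' @return Character vector of the files written (invisibly), manifest
#'   included.
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("fixture directory not writable: ", out_dir)

  vcf_header <- function(samples, chrom = "chr1") c(
    "##fileformat=VCFv4.2",
    "##source=founderhap-fixtures",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  row <- function(pos, ref, alt, ...) paste("chr1", pos, ".", ref, alt, ".",
                                            "PASS", ".", "GT", ..., sep = "\t")
  files <- character()
  emit <- function(name, lines) {
    path <- file.path(out_dir, name)
    writeLines(lines, path)
    files <<- c(files, path)
    path
  }

  emit("basic.vcf", c(vcf_header(c("S1", "S2", "S3")),
    row(100, "A", "G", "0/0", "0/1", "0/0"),
    row(200, "C", "T", "1/1", "1/1", "1/1"),
    row(300, "G", "GGCGCGGAGC", "1/1", "1/1", "1/1"),
    row(400, "T", "A", "0/1", "0/0", "./."),
    row(500, "A", "C", "1/1", "0/0", "1/1")))

  emit("missing_site.vcf", c(vcf_header(c("S1", "S2")),
    row(100, "A", "G", "1/1", "1/1"),
    row(200, "C", "T", "./.", "./."),
    row(300, "G", "A", "1/1", "1/1")))

  emit("multiallelic.vcf", c(vcf_header(c("S1", "S2")),
    row(100, "A", "G", "1/1", "1/1"),
    row(200, "C", "T,G", "1/2", "0/1"),
    row(300, "G", "A", "0/0", "0/0")))

  emit("duplicate_pos.vcf", c(vcf_header(c("S1", "S2")),
    row(100, "A", "G", "1/1", "1/1"),
    row(200, "C", "T", "0/1", "0/0"),
    row(200, "C", "A", "1/1", "1/1"),
    row(300, "G", "A", "0/0", "0/0")))

  emit("roh.vcf", c(vcf_header("S1"),
    row(100, "A", "G", "0/1"),
    vapply(1:11, function(i) row(100 + i * 100, "A", "G",
                                 if (i %% 2) "1/1" else "0/0"), ""),
    row(1300, "A", "G", "0/1")))

  emit("af.tsv", c("chrom\tpos\tref\talt\taf",
    "chr1\t100\tA\tG\t0.40",
    "chr1\t200\tC\tT\t0.012",
    "chr1\t300\tG\tGGCGCGGAGC\t0.001",
    "chr1\t400\tT\tA\t0.25",
    "chr1\t500\tA\tC\t0.03"))

  emit("map.tsv", c("bp\tcm", "0\t0", "2000000\t3"))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, manifest_path))
}
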