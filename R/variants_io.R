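#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic sites from a region of a VCF (plain or bgzipped) into a
#' [genotype_matrix()] centred on a focal variant.  Parsing is done by
#' \pkg{vcfR}; this function maps GT strings to the four-code scheme
#' (0 hom-ref / 1 het / 2 hom-alt / NA missing), applies the region and
#' multi-allelic policies, and locates the focal site.
#'
#' Regions use 0-based half-open coordinates internally, so a region
#' `chr:start-end` covers 1-based VCF positions `start+1 .. end`.
#'
#' @param vcf_path Path to the VCF file.
#' @param region Region string `"chrom:start-end"` (0-based half-open) or
#'   `NULL` to load the whole file.
#' @param focal Focal variant as `"chrom:pos:ref:alt"` (1-based pos) or a
#'   list with those fields.
#' @param multiallelic `"drop"` (default) removes multi-allelic records;
#'   `"split"` expands them into one biallelic row per alternate allele,
#'   recoding other alternate alleles as reference.
#' @param carriers_only If `TRUE`, restrict to samples homozygous for the
#'   focal alternate allele (see [filter_focal_homozygotes()]).
#' @return A `genotype_matrix`.
#' @export
read_genotype_matrix <- function(vcf_path, region = NULL, focal,
                                 multiallelic = c("drop", "split"),
                                 carriers_only = FALSE) {
  multiallelic <- match.arg(multiallelic)
  focal <- parse_focal(focal)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field: ", vcf_path)

  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- chrom == rg$chrom & pos > rg$start & pos <= rg$end
  }
  if (!any(keep)) stop("region contains no records: ", format_region(region))
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  multi <- grepl(",", alt, fixed = TRUE)
  if (multiallelic == "drop") {
    chrom <- chrom[!multi]; pos <- pos[!multi]; ref <- ref[!multi]
    gt_codes <- code_gt_matrix(gt_raw[!multi, , drop = FALSE], alt_index = 1L,
                               lines = which(!multi))
    alt <- alt[!multi]
  } else {
    rows <- list(); codes <- list()
    for (i in seq_along(pos)) {
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      for (a in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[a],
          stringsAsFactors = FALSE)
        codes[[length(codes) + 1L]] <-
          code_gt_matrix(gt_raw[i, , drop = FALSE], alt_index = a, lines = i)
      }
    }
    tab <- do.call(rbind, rows)
    chrom <- tab$chrom; pos <- tab$pos; ref <- tab$ref; alt <- tab$alt
    gt_codes <- do.call(rbind, codes)
  }
  if (length(pos) == 0L) stop("no biallelic records remain in region")

  ord <- order(pos)
  pos <- pos[ord]; chrom <- chrom[ord]; ref <- ref[ord]; alt <- alt[ord]
  gt_codes <- gt_codes[ord, , drop = FALSE]
  # duplicate physical positions collapse to the first record (deterministic)
  first <- !duplicated(pos)
  pos <- pos[first]; chrom <- chrom[first]; ref <- ref[first]; alt <- alt[first]
  gt_codes <- gt_codes[first, , drop = FALSE]

  fidx <- which(chrom == focal$chrom & pos == focal$pos &
                ref == focal$ref & alt == focal$alt)
  if (length(fidx) != 1L)
    stop(sprintf("focal variant not in region: %s:%s %s>%s",
                 focal$chrom, focal$pos, focal$ref, focal$alt))

  panel <- marker_panel(chrom, pos, ref, alt)
  G <- genotype_matrix(panel, colnames(gt_codes), t(gt_codes), fidx)
  if (carriers_only) G <- filter_focal_homozygotes(G)
  G
}

# GT strings -> codes relative to alternate allele number `alt_index`;
# any other alternate allele counts as reference.
code_gt_matrix <- function(gt_raw, alt_index = 1L, lines = NULL) {
  code1 <- function(g, line) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    suppressWarnings(ai <- as.integer(al))
    if (anyNA(ai))
      stop("malformed GT '", g, "' at VCF record ", line)
    if (length(ai) == 1L) ai <- c(ai, ai)  # haploid call treated as homozygous
    sum(ai == alt_index)
  }
  out <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                dimnames = dimnames(gt_raw))
  if (is.null(lines)) lines <- seq_len(nrow(gt_raw))
  for (i in seq_len(nrow(gt_raw)))
    for (j in seq_len(ncol(gt_raw)))
      out[i, j] <- code1(gt_raw[i, j], lines[i])
  out
}

parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(region)
  }
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", region,
                            "' (expected chrom:start-end)")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

format_region <- function(region) {
  if (is.null(region)) return("<whole file>")
  if (is.list(region)) return(sprintf("%s:%s-%s", region$chrom, region$start, region$end))
  region
}

parse_focal <- function(focal) {
  if (is.list(focal)) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(focal)))
    focal$pos <- as.numeric(focal$pos)
    return(focal)
  }
  parts <- strsplit(focal, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L)
    stop("cannot parse focal '", focal, "' (expected chrom:pos:ref:alt)")
  list(chrom = parts[1], pos = as.numeric(parts[2]),
       ref = parts[3], alt = parts[4])
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Serialises a [genotype_matrix()] with a GT-only FORMAT column.  Used by
#' the cohort simulator and the fixture suite; [read_genotype_matrix()]
#' round-trips the output exactly.
#'
#' @param G A `genotype_matrix`.
#' @param path Output path (`.vcf`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_str <- matrix("./.", ncol(G$gt), nrow(G$gt))
  codes <- t(G$gt)
  gt_str[which(codes == 0L)] <- "0/0"
  gt_str[which(codes == 1L)] <- "0/1"
  gt_str[which(codes == 2L)] <- "1/1"
  p <- G$panel
  body <- paste(p$chrom, format(p$pos, scientific = FALSE, trim = TRUE),
                ".", p$ref, p$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=founderhap",
    sprintf("##contig=<ID=%s>", p$chrom[1]),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population allele-frequency table
#'
#' TSV with header columns `chrom, pos, ref, alt, af` keyed on the full
#' variant description, emulating population-database (e.g. 1000 Genomes)
#' alternate-allele frequency annotations.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five columns.
#' @export
read_af_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c(chrom = "character", ref = "character",
                                          alt = "character"))
  names(tab) <- tolower(names(tab))
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(tab)))
    stop("AF table must have columns chrom,pos,ref,alt,af: ", path)
  if (any(tab$af < 0 | tab$af > 1, na.rm = TRUE))
    stop("AF values must lie in [0, 1]: ", path)
  tab[need]
}

#' Attach allele frequencies and genetic-map coordinates to a panel
#'
#' Joins a population AF table onto the marker panel of a genotype matrix
#' (keyed on chrom, pos, ref, alt; sites without a matching key keep a
#' missing `pop_af`) and fills the `cm` column from a [genetic_map].
#'
#' @param G A `genotype_matrix`.
#' @param af_table Data.frame with columns chrom,pos,ref,alt,af (e.g. from
#'   [read_af_table()]), or `NULL` to leave `pop_af` untouched.
#' @param map A `genetic_map`, or `NULL` to leave `cm` untouched.
#' @return The annotated `genotype_matrix`.
#' @export
attach_annotations <- function(G, af_table = NULL, map = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  panel <- G$panel
  if (!is.null(af_table)) {
    key <- function(ch, p, r, a) paste(ch, p, r, a, sep = "\r")
    idx <- match(key(panel$chrom, panel$pos, panel$ref, panel$alt),
                 key(af_table$chrom, af_table$pos, af_table$ref, af_table$alt))
    panel$pop_af <- ifelse(is.na(idx), NA_real_, af_table$af[idx])
  }
  if (!is.null(map)) panel$cm <- map_cm(map, panel$pos)
  genotype_matrix(panel, G$samples, G$gt, G$focal_index)
}
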