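#' Run the founder-haplotype pipeline end to end
#'
#' Orchestrates load -> annotate -> shared-homozygosity scan -> block
#' delineation -> shared core -> age estimation (-> homozygote-excess
#' test when cohort counts are supplied), writing one reproducible report
#' bundle: `sites.tsv`, `blocks.tsv`, `core.tsv`, `age.json`,
#' `enrichment.json` (optional), `info_content.svg` and `run.log` with
#' the full effective configuration.
#'
#' @param config A named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{vcf}{path to the multi-sample VCF (required)}
#'     \item{focal}{focal variant `"chrom:pos:ref:alt"` (required)}
#'     \item{out}{output directory (required; created if absent)}
#'     \item{region}{optional region `"chrom:start-end"`, 0-based half-open}
#'     \item{af}{optional AF table TSV path}
#'     \item{map}{optional genetic-map TSV path}
#'     \item{map_rate_cm_per_mb}{uniform map rate used when no map table is
#'       given (default 1)}
#'     \item{maf_min, max_missing, boundary}{scan/delineation settings}
#'     \item{mode, level, years_per_generation}{age-model settings}
#'     \item{enrichment}{optional list with `q`, `N`, `observed`, `null`}
#'   }
#' @return Invisibly, a list with `sites`, `blocks`, `core`, `age`,
#'   `enrichment` (or `NULL`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(region = NULL, af = NULL, map = NULL,
                   map_rate_cm_per_mb = 1, maf_min = 0.01, max_missing = 0.2,
                   boundary = "concordant", mode = "homozygote",
                   level = 0.95, years_per_generation = 25,
                   enrichment = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("vcf", "focal", "out"))
    if (is.null(config[[k]])) stop("pipeline config is missing '", k, "'")
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  G <- stage("load", read_genotype_matrix(config$vcf, region = config$region,
                                          focal = config$focal,
                                          carriers_only = TRUE))
  map <- stage("annotate", {
    if (!is.null(config$map)) read_genetic_map(config$map)
    else genetic_map_uniform(config$map_rate_cm_per_mb)
  })
  af_table <- if (!is.null(config$af)) stage("annotate", read_af_table(config$af))
  G <- stage("annotate", attach_annotations(G, af_table = af_table, map = map))

  sites <- stage("scan", scan_shared_homozygosity(G, config$maf_min,
                                                  config$max_missing))
  blocks <- stage("blocks", delineate_blocks(G, maf_min = config$maf_min,
                                             max_missing = config$max_missing,
                                             boundary = config$boundary))
  core <- stage("core", shared_core(blocks))
  obs <- stage("age", physical_to_genetic(blocks, mode = config$mode))
  age <- stage("age", estimate_generations(obs, level = config$level,
                                           years_per_generation =
                                             config$years_per_generation))
  enrich <- NULL
  if (!is.null(config$enrichment)) {
    e <- config$enrichment
    enrich <- stage("enrich", homozygote_excess(e$q, e$N, e$observed,
                                                null = e$null %||% "poisson"))
  }

  paths <- write_report_bundle(config$out, G, sites, blocks, core, age,
                               enrich, config)
  invisible(list(sites = sites, blocks = blocks, core = core, age = age,
                 enrichment = enrich, genotypes = G, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_bundle <- function(out, G, sites, blocks, core, age, enrich,
                                config) {
  tsv <- function(x, name) {
    p <- file.path(out, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list()
  site_tab <- sites
  site_tab$shared_flag <- as.integer(site_tab$shared)
  paths$sites <- tsv(site_tab, "sites.tsv")
  block_tab <- data.frame(sample = blocks$sample,
                          left_bp = blocks$left_bp,
                          right_bp = blocks$right_bp,
                          left_cM = blocks$left_morgans * 100,
                          right_cM = blocks$right_morgans * 100,
                          left_censored = blocks$left_censored,
                          right_censored = blocks$right_censored)
  paths$blocks <- tsv(block_tab, "blocks.tsv")
  paths$core <- tsv(data.frame(chrom = G$panel$chrom[1],
                               start_bp = core$start_bp,
                               end_bp = core$end_bp,
                               length_kb = core$length_kb), "core.tsv")
  paths$age <- file.path(out, "age.json")
  jsonlite::write_json(list(g_hat = age$g_hat, ci_low = age$ci_low,
                            ci_high = age$ci_high, level = age$level,
                            years = age$years, mode = age$mode,
                            model = age$model),
                       paths$age, auto_unbox = TRUE, digits = NA)
  if (!is.null(enrich)) {
    paths$enrichment <- file.path(out, "enrichment.json")
    jsonlite::write_json(list(q = enrich$q, N = enrich$N,
                              expected_hom = enrich$expected_hom,
                              observed_hom = enrich$observed_hom,
                              p_value = enrich$p_value, null = enrich$null),
                         paths$enrichment, auto_unbox = TRUE, digits = NA)
  }
  paths$plot <- file.path(out, "info_content.svg")
  grDevices::svg(paths$plot, width = 7, height = 4)
  tryCatch(plot_information_content(sites, focal_pos = G$panel$pos[G$focal_index]),
           finally = grDevices::dev.off())
  paths$log <- file.path(out, "run.log")
  writeLines(c(
    sprintf("founderhap %s", as.character(utils::packageVersion("founderhap"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "effective config:",
    paste0("  ", names(config), " = ",
           vapply(config, function(v) paste(deparse(v), collapse = " "), ""))),
    paths$log)
  paths
}

#' Information-content versus position plot
#'
#' Plots the reciprocal population allele frequency of each shared
#' homozygous marker against genomic position, the standard visual for a
#' founder haplotype: a spike of rare shared alleles around the focal
#' variant.
#'
#' @param sites Scan report from [scan_shared_homozygosity()].
#' @param focal_pos Optional focal position, drawn as a dashed vertical
#'   line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_information_content <- function(sites, focal_pos = NULL, ...) {
  sh <- sites[sites$shared & !is.na(sites$info_content), ]
  if (nrow(sh) == 0L) {
    graphics::plot(0, 0, type = "n", xlab = "position (Mb)",
                   ylab = "1 / allele frequency", main = "no shared markers")
    return(invisible(NULL))
  }
  graphics::plot(sh$pos / 1e6, sh$info_content, type = "h",
                 xlab = "position (Mb)", ylab = "1 / allele frequency",
                 main = "Shared homozygous markers", ...)
  graphics::points(sh$pos / 1e6, sh$info_content, pch = 16, cex = 0.5)
  if (!is.null(focal_pos))
    graphics::abline(v = focal_pos / 1e6, lty = 2, col = "red")
  invisible(NULL)
}
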