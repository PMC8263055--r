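test_that("a zero-generation cohort is ancestral across the whole region", {
  sim <- simulate_cohort(sim_config(n_carriers = 4, generations = 0,
                                    n_markers = 200, region_bp = 1e6,
                                    seed = 3))
  G <- sim$genotypes
  # every carrier homozygous for the founder allele at every marker
  founder_gt <- 2L * sim$founder
  for (i in seq_along(G$samples))
    expect_equal(unname(G$gt[i, ]), founder_gt)
  expect_true(all(sim$truth$censored))

  blocks <- delineate_blocks(G)
  info <- G$panel$pos[founderhap:::informative_sites(G)]
  expect_true(all(blocks$left_bp == min(info)))
  expect_true(all(blocks$right_bp == max(info)))
  expect_true(all(blocks$left_censored & blocks$right_censored))
  expect_error(estimate_generations(physical_to_genetic(blocks)),
               "age unidentifiable")
})

test_that("the same seed reproduces a byte-identical VCF", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_carriers = 3, n_markers = 100, region_bp = 2e5,
                    genotyping_error = 0.01, missing_rate = 0.02, seed = 9)
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                   unname(tools::md5sum(file.path(d2, "cohort.vcf"))))
  # a different seed changes the data
  simulate_cohort(sim_config(n_carriers = 3, n_markers = 100,
                             region_bp = 2e5, seed = 10), out_dir = d2)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d2, "cohort.vcf"))))
})

test_that("simulated one-sided lengths follow the stated exponential law", {
  # region much longer than 1/g so edge truncation is negligible
  g <- 100
  truth <- do.call(rbind, lapply(1:40, function(s)
    transform(simulate_cohort(sim_config(n_carriers = 5, generations = g,
                                         n_markers = 10, region_bp = 4e7,
                                         seed = 4000 + s))$truth,
              seed = s)))
  expect_lt(mean(truth$censored), 0.01)
  lens <- truth$length_morgans[!truth$censored]
  # per-chromosome one-sided decay at rate g: mean 1/g within MC error
  se <- 1 / (g * sqrt(length(lens)))
  expect_gt(length(lens), 500)
  expect_lt(abs(mean(lens) - 1 / g), 4 * se)

  # homozygote mode: the observed side is the min of two copies, rate 2g
  side_min <- stats::aggregate(length_morgans ~ sample + side + seed,
                               data = truth, FUN = min)
  se2 <- 1 / (2 * g * sqrt(nrow(side_min)))
  expect_lt(abs(mean(side_min$length_morgans) - 1 / (2 * g)), 4 * se2)
})

test_that("genotyping error flips the expected fraction of calls", {
  e <- 0.05
  cfg_clean <- sim_config(n_carriers = 6, generations = 50, n_markers = 800,
                          region_bp = 1e6, seed = 77)
  cfg_noisy <- sim_config(n_carriers = 6, generations = 50, n_markers = 800,
                          region_bp = 1e6, genotyping_error = e, seed = 77)
  clean <- simulate_cohort(cfg_clean)$genotypes$gt
  noisy <- simulate_cohort(cfg_noisy)$genotypes$gt
  flipped <- sum(clean != noisy)
  n_calls <- length(clean) - nrow(clean)  # focal column exempt
  expect_lt(abs(flipped - n_calls * e), 4 * sqrt(n_calls * e * (1 - e)))
  expect_gt(flipped, 0)
})

test_that("missingness hits the requested fraction and spares the focal site", {
  m <- 0.1
  sim <- simulate_cohort(sim_config(n_carriers = 6, n_markers = 800,
                                    region_bp = 1e6, missing_rate = m,
                                    seed = 55))
  gt <- sim$genotypes$gt
  expect_true(all(!is.na(gt[, sim$genotypes$focal_index])))
  frac <- mean(is.na(gt[, -sim$genotypes$focal_index]))
  expect_lt(abs(frac - m), 4 * sqrt(m * (1 - m) / length(gt)))
})

test_that("carrier mode emits heterozygous focal genotypes", {
  sim <- simulate_cohort(sim_config(n_carriers = 5, zygosity = "carrier",
                                    n_markers = 100, region_bp = 2e5,
                                    seed = 21))
  G <- sim$genotypes
  expect_true(all(G$gt[, G$focal_index] == 1L))
  expect_equal(nrow(sim$truth), 5 * 2)  # one founder copy, two sides
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(n_markers = 0), "n_markers")
  expect_error(sim_config(genotyping_error = 1.5), "rates")
  expect_error(sim_config(n_markers = 500, region_bp = 400), "markers")
})

test_that("the fixture suite is complete, deterministic and parseable", {
  d1 <- withr::local_tempdir()
  files <- make_fixture_suite(d1)
  expect_gte(length(files), 7)
  manifest <- utils::read.delim(file.path(d1, "manifest.tsv"))
  expect_gte(nrow(manifest), 6)
  expect_true(all(c("file", "md5", "bytes") %in% names(manifest)))

  d2 <- withr::local_tempdir()
  make_fixture_suite(d2)
  manifest2 <- utils::read.delim(file.path(d2, "manifest.tsv"))
  expect_identical(manifest$md5, manifest2$md5)

  focal_of <- c(basic.vcf = "chr1:300:G:GGCGCGGAGC",
                missing_site.vcf = "chr1:100:A:G",
                multiallelic.vcf = "chr1:100:A:G",
                duplicate_pos.vcf = "chr1:100:A:G",
                roh.vcf = "chr1:200:A:G")
  for (f in names(focal_of)) {
    G <- read_genotype_matrix(file.path(d1, f), focal = focal_of[[f]])
    expect_s3_class(G, "genotype_matrix")
    expect_gte(nrow(G$panel), 2)
  }
})
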