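test_that("information content is the reciprocal of the shared-allele frequency", {
  # 7 carriers all hom-alt at a rare site; hom-ref at a common one
  gt <- matrix(2L, 7, 3)
  gt[, 3] <- 0L
  G <- toy_matrix(gt, af = c(0.012, 0.001, 0.4), focal_index = 2L)
  rep <- scan_shared_homozygosity(G, maf_min = 0.001)
  expect_equal(rep$shared, c(TRUE, TRUE, TRUE))
  expect_equal(rep$shared_allele, c("alt", "alt", "ref"))
  expect_equal(rep$info_content[1], 1 / 0.012, tolerance = 1e-12)
  expect_equal(rep$info_content[1], 83.33, tolerance = 1e-3)
  expect_equal(rep$info_content[3], 1 / 0.6)
  # rare shared alleles (< 5% by default) are flagged for reporting
  expect_equal(rep$highly_informative, c(TRUE, TRUE, FALSE))
})

test_that("a single het breaks sharing; fixed sites have unit information", {
  gt <- matrix(2L, 7, 3)
  gt[4, 3] <- 1L
  G <- toy_matrix(gt, af = c(0.3, 0.001, 0.2), focal_index = 2L)
  rep <- scan_shared_homozygosity(G, maf_min = 0.001)
  expect_false(rep$shared[rep$site == 3])

  # pop_af = 1 is monomorphic-alt: MAF filter must be released to see it,
  # and the reciprocal identity gives information content exactly 1
  G1 <- toy_matrix(matrix(2L, 7, 3), af = c(0.3, 0.001, 1.0), focal_index = 2L)
  rep1 <- scan_shared_homozygosity(G1, maf_min = 0)
  expect_true(rep1$shared[rep1$site == 3])
  expect_equal(rep1$info_content[rep1$site == 3], 1.0)
})

test_that("scan preconditions and degenerate outputs behave as documented", {
  gt <- matrix(2L, 2, 3); gt[2, 2] <- 1L
  G <- toy_matrix(gt, af = c(0.3, 0.3, 0.3), focal_index = 2L)
  expect_error(scan_shared_homozygosity(G), "not homozygous")
  G2 <- toy_matrix(matrix(2L, 2, 3), af = rep(0.001, 3), focal_index = 2L)
  expect_warning(out <- scan_shared_homozygosity(G2, maf_min = 0.01),
                 "no sites pass")
  expect_equal(nrow(out), 0L)
})

test_that("scan agrees with the exhaustive per-site oracle", {
  withr::local_seed(41)
  for (trial in 1:120) {
    G <- random_matrix(sample(1:4, 1), sample(3:10, 1))
    got <- scan_shared_homozygosity(G, maf_min = 0.01, max_missing = 0.99)
    want <- oracle_scan_shared(G$gt, G$panel$pop_af, maf_min = 0.01,
                               max_missing = 0.99)
    expect_equal(got$site, want$site)
    expect_equal(got$shared, want$shared)
    expect_equal(got$shared_allele, want$shared_allele)
  }
})

test_that("fully concordant samples span the whole informative region", {
  gt <- matrix(2L, 3, 7)
  G <- toy_matrix(gt, af = rep(0.3, 7), focal_index = 4L)
  b <- delineate_block(G, "S1")
  expect_equal(b$left_bp, 100)   # first informative marker
  expect_equal(b$right_bp, 700)  # last informative marker
  expect_true(b$left_censored && b$right_censored)
})

test_that("an immediately discordant flank pins the bound to the focal position", {
  gt <- matrix(2L, 3, 5)
  gt[1, 2] <- 1L  # S1 het at the first informative site left of focal
  G <- toy_matrix(gt, af = rep(0.3, 5), focal_index = 3L)
  b <- delineate_block(G, "S1")
  expect_equal(b$left_bp, 300)  # focal position
  expect_equal(b$left_morgans, 0)
  expect_false(b$left_censored)
  expect_equal(b$right_bp, 500)
})

test_that("sub-MAF and missing calls never terminate a block", {
  gt <- matrix(2L, 3, 7)
  gt[1, 2] <- 1L            # het at a rare site: transparent for delineation
  gt[1, 6] <- NA_integer_   # missing: transparent
  G <- toy_matrix(gt, af = c(0.3, 0.005, 0.3, 0.3, 0.3, 0.3, 0.3),
                  focal_index = 4L)
  b <- delineate_block(G, "S1")
  expect_equal(b$left_bp, 100)
  expect_equal(b$right_bp, 700)
})

test_that("midpoint boundary lands between the last concordant and first discordant marker", {
  gt <- matrix(2L, 3, 5)
  gt[1, 5] <- 1L
  G <- toy_matrix(gt, af = rep(0.3, 5), focal_index = 3L)
  bc <- delineate_block(G, "S1", boundary = "concordant")
  bm <- delineate_block(G, "S1", boundary = "midpoint")
  expect_equal(bc$right_bp, 400)
  expect_equal(bm$right_bp, 450)
  expect_equal(bm$left_bp, bc$left_bp)  # censored side unaffected
})

test_that("delineated lengths match simulation truth within one marker interval", {
  sim <- simulate_cohort(sim_config(n_carriers = 7, generations = 300,
                                    seed = 42))
  G <- sim$genotypes
  blocks <- delineate_blocks(G)
  truth <- sim$truth
  # truth per (sample, side): observed min-of-two-copies genetic length
  pos <- G$panel$pos
  max_gap_cm <- max(diff(G$panel$cm))
  ok <- 0; total <- 0
  for (s in blocks$sample) for (side in c("left", "right")) {
    t_len <- min(truth$length_morgans[truth$sample == s & truth$side == side])
    b <- blocks[blocks$sample == s, ]
    d_len <- if (side == "left") b$left_morgans else b$right_morgans
    total <- total + 1
    if (abs(d_len - t_len) <= max_gap_cm / 100 + 1e-12) ok <- ok + 1
  }
  expect_gte(ok / total, 0.95)
})

test_that("shared core is the interval intersection and sits inside every block", {
  blocks <- data.frame(left_bp = c(100e3, 300e3), right_bp = c(900e3, 1200e3))
  core <- shared_core(blocks)
  expect_equal(core$start_bp, 300e3)
  expect_equal(core$end_bp, 900e3)
  expect_equal(core$length_kb, 600)
  # idempotence on identical blocks
  same <- data.frame(left_bp = c(10, 10), right_bp = c(50, 50))
  expect_equal(shared_core(same)$span_bp, 40)
  expect_error(shared_core(data.frame(left_bp = 100, right_bp = 50)[0, ]),
               "at least one")
  expect_error(shared_core(data.frame(left_bp = c(1, 100),
                                      right_bp = c(50, 200))),
               "empty intersection")
})

test_that("core is contained in every block and grows under carrier removal", {
  withr::local_seed(7)
  for (s in 1:12) {
    sim <- simulate_cohort(sim_config(n_carriers = 5, generations = 400,
                                      n_markers = 400, region_bp = 1e6,
                                      seed = 1000 + s))
    G <- sim$genotypes
    blocks <- delineate_blocks(G)
    core <- shared_core(blocks)
    expect_true(all(blocks$left_bp <= core$start_bp &
                      core$end_bp <= blocks$right_bp))
    # drop one carrier: the remaining blocks' intersection can only widen
    Gsub <- genotype_matrix(G$panel, G$samples[-1], G$gt[-1, , drop = FALSE],
                            G$focal_index)
    core_sub <- shared_core(delineate_blocks(Gsub))
    expect_lte(core_sub$start_bp, core$start_bp)
    expect_gte(core_sub$end_bp, core$end_bp)
  }
})

test_that("both core conventions are available and midpoint is the wider one", {
  sim <- simulate_cohort(sim_config(seed = 5))
  G <- sim$genotypes
  core_c <- shared_core(delineate_blocks(G, boundary = "concordant"))
  core_m <- shared_core(delineate_blocks(G, boundary = "midpoint"))
  expect_gte(core_m$length_kb, core_c$length_kb)
})
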