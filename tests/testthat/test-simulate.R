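test_that("the generated genome is deterministic, bounded and well formed", {
  g1 <- simulate_genome(10, seed = 5)
  g2 <- simulate_genome(10, seed = 5)
  expect_identical(g1, g2)

  g0 <- simulate_genome(0, seed = 1)
  expect_equal(nrow(g0$tss), 0)
  expect_equal(nrow(g0$sites), 0)

  g <- simulate_genome(60, seed = 2)
  expect_equal(nrow(validate_regions(g$promoters, g$chrom_sizes)), 0)
  expect_equal(nrow(validate_regions(g$sites, g$chrom_sizes)), 0)
  # promoters non-overlapping within a chromosome
  by_chr <- split(g$promoters, g$promoters$chrom)
  for (p in by_chr) {
    p <- p[order(p$start), ]
    if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  # sites sit inside their promoter
  expect_true(all(g$sites$start >= 0))
})

test_that("CpG counts per promoter follow the configured Poisson mean", {
  g <- simulate_genome(1000, mean_cpg = 5, seed = 77)
  per_prom <- table(factor(g$sites$gene_id, levels = g$tss$gene_id))
  m <- mean(per_prom)
  se <- sqrt(5 / 1000)
  # site dedup/truncation can only remove a few sites; allow 3 SE around 5
  expect_lt(abs(m - 5), 3 * se + 0.2)
})

test_that("intensity generation is exchangeable without effects, scaled with them", {
  g <- simulate_genome(50, seed = 1)
  s1 <- simulate_intensities(g, frac_planted = 0, seed = 2)
  s2 <- simulate_intensities(g, frac_planted = 0, seed = 2)
  expect_identical(s1$profiles, s2$profiles)
  expect_equal(nrow(s1$truth), 0)

  m <- as.matrix(s1$profiles[, -1])
  ratio <- mean(m[, s1$samples$group == "case"]) /
    mean(m[, s1$samples$group == "control"])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("planted units show the configured fold at Poisson noise", {
  sim <- simulate_unit_matrix(1000, frac_planted = 0.5, effect = 2,
                              depth = 200, noise = "poisson", seed = 12)
  hyper <- sim$truth$region_id[sim$truth$direction == "hyper"]
  expect_gte(length(hyper), 200)
  m <- as.matrix(sim$mat[, -1])
  rows <- match(hyper, sim$mat$region_id)
  is_case <- sim$samples$group == "case"
  ratio <- rowMeans(m[rows, is_case]) / rowMeans(m[rows, !is_case])
  expect_gt(mean(ratio), 1.8)
  expect_lt(mean(ratio), 2.2)
})

test_that("near-zero dispersion approaches Poisson variance", {
  sim <- simulate_smallrna(n_features = 1000, dispersion = 1e-6,
                           frac_planted = 0, seed = 30)
  m <- as.matrix(sim$counts[, -1])
  # pool per-feature variance/mean ratios; lognormal baseline varies across
  # features, so compare within feature across samples
  vm <- apply(m, 1, stats::var) / pmax(rowMeans(m), 1e-9)
  expect_lt(abs(median(vm) - 1), 0.25)

  sim_nb <- simulate_smallrna(n_features = 1000, dispersion = 0.3,
                              frac_planted = 0, seed = 30)
  m2 <- as.matrix(sim_nb$counts[, -1])
  vm2 <- apply(m2, 1, stats::var) / pmax(rowMeans(m2), 1e-9)
  expect_gt(median(vm2), median(vm) * 2)
})

test_that("reads realise the site profiles and round-trip through BED", {
  g <- simulate_genome(8, seed = 41)
  sim <- simulate_intensities(g, depth = 20, output = "reads", seed = 42)
  # conservation: per sample, total read bases = column sums of profiles
  for (s in sim$samples$sample_id) {
    rd <- sim$reads[sim$reads$sample_id == s, ]
    expect_equal(sum(rd$end - rd$start), sum(sim$profiles[[s]]))
  }
  # deterministic
  sim2 <- simulate_intensities(g, depth = 20, output = "reads", seed = 42)
  expect_identical(sim$reads, sim2$reads)

  # BED round trip
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(dplyr::mutate(g$sites, strand = "."), path)
  back <- read_bed(path, role = "cpg_site")
  expect_equal(back$chrom, g$sites$chrom)
  expect_equal(back$start, g$sites$start)
  expect_equal(back$end, g$sites$end)
  expect_equal(back$region_id, g$sites$region_id)

  # intensity TSV round trip
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_tsv(sim$profiles, path2)
  expect_equal(read_intensity_tsv(path2), sim$profiles)
})

test_that("small-RNA truth bookkeeping is consistent", {
  sim <- simulate_smallrna(n_features = 200, frac_planted = 0.2, effect = 3,
                           seed = 15)
  expect_equal(nrow(sim$truth), 40)
  expect_true(all(sim$truth$feature_id %in% sim$counts$feature_id))
  expect_true(all(sim$truth$effect[sim$truth$direction == "up"] == 3))
  expect_true(all(sim$truth$effect[sim$truth$direction == "down"] == 1 / 3))
  expect_equal(nrow(simulate_smallrna(50, frac_planted = 0, seed = 1)$truth), 0)

  props <- table(sim$subtypes$subtype) / 200
  expect_gt(props[["tRF"]], props[["rRNA"]])
})
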