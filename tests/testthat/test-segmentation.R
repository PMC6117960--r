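make_sites <- function(pos, chrom = "chr1") {
  tibble::tibble(region_id = paste0("s", seq_along(pos)), chrom = chrom,
                 start = pos, end = pos + 1, role = "cpg_site")
}

test_that("sites merge into intervals at the gap threshold", {
  iv <- merge_cpg_sites(make_sites(c(100, 110, 500)), gap_threshold = 200)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$site_ids[[1]], c("s1", "s2"))
  expect_equal(iv$site_ids[[2]], "s3")
  expect_equal(iv$start, c(100, 500))
  expect_equal(iv$end, c(111, 501))

  expect_equal(nrow(merge_cpg_sites(make_sites(numeric(0)))), 0)

  one <- merge_cpg_sites(make_sites(c(0, 50, 100)), gap_threshold = 300)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_sites, 3)

  expect_error(merge_cpg_sites(make_sites(c(500, 100))), "sorted")
  expect_error(merge_cpg_sites(make_sites(c(100, 100))), "duplicate")
})

test_that("adjacent correlations are Pearson r with a zero-variance convention", {
  profiles <- tibble::tibble(
    region_id = c("s1", "s2", "s3", "s4"),
    a = c(1, 2, 4, 5), b = c(2, 4, 3, 5), c = c(3, 6, 2, 5), d = c(4, 8, 1, 5))
  r <- adjacent_correlations(c("s1", "s2", "s3"), profiles)
  expect_equal(r$r, c(1, -1))
  # zero variance -> 0 by convention
  r2 <- adjacent_correlations(c("s3", "s4"), profiles)
  expect_equal(r2$r, 0)
  # single site -> no pairs
  expect_equal(nrow(adjacent_correlations("s1", profiles)), 0)
  expect_error(adjacent_correlations(c("s1", "s2"), profiles[, 1:3]),
               "at least 4 samples")
})

test_that("units break at sub-threshold correlations", {
  sites <- make_sites(c(100, 120, 400))
  iv <- merge_cpg_sites(sites, gap_threshold = 400)
  corr <- tibble::tibble(site_a = c("s1", "s2"), site_b = c("s2", "s3"),
                         r = c(1, -1))
  units <- split_units(iv[1, ], corr, sites, corr_threshold = 0.3)
  expect_equal(length(units$site_ids), 2)
  expect_equal(units$site_ids[[1]], c("s1", "s2"))
  expect_equal(units$site_ids[[2]], "s3")
  expect_equal(units$start, c(100, 400))

  all_joined <- split_units(iv[1, ],
                            dplyr::mutate(corr, r = c(0.9, 0.5)), sites)
  expect_equal(nrow(all_joined), 1)
  all_split <- split_units(iv[1, ],
                           dplyr::mutate(corr, r = c(0.1, -0.2)), sites)
  expect_equal(nrow(all_split), 3)
})

test_that("unit segmentation matches the exhaustive cut-set oracle", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    pos <- cumsum(c(100, sample(20:100, n - 1, replace = TRUE)))
    sites <- make_sites(pos)
    iv <- merge_cpg_sites(sites, gap_threshold = 300)
    expect_equal(nrow(iv), 1)
    r <- runif(n - 1, -1, 1)
    corr <- tibble::tibble(site_a = sites$region_id[-n],
                           site_b = sites$region_id[-1], r = r)
    units <- split_units(iv[1, ], corr, sites, corr_threshold = 0.3)
    membership <- rep(seq_len(nrow(units)), lengths(units$site_ids))
    expect_equal(membership, unname(oracle_split(r, 0.3)))
    # partition property: member multiset preserved in order
    expect_equal(unlist(units$site_ids), sites$region_id)
  }
})

test_that("raising the threshold never decreases the number of units", {
  set.seed(5)
  n <- 10
  sites <- make_sites(cumsum(c(100, sample(20:100, n - 1, replace = TRUE))))
  iv <- merge_cpg_sites(sites, gap_threshold = 300)
  r <- runif(n - 1, -1, 1)
  corr <- tibble::tibble(site_a = sites$region_id[-n],
                         site_b = sites$region_id[-1], r = r)
  counts <- vapply(seq(-1, 1, by = 0.1), function(th)
    nrow(split_units(iv[1, ], corr, sites, corr_threshold = th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("full segmentation is idempotent and label-blind by design", {
  set.seed(9)
  g <- simulate_genome(20, seed = 4)
  sim <- simulate_intensities(g, samples_per_group = 3, depth = 50, seed = 4)
  units <- segment_methylation_units(g$sites, sim$profiles)
  # partition: every site in exactly one unit
  expect_setequal(unlist(units$site_ids), g$sites$region_id)
  expect_equal(length(unlist(units$site_ids)), nrow(g$sites))

  # single-unit output re-segments to itself (correlations unchanged)
  u1 <- units[units$n_sites > 2, ][1, ]
  sub_sites <- g$sites[g$sites$region_id %in% u1$site_ids[[1]], ]
  again <- segment_methylation_units(sub_sites, sim$profiles)
  expect_equal(nrow(again), 1)
  expect_equal(again$site_ids[[1]], u1$site_ids[[1]])

  # unit profiles sum member sites
  up <- unit_profiles(units, sim$profiles)
  i <- match(u1$unit_id, up$region_id)
  expect_equal(up$case_1[i],
               sum(sim$profiles$case_1[match(u1$site_ids[[1]],
                                             sim$profiles$region_id)]))
})
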