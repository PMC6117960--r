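test_that("label assignments enumerate when few, sample deterministically when many", {
  a <- label_assignments(4, 2, n_perm = 1000)
  expect_true(attr(a, "enumerated"))
  expect_equal(ncol(a), 6) # C(4,2)
  expect_true(all(colSums(a) == 2))
  expect_equal(nrow(unique(t(a))), 6) # all distinct

  b1 <- label_assignments(12, 6, n_perm = 50, seed = 3)
  b2 <- label_assignments(12, 6, n_perm = 50, seed = 3)
  expect_false(attr(b1, "enumerated"))
  expect_identical(b1, b2)
  expect_true(all(colSums(b1) == 6))
})

test_that("one-sided p-values use the add-one tail estimator with ties inward", {
  expect_equal(one_sided_p(5, c(1, 2, 3), "hyper"), 0.25)
  expect_equal(one_sided_p(3, c(1, 2, 3), "hyper"), 0.5)   # tie counts in
  expect_equal(one_sided_p(0, c(1, 2, 3), "hyper"), 1)
  expect_equal(one_sided_p(0, c(1, 2, 3), "hypo"), 0.25)
  expect_equal(one_sided_p(1, c(1, 2, 3), "hypo"), 0.5)
  expect_error(one_sided_p(1, numeric(0), "hyper"), "empty null")
})

test_that("BH correction reproduces the step-up hand computation", {
  expect_equal(correct_multiple(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(correct_multiple(0.2), 0.2)
  expect_equal(correct_multiple(rep(1, 5)), rep(1, 5))
  expect_equal(correct_multiple(c(0.01, 0.04), method = "bonferroni"),
               c(0.02, 0.08))
  expect_error(correct_multiple(c(0, 0.5)))
})

test_that("the stratified null matches a direct enumeration oracle (2v2)", {
  fx <- tiny_matrix()
  nl <- build_null(fx$mat, fx$samples, fx$regions, n_perm = 1000,
                   n_strata = 1)
  expect_true(nl$enumerated)
  expect_equal(nl$n_assignments, 6)

  sc <- score_regions(fx$mat, fx$samples, regions = fx$regions)
  direction <- ifelse(sc$M > 0, "hyper", "hypo")
  p_pkg <- vapply(seq_len(nrow(sc)), function(i)
    one_sided_p(sc$M[i], nl$null[[nl$strata[i]]], direction[i]), numeric(1))

  values <- as.matrix(fx$mat[, fx$samples$sample_id])
  p_oracle <- oracle_perm_p(values, fx$samples$group, fx$regions$n_sites,
                            sc$M, direction)
  expect_equal(p_pkg, p_oracle)
})

test_that("sampled and enumerated p-values agree whenever enumeration triggers", {
  fx <- tiny_matrix()
  n6 <- build_null(fx$mat, fx$samples, fx$regions, n_perm = 6, n_strata = 1)
  n1000 <- build_null(fx$mat, fx$samples, fx$regions, n_perm = 1000,
                      n_strata = 1)
  expect_identical(n6$null, n1000$null)

  sim <- simulate_unit_matrix(50, samples_per_group = 3, seed = 2)
  a <- build_null(sim$mat, sim$samples, sim$regions, n_perm = 20, seed = 5)
  b <- build_null(sim$mat, sim$samples, sim$regions, n_perm = 500, seed = 99)
  expect_identical(a$null, b$null) # both enumerate C(6,3)=20, seed-free
})

test_that("exclusion shrinks the null pool and full exclusion errors", {
  fx <- tiny_matrix()
  full <- build_null(fx$mat, fx$samples, fx$regions, n_strata = 1)
  part <- build_null(fx$mat, fx$samples, fx$regions, n_strata = 1,
                     exclude = c("r1", "r2"))
  expect_equal(length(part$null[[1]]), length(full$null[[1]]) - 2 * 6)
  expect_equal(part$n_excluded, 2)
  expect_error(build_null(fx$mat, fx$samples, fx$regions,
                          exclude = fx$mat$region_id), "empty null")
  expect_error(build_null(fx$mat, fx$samples, fx$regions, exclude = "nope"),
               "unknown region ids")
})

test_that("the pooled null is centred under exchangeable data", {
  sim <- simulate_unit_matrix(400, frac_planted = 0, seed = 21)
  nl <- build_null(sim$mat, sim$samples, sim$regions, seed = 21)
  pooled <- unlist(nl$null)
  se <- stats::sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled)), 3 * se + 1e-3)
})

test_that("iterative detection is quiet on null data and stops at alpha -> 0", {
  sim <- simulate_unit_matrix(300, frac_planted = 0, seed = 8)
  fit <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 8)
  expect_true(fit$converged)
  expect_lte(sum(fit$calls$significant), 3)

  tiny_alpha <- iterative_detect(sim$mat, sim$samples, sim$regions,
                                 alpha0 = 1e-12, seed = 8)
  expect_equal(sum(tiny_alpha$calls$significant), 0)
  expect_equal(nrow(tiny_alpha$iterations), 1)
})

test_that("identical config and seed give identical call tables", {
  sim <- simulate_unit_matrix(200, frac_planted = 0.1, effect = 4, seed = 13)
  f1 <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 13)
  f2 <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 13)
  expect_identical(f1$calls, f2$calls)
  expect_identical(f1$iterations, f2$iterations)
})

test_that("events-exclusive iteration never loses true positives vs single pass", {
  worse <- 0
  for (seed in 1:20) {
    sim <- simulate_unit_matrix(300, frac_planted = 0.2, effect = 6,
                                depth = 200, seed = seed)
    it <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = seed)
    sp <- single_pass_detect(sim$mat, sim$samples, sim$regions, seed = seed)
    tp_it <- length(intersect(it$calls$region_id[it$calls$significant],
                              sim$truth$region_id))
    tp_sp <- length(intersect(sp$calls$region_id[sp$calls$significant],
                              sim$truth$region_id))
    if (tp_it < tp_sp) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("empirical FDR stays near the nominal level on planted mixtures", {
  fdp <- vapply(1:20, function(seed) {
    sim <- simulate_unit_matrix(1000, frac_planted = 0.1, effect = 6,
                                depth = 200, seed = 100 + seed)
    fit <- iterative_detect(sim$mat, sim$samples, sim$regions,
                            seed = 100 + seed)
    called <- fit$calls$region_id[fit$calls$significant]
    if (length(called) == 0) return(0)
    mean(!(called %in% sim$truth$region_id))
  }, numeric(1))
  expect_lte(mean(fdp), 1.5 * 0.05)
})

test_that("the region-resampling null mode runs and stays calibrated", {
  sim <- simulate_unit_matrix(300, frac_planted = 0, seed = 31)
  fit <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 31,
                          null_mode = "region_resample")
  expect_true(fit$converged)
  expect_lte(sum(fit$calls$significant), 5)
})

test_that("tidy, glance and plots expose the fitted object", {
  sim <- simulate_unit_matrix(100, frac_planted = 0.1, effect = 5, seed = 17)
  fit <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 17)
  td <- tidy(fit)
  expect_true(all(c("region_id", "f", "M", "direction", "p", "q",
                    "significant", "iteration_called") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_regions, 100)
  expect_equal(gl$n_significant, sum(td$significant))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_null_distribution(fit), "ggplot")
  expect_output(print(fit), "regions tested")
})
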