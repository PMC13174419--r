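iso_row <- function(met, areas, sample) {
  tibble::tibble(metabolite = met, kegg_id = NA_character_,
                 mass_shift = seq_along(areas) - 1L, sample_id = sample,
                 area = areas)
}

test_that("fractional labeling reproduces worked closed-form cases", {
  tab <- dplyr::bind_rows(iso_row("a", c(100, 0, 0), "s1"),
                          iso_row("b", c(25, 25, 50), "s1"))
  fl <- fractional_labeling(tab)
  a <- fl[fl$metabolite == "a", ]
  expect_equal(a$frac, c(1, 0, 0))
  expect_equal(unique(a$labeled_fraction), 0)
  expect_equal(unique(a$mean_enrichment), 0)
  b <- fl[fl$metabolite == "b", ]
  expect_equal(b$frac, c(0.25, 0.25, 0.5))
  expect_equal(unique(b$labeled_fraction), 0.75)
  expect_equal(unique(b$mean_enrichment), 0.625)
  expect_equal(unique(b$pool), 100)
})

test_that("fractions are homogeneous of degree zero in the areas", {
  set.seed(12)
  tab <- dplyr::bind_rows(iso_row("a", stats::runif(4, 1, 100), "s1"),
                          iso_row("a", stats::runif(4, 1, 100), "s2"))
  fl <- fractional_labeling(tab)
  scaled <- tab
  scale_by <- ifelse(scaled$sample_id == "s1", 17.3, 0.002)
  scaled$area <- scaled$area * scale_by
  fl2 <- fractional_labeling(scaled)
  expect_equal(fl2$frac, fl$frac, tolerance = 1e-12)
  expect_equal(fl2$labeled_fraction, fl$labeled_fraction, tolerance = 1e-12)
  expect_equal(fl2$mean_enrichment, fl$mean_enrichment, tolerance = 1e-12)
  expect_equal(fl2$pool, fl$pool * scale_by, tolerance = 1e-12)
  # fraction tests are invariant under the rescaling
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         condition = c("control", "control"))
  expect_equal(fractional_labeling(scaled)$frac,
               fractional_labeling(tab)$frac)
})

test_that("fractions always sum to one; unmonitored channels fill with zero area", {
  set.seed(13)
  sim <- generate_tracing(list(m1 = list(control = c(0.2, 0.3, 0.5),
                                         tumor = c(0.1, 0.1, 0.8)),
                               m2 = list(control = c(0.7, 0.3),
                                         tumor = c(0.5, 0.5))),
                          noise_cv = 0.2, seed = 13)
  fl <- fractional_labeling(sim$table)
  sums <- tapply(fl$frac, paste(fl$metabolite, fl$sample_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # drop one channel: it comes back as area 0 and fractions renormalize
  tab <- sim$table[!(sim$table$metabolite == "m1" &
                       sim$table$mass_shift == 1 &
                       sim$table$sample_id == "control_1"), ]
  fl2 <- fractional_labeling(tab, n_max = c(m1 = 2L, m2 = 1L))
  expect_equal(attr(fl2, "n_filled"), 1)
  filled <- fl2[fl2$metabolite == "m1" & fl2$sample_id == "control_1", ]
  expect_equal(filled$area[filled$mass_shift == 1], 0)
  expect_equal(sum(filled$frac), 1, tolerance = 1e-12)
})

test_that("zero pools are flagged undefined and skipped by tests with a warning", {
  tab <- dplyr::bind_rows(iso_row("dead", c(0, 0), "s1"),
                          iso_row("dead", c(0, 0), "s2"),
                          iso_row("dead", c(0, 0), "s3"),
                          iso_row("dead", c(0, 0), "s4"),
                          iso_row("live", c(1, 1), "s1"),
                          iso_row("live", c(2, 1), "s2"),
                          iso_row("live", c(1, 3), "s3"),
                          iso_row("live", c(2, 2), "s4"))
  fl <- fractional_labeling(tab)
  expect_true(all(!fl$defined[fl$metabolite == "dead"]))
  expect_true(all(is.na(fl$frac[fl$metabolite == "dead"])))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         condition = rep(c("control", "tumor"), each = 2))
  expect_warning(ft <- fraction_test(fl, meta, "control", "tumor"), "dead")
  expect_false("dead" %in% ft$tests$metabolite)
})

test_that("pool partition matches welch_test per isotopologue and handles the null", {
  set.seed(14)
  sim <- generate_tracing(list(m = list(control = c(0.5, 0.3, 0.2),
                                        tumor = c(0.2, 0.3, 0.5))),
                          n_per_group = 4, noise_cv = 0.15, seed = 14)
  pp <- pool_partition(sim$table, sim$metadata, "control", "tumor")
  # cross-check each M+i row against welch_test on an area matrix
  wide <- tidyr::pivot_wider(sim$table[, c("metabolite", "mass_shift",
                                           "sample_id", "area")],
                             names_from = "sample_id", values_from = "area")
  cond <- stats::setNames(sim$metadata$condition, sim$metadata$sample_id)
  m <- as.matrix(wide[, names(cond)])
  rownames(m) <- paste0("M+", wide$mass_shift)
  d <- welch_test(make_im(m, cond, scale = "log"), "control", "tumor")
  for (i in 0:2) {
    q <- paste0("M+", i)
    expect_equal(pp$p_value[pp$quantity == q],
                 d$p_value[d$metabolite_id == q], tolerance = 1e-12)
  }
  # labeled pool = sum of M+1..: check value consistency
  lab <- pp[pp$quantity == "labeled", ]
  expect_equal(lab$mean_ref,
               sum(d$mean_ref[d$metabolite_id != "M+0"]), tolerance = 1e-12)

  # identical tables in both conditions -> all deltas 0, p 1 by convention
  tab_null <- dplyr::bind_rows(
    iso_row("m", c(10, 20), "c1"), iso_row("m", c(11, 19), "c2"),
    iso_row("m", c(10, 20), "t1"), iso_row("m", c(11, 19), "t2"))
  meta_null <- tibble::tibble(sample_id = c("c1", "c2", "t1", "t2"),
                              condition = c("control", "control",
                                            "tumor", "tumor"))
  pp0 <- pool_partition(tab_null, meta_null, "control", "tumor")
  expect_true(all(pp0$delta == 0))
  expect_true(all(pp0$p_value == 1))
  expect_error(pool_partition(tab_null, meta_null, "control", "nope"),
               "unknown condition")
})

test_that("fraction tests detect planted labeling shifts and conserve totals", {
  set.seed(15)
  sim <- generate_tracing(list(m = list(control = c(0.9, 0.1),
                                        tumor = c(0.4, 0.6))),
                          n_per_group = 6, noise_cv = 0.1, seed = 15)
  fl <- fractional_labeling(sim$table)
  ft <- fraction_test(fl, sim$metadata, "control", "tumor")
  t_m0 <- ft$tests[ft$tests$quantity == "f0", ]
  t_m1 <- ft$tests[ft$tests$quantity == "f1", ]
  t_l <- ft$tests[ft$tests$quantity == "L", ]
  expect_identical(t_m0$direction, "down")
  expect_identical(t_m1$direction, "up")
  expect_identical(t_l$direction, "up")
  expect_true(ft$reciprocity$reciprocal)
  # fraction deltas balance to zero
  dsum <- sum(ft$tests$delta[grepl("^f", ft$tests$quantity)])
  expect_lt(abs(dsum), 1e-9)

  # identical labeling in both conditions: L test is null
  sim0 <- generate_tracing(list(m = list(control = c(0.7, 0.3),
                                         tumor = c(0.7, 0.3))),
                           n_per_group = 6, noise_cv = 0, pool_cv = 0,
                           seed = 16)
  fl0 <- fractional_labeling(sim0$table)
  ft0 <- fraction_test(fl0, sim0$metadata, "control", "tumor")
  l0 <- ft0$tests[ft0$tests$quantity == "L", ]
  expect_equal(l0$p_value, 1)
  expect_false(ft0$reciprocity$reciprocal)
})

test_that("replicate-mean fractions converge to the planted labeling as noise shrinks", {
  pi_true <- c(0.25, 0.25, 0.5)
  err_at <- vapply(c(0, 0.05, 0.2), function(cv) {
    sim <- generate_tracing(list(m = list(control = pi_true,
                                          tumor = pi_true)),
                            n_per_group = 12, noise_cv = cv, seed = 77)
    fl <- fractional_labeling(sim$table)
    est <- tapply(fl$frac, fl$mass_shift, mean)
    max(abs(est - pi_true))
  }, double(1))
  expect_lt(err_at[1], 1e-12)
  expect_lt(err_at[2], 0.02)
  expect_lt(err_at[3], 0.08)
})

test_that("enrichment discontinuity localizes the planted drain edge", {
  # uniform enrichment: all edge scores are exactly zero without noise
  pi_u <- list(control = c(0.2, 0.2, 0.6), tumor = c(0.2, 0.2, 0.6))
  sim_u <- generate_tracing(list(a = pi_u, b = pi_u, c = pi_u),
                            n_per_group = 3, noise_cv = 0, seed = 21)
  fl_u <- fractional_labeling(sim_u$table)
  d_u <- enrichment_discontinuity(fl_u, c("a", "b", "c"), sim_u$metadata,
                                  "tumor", n_boot = 50, seed = 1)
  expect_equal(d_u$edges$score, c(0, 0))
  expect_true(is.na(d_u$candidate_edge))

  # planted drain: E = (0.8, 0.8, 0.3, 0.3) -> argmax at edge 2
  hi <- list(tumor = c(0.1, 0.2, 0.7), control = c(0.1, 0.2, 0.7))  # E=0.8
  lo <- list(tumor = c(0.5, 0.4, 0.1), control = c(0.5, 0.4, 0.1))  # E=0.3
  sim_d <- generate_tracing(list(m1 = hi, m2 = hi, m3 = lo, m4 = lo),
                            n_per_group = 6, noise_cv = 0.1, seed = 22)
  fl_d <- fractional_labeling(sim_d$table)
  d_d <- enrichment_discontinuity(fl_d, paste0("m", 1:4), sim_d$metadata,
                                  "tumor", n_boot = 200, seed = 2)
  expect_equal(d_d$candidate_edge, 2)
  expect_gt(d_d$edges$score[2], 0.3)
  expect_gt(d_d$edges$ci_lower[2], 0)
  # bootstrap is seeded
  d_d2 <- enrichment_discontinuity(fl_d, paste0("m", 1:4), sim_d$metadata,
                                   "tumor", n_boot = 200, seed = 2)
  expect_identical(d_d$edges, d_d2$edges)

  expect_error(enrichment_discontinuity(fl_d, c("m1", "ghost"),
                                        sim_d$metadata, "tumor"),
               "ghost")
})
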