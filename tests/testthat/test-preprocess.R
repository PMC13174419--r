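test_that("missingness filter keeps a metabolite iff missing < tau in some condition", {
  # 10 samples per condition so missing fractions are exact
  cond <- two_groups(10, 10)
  base <- matrix(1, 3, 20, dimnames = list(c("keep", "drop", "boundary"),
                                           names(cond)))
  base["keep", 1] <- NA                   # 10% in control, 50% in tumor
  base["keep", 11:15] <- NA
  base["drop", c(1:3, 11:13)] <- NA       # 30% in both
  base["boundary", c(1:2, 11:12)] <- NA   # exactly 20% in both
  im <- make_im(base, cond)
  out <- filter_missingness(im, tau = 0.2)
  expect_identical(out$metabolite_id, "keep")
  expect_error(filter_missingness(im, tau = 0))
  one_cond <- make_im(base, stats::setNames(rep("a", 20), names(cond)))
  expect_error(filter_missingness(one_cond, 0.2), "2 conditions")
})

test_that("KEGG mapping drops unmapped metabolites and keeps duplicates", {
  cond <- two_groups(2, 2)
  m <- matrix(1:20 * 1.0, 5, 4,
              dimnames = list(paste0("met_", 1:5), names(cond)))
  im <- make_im(m, cond)
  id_map <- tibble::tibble(metabolite_id = c("met_1", "met_2", "met_4"),
                           kegg_id = c("C00041", "C00041", "C00022"))
  out <- map_kegg(im, id_map)
  expect_identical(out$metabolite_id, c("met_1", "met_2", "met_4"))
  expect_equal(sum(out$kegg_id == "C00041"), 2)
  expect_warning(
    map_kegg(im, tibble::tibble(metabolite_id = "x", kegg_id = "C1")),
    "no metabolites")
})

test_that("deduplication follows the stated rules exactly", {
  cond <- c(n1 = "normal", n2 = "normal", n3 = "normal",
            t1 = "tumor", t2 = "tumor")
  m <- rbind(a1 = c(8, 8, 8, 8, 8),
             a2 = c(6.5, 6.5, 6.5, 6.5, 6.5),
             b1 = c(1, 1.2, 1.4, 9, 9),      # normal variance 0.04
             b2 = c(1, 2, 3, 9, 9))          # normal variance 1
  colnames(m) <- names(cond)
  im <- make_im(m, cond, kegg = c("C1", "C1", "C2", "C2"))
  hm <- deduplicate(im, "higher_mean")
  expect_identical(hm$metabolite_id[hm$kegg_id == "C1"], "a1")
  lv <- deduplicate(im, "lowest_variance_in_normal")
  expect_identical(lv$metabolite_id[lv$kegg_id == "C2"], "b1")
  expect_equal(nrow(hm), 2)

  # without a normal condition the variance rule errors
  m_anon <- m; colnames(m_anon) <- NULL
  im2 <- make_im(m_anon, two_groups(3, 2), kegg = c("C1", "C1", "C2", "C2"))
  expect_error(deduplicate(im2, "lowest_variance_in_normal"), "normal")

  # no duplicates: identity
  im3 <- make_im(m, cond, kegg = paste0("C", 1:4))
  expect_identical(deduplicate(im3, "higher_mean")$metabolite_id,
                   rownames(m))
})

test_that("log transform respects scale state, missingness and zero policy", {
  cond <- two_groups(2, 2)
  m <- matrix(c(100, 10, NA, 1000, 100, 1, 10, 1), 2, 4,
              dimnames = list(c("a", "b"), names(cond)))
  im <- make_im(m, cond)
  lg <- log_transform(im, base = "10")
  expect_equal(im_values(lg)["a", "r1"], 2)
  expect_true(is.na(im_values(lg)["a", "r2"]))
  expect_identical(im_scale(lg), "log10")
  expect_error(log_transform(lg, "10"), "scale")

  m0 <- m; m0["b", 1] <- 0
  im0 <- make_im(m0, cond)
  expect_error(log_transform(im0), "`b`.*`r1`|r1.*b")
  lg0 <- log_transform(im0, zeros = "missing")
  expect_true(is.na(im_values(lg0)["b", "r1"]))
})

test_that("QRILC recovers censored-normal parameters and truncates draws", {
  # Monte-Carlo oracle: standard-normal log-intensities censored below the
  # 30th percentile must give back mu ~ 0, sigma ~ 1
  set.seed(42)
  n <- 5000
  cond <- two_groups(2, 2)
  m <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(NULL, names(cond)))
  for (j in 1:4) m[m[, j] < stats::quantile(m[, j], 0.3), j] <- NA
  im <- make_im(m, cond, scale = "log")
  res <- impute_qrilc(im, seed = 7)
  expect_true(all(abs(res$model$mu_hat) < 0.05))
  expect_true(all(abs(res$model$sigma_hat - 1) < 0.05))
  imp <- im_values(res$matrix)
  expect_false(anyNA(imp))
  for (j in 1:4) {
    imputed <- imp[is.na(m[, j]), j]
    expect_lte(max(imputed), res$model$censor_point[j])
  }
  # deterministic under a fixed seed
  res2 <- impute_qrilc(im, seed = 7)
  expect_identical(im_values(res$matrix), im_values(res2$matrix))
  res3 <- impute_qrilc(im, seed = 8)
  expect_false(identical(im_values(res$matrix), im_values(res3$matrix)))
})

test_that("QRILC leaves complete samples unchanged and enforces preconditions", {
  cond <- two_groups(2, 2)
  set.seed(1)
  m <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, names(cond)))
  m[1:3, 1] <- NA
  im <- make_im(m, cond, scale = "log")
  res <- impute_qrilc(im, seed = 1)
  expect_equal(unname(im_values(res$matrix)[, 2:4]), unname(m[, 2:4]))
  expect_equal(res$model$n_imputed, c(3L, 0L, 0L, 0L))

  # mostly-missing sample is rejected with advice
  m2 <- m; m2[1:8, 2] <- NA
  expect_error(impute_qrilc(make_im(m2, cond, scale = "log")),
               "observed")
  # raw scale rejected
  expect_error(impute_qrilc(make_im(abs(m), cond, scale = "raw")), "scale")
})

test_that("median normalization centers samples and is shift-invariant", {
  cond <- two_groups(2, 2)
  set.seed(2)
  m <- matrix(stats::rnorm(20, 5), 5, 4, dimnames = list(NULL, names(cond)))
  im <- make_im(m, cond, scale = "log")
  out <- median_normalize(im)
  expect_identical(im_scale(out), "median_centered")
  expect_equal(unname(apply(im_values(out), 2, stats::median)), rep(0, 4))

  # adding a constant to one sample leaves its centered values unchanged
  m_shift <- m; m_shift[, 1] <- m[, 1] + 7.5
  out_shift <- median_normalize(make_im(m_shift, cond, scale = "log"))
  expect_equal(im_values(out_shift)[, 1], im_values(out)[, 1])

  # constant sample maps to all zeros
  m_const <- m; m_const[, 2] <- 3
  out_const <- median_normalize(make_im(m_const, cond, scale = "log"))
  expect_true(all(im_values(out_const)[, 2] == 0))

  m_na <- m; m_na[1, 1] <- NA
  expect_error(median_normalize(make_im(m_na, cond, scale = "log")),
               "missing")
})

test_that("the composed pipeline preserves identity/order and row-count monotonicity", {
  sim <- generate_steady_state(n_metabolites = 150, n_per_group = 5,
                               effect = c(pw = 1), n_duplicates = 4,
                               seed = 31)
  res <- preprocess_pipeline(sim$matrix, sim$truth$kegg_map,
                             analysis_config(seed = 31))
  n0 <- nrow(sim$matrix)
  n_imp <- nrow(res$imputed)
  expect_lte(n_imp, n0)
  expect_identical(res$imputed$metabolite_id,
                   res$median_centered$metabolite_id)
  # surviving rows keep their input order
  expect_identical(res$imputed$metabolite_id,
                   sim$matrix$metabolite_id[sim$matrix$metabolite_id %in%
                                              res$imputed$metabolite_id])
  expect_false(anyNA(im_values(res$imputed)))
  expect_equal(anyDuplicated(res$imputed$kegg_id), 0)
  # provenance records every stage
  expect_true(any(grepl("filter_missingness", im_provenance(res$imputed))))
  expect_true(any(grepl("impute_qrilc", im_provenance(res$imputed))))
})

test_that("imputed values sit in the left tail of each sample's observed distribution", {
  sim <- generate_steady_state(n_metabolites = 400, n_per_group = 4,
                               q_c = 0.25, seed = 17)
  lg <- log_transform(sim$matrix)
  res <- impute_qrilc(lg, seed = 17)
  m_obs <- im_values(lg)
  m_imp <- im_values(res$matrix)
  for (j in seq_len(ncol(m_obs))) {
    was_missing <- is.na(m_obs[, j])
    if (!any(was_missing)) next
    # stochastic left-tail dominance: imputed median below observed median
    expect_lt(stats::median(m_imp[was_missing, j]),
              stats::median(m_obs[!was_missing, j]))
  }
})
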