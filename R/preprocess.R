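#' Filter metabolites by per-condition missingness
#'
#' A metabolite is retained iff its missing fraction is strictly below `tau`
#' in at least one condition. Row order is preserved.
#'
#' @param x an [intensity_matrix] on the raw or log scale with >= 2
#'   conditions.
#' @param tau missingness threshold in (0,1); default 0.2.
#' @return the filtered `intensity_matrix`.
#' @export
filter_missingness <- function(x, tau = 0.2) {
  stopifnot(tau > 0, tau < 1)
  stop_wrong_scale(x, c("raw", "log", "log10"), "filter_missingness")
  cond <- im_conditions(x)
  levels <- unique(cond)
  if (length(levels) < 2) {
    stop("filter_missingness requires >= 2 conditions", call. = FALSE)
  }
  m <- im_values(x)
  keep_any <- rep(FALSE, nrow(m))
  for (lv in levels) {
    cols <- names(cond)[cond == lv]
    if (length(cols) == 0) stop("condition `", lv, "` has zero samples",
                                call. = FALSE)
    miss_frac <- rowMeans(is.na(m[, cols, drop = FALSE]))
    keep_any <- keep_any | (miss_frac < tau)
  }
  im_keep_rows(x, keep_any,
               log_line = sprintf(
                 "filter_missingness: tau=%g, removed %d of %d metabolites",
                 tau, sum(!keep_any), nrow(m)))
}

#' Map metabolites to KEGG compound ids and drop the unmapped
#'
#' Metabolites absent from the map (or mapped to NA) are removed. Several
#' metabolites may map to one KEGG id; duplicates are retained here and
#' resolved by [deduplicate()].
#'
#' @param x an [intensity_matrix].
#' @param id_map a data frame with columns `metabolite_id`, `kegg_id`.
#' @return the mapped `intensity_matrix` with `kegg_id` populated.
#' @export
map_kegg <- function(x, id_map) {
  stopifnot(all(c("metabolite_id", "kegg_id") %in% names(id_map)))
  id_map <- id_map[!is.na(id_map$kegg_id) & nzchar(id_map$kegg_id), ]
  lookup <- stats::setNames(id_map$kegg_id, id_map$metabolite_id)
  kegg <- unname(lookup[x$metabolite_id])
  keep <- !is.na(kegg)
  if (!any(keep)) warning("no metabolites mapped to KEGG ids", call. = FALSE)
  vals <- tibble::as_tibble(unclass(x))
  vals$kegg_id <- kegg
  vals <- vals[keep, , drop = FALSE]
  ndup <- sum(duplicated(vals$kegg_id))
  im_update(x, values = vals,
            log_line = sprintf(
              "map_kegg: %d of %d mapped (%d duplicate KEGG ids pending dedup)",
              sum(keep), length(keep), ndup))
}

#' Resolve metabolites that map to the same KEGG id
#'
#' `"higher_mean"` keeps, per KEGG id, the row with the greatest mean over all
#' non-missing values (the convention for fly SRM panels);
#' `"lowest_variance_in_normal"` keeps the row with the smallest variance over
#' non-missing values in the `"normal"`-condition samples (the convention for
#' human cancer panels). Ties keep the first row in input order.
#'
#' @param x an [intensity_matrix] with `kegg_id` populated.
#' @param rule `"higher_mean"` or `"lowest_variance_in_normal"`.
#' @return an `intensity_matrix` with exactly one row per KEGG id.
#' @export
deduplicate <- function(x, rule = c("higher_mean",
                                    "lowest_variance_in_normal")) {
  rule <- match.arg(rule)
  if (any(is.na(x$kegg_id))) {
    stop("deduplicate requires kegg_id populated (run map_kegg first)",
         call. = FALSE)
  }
  m <- im_values(x)
  cond <- im_conditions(x)
  if (rule == "lowest_variance_in_normal") {
    normal_cols <- names(cond)[cond == "normal"]
    if (length(normal_cols) == 0) {
      stop("dedup rule `lowest_variance_in_normal` requires a `normal` condition",
           call. = FALSE)
    }
    score <- -apply(m[, normal_cols, drop = FALSE], 1,
                    function(v) stats::var(v[!is.na(v)]))
  } else {
    score <- rowMeans(m, na.rm = TRUE)
  }
  # keep, within each kegg_id, the row with the highest score (first on ties)
  ord <- order(match(x$kegg_id, unique(x$kegg_id)), -score,
               seq_len(nrow(x)))
  first <- !duplicated(x$kegg_id[ord])
  keep_rows <- sort(ord[first])
  im_keep_rows(x, keep_rows,
               log_line = sprintf("deduplicate: rule=%s, %d -> %d rows",
                                  rule, nrow(x), length(keep_rows)))
}

#' Log-transform raw intensities
#'
#' @param x an [intensity_matrix] on the raw scale.
#' @param base `"e"` (natural log) or `"10"`.
#' @param zeros `"error"` (default): an observed 0 is an error naming the
#'   cell; `"missing"`: observed zeros are converted to missing before the
#'   transform, on the view that an SRM zero is a below-detection-limit
#'   measurement.
#' @return the matrix on scale `"log"` or `"log10"`; missing stays missing.
#' @export
log_transform <- function(x, base = c("e", "10"),
                          zeros = c("error", "missing")) {
  base <- match.arg(base)
  zeros <- match.arg(zeros)
  stop_wrong_scale(x, "raw", "log_transform")
  m <- im_values(x)
  n_zero <- 0L
  zero <- which(!is.na(m) & m == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    if (zeros == "error") {
      stop(sprintf("observed zero intensity at metabolite `%s`, sample `%s`",
                   rownames(m)[zero[1, 1]], colnames(m)[zero[1, 2]]),
           call. = FALSE)
    }
    m[zero] <- NA
    n_zero <- nrow(zero)
  }
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative intensity at metabolite `%s`, sample `%s`",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]),
         call. = FALSE)
  }
  out <- if (base == "e") log(m) else log10(m)
  im_set_values(x, out, scale = if (base == "e") "log" else "log10",
                log_line = sprintf(
                  "log_transform: base=%s (%d zeros set missing)",
                  base, n_zero))
}

#' Impute left-censored missing values (QRILC)
#'
#' Quantile-regression imputation of left-censored data, fitted per sample
#' (column), matching a per-run limit of detection. For each sample with
#' observed fraction `p_obs`:
#'
#' 1. The sorted observed log-intensities are regressed against
#'    standard-normal quantiles of an equally spaced probability grid
#'    spanning `(1 - p_obs + eps, 1 - eps)` (eps = 0.001, one point per
#'    observed value), estimating the mean `mu` and sd `sigma` of the full,
#'    uncensored distribution from the straight part of the Q-Q line.
#' 2. Each missing value is drawn independently from
#'    `Normal(mu, tune_sigma * sigma)` truncated above at the estimated
#'    censoring point `Q(1 - p_obs) = mu + sigma * qnorm(1 - p_obs)`.
#'
#' @param x an [intensity_matrix] on the log or log10 scale; every sample
#'   needs >= 4 observed values.
#' @param tune_sigma positive multiplier on `sigma` for the draws (default 1).
#' @param seed integer seed; fixed seed gives identical imputations.
#' @param min_observed_frac samples with `p_obs` below this bound (default
#'   0.3) raise an error advising stronger filtering.
#' @return a list: `matrix` (no missing values) and `model`, a tibble with
#'   one row per sample (`mu_hat`, `sigma_hat`, `p_obs`, `censor_point`,
#'   `n_imputed`).
#' @export
impute_qrilc <- function(x, tune_sigma = 1.0, seed = 1L,
                         min_observed_frac = 0.3) {
  stop_wrong_scale(x, c("log", "log10"), "impute_qrilc")
  stopifnot(tune_sigma > 0)
  m <- im_values(x)
  n <- nrow(m)
  eps <- 0.001
  set.seed(as.integer(seed))
  model <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- which(!is.na(v))
    if (length(obs) < 4) {
      stop("sample `", colnames(m)[j], "` has fewer than 4 observed values",
           call. = FALSE)
    }
    p_obs <- length(obs) / n
    if (p_obs < min_observed_frac) {
      stop(sprintf(
        paste0("sample `%s` has only %.0f%% observed values; QRILC needs >= ",
               "%.0f%% - filter metabolites more aggressively first"),
        colnames(m)[j], 100 * p_obs, 100 * min_observed_frac), call. = FALSE)
    }
    probs <- seq((1 - p_obs) + eps, 1 - eps, length.out = length(obs))
    q <- stats::qnorm(probs)
    y <- sort(v[obs])
    fit <- stats::lm.fit(cbind(1, q), y)
    mu_hat <- fit$coefficients[[1]]
    sigma_hat <- fit$coefficients[[2]]
    if (!is.finite(sigma_hat) || sigma_hat <= 0) {
      stop("estimated sigma <= 0 in sample `", colnames(m)[j], "`",
           call. = FALSE)
    }
    cens <- mu_hat + sigma_hat * stats::qnorm(1 - p_obs)
    n_miss <- n - length(obs)
    if (n_miss > 0) {
      s <- tune_sigma * sigma_hat
      upper <- stats::pnorm((cens - mu_hat) / s)
      u <- stats::runif(n_miss, 0, upper)
      m[is.na(v), j] <- mu_hat + s * stats::qnorm(u)
    }
    model[[j]] <- tibble::tibble(
      sample_id = colnames(m)[j], mu_hat = mu_hat, sigma_hat = sigma_hat,
      p_obs = p_obs, censor_point = cens, n_imputed = n_miss)
  }
  model <- dplyr::bind_rows(model)
  out <- im_set_values(x, m,
                       log_line = sprintf(
                         "impute_qrilc: tune_sigma=%g, seed=%d, imputed %d values",
                         tune_sigma, as.integer(seed), sum(model$n_imputed)))
  list(matrix = out, model = model)
}

#' Median-center each sample
#'
#' Subtracts the per-sample median so metabolites at the sample median map to
#' 0, below-median metabolites to negative values, above-median to positive.
#'
#' @param x an [intensity_matrix] on the log or log10 scale with no missing
#'   values (impute first).
#' @return the matrix on scale `"median_centered"`.
#' @export
median_normalize <- function(x) {
  stop_wrong_scale(x, c("log", "log10"), "median_normalize")
  m <- im_values(x)
  if (anyNA(m)) stop("median_normalize requires no missing values",
                     call. = FALSE)
  med <- apply(m, 2, stats::median)
  out <- sweep(m, 2, med, "-")
  im_set_values(x, out, scale = "median_centered",
                log_line = "median_normalize: per-sample median subtracted")
}

#' Run the full steady-state preprocessing chain
#'
#' filter -> KEGG map -> deduplicate -> log transform -> QRILC impute ->
#' median-center, in the order the stages are meant to compose. Both the
#' imputed matrix (the enrichment input) and the median-centered matrix (the
#' display/relative-abundance input) are returned.
#'
#' @param x a raw-scale [intensity_matrix].
#' @param id_map metabolite -> KEGG map (data frame).
#' @param config an [analysis_config()].
#' @param log_base `"e"` or `"10"`.
#' @param zeros passed to [log_transform()].
#' @return a list: `imputed` and `median_centered` intensity matrices, plus
#'   the QRILC `model` tibble.
#' @export
preprocess_pipeline <- function(x, id_map, config = analysis_config(),
                                log_base = c("e", "10"),
                                zeros = c("error", "missing")) {
  log_base <- match.arg(log_base)
  x <- filter_missingness(x, tau = config$missingness_threshold)
  x <- map_kegg(x, id_map)
  x <- deduplicate(x, rule = config$dedup_rule)
  x <- log_transform(x, base = log_base, zeros = match.arg(zeros))
  imp <- impute_qrilc(x, tune_sigma = config$qrilc_tune_sigma,
                      seed = config$seed)
  list(imputed = imp$matrix,
       median_centered = median_normalize(imp$matrix),
       model = imp$model)
}
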