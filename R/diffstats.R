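#' Welch two-group test per metabolite
#'
#' Unequal-variance two-sided t test of treatment against reference for every
#' metabolite: `t = delta / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom, sample sd on the `n - 1`
#' denominator. P values are unadjusted (a Benjamini-Hochberg column `p_adj`
#' is provided but never drives the significance flag). Metabolites where
#' both groups have zero variance and equal means are degenerate: `p = 1`,
#' direction `ns`, flagged. Metabolites with < 2 non-missing values in either
#' group get `p = NA` and are flagged.
#'
#' @param x an [intensity_matrix].
#' @param reference condition label of the reference group.
#' @param treatment condition label of the treatment group.
#' @param alpha significance level for the flag (default 0.05).
#' @return a `diff_result`: a tibble with one row per metabolite
#'   (`metabolite_id`, `kegg_id`, `mean_ref`, `mean_treat`, `delta`,
#'   `statistic`, `df`, `p_value`, `p_adj`, `significant`,
#'   `direction` in up/down/ns, `degenerate`), with `alpha`, `reference`
#'   and `treatment` attributes.
#' @export
welch_test <- function(x, reference, treatment, alpha = 0.05) {
  cond <- im_conditions(x)
  for (lv in c(reference, treatment)) {
    if (!lv %in% cond) stop("unknown condition label `", lv, "`",
                            call. = FALSE)
  }
  m <- im_values(x)
  ref_cols <- names(cond)[cond == reference]
  trt_cols <- names(cond)[cond == treatment]
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    welch_stat(m[i, ref_cols][!is.na(m[i, ref_cols])],
               m[i, trt_cols][!is.na(m[i, trt_cols])])
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(
    out,
    metabolite_id = x$metabolite_id,
    kegg_id = x$kegg_id,
    .before = 1
  )
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$direction <- dplyr::case_when(
    out$significant & out$delta > 0 ~ "up",
    out$significant & out$delta < 0 ~ "down",
    .default = "ns"
  )
  structure(out, class = c("diff_result", class(out)),
            alpha = alpha, reference = reference, treatment = treatment)
}

# Welch statistic on two numeric vectors (reference, treatment).
welch_stat <- function(ref, trt) {
  n1 <- length(ref); n2 <- length(trt)
  mean_ref <- if (n1 > 0) mean(ref) else NA_real_
  mean_trt <- if (n2 > 0) mean(trt) else NA_real_
  delta <- mean_trt - mean_ref
  if (n1 < 2 || n2 < 2) {
    return(tibble::tibble(mean_ref = mean_ref, mean_treat = mean_trt,
                          delta = delta, statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, degenerate = TRUE))
  }
  v1 <- stats::var(ref); v2 <- stats::var(trt)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # zero variance in both groups: p = 1 when means agree (no evidence),
    # p = 0 when they differ (infinite t); both flagged degenerate
    p <- if (delta == 0) 1 else 0
    return(tibble::tibble(mean_ref = mean_ref, mean_treat = mean_trt,
                          delta = delta, statistic = NA_real_, df = NA_real_,
                          p_value = p, degenerate = TRUE))
  }
  t_stat <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(mean_ref = mean_ref, mean_treat = mean_trt, delta = delta,
                 statistic = t_stat, df = df, p_value = p,
                 degenerate = FALSE)
}

#' Z-score each metabolite across samples
#'
#' Per row: `(x - row mean) / row sd` (sd on `n - 1`), the display transform
#' behind row-scaled heatmaps. Constant rows are emitted as all zero and
#' flagged in the provenance log.
#'
#' @param x an [intensity_matrix] with no missing values.
#' @return an `intensity_matrix` on scale `"zscore"` (a terminal display
#'   scale: no further pipeline operation accepts it).
#' @export
row_zscore <- function(x) {
  m <- im_values(x)
  if (anyNA(m)) stop("row_zscore requires no missing values", call. = FALSE)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  const <- sd == 0 | is.na(sd)
  sd[const] <- 1
  out <- sweep(sweep(m, 1, mu, "-"), 1, sd, "/")
  out[const, ] <- 0
  im_set_values(x, out, scale = "zscore",
                log_line = sprintf("row_zscore: %d constant rows set to 0",
                                   sum(const)))
}

#' Log2 fold change of group means
#'
#' @param x a raw-scale [intensity_matrix].
#' @param reference reference condition label.
#' @param treatment treatment condition label.
#' @return a tibble `metabolite_id`, `kegg_id`, `log2_fc` =
#'   `log2(mean_treatment / mean_reference)` over non-missing values.
#' @export
log2_fold_change <- function(x, reference, treatment) {
  stop_wrong_scale(x, "raw", "log2_fold_change")
  cond <- im_conditions(x)
  m <- im_values(x)
  ref_cols <- names(cond)[cond == reference]
  trt_cols <- names(cond)[cond == treatment]
  mean_ref <- rowMeans(m[, ref_cols, drop = FALSE], na.rm = TRUE)
  mean_trt <- rowMeans(m[, trt_cols, drop = FALSE], na.rm = TRUE)
  if (any(mean_ref == 0 | mean_trt == 0, na.rm = TRUE)) {
    bad <- x$metabolite_id[which(mean_ref == 0 | mean_trt == 0)[1]]
    stop("zero group mean for metabolite `", bad, "`", call. = FALSE)
  }
  tibble::tibble(metabolite_id = x$metabolite_id, kegg_id = x$kegg_id,
                 log2_fc = unname(log2(mean_trt / mean_ref)))
}

#' @method tidy diff_result
#' @export
tidy.diff_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance diff_result
#' @export
glance.diff_result <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_degenerate = sum(x$degenerate),
    alpha = attr(x, "alpha"),
    reference = attr(x, "reference"),
    treatment = attr(x, "treatment")
  )
}
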