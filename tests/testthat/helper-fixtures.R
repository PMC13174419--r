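# Small in-code fixtures shared across tests.

# Intensity matrix from a plain numeric matrix (rows = metabolites).
make_im <- function(m, conditions, scale = "raw", kegg = NULL) {
  vals <- tibble::tibble(metabolite_id = rownames(m) %||%
                           paste0("met_", seq_len(nrow(m))))
  if (!is.null(kegg)) vals$kegg_id <- kegg
  if (is.null(colnames(m))) colnames(m) <- names(conditions)
  vals <- dplyr::bind_cols(vals, tibble::as_tibble(m))
  intensity_matrix(vals, conditions = conditions, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-condition label vector: s1..sn reference, t1..tn treatment.
two_groups <- function(n_ref = 3, n_trt = 3, reference = "control",
                       treatment = "tumor") {
  stats::setNames(rep(c(reference, treatment), c(n_ref, n_trt)),
                  c(paste0("r", seq_len(n_ref)), paste0("t", seq_len(n_trt))))
}

# A diff_result built directly from per-kegg (delta, p) pairs, for testing
# enrichment operations in isolation.
make_diff <- function(kegg, delta, p, alpha = 0.05) {
  structure(
    tibble::tibble(metabolite_id = paste0("m_", kegg), kegg_id = kegg,
                   mean_ref = 0, mean_treat = delta, delta = delta,
                   statistic = NA_real_, df = NA_real_, p_value = p,
                   p_adj = stats::p.adjust(p, "BH"),
                   significant = !is.na(p) & p < alpha,
                   direction = dplyr::case_when(
                     !is.na(p) & p < alpha & delta > 0 ~ "up",
                     !is.na(p) & p < alpha & delta < 0 ~ "down",
                     .default = "ns"),
                   degenerate = FALSE),
    class = c("diff_result", class(tibble::tibble())),
    alpha = alpha, reference = "control", treatment = "tumor")
}

# Brute-force hypergeometric upper tail by enumerating every placement of the
# K significant metabolites among N; pathway = the first m ids.
ora_bruteforce <- function(N, m, K, k) {
  if (K == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, K)
  hits <- colSums(subsets <= m)
  mean(hits >= k)
}
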