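#' Pathway over-representation analysis (hypergeometric ORA)
#'
#' Tests, per pathway, whether its measured members are over-represented among
#' the alpha-significant metabolites. The background `N` is all tested
#' metabolites (KEGG-mapped, with a defined p value); `K` the significant
#' ones; `m` the pathway members in the background; `k` the pathway members
#' among the significant. The upper-tail p is
#' `P[X >= k] = sum_{j >= k} C(m,j) C(N-m, K-j) / C(N,K)`. Results are sorted
#' by ascending p, ties broken by descending enrichment ratio
#' `(k/m)/(K/N)`, then by name.
#'
#' @param diff a `diff_result` from [welch_test()] restricted to KEGG-mapped
#'   metabolites.
#' @param pathways named list of KEGG compound id vectors (see
#'   [read_pathways_gmt()]).
#' @param alpha significance level defining the significant set (defaults to
#'   the alpha used in `diff`).
#' @param min_members pathways with fewer than this many measured members are
#'   dropped (default 2).
#' @return an `enrichment_result` tibble: `pathway`, `k`, `m`, `K`, `N`,
#'   `p_value`, `enrichment_ratio`, `rank`.
#' @export
ora <- function(diff, pathways, alpha = attr(diff, "alpha"),
                min_members = 2) {
  tested <- diff[!is.na(diff$p_value) & !is.na(diff$kegg_id), ]
  background <- unique(tested$kegg_id)
  N <- length(background)
  sig <- unique(tested$kegg_id[tested$p_value < alpha])
  K <- length(sig)
  if (K == 0) warning("no significant metabolites: all ORA p values are 1",
                      call. = FALSE)
  rows <- purrr::imap(pathways, function(members, nm) {
    in_bg <- intersect(unique(members), background)
    m <- length(in_bg)
    if (m < min_members) return(NULL)
    k <- length(intersect(in_bg, sig))
    p <- stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
    ratio <- if (K > 0) (k / m) / (K / N) else 0
    tibble::tibble(pathway = nm, k = k, m = m, K = K, N = N,
                   p_value = p, enrichment_ratio = ratio)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pathway = character(), k = integer(),
                          m = integer(), K = integer(), N = integer(),
                          p_value = double(), enrichment_ratio = double())
  }
  out <- out[order(out$p_value, -out$enrichment_ratio, out$pathway), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("enrichment_result", class(out)), alpha = alpha)
}

#' Differential-abundance (DA) score per pathway
#'
#' Summarizes the net direction of metabolite changes within each pathway:
#' `S = (U - D) / T`, where `U`/`D` are the pathway members significantly up
#' and down (from the `direction` flags of the differential result) and `T`
#' the members measured. `S` lies in `[-1, 1]`; pathways with no measured
#' members get `S = NA` and are flagged `undefined`.
#'
#' @inheritParams ora
#' @return a `da_score` tibble: `pathway`, `n_up`, `n_down`, `n_measured`,
#'   `score`, `undefined`.
#' @export
da_score <- function(diff, pathways, alpha = attr(diff, "alpha")) {
  tested <- diff[!is.na(diff$p_value) & !is.na(diff$kegg_id), ]
  sig_dir <- dplyr::case_when(
    tested$p_value < alpha & tested$delta > 0 ~ 1,
    tested$p_value < alpha & tested$delta < 0 ~ -1,
    .default = 0
  )
  dir_by_kegg <- stats::setNames(sig_dir, tested$kegg_id)
  rows <- purrr::imap(pathways, function(members, nm) {
    measured <- intersect(unique(members), names(dir_by_kegg))
    t_n <- length(measured)
    u <- sum(dir_by_kegg[measured] == 1)
    d <- sum(dir_by_kegg[measured] == -1)
    tibble::tibble(pathway = nm, n_up = u, n_down = d, n_measured = t_n,
                   score = if (t_n > 0) (u - d) / t_n else NA_real_,
                   undefined = t_n == 0)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("da_score", class(out)), alpha = alpha)
}

#' Top-k pathways by enrichment rank
#'
#' @param results an `enrichment_result` (already sorted by [ora()]).
#' @param k how many pathway names to return.
#' @return the first `min(k, nrow)` pathway names, order preserved.
#' @export
top_k_pathways <- function(results, k) {
  stopifnot(k >= 1)
  utils::head(results$pathway, k)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(x)

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(n_pathways = nrow(x),
                 n_significant = sum(x$p_value < attr(x, "alpha")),
                 alpha = attr(x, "alpha"),
                 background = if (nrow(x) > 0) x$N[1] else NA_integer_)
}

#' @method tidy da_score
#' @export
tidy.da_score <- function(x, ...) tibble::as_tibble(x)
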