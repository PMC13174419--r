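#' Shared top-enriched pathways between a reference and comparison studies
#'
#' Intersects the reference top-k pathway list with each study's top-k list,
#' and counts how many reference-top pathways appear in at least `t` studies,
#' for every threshold `t = 1..n_studies` (the default display convention is
#' `t = 1`, i.e. "shared with at least one study").
#'
#' @param ref_top ordered character vector of the reference study's top
#'   pathways (e.g. from [top_k_pathways()]); must be non-empty.
#' @param study_tops named (or unnamed) list of ordered top-pathway vectors,
#'   one per comparison study.
#' @return a list: `shared` (per study, the intersection in reference order),
#'   `count_by_threshold` (tibble `threshold`, `n_shared`), and
#'   `shared_any` (reference-top pathways shared with >= 1 study).
#' @export
shared_enriched <- function(ref_top, study_tops) {
  if (length(ref_top) == 0) stop("reference top-pathway list is empty",
                                 call. = FALSE)
  if (is.null(names(study_tops))) {
    names(study_tops) <- paste0("study_", seq_along(study_tops))
  }
  shared <- purrr::map(study_tops, function(tp) ref_top[ref_top %in% tp])
  n_hits <- vapply(ref_top,
                   function(p) sum(vapply(study_tops, function(tp) p %in% tp,
                                          logical(1))),
                   integer(1))
  thresholds <- seq_along(study_tops)
  count_by_threshold <- tibble::tibble(
    threshold = thresholds,
    n_shared = vapply(thresholds, function(t) sum(n_hits >= t), integer(1))
  )
  list(shared = shared,
       count_by_threshold = count_by_threshold,
       shared_any = ref_top[n_hits >= 1])
}

#' Direction concordance of DA scores over shared pathways
#'
#' A shared pathway is concordant when `sign(S_ref) == sign(S_study) != 0`.
#' Pathways where either score has sign 0 presume no direction and are
#' excluded from the denominator (listed in the per-pathway table with
#' `zero_sign = TRUE`).
#'
#' @param ref_da a `da_score` table for the reference study.
#' @param study_da a `da_score` table for the comparison study.
#' @param shared character vector of shared pathway names; every name must
#'   have a defined score in both tables.
#' @return a `concordance_result`: a list with `pathways` (tibble `pathway`,
#'   `sign_ref`, `sign_study`, `concordant`, `zero_sign`), `n_shared`,
#'   `n_concordant`, `n_zero_sign`, and `concordant_fraction`
#'   (`n_concordant / (n_shared - n_zero_sign)`, NA when no pathway has two
#'   nonzero signs).
#' @export
concordance <- function(ref_da, study_da, shared) {
  sgn <- function(da, who) {
    missing <- setdiff(shared, da$pathway)
    if (length(missing) > 0) {
      stop("shared pathway missing from ", who, " DA table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    s <- stats::setNames(da$score, da$pathway)[shared]
    if (any(is.na(s))) {
      stop("shared pathway with undefined DA score in ", who, " table: ",
           paste(shared[is.na(s)], collapse = ", "), call. = FALSE)
    }
    sign(s)
  }
  s_ref <- sgn(ref_da, "reference")
  s_study <- sgn(study_da, "study")
  zero <- s_ref == 0 | s_study == 0
  conc <- !zero & s_ref == s_study
  tab <- tibble::tibble(pathway = shared, sign_ref = unname(s_ref),
                        sign_study = unname(s_study),
                        concordant = unname(conc), zero_sign = unname(zero))
  denom <- sum(!zero)
  structure(
    list(pathways = tab,
         n_shared = length(shared),
         n_concordant = sum(conc),
         n_zero_sign = sum(zero),
         concordant_fraction = if (denom > 0) sum(conc) / denom else NA_real_),
    class = "concordance_result")
}

#' Pool concordance results across studies
#'
#' @param results list of `concordance_result` objects (one per study).
#' @return a tibble with one row per study plus a `pooled` row whose
#'   fraction is `sum(n_concordant) / sum(n_shared - n_zero_sign)`.
#' @export
concordance_summary <- function(results) {
  if (is.null(names(results))) {
    names(results) <- paste0("study_", seq_along(results))
  }
  per <- purrr::imap(results, function(r, nm) {
    tibble::tibble(study = nm, n_shared = r$n_shared,
                   n_concordant = r$n_concordant,
                   n_zero_sign = r$n_zero_sign,
                   concordant_fraction = r$concordant_fraction)
  })
  per <- dplyr::bind_rows(per)
  denom <- sum(per$n_shared - per$n_zero_sign)
  pooled <- tibble::tibble(
    study = "pooled", n_shared = sum(per$n_shared),
    n_concordant = sum(per$n_concordant),
    n_zero_sign = sum(per$n_zero_sign),
    concordant_fraction = if (denom > 0) sum(per$n_concordant) / denom
                          else NA_real_)
  dplyr::bind_rows(per, pooled)
}

#' Permutation null for the concordance fraction
#'
#' Permutes the study's DA direction labels across its pathways `n_perm`
#' times, recomputing the concordance fraction each time;
#' `p = (1 + #(c_perm >= c_obs)) / (1 + n_perm)`.
#'
#' @inheritParams concordance
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return a list: `c_obs`, `null` (numeric vector of permuted fractions),
#'   `p_value`.
#' @export
concordance_permutation_null <- function(ref_da, study_da, shared,
                                         n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  obs <- concordance(ref_da, study_da, shared)
  c_obs <- obs$concordant_fraction
  study_signs <- sign(stats::setNames(study_da$score, study_da$pathway))
  if (length(unique(study_signs[!is.na(study_signs)])) <= 1) {
    warning("study DA directions are all the same sign: permutation null is degenerate",
            call. = FALSE)
  }
  ref_signs <- sign(stats::setNames(ref_da$score, ref_da$pathway)[shared])
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(unname(study_signs))
    s_study <- stats::setNames(perm, names(study_signs))[shared]
    zero <- ref_signs == 0 | s_study == 0
    denom <- sum(!zero)
    if (denom == 0) return(NA_real_)
    sum(!zero & ref_signs == s_study) / denom
  }, double(1))
  p <- (1 + sum(null >= c_obs, na.rm = TRUE)) / (1 + n_perm)
  list(c_obs = c_obs, null = null, p_value = p)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> %d shared pathways: %d concordant, %d zero-sign (c = %s)\n",
    x$n_shared, x$n_concordant, x$n_zero_sign,
    format(x$concordant_fraction, digits = 4)))
  print(x$pathways)
  invisible(x)
}

#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) x$pathways

#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(n_shared = x$n_shared, n_concordant = x$n_concordant,
                 n_zero_sign = x$n_zero_sign,
                 concordant_fraction = x$concordant_fraction)
}
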