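#' Fractional labeling from isotopologue peak areas
#'
#' For each (metabolite, sample), normalizes isotopologue areas to fractions
#' `f_i = area_i / sum_j area_j` and derives:
#'
#' * labeled fraction `L = 1 - f_0` (the share of the pool carrying any 13C);
#' * mean enrichment `E = sum_i i * f_i / n_max`, the average fraction of the
#'   carbon backbone that is 13C, comparable across metabolites of different
#'   carbon number;
#' * total pool `P = sum_j area_j`.
#'
#' Mass shifts absent from the table are treated as area 0 (unmonitored
#' transitions contribute nothing to the pool); the number of filled-in
#' channels is recorded in the `n_filled` attribute. Records with `P = 0`
#' have undefined fractions and are flagged `defined = FALSE`.
#'
#' @param table isotopologue tibble with columns `metabolite`, `kegg_id`,
#'   `mass_shift`, `sample_id`, `area` (see [read_isotopologue_table()]).
#' @param n_max optional named integer vector giving each metabolite's carbon
#'   capacity; defaults to the largest observed mass shift per metabolite.
#' @return a `fractional_labeling` tibble: one row per (metabolite, sample,
#'   mass_shift) with `area`, `frac`, and per-(metabolite, sample) columns
#'   `pool`, `labeled_fraction`, `mean_enrichment`, `n_max`, `defined`.
#' @export
fractional_labeling <- function(table, n_max = NULL) {
  stopifnot(all(c("metabolite", "mass_shift", "sample_id", "area") %in%
                  names(table)))
  if (any(table$area < 0, na.rm = TRUE)) {
    stop("negative isotopologue area", call. = FALSE)
  }
  if (is.null(n_max)) {
    n_max <- tapply(table$mass_shift, table$metabolite, max)
    n_max <- stats::setNames(as.integer(n_max), names(n_max))
  }
  nmax_vec <- n_max
  bad <- table$mass_shift > nmax_vec[table$metabolite]
  if (any(bad)) {
    stop("mass shift exceeds carbon capacity for metabolite `",
         table$metabolite[which(bad)[1]], "`", call. = FALSE)
  }
  kegg <- unique(table[, c("metabolite", "kegg_id")])
  # fill unobserved (metabolite, sample, shift) channels with area 0
  full <- tidyr::expand_grid(
    metabolite = unique(table$metabolite),
    sample_id = unique(table$sample_id)
  )
  full <- dplyr::mutate(full,
                        mass_shift = purrr::map(.data$metabolite,
                                                ~seq(0L, nmax_vec[[.x]])))
  full <- tidyr::unnest(full, "mass_shift")
  n_before <- nrow(table)
  out <- dplyr::left_join(full,
                          table[, c("metabolite", "mass_shift", "sample_id",
                                    "area")],
                          by = c("metabolite", "mass_shift", "sample_id"))
  n_filled <- sum(is.na(out$area))
  out$area[is.na(out$area)] <- 0
  out <- dplyr::left_join(out, kegg, by = "metabolite")
  out <- dplyr::group_by(out, .data$metabolite, .data$sample_id)
  out <- dplyr::mutate(
    out,
    pool = sum(.data$area),
    defined = .data$pool > 0,
    frac = ifelse(.data$defined, .data$area / .data$pool, NA_real_),
    labeled_fraction = ifelse(.data$defined,
                              1 - .data$frac[.data$mass_shift == 0],
                              NA_real_),
    n_max = unname(nmax_vec[.data$metabolite[1]]),
    mean_enrichment = ifelse(
      .data$defined,
      sum(.data$mass_shift * dplyr::coalesce(.data$frac, 0)) / .data$n_max,
      NA_real_)
  )
  out <- dplyr::ungroup(out)
  out <- out[order(out$metabolite, out$sample_id, out$mass_shift),
             c("metabolite", "kegg_id", "sample_id", "mass_shift", "area",
               "frac", "pool", "labeled_fraction", "mean_enrichment",
               "n_max", "defined")]
  structure(out, class = c("fractional_labeling", class(out)),
            n_filled = n_filled, n_input_rows = n_before)
}

#' @method glance fractional_labeling
#' @export
glance.fractional_labeling <- function(x, ...) {
  per <- unique(x[, c("metabolite", "sample_id", "defined")])
  tibble::tibble(n_metabolites = length(unique(x$metabolite)),
                 n_samples = length(unique(x$sample_id)),
                 n_undefined = sum(!per$defined),
                 n_channels_filled = attr(x, "n_filled"))
}

#' Per-isotopologue pool comparisons between two conditions
#'
#' For each metabolite, compares between treatment and reference: the
#' unlabeled (M+0) pool, the total labeled pool (sum of M+n, n >= 1), and
#' each individual isotopologue pool, each with its own unadjusted Welch
#' two-sided test (applied independently per isotopologue).
#'
#' @param table isotopologue tibble (areas already protein-normalized).
#' @param metadata tibble `sample_id`, `condition`.
#' @param reference,treatment condition labels.
#' @param alpha significance level (default 0.05).
#' @return a tibble: `metabolite`, `quantity` ("M+0", "labeled", "M+1", ...),
#'   `mean_ref`, `mean_treat`, `delta`, `statistic`, `df`, `p_value`,
#'   `significant`, `direction`.
#' @export
pool_partition <- function(table, metadata, reference, treatment,
                           alpha = 0.05) {
  cond <- stats::setNames(metadata$condition, metadata$sample_id)
  check_conditions(cond, reference, treatment)
  fl <- fractional_labeling(table)
  fl$condition <- unname(cond[fl$sample_id])
  quantities <- dplyr::bind_rows(
    dplyr::reframe(
      dplyr::group_by(fl, .data$metabolite, .data$sample_id,
                      .data$condition),
      quantity = c("M+0", "labeled"),
      value = c(sum(.data$area[.data$mass_shift == 0]),
                sum(.data$area[.data$mass_shift >= 1]))),
    dplyr::transmute(fl[fl$mass_shift >= 1, ],
                     metabolite = .data$metabolite,
                     sample_id = .data$sample_id,
                     condition = .data$condition,
                     quantity = paste0("M+", .data$mass_shift),
                     value = .data$area)
  )
  welch_by_group(quantities, c("metabolite", "quantity"), reference,
                 treatment, alpha)
}

#' Welch tests on labeling fractions
#'
#' Compares, between two conditions, each isotopologue fraction `f_i` and the
#' labeled fraction `L = 1 - f_0` per metabolite (unadjusted Welch two-sided
#' tests, computed on per-replicate fractions). A metabolite is flagged
#' `reciprocal` when `f_0` is significantly down while some `f_i` (i >= 1) is
#' significantly up — the signature of increased tracer incorporation.
#'
#' @param fl a `fractional_labeling` table.
#' @param metadata tibble `sample_id`, `condition`.
#' @param reference,treatment condition labels.
#' @param alpha significance level (default 0.05).
#' @return a list: `tests` (tibble per metabolite and quantity "f0".."fn",
#'   "L") and `reciprocity` (tibble `metabolite`, `reciprocal`). Metabolites
#'   whose replicates are all undefined are skipped with a warning.
#' @export
fraction_test <- function(fl, metadata, reference, treatment, alpha = 0.05) {
  cond <- stats::setNames(metadata$condition, metadata$sample_id)
  check_conditions(cond, reference, treatment)
  dat <- fl[fl$defined, ]
  skipped <- setdiff(unique(fl$metabolite), unique(dat$metabolite))
  if (length(skipped) > 0) {
    warning("metabolites with no defined fractions skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  dat$condition <- unname(cond[dat$sample_id])
  frac_long <- dplyr::transmute(dat, metabolite = .data$metabolite,
                                sample_id = .data$sample_id,
                                condition = .data$condition,
                                quantity = paste0("f", .data$mass_shift),
                                value = .data$frac)
  l_long <- dplyr::distinct(
    dplyr::transmute(dat, metabolite = .data$metabolite,
                     sample_id = .data$sample_id,
                     condition = .data$condition,
                     quantity = "L", value = .data$labeled_fraction))
  tests <- welch_by_group(dplyr::bind_rows(frac_long, l_long),
                          c("metabolite", "quantity"), reference, treatment,
                          alpha)
  recip <- dplyr::summarise(
    dplyr::group_by(tests, .data$metabolite),
    reciprocal = any(.data$quantity == "f0" & .data$direction == "down") &&
      any(grepl("^f[1-9]", .data$quantity) & .data$direction == "up"),
    .groups = "drop")
  list(tests = tests, reciprocity = recip)
}

#' Enrichment discontinuity along a pathway chain
#'
#' Scores each edge of an ordered metabolite chain by the drop in mean
#' enrichment `d_j = E(m_j) - E(m_j+1)` (replicate-averaged within one
#' condition). A large positive score — a precursor markedly more enriched
#' than its product — marks a candidate discontinuity where carbon leaves the
#' chain. The edge with the maximal positive score is reported with a
#' percentile bootstrap CI over replicates.
#'
#' @param fl a `fractional_labeling` table.
#' @param chain ordered character vector of metabolite names (upstream ->
#'   downstream); every member must be present with defined enrichment in at
#'   least 2 replicates of `condition`.
#' @param metadata tibble `sample_id`, `condition`.
#' @param condition the condition in which to score the chain.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return a list: `edges` (tibble `edge`, `from`, `to`, `score`, `ci_lower`,
#'   `ci_upper`) and `candidate_edge` (index of the maximal positive score,
#'   or NA when no score is positive).
#' @export
enrichment_discontinuity <- function(fl, chain, metadata, condition,
                                     n_boot = 1000, seed = 1L) {
  stopifnot(length(chain) >= 2)
  cond <- stats::setNames(metadata$condition, metadata$sample_id)
  if (!condition %in% cond) stop("unknown condition label `", condition, "`",
                                 call. = FALSE)
  per <- unique(fl[fl$defined, c("metabolite", "sample_id",
                                 "mean_enrichment")])
  per <- per[unname(cond[per$sample_id]) == condition, ]
  e_by_met <- split(per$mean_enrichment, per$metabolite)
  absent <- chain[!chain %in% names(e_by_met) |
                    vapply(chain, function(m) {
                      length(e_by_met[[m]] %||% numeric()) < 2
                    }, logical(1))]
  if (length(absent) > 0) {
    stop("chain metabolite absent or with < 2 defined replicates: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  e_mean <- vapply(chain, function(m) mean(e_by_met[[m]]), double(1))
  d <- e_mean[-length(e_mean)] - e_mean[-1]
  candidate <- if (any(d > 0)) unname(which.max(d)) else NA_integer_
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(b) {
    bm <- vapply(chain, function(m) {
      v <- e_by_met[[m]]
      mean(sample(v, length(v), replace = TRUE))
    }, double(1))
    bm[-length(bm)] - bm[-1]
  }, double(length(chain) - 1))
  boots <- matrix(boots, nrow = length(chain) - 1)
  ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975))
  edges <- tibble::tibble(
    edge = seq_len(length(chain) - 1),
    from = chain[-length(chain)],
    to = chain[-1],
    score = unname(d),
    ci_lower = unname(ci[1, ]),
    ci_upper = unname(ci[2, ])
  )
  list(edges = edges, candidate_edge = candidate,
       mean_enrichment = stats::setNames(e_mean, chain))
}

# Welch tests over a long table grouped by `keys`, comparing `value` between
# conditions. Shared by pool_partition and fraction_test.
welch_by_group <- function(long, keys, reference, treatment, alpha) {
  grouped <- dplyr::group_by(long, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::reframe(
    grouped,
    welch_stat(.data$value[.data$condition == reference],
               .data$value[.data$condition == treatment]))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$direction <- dplyr::case_when(
    out$significant & out$delta > 0 ~ "up",
    out$significant & out$delta < 0 ~ "down",
    .default = "ns"
  )
  out
}

check_conditions <- function(cond, reference, treatment) {
  for (lv in c(reference, treatment)) {
    if (!lv %in% cond) stop("unknown condition label `", lv, "`",
                            call. = FALSE)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
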