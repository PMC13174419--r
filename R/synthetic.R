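#' Simulate a steady-state SRM metabolite panel with left-censored missingness
#'
#' Emulates a targeted LC-MS peak-area matrix: per-metabolite log-intensities
#' are drawn from a normal with a metabolite-specific baseline and sd, plus a
#' planted condition shift for metabolites assigned to effect-carrying
#' pathways. Raw intensities are the exponentiated values. Censoring is
#' left-tailed per sample: every value below that sample's `q_c` quantile is
#' set missing, emulating a per-run limit of detection (the mechanism the
#' QRILC imputer assumes).
#'
#' @param n_metabolites number of metabolites (default 310, the scale of a
#'   typical polar SRM panel).
#' @param n_per_group replicates per condition (>= 2; default 6).
#' @param q_c censor quantile in `[0, 1)`; default 0.15.
#' @param effect named numeric vector: log-scale mean shift
#'   (treatment - reference) planted into each named pathway's members.
#'   Metabolites outside effect pathways get shift 0.
#' @param pathway_size members per planted pathway (default 8).
#' @param n_decoy_pathways additional null pathways assembled from background
#'   metabolites (default 8).
#' @param n_duplicates number of metabolites duplicated under the same KEGG
#'   id (a second, noisier/lower row), to exercise deduplication. Default 0.
#' @param reference,treatment condition labels (default control/tumor).
#' @param baseline_mean,baseline_sd distribution of per-metabolite baseline
#'   log-intensities (defaults 18 and 1.5 on the natural-log scale, i.e. peak
#'   areas around 7e7).
#' @param met_sd_range range of per-metabolite replicate sds (default
#'   0.2-0.6).
#' @param seed integer seed.
#' @return a list: `matrix` (raw-scale [intensity_matrix]), `truth` (a
#'   `synthetic_truth` list: `effect` per metabolite, `pathway_assignment`
#'   tibble, `pathways` (GMT-style list over KEGG ids), `kegg_map` tibble,
#'   `latent` (uncensored log matrix), `q_c`, `seed`).
#' @export
generate_steady_state <- function(n_metabolites = 310, n_per_group = 6,
                                  q_c = 0.15, effect = NULL,
                                  pathway_size = 8, n_decoy_pathways = 8,
                                  n_duplicates = 0,
                                  reference = "control", treatment = "tumor",
                                  baseline_mean = 18, baseline_sd = 1.5,
                                  met_sd_range = c(0.2, 0.6), seed = 1L) {
  stopifnot(n_per_group >= 2)
  if (q_c >= 1 || q_c < 0) stop("q_c must be in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  effect <- effect %||% numeric()
  n_planted <- length(effect) * pathway_size
  if (n_planted > n_metabolites) {
    stop("not enough metabolites for the requested pathways", call. = FALSE)
  }
  met_ids <- sprintf("met_%04d", seq_len(n_metabolites))
  kegg_ids <- sprintf("C%05d", seq_len(n_metabolites))
  # pathway assignment: planted pathways first, then decoys from background
  assignment <- rep(NA_character_, n_metabolites)
  if (length(effect) > 0) {
    assignment[seq_len(n_planted)] <-
      rep(names(effect), each = pathway_size)
  }
  background <- which(is.na(assignment))
  if (n_decoy_pathways > 0 && length(background) >= 2 * n_decoy_pathways) {
    decoy_size <- min(pathway_size, floor(length(background) / n_decoy_pathways))
    idx <- background[seq_len(n_decoy_pathways * decoy_size)]
    assignment[idx] <- rep(sprintf("decoy_%02d", seq_len(n_decoy_pathways)),
                           each = decoy_size)
  }
  met_effect <- rep(0, n_metabolites)
  if (length(effect) > 0) {
    in_planted <- !is.na(assignment) & assignment %in% names(effect)
    met_effect[in_planted] <- effect[assignment[in_planted]]
  }
  baseline <- stats::rnorm(n_metabolites, baseline_mean, baseline_sd)
  met_sd <- stats::runif(n_metabolites, met_sd_range[1], met_sd_range[2])
  samples <- c(paste0(reference, "_", seq_len(n_per_group)),
               paste0(treatment, "_", seq_len(n_per_group)))
  cond <- stats::setNames(rep(c(reference, treatment), each = n_per_group),
                          samples)
  latent <- matrix(NA_real_, n_metabolites, length(samples),
                   dimnames = list(met_ids, samples))
  for (j in seq_along(samples)) {
    shift <- if (cond[j] == treatment) met_effect else 0
    latent[, j] <- stats::rnorm(n_metabolites, baseline + shift, met_sd)
  }
  raw <- exp(latent)
  if (q_c > 0) {
    for (j in seq_along(samples)) {
      lod <- stats::quantile(raw[, j], q_c, type = 7)
      raw[raw[, j] < lod, j] <- NA
    }
  }
  vals <- tibble::tibble(metabolite_id = met_ids, kegg_id = kegg_ids)
  vals <- dplyr::bind_cols(vals, tibble::as_tibble(raw))
  kegg_map <- tibble::tibble(metabolite_id = met_ids, kegg_id = kegg_ids)
  if (n_duplicates > 0) {
    dup_idx <- seq_len(min(n_duplicates, n_metabolites))
    dup_rows <- vals[dup_idx, ]
    dup_rows$metabolite_id <- paste0(dup_rows$metabolite_id, "_iso")
    # duplicate rows sit lower and noisier, so both dedup rules prefer the
    # original
    for (s in samples) {
      dup_rows[[s]] <- dup_rows[[s]] *
        exp(stats::rnorm(nrow(dup_rows), -1, 0.5))
    }
    vals <- dplyr::bind_rows(vals, dup_rows)
    kegg_map <- dplyr::bind_rows(
      kegg_map,
      tibble::tibble(metabolite_id = dup_rows$metabolite_id,
                     kegg_id = kegg_ids[dup_idx]))
  }
  pw_tbl <- tibble::tibble(metabolite_id = met_ids, kegg_id = kegg_ids,
                           pathway = assignment)
  pathways <- split(pw_tbl$kegg_id[!is.na(pw_tbl$pathway)],
                    pw_tbl$pathway[!is.na(pw_tbl$pathway)])
  truth <- structure(list(
    effect = stats::setNames(met_effect, met_ids),
    pathway_assignment = pw_tbl,
    pathways = pathways,
    kegg_map = kegg_map,
    latent = latent,
    q_c = q_c,
    reference = reference,
    treatment = treatment,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
  mat <- intensity_matrix(vals, conditions = cond, scale = "raw",
                          provenance = sprintf(
                            "generate_steady_state: n=%d, n_per_group=%d, q_c=%g, seed=%d",
                            n_metabolites, n_per_group, q_c,
                            as.integer(seed)))
  list(matrix = mat, truth = truth)
}

#' Simulate a multi-study panel with planted pathway-direction concordance
#'
#' Builds one reference study (fly-tumor-like, conditions
#' reference/treatment) and `n_studies` comparison studies (conditions
#' "normal"/"tumor", so the lowest-variance-in-normal dedup rule is
#' exercisable). Every study carries the same shared pathways with strong
#' planted effects; in each comparison study, exactly
#' `round(concordant_fraction * n_shared)` shared pathways (a seeded random
#' subset) take the reference direction and the rest the opposite. When
#' `round()` cannot realize the requested fraction exactly, the nearest
#' realizable fraction is used and recorded in the truth.
#'
#' @param n_studies number of comparison studies (default 5).
#' @param shared_pathways character vector of shared pathway names (default
#'   12 names).
#' @param concordant_fraction target fraction of shared pathways whose
#'   direction matches the reference (default 2/3).
#' @param effect_size absolute log-scale shift planted in shared-pathway
#'   members (default 2, a strong effect).
#' @param n_per_group replicates per condition per study (default 6).
#' @param n_background background (null) metabolites per study beyond the
#'   planted ones (default 120).
#' @param q_c censor quantile (default 0.15).
#' @param n_duplicates duplicate-KEGG rows per study (default 3), so the
#'   dedup rules have work to do.
#' @param seed integer seed.
#' @inheritParams generate_steady_state
#' @return a list: `reference` (the reference study's `matrix`+`truth`),
#'   `studies` (list of `matrix`+`truth` per comparison study), and `truth`
#'   (the panel-level `synthetic_truth`: `plan` tibble of pathway x study
#'   directions and concordance flags, `reference_direction`,
#'   `realized_fraction`, `seed`).
#' @export
generate_panel <- function(n_studies = 5,
                           shared_pathways = sprintf("shared_%02d", 1:12),
                           concordant_fraction = 2 / 3,
                           effect_size = 2, n_per_group = 6,
                           n_background = 120, q_c = 0.15,
                           pathway_size = 8, n_duplicates = 3, seed = 1L) {
  stopifnot(concordant_fraction >= 0, concordant_fraction <= 1)
  set.seed(as.integer(seed))
  n_shared <- length(shared_pathways)
  n_conc <- round(concordant_fraction * n_shared)
  realized <- n_conc / n_shared
  ref_dir <- stats::setNames(sample(c(-1, 1), n_shared, replace = TRUE),
                             shared_pathways)
  n_metabolites <- n_shared * pathway_size + n_background
  ref <- generate_steady_state(
    n_metabolites = n_metabolites, n_per_group = n_per_group, q_c = q_c,
    effect = ref_dir * effect_size, pathway_size = pathway_size,
    n_duplicates = n_duplicates,
    reference = "control", treatment = "tumor",
    seed = sample.int(2^31 - 1, 1))
  plan <- list()
  studies <- vector("list", n_studies)
  names(studies) <- sprintf("study_%d", seq_len(n_studies))
  for (s in seq_len(n_studies)) {
    conc_set <- sample(shared_pathways, n_conc)
    dir_s <- ifelse(shared_pathways %in% conc_set, ref_dir, -ref_dir)
    names(dir_s) <- shared_pathways
    studies[[s]] <- generate_steady_state(
      n_metabolites = n_metabolites, n_per_group = n_per_group, q_c = q_c,
      effect = dir_s * effect_size, pathway_size = pathway_size,
      n_duplicates = n_duplicates,
      reference = "normal", treatment = "tumor",
      seed = sample.int(2^31 - 1, 1))
    plan[[s]] <- tibble::tibble(
      study = names(studies)[s], pathway = shared_pathways,
      direction = unname(dir_s),
      concordant = shared_pathways %in% conc_set)
  }
  truth <- structure(list(
    plan = dplyr::bind_rows(plan),
    reference_direction = ref_dir,
    requested_fraction = concordant_fraction,
    realized_fraction = realized,
    n_concordant_per_study = n_conc,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
  list(reference = ref, studies = studies, truth = truth)
}

#' Simulate an isotopologue table from known labeling fractions
#'
#' Per replicate, a metabolite's total pool is drawn log-normally around a
#' condition mean; each isotopologue area is `pool * pi_i` times
#' multiplicative log-normal noise with coefficient of variation `noise_cv`
#' (mean 1). All areas are nonnegative by construction. With `noise_cv = 0`
#' the areas are exactly `pool * pi_i`.
#'
#' @param pi_by_condition nested list: `pi_by_condition[[metabolite]][[condition]]`
#'   is the true isotopologue probability vector `pi_0..pi_n` (must sum to 1
#'   within 1e-12).
#' @param n_per_group replicates per condition (default 6).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; default 0.1).
#' @param pool_mean mean total pool size (default 1e5).
#' @param pool_cv between-replicate cv of the pool (default 0.2).
#' @param reference,treatment condition labels (default control/tumor).
#' @param seed integer seed.
#' @return a list: `table` (long isotopologue tibble), `metadata` (tibble
#'   `sample_id`, `condition`), `truth` (`synthetic_truth` with the planted
#'   `labeling` list, noise parameters and seed).
#' @export
generate_tracing <- function(pi_by_condition, n_per_group = 6,
                             noise_cv = 0.1, pool_mean = 1e5, pool_cv = 0.2,
                             reference = "control", treatment = "tumor",
                             seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  for (met in names(pi_by_condition)) {
    for (cn in names(pi_by_condition[[met]])) {
      p <- pi_by_condition[[met]][[cn]]
      if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
        stop(sprintf("pi vector for `%s`/`%s` is not a probability vector",
                     met, cn), call. = FALSE)
      }
    }
  }
  set.seed(as.integer(seed))
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  sdlog_pool <- sqrt(log(1 + pool_cv^2))
  samples <- c(paste0(reference, "_", seq_len(n_per_group)),
               paste0(treatment, "_", seq_len(n_per_group)))
  metadata <- tibble::tibble(
    sample_id = samples,
    condition = rep(c(reference, treatment), each = n_per_group))
  rows <- list()
  mets <- names(pi_by_condition)
  for (m in seq_along(mets)) {
    met <- mets[m]
    for (r in seq_len(nrow(metadata))) {
      cn <- metadata$condition[r]
      p <- pi_by_condition[[met]][[cn]]
      if (is.null(p)) stop("no pi vector for `", met, "` in condition `",
                           cn, "`", call. = FALSE)
      pool <- stats::rlnorm(1, log(pool_mean) - sdlog_pool^2 / 2, sdlog_pool)
      noise <- stats::rlnorm(length(p), -sdlog_noise^2 / 2, sdlog_noise)
      rows[[length(rows) + 1]] <- tibble::tibble(
        metabolite = met,
        kegg_id = sprintf("C9%04d", m),
        mass_shift = seq_along(p) - 1L,
        sample_id = metadata$sample_id[r],
        area = pool * p * noise)
    }
  }
  truth <- structure(list(
    labeling = pi_by_condition,
    noise_cv = noise_cv, pool_mean = pool_mean, pool_cv = pool_cv,
    reference = reference, treatment = treatment,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
  list(table = dplyr::bind_rows(rows), metadata = metadata, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic truth object as structured text (YAML)
#'
#' Matrix components are flattened to lists; the file documents the planted
#' parameters alongside the generated tables.
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- lapply(unclass(truth), function(v) {
    if (is.matrix(v)) {
      list(rows = rownames(v), cols = colnames(v),
           values = as.vector(v))
    } else if (inherits(v, "data.frame")) {
      as.list(v)
    } else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}
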