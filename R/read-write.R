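#' Read a metabolite intensity matrix from TSV/CSV
#'
#' The file must have a header of sample ids, first column the metabolite id,
#' and optionally a second column `kegg_id`. Missing cells are empty or the
#' literal "NA". Delimiter is inferred from the extension (`.csv` -> comma,
#' otherwise tab).
#'
#' @param path path to the matrix file.
#' @param metadata_path path to a two-column TSV/CSV mapping sample id to
#'   condition (header `sample_id`, `condition`).
#' @return an [intensity_matrix] on the raw scale.
#' @export
read_intensity_matrix <- function(path, metadata_path) {
  meta <- read_sample_metadata(metadata_path)
  df <- read_delim_auto(path)
  names(df)[1] <- "metabolite_id"
  df$metabolite_id <- as.character(df$metabolite_id)
  if (names(df)[2] == "kegg_id") df$kegg_id <- as.character(df$kegg_id)
  samples <- setdiff(names(df), c("metabolite_id", "kegg_id"))
  for (s in samples) {
    col <- df[[s]]
    if (is.numeric(col)) next
    chr <- trimws(as.character(col))
    chr[chr == "" | chr == "NA"] <- NA
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf(
        "non-numeric cell in `%s`: metabolite `%s`, sample `%s` (value \"%s\")",
        path, df$metabolite_id[bad[1]], s, chr[bad[1]]), call. = FALSE)
    }
    df[[s]] <- num
  }
  cond <- stats::setNames(meta$condition, meta$sample_id)
  missing_meta <- setdiff(samples, names(cond))
  if (length(missing_meta) > 0) {
    stop("samples in matrix absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  # basename only: logs stay byte-identical when equivalent runs live in
  # different directories
  intensity_matrix(df, conditions = cond, scale = "raw",
                   provenance = sprintf("read_intensity_matrix: %s (%d metabolites, %d samples)",
                                        basename(path), nrow(df),
                                        length(samples)))
}

#' Read sample metadata
#'
#' @param path two-column TSV/CSV with header `sample_id`, `condition`.
#' @return a tibble with `sample_id` and `condition`.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("metadata must have columns `sample_id` and `condition`: ", path,
         call. = FALSE)
  }
  tibble::tibble(sample_id = as.character(df$sample_id),
                 condition = as.character(df$condition))
}

#' Write an intensity matrix (and its metadata) to TSV
#'
#' Missing values are written as "NA". A matrix written and re-read
#' reproduces values and missingness bit-exactly.
#'
#' @param x an [intensity_matrix].
#' @param path output matrix TSV path.
#' @param metadata_path optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path, metadata_path = NULL) {
  df <- tibble::as_tibble(unclass(x))
  # readr writes the shortest representation that reads back to the same
  # double, so matrix round-trips are bit-exact (reports use num12 instead).
  readr::write_tsv(df, path, na = "NA")
  if (!is.null(metadata_path)) {
    cond <- im_conditions(x)
    readr::write_tsv(tibble::tibble(sample_id = names(cond),
                                    condition = unname(cond)),
                     metadata_path)
  }
  invisible(path)
}

#' Read pathway sets from a GMT file
#'
#' One pathway per line: name, description (ignored), then member KEGG
#' compound ids, tab-separated. Duplicate members on a line are collapsed;
#' pathways with no members are skipped with a warning.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (pathway name -> member ids).
#' @export
read_pathways_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("no pathways in ", path, call. = FALSE)
    return(stats::setNames(list(), character()))
  }
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[1])) {
      stop(sprintf("unreadable GMT line %d in %s", i, path), call. = FALSE)
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning(sprintf("pathway `%s` (line %d) has no members; skipped",
                      parts[1], i), call. = FALSE)
      next
    }
    out[[parts[1]]] <- members
  }
  out
}

#' Write pathway sets to a GMT file
#'
#' @param pathways named list of character member vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathways_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format isotopologue table
#'
#' Columns: `metabolite`, `kegg_id`, `mass_shift`, `sample_id`, `area`
#' (protein-normalized peak area, >= 0).
#'
#' @param path TSV/CSV path.
#' @return a tibble.
#' @export
read_isotopologue_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("metabolite", "mass_shift", "sample_id", "area")
  if (!all(need %in% names(df))) {
    stop("isotopologue table must have columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  }
  if (!"kegg_id" %in% names(df)) df$kegg_id <- NA_character_
  df$mass_shift <- as.integer(df$mass_shift)
  df$area <- as.numeric(df$area)
  if (any(df$area < 0, na.rm = TRUE)) {
    stop("negative isotopologue area in ", path, call. = FALSE)
  }
  if (anyDuplicated(df[, c("metabolite", "mass_shift", "sample_id")]) > 0) {
    stop("duplicate (metabolite, mass_shift, sample) rows in ", path,
         call. = FALSE)
  }
  tibble::as_tibble(df[, c("metabolite", "kegg_id", "mass_shift",
                           "sample_id", "area")])
}

#' Read a metabolite -> KEGG id map
#'
#' @param path two-column TSV/CSV with header `metabolite_id`, `kegg_id`.
#' @return a tibble.
#' @export
read_kegg_map <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("metabolite_id", "kegg_id") %in% names(df))) {
    stop("KEGG map must have columns `metabolite_id` and `kegg_id`: ", path,
         call. = FALSE)
  }
  tibble::tibble(metabolite_id = as.character(df$metabolite_id),
                 kegg_id = as.character(df$kegg_id))
}

#' Analysis configuration
#'
#' Bundles the tunable parameters shared across pipeline stages.
#'
#' @param missingness_threshold tau in (0,1): a metabolite is kept iff its
#'   missing fraction is strictly below tau in at least one condition.
#' @param significance_level alpha in (0,1) for two-group tests.
#' @param top_k number of top-ranked pathways compared across studies.
#' @param dedup_rule duplicate-KEGG resolution: `"higher_mean"` keeps the row
#'   with the greater mean intensity over all samples;
#'   `"lowest_variance_in_normal"` keeps the row with the smallest variance
#'   in normal-condition samples.
#' @param qrilc_tune_sigma multiplier on the estimated sd used when drawing
#'   imputed values.
#' @param seed integer seed.
#' @return a list with class `analysis_config`.
#' @export
analysis_config <- function(missingness_threshold = 0.2,
                            significance_level = 0.05,
                            top_k = 16,
                            dedup_rule = c("higher_mean",
                                           "lowest_variance_in_normal"),
                            qrilc_tune_sigma = 1.0,
                            seed = 1L) {
  dedup_rule <- match.arg(dedup_rule)
  stopifnot(missingness_threshold > 0, missingness_threshold < 1,
            significance_level > 0, significance_level < 1,
            top_k >= 1, qrilc_tune_sigma > 0)
  structure(list(missingness_threshold = missingness_threshold,
                 significance_level = significance_level,
                 top_k = as.integer(top_k),
                 dedup_rule = dedup_rule,
                 qrilc_tune_sigma = qrilc_tune_sigma,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [analysis_config()].
#'
#' @param path YAML file of flat key/value pairs.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE,
                    trim_ws = TRUE)
}

# 12 significant digits: deterministic, round-trip-exact serialization for
# the value ranges this pipeline produces.
num12 <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- NA
  out
}
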