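#' Metabolite intensity matrix
#'
#' The central container for steady-state metabolomics data: a tibble with one
#' row per metabolite, an identifier column `metabolite_id`, an optional
#' `kegg_id` column, and one numeric column per sample. Missing measurements
#' are `NA` — distinct from 0, which is a legitimate peak area. The object
#' carries three attributes alongside the data:
#'
#' * `scale` — one of `"raw"`, `"log"`, `"log10"`, `"median_centered"`,
#'   `"zscore"`. Operations that require a particular scale reject others, so
#'   the pipeline can only move forward (raw -> log -> median_centered).
#' * `conditions` — a named character vector mapping every sample column to
#'   its condition label (e.g. control/tumor, plus extra levels such as
#'   "normal" in human panels).
#' * `provenance` — a character log of processing steps.
#'
#' @param values a data frame with columns `metabolite_id`, optionally
#'   `kegg_id`, then one numeric column per sample.
#' @param conditions named character vector: names are sample ids, values are
#'   condition labels. Every sample column must appear.
#' @param scale scale state of the values.
#' @param provenance character vector of log lines.
#' @return an `intensity_matrix` (a tibble subclass).
#' @export
intensity_matrix <- function(values, conditions,
                             scale = c("raw", "log", "log10",
                                       "median_centered", "zscore"),
                             provenance = character()) {
  scale <- match.arg(scale)
  values <- tibble::as_tibble(values)
  if (!"metabolite_id" %in% names(values)) {
    stop("`values` must have a `metabolite_id` column", call. = FALSE)
  }
  if (!"kegg_id" %in% names(values)) {
    values <- dplyr::mutate(values, kegg_id = NA_character_,
                            .after = "metabolite_id")
  }
  samples <- setdiff(names(values), c("metabolite_id", "kegg_id"))
  if (length(samples) == 0) stop("no sample columns", call. = FALSE)
  missing_meta <- setdiff(samples, names(conditions))
  if (length(missing_meta) > 0) {
    stop("samples absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  conditions <- conditions[samples]
  for (s in samples) {
    if (!is.numeric(values[[s]])) {
      stop("sample column `", s, "` is not numeric", call. = FALSE)
    }
    if (scale == "raw" && any(values[[s]] < 0, na.rm = TRUE)) {
      stop("negative raw intensity in sample `", s, "`", call. = FALSE)
    }
  }
  structure(
    values,
    class = c("intensity_matrix", class(tibble::tibble())),
    scale = scale,
    conditions = conditions,
    provenance = provenance
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d metabolites x %d samples [scale: %s]\n",
              nrow(x), length(im_samples(x)), im_scale(x)))
  cond <- im_conditions(x)
  tab <- table(cond)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  NextMethod()
}

#' Accessors for intensity matrices
#'
#' @param x an `intensity_matrix`.
#' @return `im_samples()` the sample ids; `im_conditions()` the named
#'   sample -> condition vector; `im_scale()` the scale state;
#'   `im_provenance()` the processing log; `im_values()` the numeric matrix
#'   (metabolites x samples, rownames = metabolite ids).
#' @export
im_samples <- function(x) setdiff(names(x), c("metabolite_id", "kegg_id"))

#' @rdname im_samples
#' @export
im_conditions <- function(x) attr(x, "conditions")

#' @rdname im_samples
#' @export
im_scale <- function(x) attr(x, "scale")

#' @rdname im_samples
#' @export
im_provenance <- function(x) attr(x, "provenance")

#' @rdname im_samples
#' @export
im_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, im_samples(x), drop = FALSE])
  rownames(m) <- x$metabolite_id
  m
}

# Rebuild an intensity_matrix from modified pieces, appending to provenance.
im_update <- function(x, values = NULL, scale = NULL, conditions = NULL,
                      log_line = NULL) {
  new_vals <- if (is.null(values)) tibble::as_tibble(unclass(x)) else values
  im <- intensity_matrix(
    new_vals,
    conditions = if (is.null(conditions)) im_conditions(x) else conditions,
    scale = if (is.null(scale)) im_scale(x) else scale,
    provenance = c(im_provenance(x), log_line)
  )
  im
}

# Replace the numeric block while keeping ids.
im_set_values <- function(x, m, scale = NULL, log_line = NULL) {
  vals <- tibble::tibble(metabolite_id = x$metabolite_id,
                         kegg_id = x$kegg_id)
  vals <- dplyr::bind_cols(vals, tibble::as_tibble(m))
  im_update(x, values = vals, scale = scale, log_line = log_line)
}

# Keep a subset of rows (logical or integer index), preserving attributes.
im_keep_rows <- function(x, idx, log_line = NULL) {
  vals <- tibble::as_tibble(unclass(x))[idx, , drop = FALSE]
  im_update(x, values = vals, log_line = log_line)
}

stop_wrong_scale <- function(x, allowed, op) {
  if (!im_scale(x) %in% allowed) {
    stop(sprintf("%s requires scale %s but matrix is on scale `%s`",
                 op, paste0("`", allowed, "`", collapse = "/"), im_scale(x)),
         call. = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an intensity matrix into long format
#'
#' @param x an `intensity_matrix`.
#' @param ... unused.
#' @return a tibble with columns `metabolite_id`, `kegg_id`, `sample_id`,
#'   `condition`, `value` (NA where missing) and a `scale` column.
#' @method tidy intensity_matrix
#' @export
tidy.intensity_matrix <- function(x, ...) {
  cond <- im_conditions(x)
  out <- tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                             cols = dplyr::all_of(im_samples(x)),
                             names_to = "sample_id", values_to = "value")
  out$condition <- unname(cond[out$sample_id])
  out$scale <- im_scale(x)
  out[, c("metabolite_id", "kegg_id", "sample_id", "condition",
          "value", "scale")]
}

#' Summarise an intensity matrix
#'
#' @param x an `intensity_matrix`.
#' @param ... unused.
#' @return a one-row tibble: dimensions, scale, missing fraction,
#'   number of conditions.
#' @method glance intensity_matrix
#' @export
glance.intensity_matrix <- function(x, ...) {
  m <- im_values(x)
  tibble::tibble(
    n_metabolites = nrow(m),
    n_samples = ncol(m),
    scale = im_scale(x),
    missing_fraction = mean(is.na(m)),
    n_conditions = length(unique(im_conditions(x)))
  )
}
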