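# Survey-table cleaning. A survey table is a data.frame with columns
#   site_id, x_km, y_km, state_id, lld,
#   conc_top5, conc_ahorizon            (mg/kg, one per depth horizon)
#   below_lld_top5, below_lld_ahorizon  (logical below-detection flags)
#   lab_id_top5, lab_id_ahorizon        ("N.S." marks a not-sampled horizon)
# Cleaning steps log their removal/substitution counts in the "cleaning_log"
# attribute, accumulated across steps.

horizon_cols <- function(table) {
  cols <- intersect(c("conc_top5", "conc_ahorizon", "conc"), names(table))
  if (length(cols) == 0) stop("no concentration columns found", call. = FALSE)
  cols
}

append_log <- function(table, step, ...) {
  log <- attr(table, "cleaning_log")
  if (is.null(log)) log <- list()
  log[[length(log) + 1]] <- c(list(step = step), list(...))
  attr(table, "cleaning_log") <- log
  table
}

#' Substitute below-detection concentrations with half the detection limit
#'
#' Values flagged below the lower limit of detection (LLD) are replaced by
#' `lld / 2`, the conventional censoring substitution; unflagged values are
#' untouched.
#'
#' @param table Survey table (see package overview for the column contract).
#' @return Table with substituted values; the cleaning log records the count.
#' @export
substitute_below_lld <- function(table) {
  n_sub <- 0L
  for (h in c("top5", "ahorizon")) {
    vc <- paste0("conc_", h); fc <- paste0("below_lld_", h)
    if (!all(c(vc, fc) %in% names(table))) next
    flag <- !is.na(table[[fc]]) & table[[fc]]
    if (any(flag & is.na(table$lld)))
      stop("below-detection flag set where lld is missing", call. = FALSE)
    table[[vc]][flag] <- table$lld[flag] / 2
    n_sub <- n_sub + sum(flag)
  }
  append_log(table, "substitute_below_lld", n_substituted = n_sub)
}

#' Mask concentrations of user-identified extreme outlier sites
#'
#' Sets the concentration(s) at the listed sites to missing while retaining
#' the rows, so outliers are excluded from the likelihood without altering
#' the site roster. Outlier site ids are user-supplied configuration
#' (identified externally, e.g. from prior interpolated maps).
#'
#' @param table Survey table.
#' @param site_ids Character/integer vector of site ids to mask.
#' @return Table with masked values; unknown ids raise a warning, not an error.
#' @export
mask_outliers <- function(table, site_ids) {
  if (length(site_ids) == 0) return(append_log(table, "mask_outliers", n_masked = 0L))
  unknown <- setdiff(site_ids, table$site_id)
  if (length(unknown) > 0)
    warning("unknown site ids not masked: ", paste(unknown, collapse = ", "))
  hit <- table$site_id %in% site_ids
  n_cells <- 0L
  for (vc in horizon_cols(table)) {
    n_cells <- n_cells + sum(hit & !is.na(table[[vc]]))
    table[[vc]][hit] <- NA_real_
  }
  append_log(table, "mask_outliers", n_sites = sum(hit), n_masked = n_cells,
             site_ids = as.character(site_ids[site_ids %in% table$site_id]))
}

#' Blank not-sampled horizons and drop fully not-sampled sites
#'
#' A horizon whose lab id is the literal "N.S." contributes no value; a site
#' with both horizons not sampled is dropped.
#'
#' @param table Survey table with `lab_id_top5` / `lab_id_ahorizon`.
#' @return Filtered table; counts go to the cleaning log.
#' @export
drop_not_sampled <- function(table) {
  ns <- matrix(FALSE, nrow(table), 2)
  hs <- c("top5", "ahorizon")
  for (k in seq_along(hs)) {
    lc <- paste0("lab_id_", hs[k])
    if (!lc %in% names(table)) next
    ns[, k] <- !is.na(table[[lc]]) & table[[lc]] == "N.S."
    table[[paste0("conc_", hs[k])]][ns[, k]] <- NA_real_
  }
  drop <- ns[, 1] & ns[, 2]
  out <- table[!drop, , drop = FALSE]
  attr(out, "cleaning_log") <- attr(table, "cleaning_log")
  append_log(out, "drop_not_sampled",
             n_horizons_blanked = sum(ns) - 2L * sum(drop),
             n_sites_dropped = sum(drop))
}

#' Average the two depth horizons into a single concentration per site
#'
#' Both horizons present: arithmetic mean (representing ~0-25 cm soil); one
#' present: that value is carried through (coalesce semantics); both
#' missing: the site is dropped and logged.
#'
#' @param table Survey table with `conc_top5` and `conc_ahorizon`.
#' @return Table with a single `conc` column replacing the horizon pair.
#' @export
merge_horizons <- function(table) {
  stopifnot(all(c("conc_top5", "conc_ahorizon") %in% names(table)))
  m <- cbind(table$conc_top5, table$conc_ahorizon)
  conc <- rowMeans(m, na.rm = TRUE)
  conc[is.nan(conc)] <- NA_real_
  table$conc <- conc
  drop <- is.na(conc)
  out <- table[!drop, setdiff(names(table), c("conc_top5", "conc_ahorizon",
                                              "below_lld_top5", "below_lld_ahorizon",
                                              "lab_id_top5", "lab_id_ahorizon")),
               drop = FALSE]
  attr(out, "cleaning_log") <- attr(table, "cleaning_log")
  append_log(out, "merge_horizons", n_sites_dropped = sum(drop))
}

#' Screen covariates for pairwise collinearity
#'
#' Walks covariate pairs in the declared column order; whenever a pair of
#' still-retained covariates has Pearson |r| strictly above `threshold`, the
#' later-listed covariate is dropped (so e.g. a precipitation column listed
#' after pH is the one removed when the two are collinear). Zero-variance
#' covariates are dropped with a warning.
#'
#' @param covariates Data frame of numeric covariate columns.
#' @param threshold Absolute-correlation threshold; strictly-greater rule.
#' @return List: `retained`, `dropped`, `cor_matrix` (full matrix report).
#' @export
screen_collinear <- function(covariates, threshold = 0.7) {
  stopifnot(is.data.frame(covariates), ncol(covariates) >= 2)
  if (sum(stats::complete.cases(covariates)) < 3)
    stop("need at least 3 complete rows", call. = FALSE)
  nms <- names(covariates)
  sds <- vapply(covariates, stats::sd, numeric(1), na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate))
    warning("zero-variance covariate(s) dropped: ", paste(nms[degenerate], collapse = ", "))
  C <- suppressWarnings(stats::cor(covariates, use = "pairwise.complete.obs"))
  retained <- nms[!degenerate]
  dropped <- nms[degenerate]
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      if (!(nms[i] %in% retained) || !(nms[j] %in% retained)) next
      r <- C[i, j]
      # strictly-greater rule; the epsilon keeps a pair constructed at
      # exactly the threshold on the retained side of the boundary
      if (is.finite(r) && abs(r) > threshold + 1e-10) {
        retained <- setdiff(retained, nms[j])
        dropped <- c(dropped, nms[j])
      }
    }
  }
  list(retained = retained, dropped = dropped, cor_matrix = C)
}

#' Standardize covariates to mean 0, sample SD 1
#'
#' Returns the scaled data together with the `scaling_record` of per-column
#' means/SDs, which must be reused (via [apply_scaling()]) for any new data
#' such as prediction rasters: the regression coefficients are defined on
#' the training scale, so re-estimating the transform is forbidden.
#'
#' @param covariates Data frame of numeric covariates.
#' @return List: `data` (scaled data frame), `record` (a `scaling_record`).
#' @export
standardize_covariates <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  mu <- vapply(covariates, mean, numeric(1), na.rm = TRUE)
  sd <- vapply(covariates, stats::sd, numeric(1), na.rm = TRUE)
  bad <- !is.finite(sd) | sd == 0
  if (any(bad))
    stop("zero-SD covariate(s): ", paste(names(covariates)[bad], collapse = ", "),
         call. = FALSE)
  rec <- structure(list(mean = mu, sd = sd, names = names(covariates)),
                   class = "scaling_record")
  list(data = apply_scaling(covariates, rec), record = rec)
}

#' Apply a stored scaling record to (new) covariate data
#'
#' @param covariates Data frame containing at least the recorded columns.
#' @param record A `scaling_record` from [standardize_covariates()].
#' @return Data frame with recorded columns transformed to `(x - mean)/sd`.
#' @export
apply_scaling <- function(covariates, record) {
  stopifnot(inherits(record, "scaling_record"))
  missing_cols <- setdiff(record$names, names(covariates))
  if (length(missing_cols) > 0)
    stop("covariates missing from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (nm in record$names)
    covariates[[nm]] <- (covariates[[nm]] - record$mean[[nm]]) / record$sd[[nm]]
  covariates
}

#' Read / write a survey table CSV
#'
#' Comma-separated, header row, UTF-8; the literal string "N.S." in lab-id
#' columns marks not-sampled horizons. Logical flags round-trip as
#' TRUE/FALSE.
#'
#' @param path CSV path.
#' @rdname survey_csv
#' @export
read_survey_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (fc in intersect(c("below_lld_top5", "below_lld_ahorizon"), names(tab)))
    tab[[fc]] <- as.logical(tab[[fc]])
  tab
}

#' @param table Survey table.
#' @rdname survey_csv
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the accumulated cleaning log as a JSON report
#'
#' @param table A table carrying a `cleaning_log` attribute.
#' @param path Output JSON path.
#' @export
write_cleaning_report <- function(table, path) {
  log <- attr(table, "cleaning_log")
  if (is.null(log)) log <- list()
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
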