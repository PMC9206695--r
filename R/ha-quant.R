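# Internal-standard semiquantification and the Table-1-style summary
# statistics: totals, detection counts, stability, high-content and alkanol
# classification.

#' Semiquantification configuration
#'
#' Single-point internal-standard quantification:
#' \deqn{C = d \cdot A_c / A_{is} \cdot C_{is}}
#' where \eqn{A_c} and \eqn{A_{is}} are the analyte and internal-standard
#' peak areas, \eqn{C_{is}} the in-vial internal-standard concentration and
#' \eqn{d} the vial dilution factor. With the study's headspace-vial recipe
#' (0.5 mL sample made up to 6.0 mL with ethanol solution, spiked with 60 uL
#' of 8800 ug/L 2-octanol) the in-vial internal-standard concentration is
#' 8800 x 60e-6 / 6.0e-3 = 88 ug/L and the dilution factor is
#' 6.0 / 0.5 = 12. Both are configuration, never hard-coded.
#'
#' @param c_is In-vial internal-standard concentration, ug/L (> 0).
#' @param dilution_factor Unitless vial dilution factor (> 0).
#' @param detection_limit Concentrations strictly below this (ug/L) are
#'   recorded ND; 0 means report as measured.
#' @return A list of class \code{quant_config}.
#' @export
quant_config <- function(c_is = 88, dilution_factor = 12,
                         detection_limit = 0) {
  if (c_is <= 0) stop("c_is must be positive", call. = FALSE)
  if (dilution_factor <= 0) {
    stop("dilution_factor must be positive", call. = FALSE)
  }
  structure(list(c_is = c_is, dilution_factor = dilution_factor,
                 detection_limit = detection_limit),
            class = "quant_config")
}

#' Convert peak areas to concentrations
#'
#' Applies \eqn{C = d \, A_c / A_{is} \, C_{is}} per record and assembles a
#' replicate-level concentration table. Records whose concentration falls
#' strictly below the detection limit are masked ND.
#'
#' @param peaks A [peak_table()].
#' @param quant A [quant_config()].
#' @return A replicate-level [ha_table()].
#' @export
quantify <- function(peaks, quant = quant_config()) {
  stopifnot(inherits(peaks, "peak_table"), inherits(quant, "quant_config"))
  bad <- peaks$is_area <= 0
  if (any(bad)) {
    stop("zero internal-standard area for record(s): ",
         paste(sprintf("%s/%s", peaks$compound[bad], peaks$sample_id[bad]),
               collapse = ", "), call. = FALSE)
  }
  conc <- quant$dilution_factor * peaks$area / peaks$is_area * quant$c_is
  compounds <- unique(peaks$compound)
  meta <- parse_sample_ids(unique(peaks$sample_id))
  samples <- meta$sample[order(meta$day, meta$replicate)]
  v <- matrix(NA_real_, length(compounds), length(samples),
              dimnames = list(compounds, samples))
  v[cbind(match(peaks$compound, compounds),
          match(peaks$sample_id, samples))] <- conc
  if (quant$detection_limit > 0) {
    v[!is.na(v) & v < quant$detection_limit] <- NA_real_
  }
  ha_table(replicate_values = v)
}

#' Summarize replicate concentrations per timepoint
#'
#' Per compound and day: mean of the detected replicates, standard error
#' (sample SD / sqrt(n), defined only where at least two replicates were
#' detected) and the ND mask (a timepoint is ND only if all its replicates
#' are ND).
#'
#' @param ha A replicate-level [ha_table()].
#' @return An [ha_table()] with \code{mean}, \code{se} and \code{nd} filled
#'   (replicate values carried along).
#' @export
summarize_replicates <- function(ha) {
  stopifnot(inherits(ha, "ha_table"))
  v <- ha$replicate_values
  if (is.null(v)) {
    stop("summarize_replicates needs replicate-level values", call. = FALSE)
  }
  meta <- parse_sample_ids(colnames(v))
  days <- sort(unique(meta$day))
  m <- s <- matrix(NA_real_, nrow(v), length(days),
                   dimnames = list(rownames(v), day_label(days)))
  for (i in seq_along(days)) {
    cols <- meta$sample[meta$day == days[i]]
    if (length(cols) == 0) {
      stop("timepoint with zero replicates: day ", days[i], call. = FALSE)
    }
    block <- v[, cols, drop = FALSE]
    n_det <- rowSums(!is.na(block))
    m[, i] <- ifelse(n_det > 0, rowMeans(block, na.rm = TRUE), NA_real_)
    s[, i] <- ifelse(n_det >= 2,
                     apply(block, 1, stats::sd, na.rm = TRUE) / sqrt(n_det),
                     NA_real_)
  }
  ha_table(mean = m, se = s, replicate_values = v)
}

#' Total concentration at one timepoint
#'
#' Sum of the per-compound means over compounds detected at that timepoint
#' (ND contributes nothing), in ug/L.
#'
#' @param ha A summarized [ha_table()].
#' @param timepoint Day number (e.g. \code{10}) or label (\code{"D10"}).
#' @return Total concentration in ug/L.
#' @export
total_concentration <- function(ha, timepoint) {
  stopifnot(inherits(ha, "ha_table"))
  if (is.null(ha$mean)) stop("summarize the table first", call. = FALSE)
  lab <- if (is.numeric(timepoint)) day_label(timepoint) else timepoint
  if (!lab %in% colnames(ha$mean)) {
    stop("unknown timepoint: ", lab, "; available: ",
         paste(colnames(ha$mean), collapse = ", "), call. = FALSE)
  }
  sum(ha$mean[, lab], na.rm = TRUE)
}

#' Detection statistics and stability flags
#'
#' Counts, per compound, the number of timepoints at which it was detected
#' (ND mask false) and flags it stable when detected at least
#' \code{min_detections} times; also counts detected compounds per timepoint.
#'
#' @param ha A summarized [ha_table()].
#' @param min_detections Minimum timepoint detections for the stable flag.
#' @return A list: \code{per_compound} (compound, n_detected, stable),
#'   \code{per_timepoint} (timepoint, n_compounds), \code{n_compounds}.
#' @export
detection_stats <- function(ha, min_detections = 5) {
  stopifnot(inherits(ha, "ha_table"))
  if (is.null(ha$nd)) stop("summarize the table first", call. = FALSE)
  det <- !ha$nd
  list(
    per_compound = data.frame(
      compound = rownames(det),
      n_detected = unname(rowSums(det)),
      stable = unname(rowSums(det) >= min_detections),
      stringsAsFactors = FALSE
    ),
    per_timepoint = data.frame(
      timepoint = colnames(det),
      n_compounds = unname(colSums(det)),
      stringsAsFactors = FALSE
    ),
    n_compounds = nrow(det)
  )
}

#' High-content compounds
#'
#' Compounds whose maximum mean concentration over the fermentation strictly
#' exceeds the threshold (default 1000 ug/L, i.e. "> 1 mg/L at least once").
#'
#' @param ha A summarized [ha_table()].
#' @param threshold Strict threshold in ug/L.
#' @return Character vector of compound names.
#' @export
high_content_filter <- function(ha, threshold = 1000) {
  stopifnot(inherits(ha, "ha_table"))
  if (is.null(ha$mean)) stop("summarize the table first", call. = FALSE)
  mx <- apply(ha$mean, 1, function(r) {
    if (all(is.na(r))) -Inf else max(r, na.rm = TRUE)
  })
  rownames(ha$mean)[mx > threshold]
}

normalize_compound_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read the packaged compound annotation
#'
#' Chemistry flags for the 23 higher alcohols of the study: whether the
#' compound is a straight-chain saturated alkan-1-ol, and its carbon count.
#'
#' @param path Annotation CSV; defaults to the packaged file.
#' @return A data.frame (compound, is_straight_chain_saturated_alkan1ol,
#'   carbon_count).
#' @export
read_compound_annotation <- function(path = system.file(
  "extdata", "compound_annotation.csv", package = "huangjiucore")) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "is_straight_chain_saturated_alkan1ol", "carbon_count")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Classify straight-chain saturated alkan-1-ols
#'
#' Table-driven classification (no name parsing): compounds are matched to
#' the annotation case-insensitively after punctuation normalization, and
#' those flagged as straight-chain saturated alkan-1-ols are returned.
#' Unsaturated or branched "-1-ol" names (e.g. 9,12-octadecadien-1-ol) are
#' excluded by the annotation, not by string logic.
#'
#' @param ha An [ha_table()].
#' @param annotation Annotation data.frame from [read_compound_annotation()].
#' @return Character vector of alkan-1-ol compound names (table spelling).
#' @export
classify_alkanols <- function(ha, annotation = read_compound_annotation()) {
  stopifnot(inherits(ha, "ha_table"))
  compounds <- rownames(if (is.null(ha$mean)) ha$replicate_values else ha$mean)
  key <- normalize_compound_name(annotation$compound)
  idx <- match(normalize_compound_name(compounds), key)
  if (anyNA(idx)) {
    stop("unannotated compound(s): ",
         paste(compounds[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  compounds[annotation$is_straight_chain_saturated_alkan1ol[idx]]
}

#' Load the study's higher-alcohol concentration table
#'
#' The packaged compound-by-timepoint table of mean (and optionally SE)
#' concentrations over the 10-day fermentation, with ND cells masked.
#'
#' @param with_se Load the mean-and-SE variant (default) or means only.
#' @return A summarized [ha_table()]: 23 compounds x 6 timepoints.
#' @export
ha_table1 <- function(with_se = TRUE) {
  f <- if (with_se) "table1_mean_se.csv" else "table1_mean.csv"
  read_ha_csv(system.file("extdata", f, package = "huangjiucore"))
}
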