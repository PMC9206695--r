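#' @keywords internal
"_PACKAGE"

# Sample ids follow the fermentation design: D{day}R{rep}, e.g. D4R2 is the
# second parallel mash sample drawn on day 4.

#' Parse fermentation sample identifiers
#'
#' Sample ids encode the sampling day and parallel replicate as
#' \code{D\{day\}R\{rep\}} (e.g. \code{"D10R3"}).
#'
#' @param ids Character vector of sample ids.
#' @return A data.frame with columns \code{sample}, \code{day} (integer) and
#'   \code{replicate} (integer).
#' @examples
#' parse_sample_ids(c("D0R1", "D10R3"))
#' @export
parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^D([0-9]+)R([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("sample ids not parseable as D{day}R{rep}: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    sample = ids,
    day = as.integer(vapply(m, `[`, "", 2L)),
    replicate = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Construct a taxon abundance table
#'
#' A light container for a taxa-by-samples abundance matrix (counts or
#' relative abundances) with an optional taxonomy lineage per taxon.
#'
#' @param x Non-negative numeric matrix, taxa in rows (rownames = taxon ids),
#'   samples in columns (colnames = sample ids, \code{D\{day\}R\{rep\}}).
#' @param lineage Optional character vector of rank-prefixed lineages
#'   (\code{"k__...;p__...;...;g__..."}), one per taxon.
#' @return An object of class \code{abundance_table}.
#' @export
abundance_table <- function(x, lineage = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("abundance matrix needs taxon rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate taxon ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(lineage)) {
    if (length(lineage) != nrow(x)) {
      stop("lineage length must match the number of taxa", call. = FALSE)
    }
    names(lineage) <- rownames(x)
  }
  structure(list(abund = x, lineage = lineage), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples%s\n",
              nrow(x$abund), ncol(x$abund),
              if (is.null(x$lineage)) "" else " (with lineage)"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$abund)

#' Construct a higher-alcohol concentration table
#'
#' Holds per-timepoint summaries (mean, standard error, not-detected mask)
#' and optionally the underlying replicate-level concentrations. "ND" (no
#' detection) is an explicit mask, never a zero: a compound below the
#' method's detection capability is distinct from one measured at zero.
#'
#' @param mean Compounds-by-timepoints matrix of mean concentrations (ug/L);
#'   \code{NA} where not detected. May be \code{NULL} when only
#'   replicate-level values exist (see [summarize_replicates()]).
#' @param se Matrix of standard errors, same shape as \code{mean}, or NULL.
#' @param replicate_values Optional compounds-by-samples matrix of
#'   replicate-level concentrations (\code{NA} = ND), sample ids
#'   \code{D\{day\}R\{rep\}}.
#' @return An object of class \code{ha_table} with fields \code{mean},
#'   \code{se}, \code{nd} (logical mask), \code{replicate_values}.
#' @export
ha_table <- function(mean = NULL, se = NULL, replicate_values = NULL) {
  if (is.null(mean) && is.null(replicate_values)) {
    stop("ha_table needs summary means and/or replicate values", call. = FALSE)
  }
  nd <- NULL
  if (!is.null(mean)) {
    mean <- as.matrix(mean)
    if (is.null(rownames(mean)) || is.null(colnames(mean))) {
      stop("summary matrix needs compound rownames and timepoint colnames",
           call. = FALSE)
    }
    nd <- is.na(mean)
    if (any(mean[!nd] < 0)) {
      stop("concentrations must be non-negative where detected", call. = FALSE)
    }
    if (!is.null(se)) {
      se <- as.matrix(se)
      stopifnot(identical(dim(se), dim(mean)))
    }
  }
  if (!is.null(replicate_values)) {
    replicate_values <- as.matrix(replicate_values)
    parse_sample_ids(colnames(replicate_values))  # validates ids
    if (any(replicate_values[!is.na(replicate_values)] < 0)) {
      stop("concentrations must be non-negative where detected", call. = FALSE)
    }
  }
  structure(
    list(mean = mean, se = se, nd = nd, replicate_values = replicate_values),
    class = "ha_table"
  )
}

#' @export
print.ha_table <- function(x, ...) {
  if (!is.null(x$mean)) {
    cat(sprintf("ha_table: %d compounds x %d timepoints (%d ND cells)\n",
                nrow(x$mean), ncol(x$mean), sum(x$nd)))
  }
  if (!is.null(x$replicate_values)) {
    cat(sprintf("  replicate-level: %d compounds x %d samples\n",
                nrow(x$replicate_values), ncol(x$replicate_values)))
  }
  invisible(x)
}

#' Construct a GC-MS peak table
#'
#' One record per (compound, sample): the analyte peak area and the
#' internal-standard peak area from the same chromatogram.
#'
#' @param compound Character vector of compound names.
#' @param sample_id Character vector of sample ids (\code{D\{day\}R\{rep\}}).
#' @param area Analyte peak areas (arbitrary units, >= 0).
#' @param is_area Internal-standard peak areas (> 0).
#' @return A data.frame of class \code{peak_table}.
#' @export
peak_table <- function(compound, sample_id, area, is_area) {
  df <- data.frame(
    compound = as.character(compound),
    sample_id = as.character(sample_id),
    area = as.numeric(area),
    is_area = as.numeric(is_area),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$area)) || any(df$area < 0)) {
    stop("peak areas must be finite and non-negative", call. = FALSE)
  }
  bad <- !is.finite(df$is_area) | df$is_area <= 0
  if (any(bad)) {
    stop("internal-standard area must be positive; offending records: ",
         paste(sprintf("%s/%s", df$compound[bad], df$sample_id[bad]),
               collapse = ", "), call. = FALSE)
  }
  parse_sample_ids(unique(df$sample_id))
  class(df) <- c("peak_table", "data.frame")
  df
}

# day labels for ha_table timepoint columns
day_label <- function(day) paste0("D", day)

label_day <- function(label) {
  d <- suppressWarnings(as.integer(sub("^D", "", label)))
  if (any(is.na(d))) {
    stop("timepoint labels must look like D{day}: ",
         paste(label[is.na(d)], collapse = ", "), call. = FALSE)
  }
  d
}
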