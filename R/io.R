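# Plain-text readers/writers. Readers reject malformed input with cell
# coordinates rather than coercing; every writer's output is re-readable.

# strip S3 classes recursively so config echoes serialize as plain JSON
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

parse_numeric_cells <- function(x, where) {
  # locale-independent: dot decimal; comma / thin-space / NBSP thousands
  # separators stripped
  cleaned <- gsub("[,\u2009\u202f\u00a0]", "", x)
  v <- suppressWarnings(as.numeric(cleaned))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stop("malformed numeric cell(s) at ",
         paste(utils::head(where[bad], 5), collapse = "; "),
         call. = FALSE)
  }
  v
}

#' Read a taxa-by-samples abundance TSV
#'
#' First column: taxon id; remaining columns: sample abundances; an optional
#' final \code{lineage} column carries rank-prefixed taxonomy strings.
#' Duplicate taxon ids, ragged rows and non-numeric abundance cells are
#' rejected with coordinates.
#'
#' @param path TSV file.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "",
                          na.strings = character(0))
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("abundance TSV needs a taxon column and at least one sample",
         call. = FALSE)
  }
  taxa <- df[[1]]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon ids: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  lineage <- NULL
  value_cols <- names(df)[-1]
  if (utils::tail(names(df), 1) == "lineage") {
    lineage <- df$lineage
    value_cols <- setdiff(value_cols, "lineage")
  }
  m <- matrix(NA_real_, length(taxa), length(value_cols),
              dimnames = list(taxa, value_cols))
  for (j in value_cols) {
    m[, j] <- parse_numeric_cells(
      df[[j]], sprintf("row %d (taxon %s), column %s", seq_along(taxa),
                       taxa, j))
  }
  abundance_table(m, lineage = lineage)
}

#' Write a taxa-by-samples abundance TSV
#'
#' @param table An [abundance_table()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(taxon = rownames(table$abund), table$abund,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$lineage)) df$lineage <- unname(table$lineage)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide concentration CSV
#'
#' Layout: a \code{compound} column, then \code{D\{day\}_mean} and optional
#' \code{D\{day\}_se} columns. The token \code{"ND"} maps to the
#' not-detected mask (never to 0). Thousands separators (comma, thin space)
#' are stripped; unknown columns are rejected.
#'
#' @param path CSV file.
#' @return A summarized [ha_table()].
#' @export
read_ha_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character(0))
  if (nrow(df) == 0 || !"compound" %in% names(df)) {
    stop("concentration CSV needs a compound column and data rows",
         call. = FALSE)
  }
  other <- setdiff(names(df), "compound")
  is_mean <- grepl("^D[0-9]+_mean$", other)
  is_se <- grepl("^D[0-9]+_se$", other)
  if (any(!is_mean & !is_se)) {
    stop("unknown column(s): ",
         paste(other[!is_mean & !is_se], collapse = ", "), call. = FALSE)
  }
  days <- sort(unique(as.integer(sub("^D([0-9]+)_.*$", "\\1", other))))
  labs <- day_label(days)
  compounds <- df$compound
  grab <- function(suffix) {
    cols <- paste0(labs, suffix)
    if (!any(cols %in% names(df))) return(NULL)
    m <- matrix(NA_real_, length(compounds), length(labs),
                dimnames = list(compounds, labs))
    for (j in seq_along(cols)) {
      if (!cols[j] %in% names(df)) next
      raw <- df[[cols[j]]]
      raw[raw == "ND"] <- NA
      m[, j] <- parse_numeric_cells(
        raw, sprintf("row %d (%s), column %s", seq_along(compounds),
                     compounds, cols[j]))
    }
    m
  }
  ha_table(mean = grab("_mean"), se = grab("_se"))
}

#' Write a wide concentration CSV
#'
#' Inverse of [read_ha_csv()]; ND cells are written as the literal token
#' \code{"ND"}.
#'
#' @param ha A summarized [ha_table()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_ha_csv <- function(ha, path) {
  stopifnot(inherits(ha, "ha_table"))
  if (is.null(ha$mean)) stop("summarize the table first", call. = FALSE)
  fmt <- function(m) {
    out <- ifelse(is.na(m), "ND", format(m, trim = TRUE, scientific = FALSE))
    out
  }
  df <- data.frame(compound = rownames(ha$mean), stringsAsFactors = FALSE)
  for (lab in colnames(ha$mean)) {
    df[[paste0(lab, "_mean")]] <- fmt(ha$mean[, lab])
    if (!is.null(ha$se)) df[[paste0(lab, "_se")]] <- fmt(ha$se[, lab])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a GC-MS peak CSV
#'
#' Columns: compound, sample_id, area, is_area.
#'
#' @param path CSV file.
#' @return A [peak_table()].
#' @export
read_peak_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character",
                        na.strings = character(0))
  need <- c("compound", "sample_id", "area", "is_area")
  if (!identical(sort(names(df)), sort(need))) {
    stop("peak CSV must have exactly the columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  peak_table(
    df$compound, df$sample_id,
    parse_numeric_cells(df$area, sprintf("row %d, column area",
                                         seq_len(nrow(df)))),
    parse_numeric_cells(df$is_area, sprintf("row %d, column is_area",
                                            seq_len(nrow(df))))
  )
}

#' Write a GC-MS peak CSV
#'
#' @param peaks A [peak_table()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_peak_csv <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_table"))
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Build a provenance record for a run
#'
#' Config echo, seed, package version and content hashes of any input files
#' — enough to re-identify exactly what a result was computed from.
#'
#' @param config A configuration object (echoed as-is).
#' @param seed The run's seed.
#' @param input_paths Named character vector of input files to hash (md5).
#' @return A list suitable for JSON serialization.
#' @export
provenance_record <- function(config, seed, input_paths = character(0)) {
  hashes <- if (length(input_paths) > 0) {
    as.list(tools::md5sum(input_paths))
  } else {
    list()
  }
  list(
    package = "huangjiucore",
    version = as.character(utils::packageVersion("huangjiucore")),
    seed = seed,
    config = unclass_deep(config),
    input_md5 = hashes
  )
}
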