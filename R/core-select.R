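# The two-criterion core-taxon call: permutation-significant genera that sit
# in the top abundance stratum and correlate with stably detected alcohols.

#' Core-taxon selection criteria
#'
#' @param top_fraction Abundance stratum: the genus must rank in the top
#'   fraction by mean relative abundance (default top 20\%).
#' @param min_detections A higher alcohol is "stable" when detected in at
#'   least this many timepoints (default 5 of 6).
#' @param p_cutoff Significance cutoff for the supporting taxon-HA
#'   correlation.
#' @param require_significant Restrict candidates to the
#'   permutation-significant O2PLS pool.
#' @return A list of class \code{core_criteria}.
#' @export
core_criteria <- function(top_fraction = 0.20, min_detections = 5,
                          p_cutoff = 0.05, require_significant = TRUE) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  if (min_detections < 1) stop("min_detections must be >= 1", call. = FALSE)
  structure(list(top_fraction = top_fraction,
                 min_detections = min_detections, p_cutoff = p_cutoff,
                 require_significant = require_significant),
            class = "core_criteria")
}

#' Select functional core HA-producing genera
#'
#' A genus is core when it (a) belongs to the permutation-significant pool
#' (if required), (b) ranks in the top abundance stratum, and (c) has at
#' least one significant correlation with a stable higher alcohol. The
#' correlation gate uses the BH-adjusted p-value when the association stage
#' ran with FDR, the raw p-value otherwise.
#'
#' @param significant_taxa Character vector of permutation-significant genus
#'   ids (X side of [o2pls_permutation_test()]).
#' @param assoc A taxon-HA \code{assoc_result} (filtered or not; the p/q
#'   gate is applied here).
#' @param abundance An [abundance_table()] over the same genus ids.
#' @param ha_stats [detection_stats()] output defining stability.
#' @param criteria A [core_criteria()].
#' @return An object of class \code{core_taxa_report}: \code{core_taxa}
#'   (ordered by descending mean relative abundance, then lexicographically),
#'   \code{evidence} (one row per supporting taxon-HA edge), \code{candidates}
#'   (per-taxon gate outcomes), \code{criteria}.
#' @export
select_core <- function(significant_taxa, assoc, abundance, ha_stats,
                        criteria = core_criteria()) {
  stopifnot(inherits(assoc, "assoc_result"),
            inherits(abundance, "abundance_table"),
            inherits(criteria, "core_criteria"))
  taxa <- rownames(abundance$abund)
  unmatched <- setdiff(significant_taxa, taxa)
  if (length(unmatched) > 0) {
    stop("significant taxa absent from the abundance table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  bad_src <- setdiff(assoc$edges$source, taxa)
  if (length(bad_src) > 0) {
    stop("association sources absent from the abundance table: ",
         paste(utils::head(bad_src, 5), collapse = ", "), call. = FALSE)
  }

  rel <- to_relative(abundance)$abund
  mu <- rowMeans(rel)
  top <- top_fraction(abundance, criteria$top_fraction)
  stable <- ha_stats$per_compound$compound[
    ha_stats$per_compound$n_detected >= criteria$min_detections]

  e <- assoc$edges
  gate <- if (isTRUE(assoc$config$use_fdr)) e$q else e$p
  support <- e[gate <= criteria$p_cutoff & e$target %in% stable, ,
               drop = FALSE]

  in_sig <- if (criteria$require_significant) taxa %in% significant_taxa
            else rep(TRUE, length(taxa))
  cand <- data.frame(
    taxon = taxa,
    mean_rel_abundance = unname(mu),
    abundance_rank = rank(-mu, ties.method = "min"),
    significant = in_sig,
    in_top_fraction = taxa %in% top,
    stable_ha_link = taxa %in% support$source,
    stringsAsFactors = FALSE
  )
  cand$core <- cand$significant & cand$in_top_fraction & cand$stable_ha_link
  core <- cand$taxon[cand$core]
  core <- core[order(-mu[core], core)]

  structure(list(
    core_taxa = core,
    evidence = support[support$source %in% core, , drop = FALSE],
    candidates = cand,
    stable_has = stable,
    criteria = criteria
  ), class = "core_taxa_report")
}

#' @export
print.core_taxa_report <- function(x, ...) {
  cat(sprintf("core_taxa_report: %d core genera\n", length(x$core_taxa)))
  if (length(x$core_taxa) > 0) {
    cat("  ", paste(x$core_taxa, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a core-taxon report as JSON
#'
#' @param report A \code{core_taxa_report}.
#' @param path Output JSON path.
#' @param provenance Optional provenance list to embed.
#' @return \code{path}, invisibly.
#' @export
write_core_report_json <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "core_taxa_report"))
  obj <- list(core_taxa = report$core_taxa, evidence = report$evidence,
              candidates = report$candidates, stable_has = report$stable_has,
              criteria = unclass(report$criteria))
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
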