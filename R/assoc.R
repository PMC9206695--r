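# Pearson taxon-metabolite and taxon-taxon association with BH-FDR control
# and network export.

#' Association analysis configuration
#'
#' @param p_cutoff Significance level applied to raw (and, when
#'   \code{use_fdr}, adjusted) p-values.
#' @param use_fdr Also require the Benjamini-Hochberg adjusted p-value to
#'   pass the cutoff.
#' @param robust_r Absolute-correlation threshold for the "robust" flag
#'   (a flag, not a filter: correlations can be significant without being
#'   robust).
#' @param nd_policy How ND concentrations enter correlation: \code{"zero"}
#'   (absence is signal) or \code{"drop-pairwise"} (pairwise-complete
#'   observations).
#' @param sample_matching Correlate at \code{"replicate-level"} (all
#'   samples) or on \code{"timepoint-means"}.
#' @return A list of class \code{assoc_config}.
#' @export
assoc_config <- function(p_cutoff = 0.05, use_fdr = TRUE, robust_r = 0.95,
                         nd_policy = c("zero", "drop-pairwise"),
                         sample_matching = c("replicate-level",
                                             "timepoint-means")) {
  if (p_cutoff <= 0 || p_cutoff >= 1) {
    stop("p_cutoff must be in (0, 1)", call. = FALSE)
  }
  if (robust_r <= 0 || robust_r > 1) {
    stop("robust_r must be in (0, 1]", call. = FALSE)
  }
  structure(list(p_cutoff = p_cutoff, use_fdr = use_fdr,
                 robust_r = robust_r, nd_policy = match.arg(nd_policy),
                 sample_matching = match.arg(sample_matching)),
            class = "assoc_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1 and mapped
#' back to the input order (delegates to \code{stats::p.adjust}).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# r and two-sided p for every (row of X) x (row of Y) pair; NA-aware
pairwise_cor <- function(X, Y) {
  tx <- t(X); ty <- t(Y)
  r <- suppressWarnings(stats::cor(tx, ty, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(tx), !is.na(ty))           # per-pair sample size
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[abs(r) >= 1 - 1e-15] <- 0
  p[n < 3] <- NA_real_
  list(r = r, p = p, n = n)
}

#' Pairwise Pearson correlation between two feature blocks
#'
#' Computes the sample Pearson coefficient and its two-sided t-distribution
#' p-value (n - 2 df) for every (X-feature, Y-feature) pair, adjusts all
#' p-values jointly by Benjamini-Hochberg, and returns an edge set plus node
#' metadata. Zero-variance features yield no edges and a warning.
#'
#' @param X,Y Features-by-samples numeric matrices sharing an identical
#'   ordered sample axis (colnames).
#' @param config An [assoc_config()].
#' @param type_x,type_y Node type labels (\code{"taxon"}, \code{"HA"}, ...).
#' @return An object of class \code{assoc_result}: \code{edges} (source,
#'   target, r, p, q, n, robust, sign), \code{nodes} (id, type, mean_value),
#'   \code{config}.
#' @export
pearson_pairwise <- function(X, Y, config = assoc_config(),
                             type_x = "taxon", type_y = "HA") {
  stopifnot(is.matrix(X), is.matrix(Y))
  if (!identical(colnames(X), colnames(Y))) {
    stop("X and Y must share an identical ordered sample axis", call. = FALSE)
  }
  if (ncol(X) < 3) stop("need at least 3 samples", call. = FALSE)
  drop_const <- function(M, label) {
    v <- apply(M, 1, function(z) stats::var(z, na.rm = TRUE))
    const <- !is.na(v) & v == 0 | is.na(v)
    if (any(const)) {
      warning(sprintf("dropping %d zero-variance %s feature(s): %s",
                      sum(const), label,
                      paste(utils::head(rownames(M)[const], 5),
                            collapse = ", ")), call. = FALSE)
    }
    M[!const, , drop = FALSE]
  }
  Xv <- drop_const(X, type_x)
  Yv <- drop_const(Y, type_y)
  pc <- pairwise_cor(Xv, Yv)
  edges <- data.frame(
    source = rep(rownames(Xv), times = ncol(pc$r)),
    target = rep(rownames(Yv), each = nrow(pc$r)),
    r = as.vector(pc$r), p = as.vector(pc$p), n = as.vector(pc$n),
    stringsAsFactors = FALSE
  )
  edges <- edges[!is.na(edges$r) & !is.na(edges$p), , drop = FALSE]
  edges$q <- bh_adjust(edges$p)
  edges$robust <- abs(edges$r) > config$robust_r
  edges$sign <- ifelse(edges$r >= 0, "+", "-")
  nodes <- data.frame(
    id = c(rownames(X), if (!identical(X, Y)) rownames(Y)),
    type = c(rep(type_x, nrow(X)),
             if (!identical(X, Y)) rep(type_y, nrow(Y))),
    mean_value = c(rowMeans(X, na.rm = TRUE),
                   if (!identical(X, Y)) rowMeans(Y, na.rm = TRUE)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(edges = edges, nodes = nodes, config = config),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: %d edges over %d nodes\n",
              nrow(x$edges), nrow(x$nodes)))
  invisible(x)
}

#' Filter an association edge set
#'
#' Retains edges with \code{p <= p_cutoff} (and, when the analysis used FDR,
#' \code{q <= p_cutoff}) and refreshes the robust flag at
#' \code{|r| > robust_r}.
#'
#' @param result An [pearson_pairwise()] result.
#' @param config An [assoc_config()]; defaults to the one stored in
#'   \code{result}.
#' @return The filtered \code{assoc_result} (nodes untouched, so isolated
#'   nodes remain reportable).
#' @export
filter_edges <- function(result, config = result$config) {
  stopifnot(inherits(result, "assoc_result"))
  e <- result$edges
  keep <- e$p <= config$p_cutoff
  if (config$use_fdr) {
    if (is.null(e$q)) stop("use_fdr requires adjusted p-values", call. = FALSE)
    keep <- keep & e$q <= config$p_cutoff
  }
  e <- e[keep, , drop = FALSE]
  e$robust <- abs(e$r) > config$robust_r
  result$edges <- e
  result$config <- config
  result
}

#' Correlate taxa with higher alcohols
#'
#' Aligns the abundance table and concentration table on the sample axis
#' (replicate level, n = 18 in the study design, or timepoint means, n = 6),
#' applies the ND policy, and runs [pearson_pairwise()].
#'
#' @param abundance An [abundance_table()] (converted to relative
#'   abundances internally).
#' @param ha An [ha_table()] with replicate values (for replicate-level
#'   matching) or summary means.
#' @param config An [assoc_config()].
#' @return An \code{assoc_result} of taxon-HA edges (unfiltered; apply
#'   [filter_edges()]).
#' @export
correlate_taxa_ha <- function(abundance, ha, config = assoc_config()) {
  stopifnot(inherits(abundance, "abundance_table"), inherits(ha, "ha_table"))
  rel <- to_relative(abundance)$abund
  if (config$sample_matching == "replicate-level") {
    if (is.null(ha$replicate_values)) {
      stop("replicate-level matching needs replicate concentrations",
           call. = FALSE)
    }
    Y <- ha$replicate_values
  } else {
    if (is.null(ha$mean)) stop("timepoint-means matching needs a summarized ",
                               "table", call. = FALSE)
    Y <- ha$mean
    days <- parse_sample_ids(colnames(rel))$day
    agg <- t(rowsum(t(rel), group = days) /
               as.vector(table(factor(days, levels = sort(unique(days))))))
    colnames(agg) <- day_label(sort(unique(days)))
    rel <- agg[, colnames(Y), drop = FALSE]
  }
  common <- intersect(colnames(rel), colnames(Y))
  if (length(common) < 3) {
    stop("fewer than 3 shared samples between the tables", call. = FALSE)
  }
  rel <- rel[, common, drop = FALSE]
  Y <- Y[, common, drop = FALSE]
  if (config$nd_policy == "zero") Y[is.na(Y)] <- 0
  pearson_pairwise(rel, Y, config, type_x = "taxon", type_y = "HA")
}

#' Taxon co-occurrence network
#'
#' All pairwise taxon-taxon Pearson correlations (undirected: each unordered
#' pair appears once), with BH adjustment over the pair set. Isolated taxa
#' remain in the node metadata after filtering.
#'
#' @param table An [abundance_table()] with at least 3 samples.
#' @param config An [assoc_config()].
#' @param filter Apply [filter_edges()] before returning.
#' @return An \code{assoc_result} of taxon-taxon edges.
#' @export
cooccurrence_network <- function(table, config = assoc_config(),
                                 filter = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  rel <- to_relative(table)$abund
  res <- pearson_pairwise(rel, rel, config, type_x = "taxon",
                          type_y = "taxon")
  e <- res$edges
  e <- e[e$source < e$target, , drop = FALSE]   # undirected, no self-loops
  e$q <- bh_adjust(e$p)
  res$edges <- e
  if (filter) res <- filter_edges(res, config)
  res
}

#' Write an edge list as TSV
#'
#' @param result An \code{assoc_result}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_edges_tsv <- function(result, path) {
  stopifnot(inherits(result, "assoc_result"))
  utils::write.table(result$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an association network as GraphML
#'
#' Nodes carry type and mean abundance/concentration; edges carry r, p, q,
#' robust and sign. Isolated nodes are included.
#'
#' @param result An \code{assoc_result}.
#' @param path Output GraphML file.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(result, path) {
  stopifnot(inherits(result, "assoc_result"))
  g <- igraph::graph_from_data_frame(result$edges, directed = FALSE,
                                     vertices = result$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
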