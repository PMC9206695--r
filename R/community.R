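# Abundance-table processing and alpha diversity.

#' Convert an abundance table to relative abundances
#'
#' Each sample (column) is divided by its total so columns sum to 1. Ratios
#' within a sample are preserved; the operation is idempotent.
#'
#' @param table An [abundance_table()].
#' @return An [abundance_table()] of relative abundances.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- colSums(table$abund)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(table$abund)[tot == 0], collapse = ", "),
         call. = FALSE)
  }
  abundance_table(sweep(table$abund, 2, tot, "/"), lineage = table$lineage)
}

#' Simpson index (dominance form)
#'
#' Returns \eqn{\sum_i p_i^2}: the probability that two random draws belong
#' to the same taxon. Larger values mean stronger dominance and therefore
#' lower diversity; it is minimized at \eqn{1/k} by the uniform distribution
#' over k taxa. Set \code{complement = TRUE} for the Gini-Simpson form
#' \eqn{1 - \sum p_i^2}.
#'
#' @param p Relative abundances of one sample (non-negative, summing to 1
#'   within \code{tol}).
#' @param complement Return \eqn{1 - \sum p_i^2} instead.
#' @param tol Tolerance on the sum-to-one check.
#' @return Unitless index in (0, 1].
#' @export
simpson_index <- function(p, complement = FALSE, tol = 1e-6) {
  if (any(p < 0)) stop("relative abundances must be non-negative",
                       call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("input must sum to 1 (got %.8f); normalize first", sum(p)),
         call. = FALSE)
  }
  d <- sum(p^2)
  if (complement) 1 - d else d
}

#' Chao1 richness estimator
#'
#' Bias-corrected form
#' \eqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, where
#' \eqn{F_1} and \eqn{F_2} are the singleton and doubleton counts; this form
#' is defined even when no doubletons exist. The classical form
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} is available where \eqn{F_2 > 0}.
#'
#' @param counts Integer abundances of one sample.
#' @param bias_corrected Use the +1-corrected form (default).
#' @return Estimated richness (>= observed richness, with equality iff no
#'   singletons).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("chao1 needs non-negative integer counts", call. = FALSE)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) {
      stop("classical Chao1 undefined with no doubletons; use the ",
           "bias-corrected form", call. = FALSE)
    }
    s_obs + f1^2 / (2 * f2)
  }
}

#' Per-sample alpha diversity
#'
#' Simpson dominance for every sample; observed richness and bias-corrected
#' Chao1 where the table holds integer counts (Chao1 is meaningless on
#' relative abundances and is reported NA there).
#'
#' @param table An [abundance_table()].
#' @return A data.frame: sample, observed, simpson, chao1.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$abund
  rel <- to_relative(table)$abund
  is_counts <- all(x == round(x))
  data.frame(
    sample = colnames(x),
    observed = apply(x, 2, function(v) sum(v > 0)),
    simpson = apply(rel, 2, simpson_index),
    chao1 = if (is_counts) apply(x, 2, chao1) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  out <- setNames(rep(NA_character_, length(rank_prefixes)),
                  names(rank_prefixes))
  for (p in parts) {
    m <- regmatches(p, regexec("^([kpcofgs])__(.*)$", p))[[1]]
    if (length(m) == 3) {
      rk <- names(rank_prefixes)[match(m[2], rank_prefixes)]
      out[rk] <- if (nzchar(m[3])) m[3] else NA_character_
    }
  }
  out
}

#' Aggregate an abundance table to a taxonomy rank
#'
#' Rows are summed within identical labels at the requested rank. Taxa whose
#' lineage is unclassified at that rank are pooled per deepest classified
#' ancestor into a \code{norank_} label (e.g.
#' \code{norank_f_Erysipelotrichaceae}). Each sample's total abundance is
#' conserved exactly.
#'
#' @param table An [abundance_table()] with lineage for every taxon.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @return An aggregated [abundance_table()] (no lineage).
#' @export
aggregate_to_rank <- function(table, rank = "genus") {
  stopifnot(inherits(table, "abundance_table"))
  rank <- match.arg(rank, names(rank_prefixes))
  if (is.null(table$lineage)) {
    stop("aggregate_to_rank needs a lineage for every taxon", call. = FALSE)
  }
  ranks <- names(rank_prefixes)
  upto <- ranks[seq_len(match(rank, ranks))]
  labels <- vapply(table$lineage, function(lin) {
    parsed <- parse_lineage(lin)[upto]
    if (!is.na(parsed[[rank]])) return(parsed[[rank]])
    # unclassified at the target rank: pool under the deepest named ancestor
    known <- which(!is.na(parsed))
    if (length(known) == 0) return("norank")
    deepest <- ranks[max(known)]
    sprintf("norank_%s_%s", rank_prefixes[[deepest]], parsed[[deepest]])
  }, "")
  agg <- rowsum(table$abund, group = labels)
  abundance_table(agg[order(rownames(agg)), , drop = FALSE])
}

#' Top-abundance taxon stratum
#'
#' Taxa ranked by mean relative abundance across all samples (descending,
#' ties broken lexicographically by taxon id); returns the first
#' \code{ceiling(fraction x n_taxa)} so the set is never empty.
#'
#' @param table An [abundance_table()].
#' @param fraction Proportion of taxa to keep, in (0, 1].
#' @return Character vector of taxon ids, in rank order.
#' @export
top_fraction <- function(table, fraction = 0.20) {
  stopifnot(inherits(table, "abundance_table"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  if (nrow(table$abund) == 0) stop("empty abundance table", call. = FALSE)
  rel <- to_relative(table)$abund
  mu <- rowMeans(rel)
  ord <- order(-mu, rownames(rel))
  rownames(rel)[ord][seq_len(ceiling(fraction * nrow(rel)))]
}
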