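# Synthetic fermentation generator: paired genus abundances and higher-alcohol
# concentrations with planted producer taxa, so every downstream stage has a
# recoverable ground truth.

#' Configuration for the synthetic fermentation generator
#'
#' Defaults emulate the 10-day Huangjiu study design: 6 sampling days
#' (0, 2, ..., 10), 3 parallel mash replicates per day, one strongly dominant
#' genus over a long tail of minor genera, and a handful of producer genera
#' whose abundances linearly drive a subset of higher alcohols.
#'
#' @param n_taxa Number of genera.
#' @param n_timepoints Number of sampling days (>= 2); days are
#'   \code{0, 2, 4, ...}.
#' @param n_replicates Parallel replicates per day.
#' @param n_producers Number of planted producer genera (<= n_taxa - 1; the
#'   dominant genus is never a producer).
#' @param n_has Number of higher alcohols; the first \code{n_producers} of
#'   them (capped at \code{n_has}) are producer-driven, the rest are pure
#'   noise.
#' @param effect_size Slope linking producer relative abundance to the driven
#'   alcohol's concentration (unitless; concentration also scales with
#'   \code{concentration_scale}).
#' @param noise_sd Relative SD of the multiplicative log-normal noise applied
#'   per replicate (GC-MS and community noise are roughly proportional).
#' @param dominant_taxon_fraction Lower target for the dominant genus's mean
#'   relative abundance, in [0, 1).
#' @param detection_limit Concentration (ug/L) below which a value is
#'   recorded as ND.
#' @param concentration_scale ug/L produced per unit of
#'   (effect x relative abundance).
#' @param seed Integer seed; identical configs give identical datasets.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_taxa = 50, n_timepoints = 6, n_replicates = 3,
                       n_producers = 5, n_has = 10, effect_size = 1,
                       noise_sd = 0.1, dominant_taxon_fraction = 0.5,
                       detection_limit = 0.5, concentration_scale = 1000,
                       seed = 1) {
  if (n_producers > n_taxa - 1) {
    stop("n_producers must be <= n_taxa - 1", call. = FALSE)
  }
  if (n_timepoints < 2) stop("n_timepoints must be >= 2", call. = FALSE)
  if (dominant_taxon_fraction < 0 || dominant_taxon_fraction >= 1) {
    stop("dominant_taxon_fraction must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_taxa < 2 || n_has < 1 || n_replicates < 1) {
    stop("invalid generator dimensions", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_days <- function(config) seq(0, by = 2, length.out = config$n_timepoints)

sim_sample_ids <- function(config) {
  days <- sim_days(config)
  as.vector(t(outer(days, seq_len(config$n_replicates),
                    function(d, r) sprintf("D%dR%d", d, r))))
}

# multiplicative log-normal noise, mean-preserving (E[factor] = 1)
lnoise <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  exp(stats::rnorm(n, mean = -sd^2 / 2, sd = sd))
}

#' Generate a synthetic fermentation community
#'
#' Builds a taxa-by-samples relative-abundance table with one dominant genus
#' (constant high weight), \code{n_producers} producer genera following
#' smooth temporal templates (logistic growth or a Gaussian bump, selected per
#' taxon by seed), and a compositional background of minor genera with
#' constant expected levels. Replicates share the timepoint mean and differ
#' only by noise.
#'
#' @param config A [sim_config()].
#' @return A list with elements \code{abundance} (an [abundance_table()] of
#'   relative abundances) and \code{truth}, the planted ground truth:
#'   \code{producer_ids}, \code{dominant_id}, \code{driven_has},
#'   \code{effect_matrix} (producers x alcohols slopes) and
#'   \code{planted_stable_has} (filled by [simulate_dataset()]).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  days <- sim_days(config)
  taxa <- sprintf("Genus%03d", seq_len(config$n_taxa))
  dominant <- taxa[1]
  producers <- taxa[1 + seq_len(config$n_producers)]
  samples <- sim_sample_ids(config)
  day_of <- rep(days, each = config$n_replicates)

  # expected weight per taxon per day (before closure)
  w <- matrix(0, config$n_taxa, length(days), dimnames = list(taxa, NULL))
  # background: constant low level drawn once per taxon
  bg <- setdiff(taxa, c(dominant, producers))
  w[bg, ] <- stats::rlnorm(length(bg), meanlog = log(0.008), sdlog = 0.5)
  # producers: smooth succession-like trajectories whose temporal mean sits
  # clearly inside the top-20% abundance stratum of the community
  tspan <- diff(range(days))
  for (g in producers) {
    lo <- stats::runif(1, 0.008, 0.012)
    hi <- stats::runif(1, 0.05, 0.09)
    if (stats::runif(1) < 0.5) {           # logistic growth
      t0 <- stats::runif(1, 0.3, 0.7) * tspan
      k <- stats::runif(1, 0.6, 1.2)
      w[g, ] <- lo + (hi - lo) / (1 + exp(-k * (days - t0)))
    } else {                               # Gaussian bump
      mu <- stats::runif(1, 0.3, 0.7) * tspan
      sig <- stats::runif(1, 0.2, 0.35) * tspan
      w[g, ] <- lo + (hi - lo) * exp(-(days - mu)^2 / (2 * sig^2))
    }
  }
  # dominant: weight chosen per day so its noiseless share clears the target
  # fraction with margin against closure noise
  f <- config$dominant_taxon_fraction
  target <- f + 0.15 * (1 - f)
  other_sum <- colSums(w)
  w[dominant, ] <- target / (1 - target) * other_sum

  # expand to replicates, apply per-cell multiplicative noise, close to 1
  a <- w[, match(day_of, days), drop = FALSE]
  colnames(a) <- samples
  a <- a * matrix(lnoise(length(a), config$noise_sd), nrow(a), ncol(a))
  a <- sweep(a, 2, colSums(a), "/")

  driven <- sprintf("HA%02d", seq_len(min(config$n_producers, config$n_has)))
  effect <- matrix(0, config$n_producers, config$n_has,
                   dimnames = list(producers,
                                   sprintf("HA%02d", seq_len(config$n_has))))
  for (j in seq_along(driven)) effect[j, driven[j]] <- config$effect_size

  list(
    abundance = abundance_table(a),
    truth = list(
      producer_ids = producers,
      dominant_id = dominant,
      driven_has = driven,
      effect_matrix = effect,
      planted_stable_has = character(0)
    )
  )
}

#' Generate higher-alcohol concentrations from a community
#'
#' Driven alcohols are linear in producer abundance,
#' \eqn{c_k = s \sum_j E_{jk} a_j \cdot e^{\epsilon}}, with mean-preserving
#' log-normal noise; the remaining alcohols are pure noise around a constant
#' baseline. Values below the detection limit are recorded ND (masked), not
#' zero.
#'
#' @param abundance The [abundance_table()] from [generate_community()].
#' @param truth The matching ground-truth list.
#' @param config The same [sim_config()] used to generate the community.
#' @return A replicate-level [ha_table()].
#' @export
generate_ha <- function(abundance, truth, config) {
  stopifnot(inherits(abundance, "abundance_table"),
            inherits(config, "sim_config"))
  if (!all(truth$producer_ids %in% rownames(abundance$abund))) {
    stop("ground truth producers missing from the abundance table",
         call. = FALSE)
  }
  if (nrow(truth$effect_matrix) != length(truth$producer_ids)) {
    stop("effect matrix rows must match the producer set", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  a <- abundance$abund[truth$producer_ids, , drop = FALSE]
  conc <- config$concentration_scale * t(truth$effect_matrix) %*% a
  noise_only <- colSums(truth$effect_matrix) == 0
  if (any(noise_only)) {
    base <- stats::rlnorm(sum(noise_only), meanlog = log(100), sdlog = 0.3)
    conc[noise_only, ] <- base
  }
  conc <- conc * matrix(lnoise(length(conc), config$noise_sd),
                        nrow(conc), ncol(conc))
  conc[conc < config$detection_limit] <- NA_real_
  ha_table(replicate_values = conc)
}

#' Generate a GC-MS peak table consistent with a concentration table
#'
#' Inverts the internal-standard semiquantification relation
#' \eqn{C = d \, A_c / A_{is} \, C_{is}}: areas are chosen so that
#' [quantify()] recovers the input concentrations to within 1e-9 relative
#' error. ND cells are emitted with zero analyte area.
#'
#' @param ha A replicate-level [ha_table()].
#' @param quant A [quant_config()]; its internal-standard concentration must
#'   be positive.
#' @param is_area Internal-standard peak area assigned to every record
#'   (arbitrary units).
#' @return A [peak_table()].
#' @export
generate_peak_table <- function(ha, quant, is_area = 1e5) {
  stopifnot(inherits(ha, "ha_table"))
  if (is.null(ha$replicate_values)) {
    stop("generate_peak_table needs replicate-level concentrations",
         call. = FALSE)
  }
  if (quant$c_is <= 0) {
    stop("internal-standard concentration must be positive", call. = FALSE)
  }
  v <- ha$replicate_values
  conc <- ifelse(is.na(v), 0, v)
  a_c <- conc * is_area / (quant$dilution_factor * quant$c_is)
  idx <- expand.grid(compound = rownames(v), sample_id = colnames(v),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  peak_table(idx$compound, idx$sample_id, as.vector(a_c), is_area)
}

#' Simulate a complete paired dataset
#'
#' Runs [generate_community()], [generate_ha()] and [generate_peak_table()]
#' under one configuration and fills the ground truth's
#' \code{planted_stable_has} (alcohols detected in at least
#' \code{min_detections} timepoints).
#'
#' @param config A [sim_config()].
#' @param quant A [quant_config()] used for the peak-table inversion.
#' @param min_detections Timepoint-detection threshold defining a stable
#'   alcohol.
#' @return A list: \code{abundance}, \code{truth}, \code{ha}
#'   (replicate-level), \code{ha_summary} (mean/SE/ND), \code{peaks}.
#' @export
simulate_dataset <- function(config, quant = quant_config(),
                             min_detections = 5) {
  comm <- generate_community(config)
  ha <- generate_ha(comm$abundance, comm$truth, config)
  ha_sum <- summarize_replicates(ha)
  stats <- detection_stats(ha_sum, min_detections = min_detections)
  per <- stats$per_compound
  comm$truth$planted_stable_has <-
    intersect(comm$truth$driven_has, per$compound[per$stable])
  list(abundance = comm$abundance, truth = comm$truth, ha = ha,
       ha_summary = ha_sum,
       peaks = generate_peak_table(ha, quant))
}
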