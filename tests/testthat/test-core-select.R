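toy_setup <- function() {
  set.seed(2)
  m <- matrix(rlnorm(6 * 6), 6, 6,
              dimnames = list(paste0("g", 1:6),
                              sprintf("D%dR1", c(0, 2, 4, 6, 8, 10))))
  m["g1", ] <- m["g1", ] * 50     # clear top-abundance taxon
  m["g2", ] <- m["g2", ] * 40
  abund <- abundance_table(m)
  edges <- data.frame(
    source = c("g1", "g2", "g3"),
    target = c("HA_stable", "HA_rare", "HA_stable"),
    r = c(0.99, 0.98, 0.97), p = c(1e-5, 1e-5, 1e-5),
    q = c(1e-4, 1e-4, 1e-4), robust = TRUE, sign = "+",
    stringsAsFactors = FALSE)
  assoc <- structure(list(edges = edges,
                          nodes = data.frame(id = unique(c(edges$source,
                                                           edges$target))),
                          config = assoc_config()),
                     class = "assoc_result")
  stats <- list(per_compound = data.frame(
    compound = c("HA_stable", "HA_rare"),
    n_detected = c(6, 4), stable = c(TRUE, FALSE),
    stringsAsFactors = FALSE))
  list(abund = abund, assoc = assoc, stats = stats)
}

test_that("all three gates must pass and evidence cites real edges", {
  s <- toy_setup()
  crit <- core_criteria(top_fraction = 1 / 3, min_detections = 5)
  rep <- select_core(c("g1", "g2", "g3"), s$assoc, s$abund, s$stats, crit)
  # g1: significant, top stratum, stable link -> core
  # g2: linked HA detected only 4 times -> out
  # g3: outside the top third (only g1, g2 are boosted) -> out
  expect_equal(rep$core_taxa, "g1")
  expect_true(all(rep$evidence$source == "g1"))
  expect_true(all(rep$evidence$target %in% rep$stable_has))
  # empty significant pool with require_significant gives an empty core
  rep0 <- select_core(character(0), s$assoc, s$abund, s$stats, crit)
  expect_length(rep0$core_taxa, 0)
  # dropping the significance requirement readmits by the other two gates
  crit2 <- core_criteria(top_fraction = 1 / 3, min_detections = 5,
                         require_significant = FALSE)
  rep2 <- select_core(character(0), s$assoc, s$abund, s$stats, crit2)
  expect_true("g1" %in% rep2$core_taxa)
})

test_that("relaxing any criterion never shrinks the core", {
  s <- toy_setup()
  base <- core_criteria(top_fraction = 0.3, min_detections = 5)
  core0 <- select_core(c("g1", "g2", "g3"), s$assoc, s$abund, s$stats,
                       base)$core_taxa
  wider <- list(
    core_criteria(top_fraction = 0.9, min_detections = 5),
    core_criteria(top_fraction = 0.3, min_detections = 4),
    core_criteria(top_fraction = 0.3, min_detections = 5, p_cutoff = 0.5)
  )
  for (crit in wider) {
    core1 <- select_core(c("g1", "g2", "g3"), s$assoc, s$abund, s$stats,
                         crit)$core_taxa
    expect_true(all(core0 %in% core1))
  }
})

test_that("unmatched id spaces raise alignment errors", {
  s <- toy_setup()
  expect_error(select_core(c("gX"), s$assoc, s$abund, s$stats),
               "absent from the abundance table")
})

test_that("the pipeline is deterministic and recovers the demo producers", {
  cfg <- demo_config(seed = 42, n_perm = 200)
  r1 <- suppressWarnings(run_pipeline(cfg))
  r2 <- suppressWarnings(run_pipeline(cfg))
  expect_identical(r1$report$core_taxa, r2$report$core_taxa)
  expect_identical(r1$permutation$significant_x,
                   r2$permutation$significant_x)
  rs <- recovery_stats(r1$report, r1$truth)
  expect_gte(rs["recall"], 0.8)
  expect_gte(rs["precision"], 0.8)
  # core is ordered by descending abundance and contained in the top stratum
  mu <- rowMeans(to_relative(r1$abundance)$abund)
  expect_false(is.unsorted(rev(mu[r1$report$core_taxa])))
  expect_true(all(r1$report$core_taxa %in%
                    top_fraction(r1$abundance, cfg$criteria$top_fraction)))
})

test_that("pipeline artifacts are written and configs validated", {
  out <- file.path(tempdir(), "hjc-artifacts")
  cfg <- pipeline_config(sim = sim_config(n_taxa = 20, n_producers = 3,
                                          n_has = 5),
                         o2pls = list(n = 2, nx = 1, ny = 1, n_perm = 100,
                                      alpha = 0.05),
                         out_dir = out, seed = 7)
  res <- suppressWarnings(run_pipeline(cfg))
  expect_true(file.exists(file.path(out, "abundance.tsv")))
  expect_true(file.exists(file.path(out, "core_report.json")))
  expect_true(file.exists(file.path(out, "taxon_ha_network.graphml")))
  rep <- jsonlite::read_json(file.path(out, "core_report.json"))
  expect_equal(unlist(rep$core_taxa), res$report$core_taxa,
               ignore_attr = TRUE)
  expect_error(pipeline_config(), "exactly one")
  expect_error(pipeline_config(sim = sim_config(),
                               paths = list(abundance = "x")),
               "exactly one")
  bad <- pipeline_config(paths = list(abundance = "missing.tsv",
                                      ha = "missing.csv"))
  expect_error(run_pipeline(bad), "read-abundance")
})
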