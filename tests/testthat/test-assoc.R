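mk <- function(v, ids = NULL) {
  m <- do.call(rbind, v)
  rownames(m) <- if (is.null(ids)) paste0("f", seq_len(nrow(m))) else ids
  colnames(m) <- sprintf("D%dR1", 2 * (seq_len(ncol(m)) - 1))
  m
}

test_that("pearson matches hand values and the covariance definition", {
  x <- c(1, 2, 3, 4, 5)
  res <- pearson_pairwise(mk(list(x)), mk(list(2 * x + 1)))
  expect_equal(res$edges$r, 1)
  expect_equal(res$edges$p, 0)
  res0 <- pearson_pairwise(mk(list(c(-1, 0, 1))), mk(list(c(1, -2, 1))))
  expect_equal(res0$edges$r, 0)
  res8 <- pearson_pairwise(mk(list(x)), mk(list(c(2, 1, 4, 3, 5))))
  expect_equal(res8$edges$r, 0.8)
  # agreement with a direct covariance/SD evaluation on random vectors
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    r <- pearson_pairwise(mk(list(a)), mk(list(b)))$edges$r
    expect_equal(r, pearson_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("p-values follow the t distribution and edges carry q >= p", {
  set.seed(11)
  X <- mk(lapply(1:4, function(i) rnorm(8)))
  Y <- mk(lapply(1:3, function(i) rnorm(8)))
  res <- pearson_pairwise(X, Y)
  e <- res$edges
  expect_equal(nrow(e), 12)
  tstat <- e$r * sqrt(6) / sqrt(1 - e$r^2)
  expect_equal(e$p, 2 * pt(-abs(tstat), df = 6), tolerance = 1e-12)
  expect_true(all(e$q >= e$p - 1e-15))
  expect_true(all(abs(e$r) <= 1))
})

test_that("zero-variance features are dropped with a warning, not an edge", {
  X <- mk(list(c(1, 2, 3, 4), rep(2, 4)), ids = c("ok", "flat"))
  Y <- mk(list(c(4, 3, 2, 1)))
  expect_warning(res <- pearson_pairwise(X, Y), "zero-variance")
  expect_equal(res$edges$source, "ok")
  expect_true(all(c("ok", "flat") %in% res$nodes$id))
})

test_that("BH adjustment matches the brute-force step-up everywhere", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 0.01)), c(0.5, 0.02))
  set.seed(9)
  for (i in 1:5) {
    p <- runif(5)
    for (perm in list(1:5, 5:1, sample(5))) {
      expect_equal(bh_adjust(p[perm]), bh_bruteforce(p[perm]),
                   tolerance = 1e-14)
    }
    # monotone: sorted p give non-decreasing q
    q <- bh_adjust(sort(p))
    expect_true(all(diff(q) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("edge filtering applies the raw and adjusted cutoffs", {
  res <- structure(list(
    edges = data.frame(source = c("a", "b", "c"), target = "h",
                       r = c(0.99, 0.7, 0.9), p = c(0.001, 0.04, 0.2),
                       q = c(0.004, 0.08, 0.4),
                       robust = NA, sign = "+", stringsAsFactors = FALSE),
    nodes = data.frame(id = c("a", "b", "c", "h")),
    config = assoc_config()), class = "assoc_result")
  kept <- filter_edges(res, assoc_config(use_fdr = TRUE))
  expect_equal(kept$edges$source, "a")
  expect_true(kept$edges$robust)           # |r| = 0.99 > 0.95
  kept_raw <- filter_edges(res, assoc_config(use_fdr = FALSE))
  expect_setequal(kept_raw$edges$source, c("a", "b"))
})

test_that("planted taxon-HA pairs survive filtering across seeds", {
  hits <- 0
  for (s in 1:20) {
    dat <- simulate_dataset(sim_config(noise_sd = 0.05, seed = s))
    res <- filter_edges(correlate_taxa_ha(dat$abundance, dat$ha))
    pair_found <- any(res$edges$source == dat$truth$producer_ids[1] &
                        res$edges$target == dat$truth$driven_has[1])
    hits <- hits + pair_found
  }
  expect_gte(hits, 18)
})

test_that("null data retain about the nominal fraction of raw-p edges", {
  cfg <- assoc_config(use_fdr = FALSE)
  kept <- tot <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    X <- mk(lapply(1:20, function(i) rnorm(10)))
    Y <- mk(lapply(1:10, function(i) rnorm(10)))
    res <- filter_edges(pearson_pairwise(X, Y, cfg), cfg)
    kept <- kept + nrow(res$edges)
    tot <- tot + 200
  }
  se <- sqrt(0.05 * 0.95 / tot)
  expect_gte(kept / tot, 0.05 - 3 * se)
  expect_lte(kept / tot, 0.05 + 3 * se)
})

test_that("co-occurrence networks are undirected and closure-aware", {
  # two identical rows correlate exactly
  m <- mk(list(c(1, 2, 3, 1), c(1, 2, 3, 1), c(5, 1, 2, 9)),
          ids = c("a", "b", "c"))
  res <- cooccurrence_network(abundance_table(m), filter = FALSE)
  ab <- res$edges[res$edges$source == "a" & res$edges$target == "b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "+")
  # each unordered pair appears exactly once
  expect_equal(nrow(res$edges), 3)
  expect_true(all(res$edges$source < res$edges$target))
  # two-taxon composition: one taxon is the other's complement
  comp <- to_relative(abundance_table(mk(list(c(1, 2, 3, 4), c(9, 7, 2, 1)),
                                         ids = c("a", "b"))))
  res2 <- cooccurrence_network(comp, filter = FALSE)
  expect_equal(res2$edges$r, -1)
  # isolated nodes stay in the metadata after filtering
  res3 <- cooccurrence_network(abundance_table(m))
  expect_true(all(c("a", "b", "c") %in% res3$nodes$id))
})

test_that("sample-axis mismatches and tiny n are rejected", {
  X <- mk(list(1:4))
  Y <- mk(list(1:4))
  colnames(Y)[1] <- "D9R9"
  expect_error(pearson_pairwise(X, Y), "sample axis")
  expect_error(pearson_pairwise(mk(list(1:2)), mk(list(2:1))), "3 samples")
})
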