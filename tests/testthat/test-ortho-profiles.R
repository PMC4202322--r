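staged <- function(m, unit = "rpm") expr_matrix(m, unit = unit)

toy_staged_pair <- function() {
  a <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                0, 0, 0, 0,
                5, 5, 2, 9), 4, 4, byrow = TRUE,
              dimnames = list(c("x_a", "y_a", "z_a", "w_a"),
                              paste0("sA", 1:4)))
  b <- matrix(c(2, 4, 6, 8,
                8, 6, 4, 2,
                1, 2, 1, 3,
                0, 0, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(c("x_b", "y_b", "z_b", "w_b"),
                              paste0("sB", 1:4)))
  list(a = staged(a), b = staged(b),
       map = data.frame(stage_a = paste0("sA", 1:4),
                        stage_b = paste0("sB", 1:4)))
}

test_that("ortholog profile correlations skip constant profiles and use the stage map", {
  tp <- toy_staged_pair()
  pairs <- make_orthologs(c("x_a", "y_a", "z_a", "w_a"),
                          c("x_b", "y_b", "z_b", "w_b"))
  recs <- suppressMessages(
    ortholog_profile_correlations(tp$a, tp$b, pairs, tp$map))
  expect_equal(nrow(recs), 2L)                  # z (zero in a), w (zero in b)
  expect_equal(recs$r[recs$id_1 == "x_a"], 1)   # identical linear profile
  expect_equal(recs$r[recs$id_1 == "y_a"], 1)
  expect_equal(unique(recs$pair_kind), "ortholog")
  expect_equal(unique(recs$n_stages), 4L)
  expect_message(ortholog_profile_correlations(tp$a, tp$b, pairs, tp$map),
                 "skipped")

  bad_map <- tp$map; bad_map$stage_b[2] <- "sB1"
  expect_error(ortholog_profile_correlations(tp$a, tp$b, pairs, bad_map),
               "1-to-1")
})

test_that("cluster records enumerate unordered within-cluster pairs", {
  set.seed(10)
  m <- staged(matrix(rexp(24), 6, 4,
                     dimnames = list(paste0("m", 1:6), paste0("s", 1:4))))
  cl <- list(membership = setNames(c("c1", "c1", "c2", "c2", "c2", "c2"),
                                   paste0("m", 1:6)),
             clusters = list(c1 = c("m1", "m2"),
                             c2 = c("m3", "m4", "m5", "m6")))
  class(cl) <- "mirna_clusters"
  recs <- cluster_profile_correlations(m, cl)
  expect_equal(nrow(recs), 1L + choose(4, 2))
  expect_equal(recs$r[1], pearson_r(unclass(m)["m1", ],
                                    unclass(m)["m2", ]))
  singles <- list(membership = setNames(c("c1", "c2"), c("m1", "m2")),
                  clusters = list(c1 = "m1", c2 = "m2"))
  class(singles) <- "mirna_clusters"
  expect_equal(nrow(cluster_profile_correlations(m, singles)), 0L)
})

test_that("the random-pair null is seed-deterministic and avoids orthologs", {
  set.seed(11)
  n <- 30
  a <- staged(matrix(rexp(n * 5), n, 5,
                     dimnames = list(paste0("g", 1:n, "_a"),
                                     paste0("sA", 1:5))))
  b <- staged(matrix(rexp(n * 5), n, 5,
                     dimnames = list(paste0("g", 1:n, "_b"),
                                     paste0("sB", 1:5))))
  map <- data.frame(stage_a = paste0("sA", 1:5),
                    stage_b = paste0("sB", 1:5))
  pairs <- make_orthologs(paste0("g", 1:n, "_a"), paste0("g", 1:n, "_b"))
  n1 <- random_pair_null(a, b, pairs, 100, seed = 42, stage_map = map)
  n2 <- random_pair_null(a, b, pairs, 100, seed = 42, stage_map = map)
  expect_identical(n1, n2)
  expect_false(any(paste(n1$id_1, n1$id_2) %in%
                     paste(pairs$id_a, pairs$id_b)))
  expect_error(random_pair_null(a, b, pairs, 0, 1, map), ">= 1")
  expect_error(random_pair_null(a, b, pairs, n * n, 1, map), "exceeds")

  # independent random profiles: null mean near zero by the CLT
  big <- random_pair_null(a, b, pairs, 500, seed = 1, stage_map = map)
  expect_lt(abs(mean(big$r)), 3 * sd(big$r) / sqrt(nrow(big)) + 0.05)
})

test_that("group comparison reproduces the rank-sum statistic", {
  x <- profile_records_for_test(c(0.9, 0.8, 0.85, 0.7, 0.95))
  y <- profile_records_for_test(c(0.1, 0.3, -0.2, 0.05, 0.2))
  res <- compare_groups(x, y)
  expect_equal(res$statistic, ranksum_W(x$r, y$r))
  expect_lt(res$p, 0.05)
  same <- compare_groups(x, x)
  expect_gt(same$p, 0.99)
  expect_equal(res$median_x, 0.85)
  expect_error(compare_groups(x[1:2, ], y), "at least 3")
})

test_that("rate-conservation association recovers linear and independent cases", {
  recs <- profile_records_for_test(seq(0.1, 1, length.out = 10),
                                   ids = paste0("a", 1:10))
  pairs <- make_orthologs(paste0("a", 1:10), paste0("b", 1:10))
  pairs$hairpin_div <- seq(0.01, 0.1, length.out = 10)
  pairs$rate_class <- rep(c("low", "medium", "high"), length.out = 10)
  res <- rate_conservation_association(recs, pairs, "hairpin_div")
  expect_equal(res$r, 1)
  expect_equal(names(res$by_class), c("low", "medium", "high"))

  set.seed(12)
  n <- 150
  recs2 <- profile_records_for_test(runif(n, -1, 1), ids = paste0("a", 1:n))
  pairs2 <- make_orthologs(paste0("a", 1:n), paste0("b", 1:n))
  pairs2$hairpin_div <- runif(n, 0, 0.2)
  res2 <- rate_conservation_association(recs2, pairs2, "hairpin_div")
  expect_lt(abs(res2$r), 0.2)

  expect_error(rate_conservation_association(recs[1:4, ], pairs,
                                             "hairpin_div"), "at least 5")
  pairs$hairpin_div <- rep(0.05, 10)
  expect_error(rate_conservation_association(recs, pairs, "hairpin_div"),
               "constant")
})

test_that("conserved ortholog profiles separate from the random-pair null", {
  ds <- simulate_mirna_dataset(conserved_profile_config(14))
  res <- analyze_dataset(ds$loci_a, ds$loci_b, ds$orthologs, ds$counts_a,
                         ds$counts_b, ds$samples, seed = 14)
  orth <- res$records[res$records$pair_kind == "ortholog", ]
  null <- res$records[res$records$pair_kind == "random_cross", ]
  expect_gt(median(orth$r), quantile(null$r, 0.95))
  expect_lt(res$group_tests$ortholog_vs_random$p, 0.01)
})

test_that("clustered microRNA co-expression is comparable to ortholog conservation", {
  # cluster members share one primary transcript; with co-expression
  # scatter calibrated to the cross-species divergence the two r
  # distributions should be indistinguishable at alpha = 0.01 in the
  # large majority of generated datasets
  not_rejected <- 0L
  for (s in 1:10) {
    ds <- simulate_mirna_dataset(conserved_profile_config(s))
    res <- analyze_dataset(ds$loci_a, ds$loci_b, ds$orthologs,
                           ds$counts_a, ds$counts_b, ds$samples, seed = s)
    if (res$group_tests$ortholog_vs_cluster$p > 0.01)
      not_rejected <- not_rejected + 1L
  }
  expect_gte(not_rejected, 7L)
})

test_that("module output is reproducible for identical inputs and seed", {
  ds <- simulate_mirna_dataset(small_sim_config(15))
  r1 <- analyze_dataset(ds$loci_a, ds$loci_b, ds$orthologs, ds$counts_a,
                        ds$counts_b, ds$samples, seed = 5)
  r2 <- analyze_dataset(ds$loci_a, ds$loci_b, ds$orthologs, ds$counts_a,
                        ds$counts_b, ds$samples, seed = 5)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$hourglass, r2$hourglass)
})
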