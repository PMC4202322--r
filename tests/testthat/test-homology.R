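test_that("global affine alignment handles matches, mismatches and terminal gaps", {
  a1 <- align_pair("ACGU", "ACGU")
  expect_equal(a1$score, 4)
  expect_equal(a1$aligned_a, "ACGU")
  expect_equal(a1$aligned_b, "ACGU")

  a2 <- align_pair("ACGU", "ACGA")
  expect_equal(a2$score, 2)                     # 3 matches - 1 mismatch
  expect_false(grepl("-", paste0(a2$aligned_a, a2$aligned_b)))

  a3 <- align_pair("ACGU", "ACG")
  expect_equal(nchar(a3$aligned_a), 4L)
  expect_equal(sum(strsplit(a3$aligned_b, "")[[1]] == "-"), 1L)
  expect_equal(a3$score, 3 - 5 - 2)             # one gap of length 1

  expect_error(align_pair("", "ACG"), "non-empty")
  expect_error(align_pair("ACGX", "ACG"), "non-nucleotide")
})

test_that("alignment score equals the exhaustive-enumeration optimum", {
  set.seed(5)
  for (i in 1:60) {
    a <- random_nt(sample(1:6, 1))
    b <- random_nt(sample(1:6, 1))
    al <- align_pair(a, b)
    # degapping the rows must give back the inputs
    expect_identical(gsub("-", "", al$aligned_a), a)
    expect_identical(gsub("-", "", al$aligned_b), b)
    # the reported score must rescore from the alignment itself
    expect_equal(score_alignment(al$aligned_a, al$aligned_b), al$score)
    expect_equal(al$score, enumerate_align_score(a, b))
  }
})

test_that("substitutions per site excludes gap columns and treats U as T", {
  expect_equal(substitutions_per_site(
    list(aligned_a = "ACGT", aligned_b = "ACGA")), 0.25)
  expect_equal(substitutions_per_site(
    list(aligned_a = "ACG-T", aligned_b = "ACGAT")), 0)
  arm <- random_nt(22)
  expect_equal(substitutions_per_site(align_pair(arm, arm)), 0)
  expect_equal(substitutions_per_site(
    list(aligned_a = "ACGU", aligned_b = "ACGT")), 0)
  # symmetry
  expect_equal(substitutions_per_site(
    list(aligned_a = "AAGT", aligned_b = "ACGT")),
    substitutions_per_site(
      list(aligned_a = "ACGT", aligned_b = "AAGT")))
  expect_error(substitutions_per_site(
    list(aligned_a = "A--", aligned_b = "-GT")), "no gap-free")
})

test_that("divergence annotation pools mature arms and respects shared arms", {
  set.seed(8)
  hp <- random_nt(90)
  iv5 <- c(4L, 26L); iv3 <- c(60L, 82L)
  mk <- function(id, species, seq, arms = c("5p", "3p")) {
    ivs <- list("5p" = iv5, "3p" = iv3)[arms]
    mirna_locus(id, species, "chr2L", "+", 1000L, 1000L + nchar(seq), ivs,
                seq, vapply(ivs, function(iv)
                  substr(seq, iv[1] + 1, iv[2]), ""))
  }
  # one substitution inside the 5p arm, nothing else
  hp_mut <- hp
  substr(hp_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(hp, 10, 10))[1]
  la <- mirna_loci(list(mk("x_a", "a", hp)))
  lb <- mirna_loci(list(mk("x_b", "b", hp_mut)))
  pairs <- annotate_divergence(make_orthologs("x_a", "x_b"), la, lb)
  expect_equal(pairs$mature_div, 1 / 44)        # 1 sub over 22+22 sites
  expect_equal(pairs$hairpin_div, 1 / 90)

  # only the 5p arm is annotated in species B: mature_div from 5p alone
  lb2 <- mirna_loci(list(mk("x_b", "b", hp_mut, arms = "5p")))
  pairs2 <- annotate_divergence(make_orthologs("x_a", "x_b"), la, lb2)
  expect_equal(pairs2$mature_div, 1 / 22)

  ident <- annotate_divergence(make_orthologs("x_a", "x_b"), la,
                               mirna_loci(list(mk("x_b", "b", hp))))
  expect_equal(c(ident$hairpin_div, ident$mature_div), c(0, 0))
})

test_that("rate classes form deterministic tertiles", {
  p <- make_orthologs(paste0("a", 1:3), paste0("b", 1:3))
  p$hairpin_div <- c(0, 0.1, 0.2)
  expect_equal(classify_rates(p, "hairpin_div")$rate_class,
               c("low", "medium", "high"))

  p9 <- make_orthologs(paste0("a", 1:9), paste0("b", 1:9))
  p9$hairpin_div <- seq(0.01, 0.09, by = 0.01)[sample(9)]
  cls <- classify_rates(p9, "hairpin_div")
  expect_equal(unname(table(cls$rate_class)[c("low", "medium", "high")]),
               rep(3L, 3), ignore_attr = TRUE)
  expect_equal(cls$rate_class[order(p9$hairpin_div)],
               rep(c("low", "medium", "high"), each = 3))

  p9$hairpin_div <- rep(0.05, 9)
  expect_warning(tied <- classify_rates(p9, "hairpin_div"), "tied")
  expect_equal(tied$rate_class[order(p9$id_a)],
               rep(c("low", "medium", "high"), each = 3))

  expect_error(classify_rates(p9[1:2, ], "hairpin_div"), "at least 3")
})

test_that("cluster detection applies the 10 kb same-strand rule inclusively", {
  mk <- function(id, start, strand = "+")
    toy_locus(id, strand = strand, start = as.integer(start))
  len <- 60L
  near <- mirna_loci(list(mk("u", 0), mk("v", len + 9999)))     # gap 9999
  expect_equal(unname(find_clusters(near)$membership["u"]),
               unname(find_clusters(near)$membership["v"]))
  edge <- mirna_loci(list(mk("u", 0), mk("v", len + 10000)))    # gap 10000
  expect_equal(length(find_clusters(edge)$clusters), 1L)
  far <- mirna_loci(list(mk("u", 0), mk("v", len + 10001)))     # gap 10001
  expect_equal(length(find_clusters(far)$clusters), 2L)
  opp <- mirna_loci(list(mk("u", 0), mk("v", 200, strand = "-")))
  expect_equal(length(find_clusters(opp)$clusters), 2L)
  expect_length(find_clusters(mirna_loci(list()))$membership, 0L)
})

test_that("chained clustering matches the all-pairs single-linkage oracle", {
  set.seed(13)
  for (trial in 1:25) {
    n <- sample(2:20, 1)
    df <- data.frame(
      locus_id = paste0("m", seq_len(n)),
      chrom = sample(c("chr2L", "chr3R"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = sort(sample(0:2e5, n)))
    df$end <- df$start + 60L
    loci <- mirna_loci(lapply(seq_len(n), function(i)
      toy_locus(df$locus_id[i], strand = df$strand[i],
                start = df$start[i])))
    # patch chromosomes after construction to vary them
    for (i in seq_len(n)) loci[[i]]$chrom <- df$chrom[i]
    expect_identical(canonical_partition(find_clusters(loci)),
                     oracle_single_linkage(df, 10000))
  }
})

test_that("simulated substitution rates are recovered by the divergence estimator", {
  cfg <- simulation_config(n_ortholog_families = 30, n_specific_a = 0,
                           n_specific_b = 0, n_clusters = 0,
                           multimap_fraction = 0,
                           substitution_rate_range = c(0.1, 0.1),
                           seed = 31)
  g <- simulate_genomes(cfg)
  pairs <- annotate_divergence(g$orthologs, g$loci_a, g$loci_b)
  L <- 30 * 90
  expect_lt(abs(mean(pairs$hairpin_div) - 0.1),
            3 * sqrt(0.1 * 0.9 / L))
})

test_that("loop indels produce gapped alignments with finite divergence", {
  cfg <- simulation_config(n_ortholog_families = 10, n_specific_a = 0,
                           n_specific_b = 0, n_clusters = 0,
                           multimap_fraction = 0, indel_rate = 1,
                           substitution_rate_range = c(0.05, 0.05),
                           seed = 32)
  g <- simulate_genomes(cfg)
  lens_b <- vapply(g$loci_b, function(l) nchar(l$hairpin_seq), 0L)
  expect_true(any(lens_b < 90))
  pairs <- annotate_divergence(g$orthologs, g$loci_a, g$loci_b)
  al <- align_pair(g$loci_a[[1]]$hairpin_seq, g$loci_b[[1]]$hairpin_seq)
  expect_true(all(is.finite(pairs$hairpin_div)))
  expect_true(any(grepl("-", vapply(g$orthologs$id_a, function(ia) {
    ib <- g$orthologs$id_b[g$orthologs$id_a == ia]
    align_pair(g$loci_a[[ia]]$hairpin_seq,
               g$loci_b[[ib]]$hairpin_seq)$aligned_b
  }, ""))))
})
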