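write_gff <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
write_fa <- function(path, seqs) {
  writeLines(as.character(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]])))), path)
  path
}

test_that("GFF coordinates convert to 0-based half-open hairpin-local intervals", {
  hp <- random_nt(72)
  mat <- substr(hp, 6, 27)                     # local [5, 27), 22 nt
  td <- withr::local_tempdir()
  gff <- write_gff(file.path(td, "a.gff3"), c(
    "chr2L\tx\tmiRNA_primary_transcript\t100\t171\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA\t105\t126\t.\t+\t.\tID=mirX_5p;Derives_from=mirX"))
  loci <- load_annotations(gff,
                           write_fa(file.path(td, "h.fa"), list(mirX = hp)),
                           write_fa(file.path(td, "m.fa"),
                                    list(mirX_5p = mat)), "sp")
  l <- loci[["mirX"]]
  expect_equal(c(l$start, l$end), c(99L, 171L))
  expect_equal(unname(l$mature_intervals[["5p"]]), c(5L, 27L))
  expect_equal(l$mature_seqs[["5p"]], mat)
})

test_that("minus-strand loci store reading-direction sequences and intervals", {
  set.seed(42)
  l_minus <- toy_locus("mirM", strand = "-",
                       hairpin = random_nt(60))
  l_plus <- toy_locus("mirP", strand = "+", start = 5000L,
                      hairpin = random_nt(60))
  td <- withr::local_tempdir()
  paths <- list(gff = file.path(td, "a.gff3"), hp = file.path(td, "h.fa"),
                mat = file.path(td, "m.fa"))
  write_annotations(mirna_loci(list(l_minus, l_plus)),
                    paths$gff, paths$hp, paths$mat)
  back <- load_annotations(paths$gff, paths$hp, paths$mat, "sp")
  # field-by-field round trip, both strands
  for (id in c("mirM", "mirP"))
    expect_equal(back[[id]], mirna_loci(list(l_minus, l_plus))[[id]])
  # the GFF itself must carry genomic (not reading-direction) intervals:
  # a 0-based -> 1-based -> 0-based cycle is the identity
  expect_equal(as.data.frame(back), as.data.frame(
    mirna_loci(list(l_minus, l_plus))))
})

test_that("annotation loading validates linkage, sequences and ids", {
  hp <- random_nt(72)
  td <- withr::local_tempdir()
  hfa <- write_fa(file.path(td, "h.fa"), list(mirX = hp))
  # mature without parent hairpin
  gff1 <- write_gff(file.path(td, "bad1.gff3"), c(
    "chr2L\tx\tmiRNA_primary_transcript\t100\t171\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA\t105\t126\t.\t+\t.\tID=orphan_5p;Derives_from=nope"))
  mfa <- write_fa(file.path(td, "m.fa"),
                  list(orphan_5p = substr(hp, 6, 27)))
  expect_error(load_annotations(gff1, hfa, mfa, "sp"), "orphan")
  # mature sequence that is not the hairpin subsequence at its offset
  gff2 <- write_gff(file.path(td, "bad2.gff3"), c(
    "chr2L\tx\tmiRNA_primary_transcript\t100\t171\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA\t105\t126\t.\t+\t.\tID=mirX_5p;Derives_from=mirX"))
  mfa2 <- write_fa(file.path(td, "m2.fa"),
                   list(mirX_5p = paste(rep("A", 22), collapse = "")))
  expect_error(load_annotations(gff2, hfa, mfa2, "sp"),
               "does not match the hairpin subsequence")
  # duplicate hairpin ids
  gff3 <- write_gff(file.path(td, "bad3.gff3"), c(
    "chr2L\tx\tmiRNA_primary_transcript\t100\t171\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA_primary_transcript\t500\t571\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA\t105\t126\t.\t+\t.\tID=mirX_5p;Derives_from=mirX"))
  expect_error(load_annotations(gff3, hfa, mfa, "sp"), "duplicate")
})

test_that("empty GFF warns and returns no loci; unknown types are skipped", {
  td <- withr::local_tempdir()
  gff <- write_gff(file.path(td, "empty.gff3"), character(0))
  fa <- write_fa(file.path(td, "e.fa"), list())
  expect_warning(loci <- load_annotations(gff, fa, fa, "sp"),
                 "no features")
  expect_length(loci, 0L)

  hp <- random_nt(72)
  gff2 <- write_gff(file.path(td, "extra.gff3"), c(
    "chr2L\tx\tgene\t1\t50\t.\t+\t.\tID=someGene",
    "chr2L\tx\tmiRNA_primary_transcript\t100\t171\t.\t+\t.\tID=mirX",
    "chr2L\tx\tmiRNA\t105\t126\t.\t+\t.\tID=mirX_5p;Derives_from=mirX"))
  hfa <- write_fa(file.path(td, "h.fa"), list(mirX = hp))
  mfa <- write_fa(file.path(td, "m.fa"), list(mirX_5p = substr(hp, 6, 27)))
  expect_warning(loci <- load_annotations(gff2, hfa, mfa, "sp"),
                 "unknown type")
  expect_length(loci, 1L)
})

test_that("ortholog tables enforce resolvable ids and the 1-to-1 property", {
  la <- mirna_loci(list(toy_locus("mir-5_mel", species = "mel"),
                        toy_locus("mir-6_mel", species = "mel",
                                  start = 50000L)))
  lb <- mirna_loci(list(toy_locus("mir-5_vir", species = "vir"),
                        toy_locus("mir-6_vir", species = "vir",
                                  start = 50000L)))
  td <- withr::local_tempdir()
  p <- file.path(td, "orth.tsv")
  writeLines(c("id_a\tid_b", "mir-5_mel\tmir-5_vir"), p)
  pairs <- load_orthologs(p, la, lb)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$rate_class, "unset")

  writeLines(c("mir-5_mel\tmir-5_vir", "mir-5_mel\tmir-6_vir"), p)
  expect_error(load_orthologs(p, la, lb), "1-to-1")
  writeLines(c("mir-5_mel\tmir-9_vir"), p)
  expect_error(load_orthologs(p, la, lb), "mir-9_vir")
})

test_that("a generated ortholog table round-trips through write and load", {
  ds <- simulate_mirna_dataset(small_sim_config(3))
  td <- withr::local_tempdir()
  p <- write_ortholog_table(ds$orthologs, file.path(td, "o.tsv"),
                            divergence = FALSE)
  back <- load_orthologs(p, ds$loci_a, ds$loci_b)
  expect_equal(back$id_a, ds$orthologs$id_a)
  expect_equal(back$id_b, ds$orthologs$id_b)
})

test_that("sample sheets validate windows, ids and symbolic stages", {
  td <- withr::local_tempdir()
  p <- file.path(td, "samples.tsv")
  writeLines(c(
    "library_id\tspecies\tstage_label\ttime_start\ttime_end\treplicate_group",
    "vir_e0_2\tdvir\te0-2\t0\t2\tr1",
    "mel_am\tdmel\tadult_male\t\t\tadult",
    "mel_af\tdmel\tadult_female\t\t\tadult"), p)
  s <- load_samples(p)
  expect_equal(nrow(s), 3L)
  expect_equal(s$time_end[1], 2)
  expect_true(all(is.na(s$time_start[2:3])))
  # separate-sex adults share one replicate group and will be averaged
  expect_equal(s$replicate_group[2:3], c("adult", "adult"))

  writeLines(c(
    "library_id\tspecies\tstage_label\ttime_start\ttime_end\treplicate_group",
    "libX\tdvir\te2-4\t4\t2\tr1"), p)
  expect_error(load_samples(p), "time_start")
  writeLines(c(
    "library_id\tspecies\tstage_label\ttime_start\ttime_end\treplicate_group",
    "libX\tdvir\te2-4\t2\t4\tr1",
    "libX\tdvir\te4-6\t4\t6\tr1"), p)
  expect_error(load_samples(p), "duplicate")
})

test_that("count matrices round-trip through TSV with their unit", {
  m <- expr_matrix(matrix(c(1.25, 3, 0, 7.5), 2, 2,
                          dimnames = list(c("x|5p", "y|3p"),
                                          c("lib1", "lib2"))),
                   unit = "raw_fractional_count", species = "sp")
  td <- withr::local_tempdir()
  p <- write_count_matrix(m, file.path(td, "c.tsv"))
  back <- read_count_matrix(p, "sp")
  expect_equal(expr_unit(back), "raw_fractional_count")
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_identical(dimnames(back), dimnames(m))
})
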