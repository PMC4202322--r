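# Shared fixtures built in code.

# a compact simulated two-species dataset for fast tests
small_sim_config <- function(seed, ...) {
  args <- list(n_ortholog_families = 15L, n_specific_a = 4L,
               n_specific_b = 2L, n_clusters = 3L,
               cluster_size_range = c(2L, 3L), library_depth = 2e4,
               multimap_fraction = 0.1, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# the conserved-profiles study condition: flat, low cross-species
# divergence with co-expression scatter calibrated to it
conserved_profile_config <- function(seed) {
  simulation_config(seed = seed,
                    stage_divergence_profile = rep(0.2, 6),
                    cluster_noise_sd = 0.2,
                    n_clusters = 15L, cluster_size_range = c(2L, 4L))
}

# hand-built locus: hairpin with known arms, for unit tests
toy_locus <- function(id = "mirX", species = "sp", strand = "+",
                      start = 1000L,
                      hairpin = paste(rep(c("A", "C", "G", "T"), 15),
                                      collapse = "")) {
  len <- nchar(hairpin)
  iv5 <- c(4L, 26L); iv3 <- c(len - 26L, len - 4L)
  mirna_locus(id, species, "chr2L", strand, start, start + len,
              mature_intervals = list("5p" = iv5, "3p" = iv3),
              hairpin_seq = hairpin,
              mature_seqs = c("5p" = substr(hairpin, iv5[1] + 1, iv5[2]),
                              "3p" = substr(hairpin, iv3[1] + 1, iv3[2])))
}

# minimal SAM writer for counting tests
write_toy_sam <- function(path, loci, records) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              vapply(loci, function(l)
                sprintf("@SQ\tSN:%s\tLN:%d", l$locus_id,
                        nchar(l$hairpin_seq)), ""))
  lines <- vapply(records, function(r) {
    len <- nchar(r$seq)
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
            r$qname, r$flag %||% 0L, r$rname, r$pos, len, r$seq)
  }, "")
  writeLines(c(header, lines), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# profile_records built directly from r values
profile_records_for_test <- function(r, ids = paste0("a", seq_along(r))) {
  structure(data.frame(pair_kind = "ortholog", id_1 = ids,
                       id_2 = sub("^a", "b", ids), r = r,
                       n_stages = 6L, stringsAsFactors = FALSE),
            class = c("profile_records", "data.frame"))
}

# stage_cor object built directly, for hourglass unit tests
toy_stage_cor <- function(diag_rho, stages_a = NULL, stages_b = NULL) {
  n <- length(diag_rho)
  if (is.null(stages_a)) stages_a <- paste0("a", seq_len(n))
  if (is.null(stages_b)) stages_b <- paste0("b", seq_len(n))
  v <- matrix(-1, n, n, dimnames = list(stages_a, stages_b))
  diag(v) <- diag_rho
  structure(list(values = v, metric = "spearman", row_stages = stages_a,
                 col_stages = stages_b, replicate_sd = NULL,
                 row_order = NULL, col_order = NULL),
            class = "stage_cor")
}
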