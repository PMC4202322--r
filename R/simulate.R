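#' Configuration of the two-species synthetic dataset
#'
#' Defaults mirror the scale of a two-fly developmental small-RNA study:
#' 118 one-to-one ortholog families plus 54 / 5 species-specific loci,
#' six species-A stage groups sampled in two replicates against eleven
#' species-B libraries (eight 2-h embryonic windows, a late-embryo
#' window, larva and adult), a 1.5-fold slower species-B clock, per-family
#' substitution rates drawn uniformly from 0-0.2 substitutions per site,
#' genomic clusters co-expressed from one primary transcript, and a
#' U-shaped per-stage cross-species noise SD that embeds an hourglass of
#' expression conservation (set a constant vector for no hourglass).
#'
#' @param n_ortholog_families Number of 1-to-1 ortholog families.
#' @param n_specific_a,n_specific_b Species-specific locus counts.
#' @param n_clusters Number of genomic clusters (among ortholog families).
#' @param cluster_size_range Integer range cluster sizes are drawn from.
#' @param hairpin_len,arm_len Hairpin and mature arm lengths (nt).
#' @param substitution_rate_range Per-site substitution probability range
#'   family rates are drawn from.
#' @param time_scale Species-B developmental clock scaling (B time =
#'   `time_scale` x A time).
#' @param stage_grid_a,stage_grid_b Data frames (`stage_label`, `t0`,
#'   `t1`, `symbolic`) of library time windows on each species' own
#'   clock; `NULL` for the built-in grids.
#' @param replicates_a,replicates_b Libraries per stage.
#' @param profile_mix Probabilities of the per-miRNA profile classes
#'   (maternal decay, zygotic pulse, constant).
#' @param stage_divergence_profile Per-comparable-stage SD (log scale) of
#'   the multiplicative cross-species expression noise applied to species
#'   B; one value per homologous stage pair (6 with the default grids).
#' @param library_depth Expected reads per library.
#' @param multimap_fraction Fraction of ortholog families that receive a
#'   species-specific paralog with an identical hairpin (multi-mapping
#'   reads).
#' @param decoy_fraction Fraction of extra off-length (18 nt) reads in
#'   simulated SAM output.
#' @param cluster_noise_sd Log-scale SD of the i.i.d. noise around the
#'   shared primary-transcript profile of cluster members.
#' @param indel_rate Per-family probability of a short loop-region
#'   deletion in the species-B hairpin (exercises alignment gaps).
#' @param species_a,species_b Species tags.
#' @param seed Integer seed governing all draws.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_ortholog_families = 118L,
                              n_specific_a = 54L, n_specific_b = 5L,
                              n_clusters = 10L,
                              cluster_size_range = c(2L, 6L),
                              hairpin_len = 90L, arm_len = 22L,
                              substitution_rate_range = c(0, 0.2),
                              time_scale = 1.5,
                              stage_grid_a = NULL, stage_grid_b = NULL,
                              replicates_a = 2L, replicates_b = 1L,
                              profile_mix = c(maternal = 0.25,
                                              zygotic = 0.65,
                                              constant = 0.10),
                              stage_divergence_profile =
                                c(0.9, 0.55, 0.25, 0.3, 0.6, 0.9),
                              library_depth = 1e6,
                              multimap_fraction = 0.05,
                              decoy_fraction = 0.02,
                              cluster_noise_sd = 0.4,
                              indel_rate = 0,
                              species_a = "dmel", species_b = "dvir",
                              seed = 1L) {
  if (is.null(stage_grid_a)) stage_grid_a <- default_stage_grid_a()
  if (is.null(stage_grid_b)) stage_grid_b <- default_stage_grid_b()
  stopifnot(n_ortholog_families >= 1L, n_specific_a >= 0L,
            n_specific_b >= 0L, n_clusters >= 0L,
            hairpin_len >= 2L * arm_len + 10L,
            all(substitution_rate_range >= 0),
            all(substitution_rate_range <= 1), time_scale > 0,
            multimap_fraction >= 0, multimap_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            library_depth > 0, replicates_a >= 1L, replicates_b >= 1L,
            abs(sum(profile_mix) - 1) < 1e-8)
  structure(list(
    n_ortholog_families = as.integer(n_ortholog_families),
    n_specific_a = as.integer(n_specific_a),
    n_specific_b = as.integer(n_specific_b),
    n_clusters = as.integer(n_clusters),
    cluster_size_range = as.integer(cluster_size_range),
    hairpin_len = as.integer(hairpin_len), arm_len = as.integer(arm_len),
    substitution_rate_range = substitution_rate_range,
    time_scale = time_scale,
    stage_grid_a = stage_grid_a, stage_grid_b = stage_grid_b,
    replicates_a = as.integer(replicates_a),
    replicates_b = as.integer(replicates_b),
    profile_mix = profile_mix,
    stage_divergence_profile = stage_divergence_profile,
    library_depth = library_depth,
    multimap_fraction = multimap_fraction,
    decoy_fraction = decoy_fraction,
    cluster_noise_sd = cluster_noise_sd,
    indel_rate = indel_rate,
    species_a = species_a, species_b = species_b,
    seed = as.integer(seed)), class = "sim_config")
}

#' Built-in stage grids
#'
#' Species A: `e0-1, e2-6, e6-10, e12-24` plus larva and adult windows on
#' a 0-168 h clock.  Species B: eight 2-h embryonic windows (0-16 h), a
#' late-embryo 16-30 h window, larva and adult, on the 1.5x slower clock.
#'
#' @return Data frame with columns `stage_label`, `t0`, `t1`, `symbolic`,
#'   `comparable_group` (index of the homologous stage pair).
#' @export
default_stage_grid_a <- function() {
  data.frame(
    stage_label = c("e0-1", "e2-6", "e6-10", "e12-24", "larva", "adult"),
    t0 = c(0, 2, 6, 12, 24, 120), t1 = c(1, 6, 10, 24, 120, 168),
    symbolic = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    comparable_group = 1:6, stringsAsFactors = FALSE)
}

#' @rdname default_stage_grid_a
#' @export
default_stage_grid_b <- function() {
  data.frame(
    stage_label = c("e0-2", "e2-4", "e4-6", "e6-8", "e8-10", "e10-12",
                    "e12-14", "e14-16", "e16-30", "larva", "adult"),
    t0 = c(seq(0, 14, 2), 16, 36, 180),
    t1 = c(seq(2, 16, 2), 30, 180, 252),
    symbolic = c(rep(FALSE, 9), TRUE, TRUE),
    comparable_group = c(1, 1, 2, 2, 2, 3, 3, 3, 4, 5, 6),
    stringsAsFactors = FALSE)
}

random_hairpin <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                             replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
  }
  paste(ch, collapse = "")
}

make_locus <- function(id, species, chrom, strand, start, hairpin_seq,
                       arm_len) {
  hairpin_seq <- unname(hairpin_seq)
  hp_len <- nchar(hairpin_seq)
  iv5 <- c(4L, 4L + arm_len)
  iv3 <- c(hp_len - 4L - arm_len, hp_len - 4L)
  mirna_locus(locus_id = id, species = species, chrom = chrom,
              strand = strand, start = start, end = start + hp_len,
              mature_intervals = list("5p" = iv5, "3p" = iv3),
              hairpin_seq = hairpin_seq,
              mature_seqs = c("5p" = substr(hairpin_seq, iv5[1] + 1L, iv5[2]),
                              "3p" = substr(hairpin_seq, iv3[1] + 1L, iv3[2])))
}

#' Simulate the two genomes
#'
#' Draws random hairpins with embedded 5p/3p arms for every ortholog
#' family, derives the species-B hairpin by i.i.d. per-site substitution
#' at the family's rate (optionally with a short loop deletion), adds
#' species-specific loci and identical-hairpin paralogs for multi-mapping
#' families, and places everything on one chromosome per species:
#' clustered families on one strand with inter-locus gaps <= 10 kb,
#' everything else separated by > 10 kb.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_genomes`: `loci_a`, `loci_b`
#'   ([mirna_loci()]), `orthologs` (`mirna_orthologs` truth),
#'   `families` (data frame with `family`, `rate`, `cluster_id`,
#'   `multimap`), `cluster_truth_a`, `cluster_truth_b` (named membership
#'   vectors).
#' @export
simulate_genomes <- function(config) {
  set.seed(config$seed)
  nf <- config$n_ortholog_families
  fam <- sprintf("fam%03d", seq_len(nf))
  rates <- runif(nf, config$substitution_rate_range[1],
                 config$substitution_rate_range[2])

  # cluster memberships at family level (conserved between species)
  cluster_id <- rep(NA_character_, nf)
  if (config$n_clusters > 0L) {
    pool <- seq_len(nf)
    for (ci in seq_len(config$n_clusters)) {
      size <- sample(seq(config$cluster_size_range[1],
                         config$cluster_size_range[2]), 1L)
      if (length(pool) < size) break
      take <- pool[seq_len(size)]
      pool <- setdiff(pool, take)
      cluster_id[take] <- sprintf("truecl%02d", ci)
    }
  }
  n_multi <- floor(config$multimap_fraction * nf)
  multimap <- rep(FALSE, nf)
  if (n_multi > 0L)
    multimap[sample(which(is.na(cluster_id)), n_multi)] <- TRUE

  hp_a <- vapply(seq_len(nf), function(i)
    random_hairpin(config$hairpin_len), "")
  hp_b <- vapply(seq_len(nf), function(i)
    mutate_seq(hp_a[i], rates[i]), "")
  if (config$indel_rate > 0) {
    del <- runif(nf) < config$indel_rate
    for (i in which(del)) {
      # delete 1-2 nt from the loop, between the two arms
      loop0 <- 4L + config$arm_len + 2L
      loop1 <- config$hairpin_len - 4L - config$arm_len - 2L
      if (loop1 - loop0 > 4L) {
        at <- sample(seq(loop0, loop1 - 2L), 1L)
        k <- sample(1:2, 1L)
        hp_b[i] <- paste0(substr(hp_b[i], 1L, at),
                          substr(hp_b[i], at + k + 1L,
                                 nchar(hp_b[i])))
      }
    }
  }

  build_species <- function(species, hp, ids, cluster_of, specific_n,
                            specific_prefix, multi_idx) {
    seqs <- hp
    all_ids <- ids
    all_cl <- cluster_of
    if (specific_n > 0L) {
      all_ids <- c(all_ids, sprintf("%s%03d", specific_prefix,
                                    seq_len(specific_n)))
      seqs <- c(seqs, vapply(seq_len(specific_n), function(i)
        random_hairpin(config$hairpin_len), ""))
      all_cl <- c(all_cl, rep(NA_character_, specific_n))
    }
    if (length(multi_idx)) {                 # identical-hairpin paralogs
      all_ids <- c(all_ids, paste0(ids[multi_idx], "p"))
      seqs <- c(seqs, hp[multi_idx])
      all_cl <- c(all_cl, rep(NA_character_, length(multi_idx)))
    }
    # placement: cluster blocks first, then unclustered loci
    ord <- order(!is.na(all_cl), all_cl, decreasing = c(TRUE, FALSE),
                 method = "radix", na.last = TRUE)
    pos <- 10000L
    loci <- list()
    prev_cl <- NA_character_
    strand <- "+"
    for (i in ord) {
      same_cluster <- !is.na(all_cl[i]) && identical(all_cl[i], prev_cl)
      if (same_cluster) {
        gap <- sample(200:9000, 1L)          # joins: gap <= 10 kb
      } else {
        gap <- sample(15000:60000, 1L)       # splits: gap > 10 kb
        strand <- sample(c("+", "-"), 1L)
      }
      start <- pos + gap
      loci[[length(loci) + 1L]] <-
        make_locus(all_ids[i], species, "chr2L", strand, start,
                   seqs[i], config$arm_len)
      pos <- start + nchar(seqs[i])
      prev_cl <- all_cl[i]
    }
    mirna_loci(loci)
  }

  id_a <- paste0(fam, "_a"); id_b <- paste0(fam, "_b")
  loci_a <- build_species(config$species_a, setNames(hp_a, id_a), id_a,
                          cluster_id, config$n_specific_a, "spa",
                          which(multimap))
  loci_b <- build_species(config$species_b, setNames(hp_b, id_b), id_b,
                          cluster_id, config$n_specific_b, "spb",
                          which(multimap))

  cl_truth <- function(ids) {
    cl <- setNames(cluster_id, ids)
    cl[!is.na(cl)]
  }
  structure(list(
    loci_a = loci_a, loci_b = loci_b,
    orthologs = make_orthologs(id_a, id_b),
    families = data.frame(family = fam, id_a = id_a, id_b = id_b,
                          rate = rates, cluster_id = cluster_id,
                          multimap = multimap, stringsAsFactors = FALSE),
    cluster_truth_a = cl_truth(id_a), cluster_truth_b = cl_truth(id_b)),
    class = "sim_genomes")
}

# temporal profile value (arbitrary abundance units) on the species-A
# clock.  Zygotic expression is modelled as sigmoidal onset followed by
# slow clearance (mature miRNAs are long-lived and accumulate), not as a
# narrow pulse.
zygotic_component <- function(t, onset, rise, persist)
  stats::plogis((t - onset) / rise) * exp(-pmax(0, t - onset) / persist)

profile_value <- function(par, t) {
  v <- switch(par$type,
              maternal = par$amp * exp(-t / par$tau),
              zygotic = par$amp * zygotic_component(t, par$onset,
                                                    par$rise, par$persist),
              constant = par$amp)
  if (!is.null(par$center2))                 # adult re-deposition bump
    v <- v + par$amp2 * exp(-(t - par$center2)^2 / (2 * par$width2^2))
  if (!is.null(par$onset2))                  # second expression phase
    v <- v + par$amp2b * zygotic_component(t, par$onset2, par$rise2,
                                           par$persist2)
  v + 0.02 * par$amp                         # small floor, keeps rows alive
}

draw_profile <- function(config) {
  type <- sample(names(config$profile_mix), 1L, prob = config$profile_mix)
  amp <- exp(rnorm(1, log(200), 1.5))
  par <- list(type = type, amp = amp)
  if (type == "maternal") {
    par$tau <- runif(1, 1, 8)
    if (runif(1) < 0.6) {                    # adult re-deposition (ovary)
      par$center2 <- runif(1, 130, 168)
      par$width2 <- runif(1, 10, 30)
      par$amp2 <- amp * runif(1, 0.1, 0.8)
    }
  }
  if (type == "zygotic") {
    u <- runif(1)
    par$onset <- if (u < 0.75) runif(1, 1, 30)       # embryonic, varied
    else if (u < 0.875) runif(1, 24, 120) else runif(1, 120, 168)
    par$rise <- runif(1, 0.5, 3)
    par$persist <- runif(1, 5, 150)          # stage-restricted to stable
  }
  if (is.null(par$center2) && runif(1) < 0.3) {  # second expression phase
    par$onset2 <- runif(1, 0, 160)
    par$rise2 <- runif(1, 0.5, 3)
    par$persist2 <- runif(1, 5, 150)
    par$amp2b <- amp * runif(1, 0.15, 0.5)
  }
  par
}

window_mean <- function(par, t0, t1) {
  tt <- seq(t0, t1, length.out = 21L)
  mean(profile_value(par, tt))
}

#' Simulate expression and library counts
#'
#' Every locus gets a continuous temporal profile (maternal decay,
#' zygotic pulse or constant); cluster members share their cluster's
#' primary profile times small i.i.d. per-stage noise.  The true stage
#' mean is the profile's average over the library's time window, with
#' species B read on its 1.5x-scaled clock.  Species-B stage means are
#' additionally multiplied by log-normal noise whose SD follows the
#' configured per-comparable-stage divergence profile (the hourglass
#' knob).  Library counts are multinomial draws of `library_depth` reads
#' over the arm-level means; replicates are independent draws.
#'
#' @param config A [simulation_config()].
#' @param genomes A `sim_genomes` from [simulate_genomes()].
#' @return List of class `sim_expression`: `counts_a`, `counts_b`
#'   (arm-level `mir_expr` raw counts), `samples` (`mirna_samples` for
#'   both species), and `truth` (stage-mean matrices, arm fractions,
#'   profile parameters, divergence profile).
#' @export
simulate_expression <- function(config, genomes) {
  set.seed(config$seed + 1L)
  fam <- genomes$families

  ids_a <- names(genomes$loci_a); ids_b <- names(genomes$loci_b)
  all_units <- union(sub("_a$", "", ids_a), sub("_b$", "", ids_b))

  # one profile per cluster (primary transcript) and per free unit
  cluster_profile <- lapply(unique(stats::na.omit(fam$cluster_id)),
                            function(x) draw_profile(config))
  names(cluster_profile) <- unique(stats::na.omit(fam$cluster_id))
  unit_profile <- list()
  for (u in all_units) {
    cl <- fam$cluster_id[match(u, fam$family)]
    unit_profile[[u]] <- if (!is.na(cl))
      cluster_profile[[cl]] else draw_profile(config)
  }
  arm_frac <- lapply(setNames(all_units, all_units), function(u) {
    dom <- sample(c("5p", "3p"), 1L)
    f <- runif(1, 0.7, 0.95)
    if (dom == "5p") c("5p" = f, "3p" = 1 - f) else c("5p" = 1 - f, "3p" = f)
  })

  grid_a <- config$stage_grid_a
  grid_b <- config$stage_grid_b
  n_groups <- max(grid_a$comparable_group, grid_b$comparable_group)
  # member-specific deviation from the shared primary-transcript profile;
  # drawn once per family so it is conserved between the two orthologs
  # (cis-encoded), per comparable stage group
  unit_dev <- lapply(setNames(all_units, all_units), function(u) {
    cl <- fam$cluster_id[match(u, fam$family)]
    if (is.na(cl)) rep(0, n_groups)
    else rnorm(n_groups, 0, config$cluster_noise_sd)
  })
  stage_means <- function(ids, grid, scale) {
    m <- matrix(0, length(ids), nrow(grid),
                dimnames = list(ids, grid$stage_label))
    for (i in seq_along(ids)) {
      u <- sub("_[ab]$", "", ids[i])
      par <- unit_profile[[u]]
      dev <- unit_dev[[u]]
      for (j in seq_len(nrow(grid))) {
        v <- window_mean(par, grid$t0[j] / scale, grid$t1[j] / scale)
        m[i, j] <- v * exp(dev[grid$comparable_group[j]])
      }
    }
    m
  }
  means_a <- stage_means(ids_a, grid_a, 1)
  means_b <- stage_means(ids_b, grid_b, config$time_scale)

  # hourglass knob: stage-dependent expression divergence on species B.
  # The noise is drawn per transcription unit (a cluster's primary
  # transcript, or a singleton locus) and comparable stage group, so
  # co-transcribed cluster members diverge together.
  sdp <- config$stage_divergence_profile
  groups <- grid_b$comparable_group
  if (max(groups) > length(sdp))
    stop("stage_divergence_profile shorter than the number of ",
         "comparable stage groups")
  tx_unit <- vapply(rownames(means_b), function(id) {
    cl <- fam$cluster_id[match(sub("_[ab]$", "", id), fam$family)]
    if (is.na(cl)) id else cl
  }, "")
  tx_noise <- lapply(setNames(unique(tx_unit), unique(tx_unit)),
                     function(u) exp(rnorm(length(sdp), 0, sdp)))
  for (i in seq_len(nrow(means_b)))
    means_b[i, ] <- means_b[i, ] * tx_noise[[tx_unit[i]]][groups]

  to_arms <- function(means, loci) {
    rows <- arm_rows(loci)
    ids <- split_arm_row_id(rows)
    frac <- vapply(seq_along(rows), function(k) {
      u <- sub("_[ab]$", "", ids$locus_id[k])
      arm_frac[[u]][[ids$arm[k]]]
    }, 0)
    m <- means[ids$locus_id, , drop = FALSE] * frac
    rownames(m) <- rows
    m
  }
  arm_a <- to_arms(means_a, genomes$loci_a)
  arm_b <- to_arms(means_b, genomes$loci_b)

  draw_counts <- function(arm_means, grid, species, reps) {
    cols <- list(); info <- list()
    for (j in seq_len(nrow(grid))) for (r in seq_len(reps)) {
      lib <- paste(species, grid$stage_label[j], paste0("r", r), sep = "_")
      p <- arm_means[, j]
      if (sum(p) <= 0) stop("all-zero stage mean vector for ", lib)
      cols[[lib]] <- rmultinom(1, size = config$library_depth,
                               prob = p / sum(p))[, 1]
      info[[lib]] <- data.frame(
        library_id = lib, species = species,
        stage_label = grid$stage_label[j],
        time_start = ifelse(grid$symbolic[j], NA_real_, grid$t0[j]),
        time_end = ifelse(grid$symbolic[j], NA_real_, grid$t1[j]),
        replicate_group = grid$stage_label[j], stringsAsFactors = FALSE)
    }
    list(counts = expr_matrix(do.call(cbind, cols),
                              unit = "raw_fractional_count",
                              species = species),
         samples = do.call(rbind, info))
  }
  da <- draw_counts(arm_a, grid_a, config$species_a, config$replicates_a)
  db <- draw_counts(arm_b, grid_b, config$species_b, config$replicates_b)

  structure(list(
    counts_a = da$counts, counts_b = db$counts,
    samples = mirna_samples(rbind(da$samples, db$samples)),
    truth = list(stage_means_a = means_a, stage_means_b = means_b,
                 arm_means_a = arm_a, arm_means_b = arm_b,
                 arm_frac = arm_frac,
                 profiles = unit_profile,
                 stage_divergence_profile = sdp,
                 comparable_group_b = setNames(groups,
                                               grid_b$stage_label))),
    class = "sim_expression")
}

#' Simulate a complete two-species dataset
#'
#' Runs [simulate_genomes()] and [simulate_expression()] under one seed.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_dataset` with `loci_a`, `loci_b`,
#'   `orthologs`, `counts_a`, `counts_b`, `samples`, `families`,
#'   `cluster_truth_a`, `cluster_truth_b`, `truth`, `config`.
#' @export
simulate_mirna_dataset <- function(config = simulation_config()) {
  g <- simulate_genomes(config)
  e <- simulate_expression(config, g)
  structure(c(g[c("loci_a", "loci_b", "orthologs", "families",
                  "cluster_truth_a", "cluster_truth_b")],
              e[c("counts_a", "counts_b", "samples", "truth")],
              list(config = config)),
            class = "sim_dataset")
}

#' Simulate SAM files from a count table
#'
#' Emits one SAM file per library.  Every counted read is sampled from
#' its mature arm with the 5' end anchored at the annotated arm start and
#' the 3' end jittered by +/-1 nt; reads from identical-hairpin paralog
#' families get one alignment record per matching locus under the same
#' query name.  A configurable fraction of 18-nt decoy reads (excluded by
#' the 19-24 nt counting window) is added.
#'
#' @param config A [simulation_config()].
#' @param counts Integer arm-level `mir_expr` count matrix (unit
#'   `raw_fractional_count`), e.g. `counts_a` of a `sim_dataset`.
#' @param loci Matching [mirna_loci()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of SAM paths (one per library).
#' @export
simulate_reads <- function(config, counts, loci, dir) {
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # multimap groups: loci sharing an identical hairpin sequence
  seqs <- vapply(loci, `[[`, "", "hairpin_seq")
  grp <- split(names(seqs), seqs)
  mates <- list()
  for (g in grp) for (id in g) mates[[id]] <- g

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              vapply(loci, function(l)
                sprintf("@SQ\tSN:%s\tLN:%d", l$locus_id,
                        nchar(l$hairpin_seq)), ""))
  row_info <- split_arm_row_id(rownames(counts))
  hp_seq <- vapply(loci, `[[`, "", "hairpin_seq")
  arm_start <- vapply(seq_len(nrow(row_info)), function(k)
    loci[[row_info$locus_id[k]]]$mature_intervals[[row_info$arm[k]]][1],
    0L)
  names(arm_start) <- rownames(counts)

  paths <- character(0)
  for (lib in colnames(counts)) {
    n_per_row <- as.integer(round(unclass(counts)[, lib]))
    read_row <- rep(rownames(counts), pmax(n_per_row, 0L))
    lens <- config$arm_len +
      sample(c(-1L, 0L, 1L), length(read_row), replace = TRUE)
    n_decoy <- round(config$decoy_fraction * length(read_row))
    if (n_decoy > 0L) {
      read_row <- c(read_row,
                    sample(rownames(counts), n_decoy, replace = TRUE))
      lens <- c(lens, rep(18L, n_decoy))
    }
    recs <- character(0)
    if (length(read_row)) {
      locus <- row_info$locus_id[match(read_row, rownames(counts))]
      st <- arm_start[read_row]
      lens <- pmin(lens, nchar(hp_seq[locus]) - st)
      sq <- substr(hp_seq[locus], st + 1L, st + lens)
      qn <- sprintf("%s_read%07d", lib, seq_along(read_row))
      k <- lengths(mates)[locus]
      ridx <- rep(seq_along(read_row), k)
      mate <- unlist(mates[locus], use.names = FALSE)
      flag <- ifelse(sequence(k) == 1L, 0L, 256L)
      recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                      qn[ridx], flag, mate, st[ridx] + 1L, lens[ridx],
                      sq[ridx])
    }
    path <- file.path(dir, paste0(lib, ".sam"))
    writeLines(c(header, recs), path)
    paths[lib] <- path
  }
  paths
}

#' Write a simulated dataset as a loadable file tree
#'
#' Emits GFF3 + FASTA annotations per species, the ortholog table, the
#' sample sheet, raw count tables and a ground-truth JSON; optionally
#' simulated SAM files.  Everything is loadable by the annotation I/O
#' functions.
#'
#' @param dataset A `sim_dataset` from [simulate_mirna_dataset()].
#' @param outdir Output directory (created).
#' @param sam Also write simulated SAM files under `outdir/sam_a`,
#'   `outdir/sam_b`.
#' @return Invisibly, a named list of the written paths.
#' @export
write_dataset <- function(dataset, outdir, sam = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    gff_a = file.path(outdir, "annotations_a.gff3"),
    hairpin_a = file.path(outdir, "hairpin_a.fa"),
    mature_a = file.path(outdir, "mature_a.fa"),
    gff_b = file.path(outdir, "annotations_b.gff3"),
    hairpin_b = file.path(outdir, "hairpin_b.fa"),
    mature_b = file.path(outdir, "mature_b.fa"),
    orthologs = file.path(outdir, "orthologs.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    counts_a = file.path(outdir, "counts_a.tsv"),
    counts_b = file.path(outdir, "counts_b.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_annotations(dataset$loci_a, p$gff_a, p$hairpin_a, p$mature_a)
  write_annotations(dataset$loci_b, p$gff_b, p$hairpin_b, p$mature_b)
  write_ortholog_table(dataset$orthologs, p$orthologs, divergence = FALSE)
  write_sample_sheet(dataset$samples, p$samples)
  write_count_matrix(dataset$counts_a, p$counts_a)
  write_count_matrix(dataset$counts_b, p$counts_b)
  jsonlite::write_json(list(
    seed = dataset$config$seed,
    families = dataset$families,
    stage_divergence_profile = dataset$truth$stage_divergence_profile,
    cluster_truth_a = as.list(dataset$cluster_truth_a),
    cluster_truth_b = as.list(dataset$cluster_truth_b),
    stage_means_a = as.data.frame(dataset$truth$stage_means_a),
    stage_means_b = as.data.frame(dataset$truth$stage_means_b)),
    p$truth, digits = NA, auto_unbox = TRUE)
  if (sam) {
    p$sam_a <- simulate_reads(dataset$config, dataset$counts_a,
                              dataset$loci_a, file.path(outdir, "sam_a"))
    p$sam_b <- simulate_reads(dataset$config, dataset$counts_b,
                              dataset$loci_b, file.path(outdir, "sam_b"))
  }
  invisible(p)
}
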