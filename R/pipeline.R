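#' Run the full cross-species analysis on in-memory objects
#'
#' Orchestrates the fixed analysis order - filter low-expression rows on
#' raw counts, normalise to RPM, average replicates, pool species-B
#' stages on raw counts, correlate stages within and between species,
#' cluster, and compute ortholog / cluster / random-pair temporal profile
#' conservation with divergence stratification and the hourglass profile.
#'
#' @param loci_a,loci_b [mirna_loci()] of the two species.
#' @param orthologs `mirna_orthologs` 1-to-1 table.
#' @param counts_a,counts_b Arm-level raw count `mir_expr` matrices
#'   (columns = library ids).
#' @param samples `mirna_samples` covering all libraries.
#' @param pooling_map Named list pooling species-B stage labels (see
#'   [default_virilis_pooling()]); `NULL` for none.
#' @param stage_map Homologous stage pairs ([default_stage_map()] layout);
#'   `stage_a` must match species-A replicate groups, `stage_b` the
#'   pooled species-B stage labels.
#' @param config A [counting_config()] (filter threshold).
#' @param max_gap Genomic cluster joining distance (bp).
#' @param n_null_draws Random-pair null size; default matches the number
#'   of ortholog records.
#' @param seed Seed for the random-pair null.
#' @param mid Hourglass mid-window positions (default: middle third).
#' @return A list of class `mirglass_results`; see Details.
#' @details Components: `within_a`, `within_b` (library-level Spearman
#'   `stage_cor` with dendrogram orders), `cross_stage` (stage x library
#'   cross-species matrix with replicate SD), `cross_pooled`
#'   (comparable-stage matrix), `hourglass`, `zscaled` (z-scaled ortholog
#'   profiles), `records` (all profile correlations), `group_tests`,
#'   `pairs` (orthologs with divergence + rate classes),
#'   `rate_association`, `clusters_a`, `clusters_b`, `staged_a`,
#'   `staged_b`.
#' @export
analyze_dataset <- function(loci_a, loci_b, orthologs, counts_a, counts_b,
                            samples, pooling_map = default_virilis_pooling(),
                            stage_map = default_stage_map(),
                            config = counting_config(), max_gap = 10000,
                            n_null_draws = NULL, seed = 1L, mid = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(orthologs) || nrow(orthologs) == 0L)
    stop("pipeline stage 'stagecompare cross-species' failed: ",
         "no ortholog table supplied", call. = FALSE)

  sa <- samples[samples$species == attr(counts_a, "species"), ]
  sb <- samples[samples$species == attr(counts_b, "species"), ]

  filt_a <- stage("quantify filter", filter_low_expression(counts_a, config))
  filt_b <- stage("quantify filter", filter_low_expression(counts_b, config))
  rpm_a <- stage("quantify normalize", normalize_rpm(filt_a))
  rpm_b <- stage("quantify normalize", normalize_rpm(filt_b))
  avg_a <- stage("quantify average", average_replicates(rpm_a, sa))
  avg_b <- stage("quantify average", average_replicates(rpm_b, sb))

  # within-species all-versus-all library matrices with dendrograms
  within_a <- stage("stagecompare within",
                    hcluster(correlation_matrix(rpm_a, rpm_a)))
  within_b <- stage("stagecompare within",
                    hcluster(correlation_matrix(rpm_b, rpm_b)))

  # cross-species stage matrix: species-A stages vs species-B libraries,
  # with per-A-replicate spread
  arm_map <- ortholog_row_map(orthologs, rpm_a, rpm_b)
  rep_mats <- split_replicate_matrices(rpm_a, sa)
  cross_stage <- stage("stagecompare cross-species", {
    if (length(rep_mats) >= 2L)
      replicate_spread(rep_mats, rpm_b, arm_map)
    else correlation_matrix(avg_a, rpm_b, arm_map)
  })

  # pooled comparable stages
  staged_a <- avg_a
  pooled_b <- stage("quantify pooling", {
    pm <- translate_pooling_map(pooling_map, sb)
    pool_stages(filt_b, pm)
  })
  colnames(pooled_b) <- stage_label_of(colnames(pooled_b), sb)
  staged_b <- stage("quantify normalize", normalize_rpm(pooled_b))

  pooled_map <- ortholog_row_map(orthologs, staged_a, staged_b)
  cross_pooled <- stage("stagecompare pooled",
                        correlation_matrix(staged_a, staged_b, pooled_map))
  hourglass <- stage("stagecompare hourglass",
                     hourglass_profile(cross_pooled, stage_map, mid = mid))

  # locus-level temporal profiles on the comparable stages
  la <- collapse_arms(staged_a)
  lb <- collapse_arms(staged_b)
  rec_orth <- stage("ortho_profiles orthologs",
                    ortholog_profile_correlations(la, lb, orthologs,
                                                  stage_map))
  clusters_a <- stage("homology clusters", find_clusters(loci_a, max_gap))
  clusters_b <- stage("homology clusters", find_clusters(loci_b, max_gap))
  rec_cl_a <- cluster_profile_correlations(la, clusters_a,
                                           "cluster_within_a")
  rec_cl_b <- cluster_profile_correlations(lb, clusters_b,
                                           "cluster_within_b")
  if (is.null(n_null_draws)) n_null_draws <- max(1L, nrow(rec_orth))
  rec_null <- stage("ortho_profiles null",
                    random_pair_null(la, lb, orthologs, n_null_draws,
                                     seed, stage_map))
  records <- profile_records(list(rec_orth, rec_cl_a, rec_cl_b, rec_null))

  group_tests <- list(
    ortholog_vs_random = stage("ortho_profiles tests",
                               compare_groups(rec_orth, rec_null)),
    ortholog_vs_cluster = if (nrow(rec_cl_a) + nrow(rec_cl_b) >= 3L)
      compare_groups(rec_orth,
                     profile_records(list(rec_cl_a, rec_cl_b))) else NULL)

  pairs <- stage("homology divergence",
                 annotate_divergence(orthologs, loci_a, loci_b))
  pairs <- stage("homology rates", classify_rates(pairs, "hairpin_div"))
  rate_association <- list(
    hairpin = stage("ortho_profiles rate association",
                    rate_conservation_association(rec_orth, pairs,
                                                  "hairpin_div")),
    mature = tryCatch(
      rate_conservation_association(rec_orth,
                                    classify_rates(pairs, "mature_div"),
                                    "mature_div"),
      error = function(e) NULL))

  zscaled <- stage("ortho_profiles zscale",
                   zscaled_profile_table(la, lb, orthologs, stage_map))

  structure(list(within_a = within_a, within_b = within_b,
                 cross_stage = cross_stage, cross_pooled = cross_pooled,
                 hourglass = hourglass, zscaled = zscaled,
                 records = records, group_tests = group_tests,
                 pairs = pairs, rate_association = rate_association,
                 clusters_a = clusters_a, clusters_b = clusters_b,
                 staged_a = staged_a, staged_b = staged_b,
                 seed = seed),
            class = "mirglass_results")
}

# one stage-level matrix per replicate index (k-th library of each group)
split_replicate_matrices <- function(rpm, samples) {
  idx <- match(colnames(rpm), samples$library_id)
  grp <- samples$replicate_group[idx]
  ks <- unlist(lapply(split(seq_along(grp), grp),
                      function(v) setNames(seq_along(v), v)))
  by_group <- split(seq_along(grp), grp)
  nmax <- max(lengths(by_group))
  lapply(seq_len(nmax), function(k) {
    cols <- vapply(by_group, function(v) v[min(k, length(v))], 0L)
    m <- unclass(rpm)[, cols, drop = FALSE]
    colnames(m) <- names(by_group)
    as_expr(m, rpm)
  })
}

# pooling map given in stage labels -> library-id members
translate_pooling_map <- function(pooling_map, samples) {
  if (is.null(pooling_map) || length(pooling_map) == 0L) return(list())
  lapply(pooling_map, function(stages)
    samples$library_id[samples$stage_label %in% stages])
}

stage_label_of <- function(cols, samples) {
  hit <- match(cols, samples$library_id)
  ifelse(is.na(hit), cols, samples$stage_label[hit])
}

#' @export
print.mirglass_results <- function(x, ...) {
  cat("<mirglass_results>\n")
  cat(sprintf("  stages: %d x %d cross-species comparable matrix\n",
              nrow(x$cross_pooled$values), ncol(x$cross_pooled$values)))
  gt <- x$group_tests$ortholog_vs_random
  cat(sprintf("  ortholog pairs: %d (median r = %.3f) vs random null median r = %.3f, rank-sum p = %.3g\n",
              gt$n_x, gt$median_x, gt$median_y, gt$p))
  ra <- x$rate_association$hairpin
  cat(sprintf("  rate vs conservation: r = %.3f, p = %.3g (n = %d)\n",
              ra$r, ra$p, ra$n))
  cat(sprintf("  hourglass score: %.4f, argmax pair %s ~ %s\n",
              x$hourglass$score,
              x$hourglass$diagonal$stage_a[x$hourglass$argmax],
              x$hourglass$diagonal$stage_b[x$hourglass$argmax]))
  invisible(x)
}

#' Run the pipeline from a config file or list
#'
#' Reads a YAML (or list) run configuration naming all inputs, executes
#' [analyze_dataset()] and, when `outdir` is given, writes the results
#' bundle as TSV/JSON tables.  Counts are taken from count TSVs when
#' given, otherwise quantified from SAM files.
#'
#' Config keys: `species_a`, `species_b`; per species `gff`, `hairpin_fasta`,
#' `mature_fasta` and either `counts` (TSV) or `sam` (named list
#' library_id -> SAM path) nested under `a:`/`b:`; `orthologs`,
#' `samples`; optional `pooling_map`, `stage_map`, `min_read_len`,
#' `max_read_len`, `min_total_reads`, `max_gap`, `n_null_draws`, `seed`,
#' `mid`.
#'
#' @param config Path to a YAML config, or an equivalent list.
#' @param outdir Optional output directory for the results bundle.
#' @return A `mirglass_results` object (invisibly when writing).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cc <- counting_config(
    min_read_len = config$min_read_len %||% 19L,
    max_read_len = config$max_read_len %||% 24L,
    min_total_reads = config$min_total_reads %||% 10L)
  get_side <- function(side, species) {
    s <- config[[side]]
    if (is.null(s)) stop("config missing '", side, "' input block")
    loci <- load_annotations(s$gff, s$hairpin_fasta, s$mature_fasta,
                             species)
    counts <- if (!is.null(s$counts)) read_count_matrix(s$counts, species)
    else if (!is.null(s$sam))
      count_mirna_libraries(unlist(s$sam), loci, cc)
    else stop("config side '", side, "' needs 'counts' or 'sam'")
    list(loci = loci, counts = counts)
  }
  a <- get_side("a", config$species_a %||% "species_a")
  b <- get_side("b", config$species_b %||% "species_b")
  samples <- load_samples(config$samples)
  if (is.null(config$orthologs))
    stop("pipeline stage 'stagecompare cross-species' failed: config ",
         "missing the ortholog table", call. = FALSE)
  orthologs <- load_orthologs(config$orthologs, a$loci, b$loci)
  stage_map <- if (!is.null(config$stage_map))
    data.frame(stage_a = vapply(config$stage_map, `[[`, "", 1L),
               stage_b = vapply(config$stage_map, `[[`, "", 2L),
               stringsAsFactors = FALSE) else default_stage_map()
  pooling_map <- config$pooling_map %||% default_virilis_pooling()

  res <- analyze_dataset(
    a$loci, b$loci, orthologs, a$counts, b$counts, samples,
    pooling_map = pooling_map, stage_map = stage_map, config = cc,
    max_gap = config$max_gap %||% 10000,
    n_null_draws = config$n_null_draws,
    seed = config$seed %||% 1L,
    mid = config$mid)
  if (!is.null(outdir)) {
    write_results_bundle(res, outdir, config)
    return(invisible(res))
  }
  res
}

write_results_bundle <- function(res, outdir, config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    df <- data.frame(stage = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wm(res$within_a$values, "within_a_spearman.tsv")
  wm(res$within_b$values, "within_b_spearman.tsv")
  wm(res$cross_stage$values, "cross_stage_spearman.tsv")
  if (!is.null(res$cross_stage$replicate_sd))
    wm(res$cross_stage$replicate_sd, "cross_stage_replicate_sd.tsv")
  wm(res$cross_pooled$values, "cross_pooled_spearman.tsv")
  write.table(res$zscaled, file.path(outdir, "zscaled_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(res$records),
              file.path(outdir, "profile_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_ortholog_table(res$pairs, file.path(outdir, "ortholog_divergence.tsv"))
  write_cluster_table(res$clusters_a, file.path(outdir, "clusters_a.tsv"))
  write_cluster_table(res$clusters_b, file.path(outdir, "clusters_b.tsv"))
  summary <- list(
    package_version = as.character(utils::packageVersion("mirglass")),
    seed = res$seed,
    hourglass = list(score = res$hourglass$score,
                     argmax = res$hourglass$argmax,
                     diagonal = res$hourglass$diagonal),
    group_tests = res$group_tests,
    rate_association = lapply(res$rate_association, function(x)
      if (is.null(x)) NULL else x[c("r", "p", "n")]))
  if (!is.null(config)) {
    tf <- tempfile(); yaml::write_yaml(config, tf)
    summary$config_md5 <- unname(tools::md5sum(tf)); unlink(tf)
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
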