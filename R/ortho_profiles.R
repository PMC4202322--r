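#' Temporal profile correlations of ortholog pairs
#'
#' For each 1-to-1 ortholog pair, extracts the two species' expression
#' time courses over the comparable (pooled) stages aligned by
#' `stage_map` and computes the Pearson correlation.  Pairs whose profile
#' is constant (e.g. all-zero) in either species are skipped with a
#' message.
#'
#' @param matrix_a_staged,matrix_b_staged Locus-level staged `mir_expr`
#'   matrices (see [collapse_arms()]), unit `rpm`.
#' @param pairs `mirna_orthologs` data frame.
#' @param stage_map Data frame (`stage_a`, `stage_b`) aligning the two
#'   stage sets 1-to-1; see [default_stage_map()].
#' @return A `profile_records` data frame: `pair_kind` (`"ortholog"`),
#'   `id_1`, `id_2`, `r`, `n_stages`.
#' @export
ortholog_profile_correlations <- function(matrix_a_staged, matrix_b_staged,
                                          pairs, stage_map) {
  if (anyDuplicated(stage_map$stage_a) || anyDuplicated(stage_map$stage_b))
    stop("stage_map is not 1-to-1")
  miss <- c(setdiff(stage_map$stage_a, colnames(matrix_a_staged)),
            setdiff(stage_map$stage_b, colnames(matrix_b_staged)))
  if (length(miss))
    stop("stage_map names unknown stages: ", paste(miss, collapse = ", "))
  A <- unclass(matrix_a_staged)[, stage_map$stage_a, drop = FALSE]
  B <- unclass(matrix_b_staged)[, stage_map$stage_b, drop = FALSE]
  recs <- list(); skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    ia <- pairs$id_a[i]; ib <- pairs$id_b[i]
    if (!ia %in% rownames(A) || !ib %in% rownames(B)) { next }
    x <- A[ia, ]; y <- B[ib, ]
    if (sd(x) == 0 || sd(y) == 0) { skipped <- skipped + 1L; next }
    recs[[length(recs) + 1L]] <-
      data.frame(pair_kind = "ortholog", id_1 = ia, id_2 = ib,
                 r = pearson_r(x, y), n_stages = length(x),
                 stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " ortholog pair(s) skipped (constant profile)")
  profile_records(recs)
}

profile_records <- function(recs) {
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(pair_kind = character(), id_1 = character(),
               id_2 = character(), r = numeric(), n_stages = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("profile_records", "data.frame"))
}

#' Co-expression of genomically clustered microRNAs
#'
#' One record per unordered pair of distinct miRNAs within each genomic
#' cluster (positive control: cluster members are typically co-transcribed
#' from one primary transcript).  Constant-profile members are skipped.
#'
#' @param staged_matrix Locus-level staged `mir_expr` matrix of one
#'   species, unit `rpm`.
#' @param clusters `mirna_clusters` from [find_clusters()].
#' @param pair_kind Label for the records, e.g. `"cluster_within_a"`.
#' @return A `profile_records` data frame.
#' @export
cluster_profile_correlations <- function(staged_matrix, clusters,
                                         pair_kind = "cluster_within_a") {
  M <- unclass(staged_matrix)
  recs <- list()
  for (members in clusters$clusters) {
    members <- intersect(members, rownames(M))
    if (length(members) < 2L) next
    for (i in seq_len(length(members) - 1L))
      for (j in seq.int(i + 1L, length(members))) {
        x <- M[members[i], ]; y <- M[members[j], ]
        if (sd(x) == 0 || sd(y) == 0) next
        recs[[length(recs) + 1L]] <-
          data.frame(pair_kind = pair_kind, id_1 = members[i],
                     id_2 = members[j], r = pearson_r(x, y),
                     n_stages = length(x), stringsAsFactors = FALSE)
      }
  }
  profile_records(recs)
}

#' Random cross-species pair null
#'
#' Draws `n_draws` cross-species miRNA pairs uniformly without replacement
#' from the non-orthologous combinations and correlates their temporal
#' profiles - the negative control for ortholog profile conservation.
#' Deterministic given `seed`.
#'
#' @inheritParams ortholog_profile_correlations
#' @param n_draws Number of random pairs (>= 1); defaults elsewhere to the
#'   number of ortholog records so box plots are size-matched.
#' @param seed Integer seed.
#' @param stage_map As in [ortholog_profile_correlations()].
#' @return A `profile_records` data frame (`pair_kind = "random_cross"`).
#' @export
random_pair_null <- function(matrix_a_staged, matrix_b_staged, pairs,
                             n_draws, seed, stage_map) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  A <- unclass(matrix_a_staged)[, stage_map$stage_a, drop = FALSE]
  B <- unclass(matrix_b_staged)[, stage_map$stage_b, drop = FALSE]
  ids_a <- rownames(A); ids_b <- rownames(B)
  na <- length(ids_a); nb <- length(ids_b)
  is_orth <- matrix(FALSE, na, nb, dimnames = list(ids_a, ids_b))
  ok <- pairs$id_a %in% ids_a & pairs$id_b %in% ids_b
  is_orth[cbind(pairs$id_a[ok], pairs$id_b[ok])] <- TRUE
  avail <- which(!is_orth)
  if (n_draws > length(avail))
    stop("n_draws exceeds the ", length(avail),
         " available non-ortholog combinations")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- sample(avail, n_draws)
  recs <- list()
  for (d in draw) {
    i <- (d - 1L) %% na + 1L; j <- (d - 1L) %/% na + 1L
    x <- A[i, ]; y <- B[j, ]
    if (sd(x) == 0 || sd(y) == 0) next
    recs[[length(recs) + 1L]] <-
      data.frame(pair_kind = "random_cross", id_1 = ids_a[i],
                 id_2 = ids_b[j], r = pearson_r(x, y),
                 n_stages = length(x), stringsAsFactors = FALSE)
  }
  profile_records(recs)
}

.Random.seed_save <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Compare two groups of profile correlations
#'
#' Two-sided Wilcoxon rank-sum test on the `r` distributions of two
#' record groups (e.g. orthologs versus the random-pair null), with
#' summary locations.
#'
#' @param records_x,records_y `profile_records` with >= 3 rows each.
#' @return List: `statistic` (rank-sum W), `p`, `median_x`, `median_y`,
#'   `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
compare_groups <- function(records_x, records_y) {
  if (nrow(records_x) < 3L || nrow(records_y) < 3L)
    stop("each group needs at least 3 records")
  wt <- suppressWarnings(wilcox.test(records_x$r, records_y$r,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_x = median(records_x$r), median_y = median(records_y$r),
       mean_x = mean(records_x$r), mean_y = mean(records_y$r),
       n_x = nrow(records_x), n_y = nrow(records_y))
}

#' Association between evolutionary rate and temporal conservation
#'
#' Pearson correlation (with the standard t-based two-sided p-value)
#' between per-pair sequence divergence and per-pair temporal profile r,
#' plus the per-rate-class r distributions.
#'
#' @param ortholog_records `profile_records` of ortholog pairs.
#' @param pairs `mirna_orthologs` with divergence (and, for the class
#'   summary, `rate_class`) set.
#' @param field `"hairpin_div"` or `"mature_div"`.
#' @return List: `r`, `p`, `n`, and `by_class` (named list of r vectors
#'   for low/medium/high).
#' @export
rate_conservation_association <- function(ortholog_records, pairs,
                                          field = c("hairpin_div",
                                                    "mature_div")) {
  field <- match.arg(field)
  m <- merge(ortholog_records, pairs, by.x = "id_1", by.y = "id_a")
  m <- m[!is.na(m[[field]]), ]
  if (nrow(m) < 5L)
    stop("need at least 5 pairs with temporal r and ", field)
  if (sd(m[[field]]) == 0)
    stop("divergence values are constant; association undefined")
  ct <- cor.test(m[[field]], m$r, method = "pearson")
  by_class <- split(m$r, factor(m$rate_class,
                                levels = c("low", "medium", "high")))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       by_class = by_class)
}

#' Z-scaled ortholog profile table
#'
#' For each ortholog pair present in both staged matrices, z-scores the
#' temporal profile of each species across its comparable stages and
#' binds them into one table (columns: species-A stages then species-B
#' stages) - the tabular analogue of a two-species z-scaled expression
#' heatmap.
#'
#' @inheritParams ortholog_profile_correlations
#' @return Data frame, one row per pair.
#' @export
zscaled_profile_table <- function(matrix_a_staged, matrix_b_staged, pairs,
                                  stage_map) {
  A <- unclass(matrix_a_staged)[, stage_map$stage_a, drop = FALSE]
  B <- unclass(matrix_b_staged)[, stage_map$stage_b, drop = FALSE]
  ok <- pairs$id_a %in% rownames(A) & pairs$id_b %in% rownames(B)
  pa <- pairs$id_a[ok]; pb <- pairs$id_b[ok]
  keep <- apply(A[pa, , drop = FALSE], 1, sd) > 0 &
    apply(B[pb, , drop = FALSE], 1, sd) > 0
  pa <- pa[keep]; pb <- pb[keep]
  za <- t(scale(t(A[pa, , drop = FALSE])))
  zb <- t(scale(t(B[pb, , drop = FALSE])))
  colnames(za) <- paste0("a:", stage_map$stage_a)
  colnames(zb) <- paste0("b:", stage_map$stage_b)
  cbind(data.frame(id_a = pa, id_b = pb, stringsAsFactors = FALSE),
        as.data.frame(za, row.names = FALSE),
        as.data.frame(zb, row.names = FALSE))
}
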