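#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); the
#' metric used for all global stage-versus-stage expression comparisons,
#' chosen for robustness to non-normality and outliers.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, not constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "spearman")
}

#' Pearson product-moment correlation
#'
#' Used for temporal profiles of orthologous and clustered microRNAs.
#'
#' @inheritParams spearman_rho
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  invisible(TRUE)
}

#' All-versus-all stage similarity matrix
#'
#' Builds the stage-by-stage similarity matrix between two staged RPM
#' matrices.  For cross-species comparisons, rows are restricted and
#' matched through `row_map` (1-to-1 ortholog row pairs); within species
#' the identity map over shared row names is used.  With
#' `metric = "spearman"` each cell is the Spearman correlation of the
#' matched expression vectors; with `metric = "euclidean_z"` each row is
#' first z-scored across its own species' stages (zero-variance rows
#' dropped from both, with a message) and cells store Euclidean distances.
#'
#' @param matrix_a,matrix_b `mir_expr` matrices, unit `rpm`, columns =
#'   stages.  Pass the same matrix twice for a within-species matrix.
#' @param row_map Two-column data frame (`row_a`, `row_b`) matching row
#'   names of `matrix_a` to `matrix_b`; `NULL` for the identity map.
#' @param metric `"spearman"` or `"euclidean_z"`.
#' @param species_a,species_b Optional tags prefixed to stage labels.
#' @return A list of class `stage_cor`: `values` (similarity matrix,
#'   rows = stages of A), `metric`, `row_stages`, `col_stages`,
#'   `replicate_sd` and dendrogram leaf orders (`row_order`, `col_order`;
#'   unset until [hcluster()]).
#' @export
correlation_matrix <- function(matrix_a, matrix_b, row_map = NULL,
                               metric = c("spearman", "euclidean_z"),
                               species_a = NULL, species_b = NULL) {
  metric <- match.arg(metric)
  if (expr_unit(matrix_a) != "rpm" || expr_unit(matrix_b) != "rpm")
    stop("stage comparison expects rpm matrices")
  if (is.null(row_map)) {
    shared <- intersect(rownames(matrix_a), rownames(matrix_b))
    row_map <- data.frame(row_a = shared, row_b = shared,
                          stringsAsFactors = FALSE)
  }
  miss_a <- setdiff(row_map$row_a, rownames(matrix_a))
  miss_b <- setdiff(row_map$row_b, rownames(matrix_b))
  if (length(miss_a) || length(miss_b))
    stop("row_map names rows missing from the matrices: ",
         paste(c(miss_a, miss_b), collapse = ", "))
  if (nrow(row_map) < 3L)
    stop("need at least 3 shared rows to compare stages")
  A <- unclass(matrix_a)[row_map$row_a, , drop = FALSE]
  B <- unclass(matrix_b)[row_map$row_b, , drop = FALSE]

  if (metric == "euclidean_z") {
    za <- t(scale(t(A))); zb <- t(scale(t(B)))
    bad <- apply(A, 1, sd) == 0 | apply(B, 1, sd) == 0
    if (any(bad)) {
      message("dropping ", sum(bad),
              " zero-variance row(s) from the z-scored comparison")
      za <- za[!bad, , drop = FALSE]; zb <- zb[!bad, , drop = FALSE]
    }
    if (nrow(za) < 3L) stop("fewer than 3 rows left after z-scoring")
    vals <- matrix(0, ncol(A), ncol(B))
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B)))
      vals[i, j] <- sqrt(sum((za[, i] - zb[, j])^2))
  } else {
    ra <- apply(A, 2, rank)
    rb <- apply(B, 2, rank)
    vals <- suppressWarnings(cor(ra, rb))
    if (anyNA(vals)) stop("constant stage vector; Spearman undefined")
  }
  row_stages <- tag_stage(colnames(A), species_a)
  col_stages <- tag_stage(colnames(B), species_b)
  dimnames(vals) <- list(row_stages, col_stages)
  structure(list(values = vals, metric = metric,
                 row_stages = row_stages, col_stages = col_stages,
                 replicate_sd = NULL, row_order = NULL, col_order = NULL),
            class = "stage_cor")
}

tag_stage <- function(stages, species)
  if (is.null(species)) stages else paste(species, stages, sep = ":")

#' @export
print.stage_cor <- function(x, digits = 3, ...) {
  cat(sprintf("<stage_cor> %d x %d, metric %s\n", nrow(x$values),
              ncol(x$values), x$metric))
  print(round(x$values, digits))
  invisible(x)
}

#' Replicate spread of stage correlations
#'
#' Recomputes the cross-species stage matrix once per replicate matrix and
#' summarises each cell by the mean and the (n-1) standard deviation of
#' the per-replicate coefficients - the error bars of the cross-species
#' comparison.
#'
#' @param matrices_per_replicate List of >= 2 staged `mir_expr` matrices,
#'   one per replicate set, sharing stage columns.
#' @param matrix_b Staged `mir_expr` matrix of the other species.
#' @param row_map,metric,species_a,species_b As in [correlation_matrix()].
#' @return A `stage_cor` whose `values` are the mean coefficients and
#'   whose `replicate_sd` holds the per-cell SD (NA with a warning for a
#'   singleton replicate list).
#' @export
replicate_spread <- function(matrices_per_replicate, matrix_b,
                             row_map = NULL,
                             metric = c("spearman", "euclidean_z"),
                             species_a = NULL, species_b = NULL) {
  metric <- match.arg(metric)
  reps <- lapply(matrices_per_replicate, correlation_matrix,
                 matrix_b = matrix_b, row_map = row_map, metric = metric,
                 species_a = species_a, species_b = species_b)
  arr <- simplify2array(lapply(reps, `[[`, "values"))
  out <- reps[[1]]
  out$values <- apply(arr, c(1, 2), mean)
  if (length(reps) < 2L) {
    warning("single replicate; spread undefined")
    out$replicate_sd <- NULL
  } else {
    out$replicate_sd <- apply(arr, c(1, 2), sd)
  }
  out
}

#' Hierarchically cluster a within-species stage matrix
#'
#' Average-linkage agglomerative clustering on `1 - rho` (Spearman) or on
#' the stored distances (`euclidean_z`); the resulting dendrogram leaf
#' order is stored in `row_order`/`col_order`.
#'
#' @param result Symmetric within-species `stage_cor`.
#' @return `result` with leaf orders set and the `hclust` tree attached
#'   as `tree`.
#' @export
hcluster <- function(result) {
  v <- result$values
  if (nrow(v) != ncol(v) || !isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
    stop("hierarchical clustering needs a symmetric within-species matrix")
  if (nrow(v) == 1L) {
    result$row_order <- result$col_order <- 1L
    return(result)
  }
  d <- if (result$metric == "spearman") as.dist(1 - v) else as.dist(v)
  tree <- hclust(d, method = "average")
  result$row_order <- result$col_order <- tree$order
  result$tree <- tree
  result
}

#' Extract the hourglass profile of cross-species conservation
#'
#' Reads the similarity values along the homologous-stage diagonal of a
#' cross-species `stage_cor`, reports the most-similar homologous pair,
#' and scores the hourglass shape as
#' `mean(rho over the mid pairs) - mean(rho over the first and last
#' pair)`; a positive score means mid-development is the most conserved.
#' Also reports, per stage of each species, the other-species stage with
#' the highest similarity (the best-partner check).
#'
#' @param cross_species_result `stage_cor` between species A (rows) and B
#'   (columns), Spearman metric.
#' @param homologous_pairs Data frame (`stage_a`, `stage_b`) of
#'   homologous stages ordered by developmental time; labels must match
#'   the result's (possibly species-tagged) stage labels.
#' @param mid Integer positions of the designated mid-developmental pairs;
#'   default is the middle third, `(floor(n/3)+1):(n-floor(n/3))`.
#' @return A list of class `hourglass_profile`: `diagonal` (data frame
#'   stage_a, stage_b, rho), `argmax`, `score`, `mid`, and
#'   `best_partner_a` / `best_partner_b`.
#' @export
hourglass_profile <- function(cross_species_result, homologous_pairs,
                              mid = NULL) {
  v <- cross_species_result$values
  hp <- homologous_pairs
  n <- nrow(hp)
  if (n < 3L) stop("need at least 3 homologous stage pairs")
  miss <- setdiff(c(hp$stage_a), rownames(v))
  miss <- c(miss, setdiff(hp$stage_b, colnames(v)))
  if (length(miss))
    stop("homologous pairs name unknown stages: ",
         paste(miss, collapse = ", "))
  rho <- v[cbind(hp$stage_a, hp$stage_b)]
  if (is.null(mid)) {
    k <- floor(n / 3)
    mid <- seq.int(k + 1L, n - k)
  }
  score <- mean(rho[mid]) - mean(rho[c(1L, n)])
  structure(list(
    diagonal = data.frame(stage_a = hp$stage_a, stage_b = hp$stage_b,
                          rho = rho, stringsAsFactors = FALSE),
    argmax = which.max(rho),
    score = score,
    mid = mid,
    best_partner_a = colnames(v)[apply(v, 1, which.max)],
    best_partner_b = rownames(v)[apply(v, 2, which.max)]),
    class = "hourglass_profile")
}

#' @export
print.hourglass_profile <- function(x, ...) {
  cat("<hourglass_profile>\n")
  print(transform(x$diagonal, rho = round(rho, 3)))
  cat(sprintf("argmax pair: %s ~ %s (position %d)\nhourglass score: %.4f (mid pairs %s)\n",
              x$diagonal$stage_a[x$argmax], x$diagonal$stage_b[x$argmax],
              x$argmax, x$score, paste(x$mid, collapse = ",")))
  invisible(x)
}

#' Ortholog-matched row map for cross-species comparison
#'
#' Expands a locus-level ortholog table into matched arm-level row pairs
#' present in both expression matrices (for arm-level matrices) or into
#' matched locus rows (for locus-level matrices).
#'
#' @param pairs `mirna_orthologs` data frame.
#' @param matrix_a,matrix_b `mir_expr` matrices whose row names the map
#'   must resolve in.
#' @return Data frame with columns `row_a`, `row_b`.
#' @export
ortholog_row_map <- function(pairs, matrix_a, matrix_b) {
  if (any(grepl("|", rownames(matrix_a), fixed = TRUE))) {
    maps <- lapply(c("5p", "3p"), function(arm) {
      ra <- arm_row_id(pairs$id_a, arm)
      rb <- arm_row_id(pairs$id_b, arm)
      ok <- ra %in% rownames(matrix_a) & rb %in% rownames(matrix_b)
      data.frame(row_a = ra[ok], row_b = rb[ok], stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  } else {
    ok <- pairs$id_a %in% rownames(matrix_a) &
      pairs$id_b %in% rownames(matrix_b)
    data.frame(row_a = pairs$id_a[ok], row_b = pairs$id_b[ok],
               stringsAsFactors = FALSE)
  }
}

#' Default homologous stage map
#'
#' The comparable developmental intervals used for ortholog time courses:
#' D. melanogaster `e0-1, e2-6, e6-10, e12-24, larva, adult` matched to
#' the pooled D. virilis `e0-4, e4-10, e10-16, e16-30, larva, adult`,
#' reflecting the ~1.5x slower D. virilis embryonic clock.
#'
#' @return Data frame with columns `stage_a`, `stage_b`.
#' @export
default_stage_map <- function() {
  data.frame(
    stage_a = c("e0-1", "e2-6", "e6-10", "e12-24", "larva", "adult"),
    stage_b = c("e0-4", "e4-10", "e10-16", "e16-30", "larva", "adult"),
    stringsAsFactors = FALSE)
}
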