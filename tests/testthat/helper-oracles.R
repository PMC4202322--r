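# Independent brute-force oracles used across the suite.

# affine score of one explicit alignment: gap run of length L costs
# gap_open + L * gap_extend
score_alignment <- function(sa, sb, scoring = c(1, -1, -5, -2)) {
  A <- strsplit(chartr("uU", "tT", toupper(sa)), "")[[1]]
  B <- strsplit(chartr("uU", "tT", toupper(sb)), "")[[1]]
  stopifnot(length(A) == length(B), !any(A == "-" & B == "-"))
  ng <- A != "-" & B != "-"
  sc <- sum(ifelse(A[ng] == B[ng], scoring[1], scoring[2]))
  gap_runs <- function(x) { r <- rle(x == "-"); r$lengths[r$values] }
  for (L in c(gap_runs(A), gap_runs(B)))
    sc <- sc + scoring[3] + L * scoring[4]
  sc
}

# exhaustive enumeration of all global alignments (feasible for len <= 6)
enumerate_align_score <- function(a, b, scoring = c(1, -1, -5, -2)) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(paste(ca, collapse = ""),
                                         paste(cb, collapse = ""),
                                         scoring))
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1L, j + 1L, c(ca, av[i]), c(cb, bv[j]))
    if (i <= length(av)) rec(i + 1L, j, c(ca, av[i]), c(cb, "-"))
    if (j <= length(bv)) rec(i, j + 1L, c(ca, "-"), c(cb, bv[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

random_nt <- function(len, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

# definitional correlation formulas
pearson_def <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
spearman_def <- function(x, y) pearson_def(rank(x), rank(y))

# all-pairs single-linkage clustering oracle: connected components of the
# "same chrom+strand and gap <= max_gap" graph; returns a canonical
# partition (sorted list of sorted member sets)
oracle_single_linkage <- function(df, max_gap) {
  n <- nrow(df)
  if (n == 0L) return(list())
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (df$chrom[i] != df$chrom[j] || df$strand[i] != df$strand[j]) next
    gap <- max(df$start[j] - df$end[i], df$start[i] - df$end[j], 0)
    if (gap <= max_gap) adj[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
    if (identical(new, comp)) break
    comp <- new
  }
  parts <- lapply(split(df$locus_id, comp), sort)
  unname(parts[order(vapply(parts, `[`, "", 1L))])
}

canonical_partition <- function(clusters) {
  parts <- lapply(clusters$clusters, sort)
  unname(parts[order(vapply(parts, `[`, "", 1L))])
}

# average-linkage oracle replicating hclust's merge and leaf-order
# conventions (singletons negative, within-row negatives first ascending,
# leaf order = recursive left-first expansion)
oracle_average_linkage_order <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))     # original indices per active cluster
  labels <- as.list(-seq_len(n))     # hclust-style cluster labels
  merges <- list()
  while (length(members) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(members) - 1L))
      for (j in seq.int(i + 1L, length(members))) {
        avg <- mean(d[members[[i]], members[[j]]])
        if (avg < bestd) { bestd <- avg; best <- c(i, j) }
      }
    i <- best[1]; j <- best[2]
    la <- labels[[i]]; lb <- labels[[j]]
    row <- if (la < 0 && lb < 0) c(max(la, lb), min(la, lb))
    else if (la < 0) c(la, lb)
    else if (lb < 0) c(lb, la)
    else sort(c(la, lb))
    merges[[length(merges) + 1L]] <- row
    members[[i]] <- c(members[[i]], members[[j]])
    labels[[i]] <- length(merges)
    members[[j]] <- NULL; labels[[j]] <- NULL
  }
  expand <- function(lab) {
    if (lab < 0) return(-lab)
    row <- merges[[lab]]
    c(expand(row[1]), expand(row[2]))
  }
  expand(length(merges))
}

# brute-force Wilcoxon rank-sum statistic (W, as reported by wilcox.test)
ranksum_W <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}
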