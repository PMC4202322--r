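#' Global pairwise alignment with affine gap costs
#'
#' End-to-end (Needleman-Wunsch/Gotoh) optimal alignment of two nucleotide
#' sequences.  A gap run of length L costs `gap_open + L * gap_extend`.
#' Traceback tie-breaking is deterministic: diagonal, then up (gap in
#' `seq_b`), then left.  U and T are treated as identical for scoring, but
#' the input symbols are preserved in the aligned strings.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings over A, C, G, T/U.
#' @param scoring Numeric vector `c(match, mismatch, gap_open, gap_extend)`.
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length strings over the nucleotide alphabet plus
#'   `-`) and `score`.
#' @export
align_pair <- function(seq_a, seq_b,
                       scoring = c(match = 1, mismatch = -1,
                                   gap_open = -5, gap_extend = -2)) {
  for (s in list(seq_a, seq_b)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s))
      stop("sequences must be non-empty strings")
    if (grepl("[^ACGTUacgtu]", s))
      stop("non-nucleotide symbol in sequence: ", s)
  }
  stopifnot(length(scoring) == 4L)
  a <- toupper(seq_a); b <- toupper(seq_b)
  res <- align_affine_cpp(norm_nt(a), norm_nt(b),
                          scoring[[1]], scoring[[2]],
                          scoring[[3]], scoring[[4]])
  # restore the original (possibly U-containing) symbols
  restore <- function(aligned, orig) {
    ch <- strsplit(aligned, "")[[1]]
    ch[ch != "-"] <- strsplit(orig, "")[[1]]
    paste(ch, collapse = "")
  }
  structure(list(aligned_a = restore(res$aligned_a, a),
                 aligned_b = restore(res$aligned_b, b),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\nscore: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Substitutions per site of an alignment (p-distance)
#'
#' Counts alignment columns with two non-gap, unequal symbols and divides
#' by the number of columns with two non-gap symbols.  Columns containing
#' a gap enter neither numerator nor denominator; U and T are identical.
#' No multiple-hit correction is applied.
#'
#' @param alignment A `pairwise_alignment` (or any list with `aligned_a`,
#'   `aligned_b`).
#' @return Proportion in `[0, 1]`.
#' @export
substitutions_per_site <- function(alignment) {
  a <- strsplit(norm_nt(alignment$aligned_a), "")[[1]]
  b <- strsplit(norm_nt(alignment$aligned_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned rows differ in length")
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("alignment has no gap-free columns; rate undefined")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Annotate ortholog pairs with sequence divergence
#'
#' Aligns hairpin sequences and shared mature arms of every ortholog pair
#' and fills `hairpin_div` and `mature_div` (substitutions per site).
#' Mature divergence pools the two arms: substitutions summed over both
#' arm alignments divided by the summed gap-free sites.  Only arms
#' annotated in both species are used; pairs without a shared arm keep
#' `mature_div` unset (NA).
#'
#' @param pairs A `mirna_orthologs` data frame.
#' @param loci_a,loci_b [mirna_loci()] of the two species.
#' @param scoring Alignment scoring passed to [align_pair()].
#' @return `pairs` with divergence columns filled.
#' @export
annotate_divergence <- function(pairs, loci_a, loci_b,
                                scoring = c(1, -1, -5, -2)) {
  for (i in seq_len(nrow(pairs))) {
    la <- loci_a[[pairs$id_a[i]]]; lb <- loci_b[[pairs$id_b[i]]]
    if (is.null(la) || is.null(lb))
      stop("ortholog pair references unknown locus: ",
           pairs$id_a[i], " / ", pairs$id_b[i])
    if (!nzchar(la$hairpin_seq) || !nzchar(lb$hairpin_seq))
      stop("missing hairpin sequence for pair ", pairs$id_a[i])
    pairs$hairpin_div[i] <-
      substitutions_per_site(align_pair(la$hairpin_seq, lb$hairpin_seq,
                                        scoring))
    shared <- intersect(names(la$mature_seqs), names(lb$mature_seqs))
    if (length(shared)) {
      subs <- 0; sites <- 0
      for (arm in shared) {
        al <- align_pair(la$mature_seqs[[arm]], lb$mature_seqs[[arm]],
                         scoring)
        aa <- strsplit(norm_nt(al$aligned_a), "")[[1]]
        bb <- strsplit(norm_nt(al$aligned_b), "")[[1]]
        ok <- aa != "-" & bb != "-"
        subs <- subs + sum(aa[ok] != bb[ok])
        sites <- sites + sum(ok)
      }
      pairs$mature_div[i] <- if (sites > 0) subs / sites else NA_real_
    } else {
      pairs$mature_div[i] <- NA_real_
    }
  }
  pairs
}

#' Split ortholog pairs into low/medium/high rate classes
#'
#' Tertile split on the chosen divergence field: pairs are stably sorted
#' ascending on `(value, id_a)`; the first `ceiling(n/3)` become `low`,
#' the last `ceiling(n/3)` become `high`, the remainder `medium`.  Pairs
#' with the field unset are excluded (rate_class stays `"unset"`).
#'
#' @param pairs `mirna_orthologs` with divergence annotated.
#' @param field `"hairpin_div"` or `"mature_div"`.
#' @return `pairs` with `rate_class` set.
#' @export
classify_rates <- function(pairs, field = c("hairpin_div", "mature_div")) {
  field <- match.arg(field)
  vals <- pairs[[field]]
  idx <- which(!is.na(vals))
  n <- length(idx)
  if (n < 3L) stop("need at least 3 pairs with ", field, " set")
  if (length(unique(vals[idx])) == 1L)
    warning("all ", field, " values tied; tertile split is by id order")
  ord <- idx[order(vals[idx], pairs$id_a[idx], method = "radix")]
  k <- ceiling(n / 3)
  cls <- rep("medium", n)
  cls[seq_len(k)] <- "low"
  cls[seq.int(n - k + 1L, n)] <- "high"
  pairs$rate_class <- rep("unset", nrow(pairs))
  pairs$rate_class[ord] <- cls
  pairs
}

#' Find genomic miRNA clusters
#'
#' Single-linkage chaining per (chromosome, strand): loci sorted by start
#' are chained while the inter-locus gap (next start minus current end;
#' 0-based half-open coordinates, so the non-overlap gap length) is at
#' most `max_gap`.  Overlapping loci always chain.  Singleton loci get
#' singleton clusters.
#'
#' @param loci [mirna_loci()] of one species.
#' @param max_gap Maximum joining gap in bp (default 10 kb, inclusive).
#' @return List of class `mirna_clusters`: `membership` (named vector
#'   locus -> cluster id) and `clusters` (cluster id -> ordered members).
#' @export
find_clusters <- function(loci, max_gap = 10000) {
  df <- as.data.frame(loci)
  membership <- character(0)
  clusters <- list()
  if (nrow(df)) {
    cid <- 0L
    for (key in split(seq_len(nrow(df)),
                      paste(df$chrom, df$strand, sep = "\r"))) {
      key <- key[order(df$start[key])]
      cur <- df$locus_id[key[1]]
      cur_end <- df$end[key[1]]
      for (i in key[-1]) {
        if (df$start[i] - cur_end <= max_gap) {
          cur <- c(cur, df$locus_id[i])
        } else {
          cid <- cid + 1L
          clusters[[paste0("cl", cid)]] <- cur
          cur <- df$locus_id[i]
        }
        cur_end <- max(cur_end, df$end[i])
      }
      cid <- cid + 1L
      clusters[[paste0("cl", cid)]] <- cur
    }
    membership <- setNames(rep(names(clusters), lengths(clusters)),
                           unlist(clusters, use.names = FALSE))
  }
  structure(list(membership = membership, clusters = clusters),
            class = "mirna_clusters")
}

#' @export
print.mirna_clusters <- function(x, ...) {
  multi <- sum(lengths(x$clusters) > 1L)
  cat(sprintf("<mirna_clusters> %d loci in %d clusters (%d multi-member)\n",
              length(x$membership), length(x$clusters), multi))
  invisible(x)
}

#' Write a cluster table
#' @param clusters A `mirna_clusters` object.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- data.frame(cluster_id = names(clusters$clusters),
                   n_members = lengths(clusters$clusters),
                   members = vapply(clusters$clusters, paste, "",
                                    collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
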