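#' Read-counting configuration
#'
#' Holds the counting rules: the retained read-length window (19-24 nt),
#' the low-expression threshold (rows with fewer than `min_total_reads`
#' summed reads over all libraries are dropped) and the arm-attribution
#' rule (a read belongs to the mature arm containing its 5'-most aligned
#' base).
#'
#' @param min_read_len,max_read_len Retained read lengths, inclusive.
#' @param min_total_reads Minimum summed raw count for a row to survive
#'   [filter_low_expression()]; the boundary is strict (`sum < threshold`
#'   is removed, an exact `sum == threshold` survives).
#' @param arm_attribution Attribution rule; only `"five_prime_anchor"`.
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(min_read_len = 19L, max_read_len = 24L,
                            min_total_reads = 10L,
                            arm_attribution = "five_prime_anchor") {
  stopifnot(min_read_len > 0L, min_read_len <= max_read_len,
            min_total_reads >= 0L,
            identical(arm_attribution, "five_prime_anchor"))
  structure(list(min_read_len = as.integer(min_read_len),
                 max_read_len = as.integer(max_read_len),
                 min_total_reads = as.integer(min_total_reads),
                 arm_attribution = arm_attribution),
            class = "counting_config")
}

#' Count miRNA reads from a SAM file
#'
#' Turns alignments against hairpin reference sequences (reference names =
#' locus ids) into fractional per-arm read counts.  Reads outside the
#' configured length window are ignored.  A read aligning to k distinct
#' loci contributes 1/k to each (the multiple-mapping correction); within
#' a locus it is attributed to the mature arm whose interval contains its
#' 5'-most aligned base, otherwise to a hairpin-other bucket that is
#' excluded from the mature counts (kept as the `other_count` attribute).
#'
#' @param sam_path SAM file (with header) aligned against hairpin refs.
#' @param loci [mirna_loci()] of the species the library belongs to.
#' @param config A [counting_config()].
#' @param library_id Column name of the returned one-column matrix;
#'   defaults to the SAM file name without extension.
#' @return A one-column `mir_expr` matrix (unit `raw_fractional_count`)
#'   with one row per annotated mature arm (`locus|arm`).  Attributes:
#'   `other_count` (fractional reads falling outside mature arms) and
#'   `n_retained` (distinct retained query names).
#' @export
count_mirna_reads <- function(sam_path, loci, config = counting_config(),
                              library_id = NULL) {
  if (is.null(library_id))
    library_id <- sub("\\.[^.]*$", "", basename(sam_path))
  rows <- arm_rows(loci)
  counts <- setNames(numeric(length(rows)), rows)
  other <- 0

  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  aln <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")))[[1]]

  mapped <- !bitwAnd(aln$flag, 4L)
  if (!any(mapped)) {
    warning("no mapped reads in ", sam_path)
    return(structure(expr_matrix(matrix(counts, ncol = 1,
                                        dimnames = list(rows, library_id)),
                                 unit = "raw_fractional_count",
                                 species = attr(loci, "species")),
                     other_count = 0, n_retained = 0L))
  }
  qname <- aln$qname[mapped]
  rname <- as.character(aln$rname[mapped])
  pos <- aln$pos[mapped]
  qw <- aln$qwidth[mapped]
  rev <- bitwAnd(aln$flag[mapped], 16L) > 0L

  bad_ref <- setdiff(unique(rname), names(loci))
  if (length(bad_ref))
    stop("SAM reference name(s) not among the loci: ",
         paste(bad_ref, collapse = ", "))

  keep <- qw >= config$min_read_len & qw <= config$max_read_len
  n_skipped <- sum(!keep)
  qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]
  qw <- qw[keep]; rev <- rev[keep]

  # one record per (query, locus); duplicates within a locus count once
  key <- paste(qname, rname, sep = "\r")
  first <- !duplicated(key)
  qname <- qname[first]; rname <- rname[first]; pos <- pos[first]
  qw <- qw[first]; rev <- rev[first]

  k <- table(qname)
  w <- 1 / as.numeric(k[qname])

  # hairpin-local 0-based position of the read's 5'-most aligned base
  p5 <- ifelse(rev, pos - 1L + qw - 1L, pos - 1L)
  arm_iv <- function(arm, k) vapply(loci, function(l) {
    iv <- l$mature_intervals[[arm]]
    if (is.null(iv)) NA_integer_ else iv[k]
  }, 0L)
  iv5s <- arm_iv("5p", 1L); iv5e <- arm_iv("5p", 2L)
  iv3s <- arm_iv("3p", 1L); iv3e <- arm_iv("3p", 2L)
  in5 <- !is.na(iv5s[rname]) & p5 >= iv5s[rname] & p5 < iv5e[rname]
  in3 <- !in5 & !is.na(iv3s[rname]) & p5 >= iv3s[rname] & p5 < iv3e[rname]
  target <- character(length(qname))
  target[in5] <- arm_row_id(rname[in5], "5p")
  target[in3] <- arm_row_id(rname[in3], "3p")
  in_arm <- nzchar(target)
  if (any(in_arm)) {
    agg <- rowsum(w[in_arm], group = target[in_arm])
    counts[rownames(agg)] <- counts[rownames(agg)] + agg[, 1]
  }
  other <- sum(w[!in_arm])
  message(sprintf(
    "%s: %d retained query names, %.3f fractional reads outside mature arms, %d off-length/unmapped records skipped",
    library_id, length(k), other, n_skipped + sum(!mapped)))

  structure(expr_matrix(matrix(counts, ncol = 1,
                               dimnames = list(rows, library_id)),
                        unit = "raw_fractional_count",
                        species = attr(loci, "species")),
            other_count = other, n_retained = length(k))
}

#' Count several libraries into one matrix
#'
#' @param sam_paths Named character vector of SAM paths; names become
#'   library ids.
#' @inheritParams count_mirna_reads
#' @return `mir_expr` matrix (unit `raw_fractional_count`), one column per
#'   library.
#' @export
count_mirna_libraries <- function(sam_paths, loci,
                                  config = counting_config()) {
  stopifnot(length(sam_paths) > 0L, !is.null(names(sam_paths)))
  cols <- lapply(names(sam_paths), function(id)
    count_mirna_reads(sam_paths[[id]], loci, config, library_id = id))
  as_expr(do.call(cbind, lapply(cols, unclass)), cols[[1]])
}

#' Drop rows with fewer than the threshold total reads
#'
#' Rows whose summed raw count over all libraries is below
#' `config$min_total_reads` are removed (strictly fewer: a row summing to
#' exactly the threshold survives).  Must run on raw counts, before
#' normalisation.
#'
#' @param matrix_all_libraries `mir_expr` over all libraries of a species,
#'   unit `raw_fractional_count`.
#' @param config A [counting_config()].
#' @return Filtered `mir_expr` matrix, row order preserved.
#' @export
filter_low_expression <- function(matrix_all_libraries,
                                  config = counting_config()) {
  if (expr_unit(matrix_all_libraries) != "raw_fractional_count")
    stop("low-expression filtering must precede normalization ",
         "(unit must be raw_fractional_count)")
  keep <- rowSums(matrix_all_libraries) >= config$min_total_reads
  as_expr(unclass(matrix_all_libraries)[keep, , drop = FALSE],
          matrix_all_libraries)
}

#' Normalise to reads per million mapping to microRNAs
#'
#' Each column is scaled so that its values sum to one million.
#'
#' @param matrix `mir_expr`, unit `raw_fractional_count`.
#' @return `mir_expr` with unit `rpm`.
#' @export
normalize_rpm <- function(matrix) {
  if (expr_unit(matrix) != "rpm" &&
      expr_unit(matrix) != "raw_fractional_count")
    stop("cannot normalise a matrix of unit ", expr_unit(matrix))
  tot <- colSums(matrix)
  if (any(tot <= 0))
    stop("zero-total column(s): ",
         paste(colnames(matrix)[tot <= 0], collapse = ", "))
  as_expr(sweep(unclass(matrix), 2, tot, "/") * 1e6, matrix, unit = "rpm")
}

#' Average replicate libraries
#'
#' Columns sharing a `replicate_group` are replaced by their per-row
#' arithmetic mean (this is also how separate-sex adult libraries are
#' combined into one adult column); singleton groups pass through.  The
#' per-group per-row standard deviation is retained in the
#' `replicate_sd` attribute for error bars.
#'
#' @param matrix `mir_expr`, unit `rpm`, columns = library ids.
#' @param samples `mirna_samples` covering the columns.
#' @return `mir_expr` keyed by replicate group (stage label), with a
#'   `replicate_sd` attribute (NA for singleton groups).
#' @export
average_replicates <- function(matrix, samples) {
  if (expr_unit(matrix) != "rpm")
    stop("replicate averaging expects rpm values")
  idx <- match(colnames(matrix), samples$library_id)
  if (anyNA(idx))
    stop("columns missing from the sample sheet: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  grp <- samples$replicate_group[idx]
  spp <- samples$species[idx]
  for (g in unique(grp))
    if (length(unique(spp[grp == g])) > 1L)
      stop("replicate group ", g, " mixes species")
  groups <- unique(grp)
  mean_m <- vapply(groups, function(g)
    rowMeans(unclass(matrix)[, grp == g, drop = FALSE]),
    numeric(nrow(matrix)))
  sd_m <- vapply(groups, function(g) {
    cols <- unclass(matrix)[, grp == g, drop = FALSE]
    if (ncol(cols) < 2L) rep(NA_real_, nrow(cols)) else apply(cols, 1, sd)
  }, numeric(nrow(matrix)))
  mean_m <- matrix(mean_m, nrow = nrow(matrix),
                   dimnames = list(rownames(matrix), groups))
  sd_m <- matrix(sd_m, nrow = nrow(matrix),
                 dimnames = list(rownames(matrix), groups))
  structure(as_expr(mean_m, matrix), replicate_sd = sd_m)
}

#' Pool adjacent developmental stages
#'
#' Sums raw counts of member columns into one pooled column; pooling
#' operates on raw counts so that re-normalisation to RPM is a subsequent
#' explicit [normalize_rpm()] call.  Non-pooled columns are unchanged;
#' pooled columns appear at the position of their first member.
#'
#' @param raw_count_matrix `mir_expr`, unit `raw_fractional_count`.
#' @param pooling_map Named list: pooled label -> character vector of
#'   member column names; must partition a subset of the columns.
#' @return `mir_expr`, unit `raw_fractional_count`.
#' @export
pool_stages <- function(raw_count_matrix, pooling_map) {
  if (expr_unit(raw_count_matrix) != "raw_fractional_count")
    stop("stage pooling operates on raw counts")
  if (length(pooling_map) == 0L) return(raw_count_matrix)
  members <- unlist(pooling_map, use.names = FALSE)
  if (anyDuplicated(members))
    stop("column(s) assigned to two pools: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  miss <- setdiff(members, colnames(raw_count_matrix))
  if (length(miss))
    stop("pooling map names unknown column(s): ",
         paste(miss, collapse = ", "))
  m <- unclass(raw_count_matrix)
  out <- list()
  done <- character()
  for (cn in colnames(m)) {
    if (cn %in% done) next
    pool <- names(pooling_map)[vapply(pooling_map, function(v) cn %in% v, TRUE)]
    if (length(pool)) {
      out[[pool]] <- rowSums(m[, pooling_map[[pool]], drop = FALSE])
      done <- c(done, pooling_map[[pool]])
    } else {
      out[[cn]] <- m[, cn]
    }
  }
  res <- do.call(cbind, out)
  rownames(res) <- rownames(m)
  as_expr(res, raw_count_matrix)
}

#' Default D. virilis embryo pooling map
#'
#' Groups the 2-h D. virilis embryonic libraries into the three
#' morphologically comparable windows: 0-4 h (cleavage), 4-10 h
#' (gastrulation + germband elongation) and 10-16 h (germband shortening).
#'
#' @return Named list usable as `pooling_map` in [pool_stages()].
#' @export
default_virilis_pooling <- function() {
  list("e0-4" = c("e0-2", "e2-4"),
       "e4-10" = c("e4-6", "e6-8", "e8-10"),
       "e10-16" = c("e10-12", "e12-14", "e14-16"))
}
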