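#' Create a microRNA locus record
#'
#' A locus is one annotated hairpin precursor with its 1-2 mature arms.
#' Genomic coordinates are stored 0-based half-open.  For minus-strand loci
#' the stored sequences are the reading-direction (reverse-complemented)
#' sequences, and mature intervals are hairpin-local coordinates along the
#' reading direction, so that all downstream arm logic is strand-free.
#'
#' @param locus_id Unique (within species) locus identifier; also the SAM
#'   reference name the hairpin is aligned against.
#' @param species Species tag, e.g. `"dmel"`.
#' @param chrom Chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param start,end Genomic hairpin interval, 0-based half-open.
#' @param mature_intervals Named list (`"5p"`, `"3p"`) of integer pairs
#'   `c(start, end)`, hairpin-local 0-based half-open, reading direction.
#' @param hairpin_seq Hairpin nucleotide sequence (reading direction).
#' @param mature_seqs Named character vector of mature arm sequences; must
#'   equal the hairpin subsequence at the corresponding interval.
#' @return An object of class `mirna_locus`.
#' @export
mirna_locus <- function(locus_id, species, chrom, strand, start, end,
                        mature_intervals, hairpin_seq, mature_seqs) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for locus ", locus_id)
  start <- as.integer(start); end <- as.integer(end)
  if (end - start != nchar(hairpin_seq))
    stop("hairpin interval length does not match hairpin sequence for locus ",
         locus_id)
  if (length(mature_intervals) < 1L || length(mature_intervals) > 2L)
    stop("locus ", locus_id, " must have 1 or 2 mature arms")
  if (!all(names(mature_intervals) %in% c("5p", "3p")))
    stop("mature arm labels must be '5p'/'3p' for locus ", locus_id)
  if (!setequal(names(mature_intervals), names(mature_seqs)))
    stop("mature interval and sequence labels disagree for locus ", locus_id)
  hp_len <- end - start
  for (arm in names(mature_intervals)) {
    iv <- as.integer(mature_intervals[[arm]])
    if (iv[1] < 0L || iv[2] > hp_len || iv[1] >= iv[2])
      stop("mature ", arm, " interval outside hairpin for locus ", locus_id)
    sub <- substr(hairpin_seq, iv[1] + 1L, iv[2])
    if (!identical(norm_nt(sub), norm_nt(mature_seqs[[arm]])))
      stop("mature ", arm, " sequence of locus ", locus_id,
           " does not match the hairpin subsequence at its interval")
    mature_intervals[[arm]] <- iv
  }
  structure(list(locus_id = locus_id, species = species, chrom = chrom,
                 strand = strand, start = start, end = end,
                 mature_intervals = mature_intervals,
                 hairpin_seq = toupper(hairpin_seq),
                 mature_seqs = vapply(mature_seqs, toupper, "")),
            class = "mirna_locus")
}

# uppercase and collapse U to T for sequence comparisons
norm_nt <- function(x) chartr("uU", "tT", toupper(x))

#' Bundle loci of one species
#'
#' @param loci List of [mirna_locus()] objects, all of the same species.
#' @return Named list of class `mirna_loci` (names are locus ids).
#' @export
mirna_loci <- function(loci) {
  if (length(loci) == 0L)
    return(structure(list(), class = "mirna_loci"))
  stopifnot(all(vapply(loci, inherits, TRUE, "mirna_locus")))
  ids <- vapply(loci, `[[`, "", "locus_id")
  if (anyDuplicated(ids))
    stop("duplicate locus ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sp <- unique(vapply(loci, `[[`, "", "species"))
  if (length(sp) > 1L)
    stop("loci mix species: ", paste(sp, collapse = ", "))
  names(loci) <- ids
  structure(loci, class = "mirna_loci", species = sp)
}

#' @export
print.mirna_locus <- function(x, ...) {
  cat(sprintf("<mirna_locus> %s (%s) %s:%d-%d(%s), arms: %s\n",
              x$locus_id, x$species, x$chrom, x$start, x$end, x$strand,
              paste(names(x$mature_intervals), collapse = ",")))
  invisible(x)
}

#' @export
print.mirna_loci <- function(x, ...) {
  cat(sprintf("<mirna_loci> %d loci of species %s\n",
              length(x), attr(x, "species") %||% "?"))
  invisible(x)
}

#' @export
as.data.frame.mirna_loci <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(locus_id = character(), species = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  data.frame(locus_id = vapply(x, `[[`, "", "locus_id"),
             species = vapply(x, `[[`, "", "species"),
             chrom = vapply(x, `[[`, "", "chrom"),
             strand = vapply(x, `[[`, "", "strand"),
             start = vapply(x, `[[`, 0L, "start"),
             end = vapply(x, `[[`, 0L, "end"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# all arm-level row ids of a locus set, in locus order with 5p before 3p
arm_rows <- function(loci) {
  unlist(lapply(loci, function(l) {
    arms <- intersect(c("5p", "3p"), names(l$mature_intervals))
    arm_row_id(l$locus_id, arms)
  }), use.names = FALSE)
}
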