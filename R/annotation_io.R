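#' Load miRNA annotations from GFF3 and FASTA
#'
#' Reads a miRBase-dialect GFF3 (`miRNA_primary_transcript` hairpins and
#' `miRNA` mature features linked by `Derives_from`, or by ID prefix when
#' `Derives_from` is absent) together with hairpin and mature FASTA files,
#' and assembles validated [mirna_locus()] records.  GFF 1-based closed
#' coordinates are converted to the internal 0-based half-open convention
#' at this boundary; minus-strand mature intervals are re-expressed in
#' hairpin-local reading-direction coordinates.  Unknown feature types are
#' skipped with a warning.
#'
#' Arm labels are taken from a `-5p`/`-3p` suffix on the mature feature's
#' ID or Name when present, and otherwise inferred from position (the arm
#' nearer the hairpin's 5' end in reading direction is `5p`).
#'
#' @param gff_path GFF3 annotation file.
#' @param hairpin_fasta_path FASTA of hairpin sequences keyed by hairpin ID.
#' @param mature_fasta_path FASTA of mature sequences keyed by mature ID.
#' @param species Species tag stored on each locus.
#' @return A [mirna_loci()] collection.
#' @export
load_annotations <- function(gff_path, hairpin_fasta_path,
                             mature_fasta_path, species) {
  lines <- readLines(gff_path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    warning("no features in GFF file ", gff_path)
    return(mirna_loci(list()))
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  hp_fa <- read_fasta_chr(hairpin_fasta_path)
  mat_fa <- read_fasta_chr(mature_fasta_path)

  type <- as.character(gr$type)
  known <- type %in% c("miRNA_primary_transcript", "miRNA")
  if (any(!known)) {
    warning("skipping ", sum(!known), " GFF feature(s) of unknown type: ",
            paste(unique(type[!known]), collapse = ", "))
    gr <- gr[known]
    type <- type[known]
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every miRNA feature needs an ID attribute")
  hp <- gr[type == "miRNA_primary_transcript"]
  mat <- gr[type == "miRNA"]
  if (anyDuplicated(hp$ID))
    stop("duplicate hairpin ids in GFF: ",
         paste(unique(hp$ID[duplicated(hp$ID)]), collapse = ", "))
  if (anyDuplicated(mat$ID))
    stop("duplicate mature ids in GFF: ",
         paste(unique(mat$ID[duplicated(mat$ID)]), collapse = ", "))

  hp_id_of <- function(k) {
    df <- if ("Derives_from" %in% names(S4Vectors::mcols(mat)))
      as.character(mat$Derives_from[k]) else NA_character_
    if (!is.na(df) && nzchar(df)) {
      if (!df %in% hp$ID)
        stop("mature feature ", mat$ID[k], " has no parent hairpin ",
             "(Derives_from=", df, " unresolvable)")
      return(df)
    }
    # fall back to ID prefix: mature "<hairpin>_<suffix>"
    pref <- hp$ID[startsWith(as.character(mat$ID[k]),
                             paste0(as.character(hp$ID), "_"))]
    if (length(pref) == 1L) return(pref)
    stop("mature feature ", mat$ID[k],
         " has no parent hairpin (missing/unresolvable Derives_from)")
  }
  parent_of <- vapply(seq_along(mat), hp_id_of, "")

  loci <- lapply(seq_along(hp), function(i) {
    id <- as.character(hp$ID[i])
    strand <- as.character(BiocGenerics::strand(hp[i]))
    if (!strand %in% c("+", "-"))
      stop("hairpin ", id, " has no stranded annotation")
    h0 <- GenomicRanges::start(hp[i]) - 1L   # 0-based half-open
    h1 <- GenomicRanges::end(hp[i])
    if (!id %in% names(hp_fa))
      stop("hairpin ", id, " missing from hairpin FASTA")
    hseq <- hp_fa[[id]]

    kk <- which(parent_of == id)
    if (length(kk) == 0L)
      stop("hairpin ", id, " has no mature features")
    ivs <- list(); seqs <- character()
    for (k in kk) {
      m0 <- GenomicRanges::start(mat[k]) - 1L
      m1 <- GenomicRanges::end(mat[k])
      if (m0 < h0 || m1 > h1)
        stop("mature feature ", mat$ID[k], " lies outside hairpin ", id)
      if (strand == "+") iv <- c(m0 - h0, m1 - h0) else iv <- c(h1 - m1, h1 - m0)
      arm <- arm_label(as.character(mat$ID[k]),
                       if ("Name" %in% names(S4Vectors::mcols(mat)))
                         as.character(mat$Name[k]) else NA_character_)
      mid <- as.character(mat$ID[k])
      if (!mid %in% names(mat_fa))
        stop("mature sequence ", mid, " missing from mature FASTA")
      ivs[[length(ivs) + 1L]] <- iv
      names(ivs)[length(ivs)] <- arm %||% NA_character_
      seqs[length(seqs) + 1L] <- mat_fa[[mid]]
    }
    # positional fallback for unlabeled arms: 5p is nearer the 5' end
    if (anyNA(names(ivs))) {
      ord <- order(vapply(ivs, `[`, 0, 1L))
      lab <- names(ivs)
      if (length(ivs) == 1L) lab[is.na(lab)] <- "5p"
      else lab[ord] <- ifelse(is.na(lab[ord]), c("5p", "3p"), lab[ord])
      names(ivs) <- lab
    }
    names(seqs) <- names(ivs)
    mirna_locus(locus_id = id, species = species,
                chrom = as.character(GenomicRanges::seqnames(hp[i])),
                strand = strand, start = h0, end = h1,
                mature_intervals = ivs, hairpin_seq = hseq,
                mature_seqs = seqs)
  })
  mirna_loci(loci)
}

arm_label <- function(id, name) {
  for (s in c(id, name)) {
    if (!is.na(s) && grepl("[-_]([35]p)$", s))
      return(sub("^.*[-_]([35]p)$", "\\1", s))
  }
  NULL
}

read_fasta_chr <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  as.list(out)
}

#' Write miRNA annotations to GFF3 and FASTA
#'
#' Inverse of [load_annotations()]: emits a miRBase-dialect GFF3 (1-based
#' closed coordinates, `Derives_from` linkage) plus hairpin and mature
#' FASTA files keyed by feature IDs.  Mature feature IDs are
#' `<locus>_<arm>` and Names `<locus>-<arm>`.
#'
#' @param loci A [mirna_loci()] collection.
#' @param gff_path,hairpin_fasta_path,mature_fasta_path Output paths.
#' @return Invisibly, the GFF path.
#' @export
write_annotations <- function(loci, gff_path, hairpin_fasta_path,
                              mature_fasta_path) {
  rows <- list(); hp_seq <- character(); mat_seq <- character()
  for (l in loci) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = l$chrom, start = l$start + 1L, end = l$end,
      strand = l$strand, type = "miRNA_primary_transcript",
      ID = l$locus_id, Name = l$locus_id, Derives_from = NA_character_,
      stringsAsFactors = FALSE)
    hp_seq[l$locus_id] <- l$hairpin_seq
    for (arm in names(l$mature_intervals)) {
      iv <- l$mature_intervals[[arm]]
      if (l$strand == "+") { g0 <- l$start + iv[1]; g1 <- l$start + iv[2] }
      else { g0 <- l$end - iv[2]; g1 <- l$end - iv[1] }
      mid <- paste0(l$locus_id, "_", arm)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = l$chrom, start = g0 + 1L, end = g1, strand = l$strand,
        type = "miRNA", ID = mid, Name = paste0(l$locus_id, "-", arm),
        Derives_from = l$locus_id, stringsAsFactors = FALSE)
      mat_seq[mid] <- l$mature_seqs[[arm]]
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, source = "mirglass",
    ID = df$ID, Name = df$Name, Derives_from = df$Derives_from)
  rtracklayer::export(gr, gff_path, format = "gff3")
  Biostrings::writeXStringSet(Biostrings::BStringSet(hp_seq),
                              hairpin_fasta_path)
  Biostrings::writeXStringSet(Biostrings::BStringSet(mat_seq),
                              mature_fasta_path)
  invisible(gff_path)
}

#' Load a 1-to-1 ortholog table
#'
#' Reads a two-column TSV (optional header) of locus ids in species A and
#' B, checks every id against the supplied locus sets and enforces the
#' 1-to-1 property.
#'
#' @param tsv_path Two-column TSV path.
#' @param loci_a,loci_b [mirna_loci()] collections the ids must resolve in.
#' @return A `mirna_orthologs` data frame with columns `id_a`, `id_b`,
#'   `hairpin_div`, `mature_div` (unset, `NA`) and `rate_class` (`"unset"`).
#' @export
load_orthologs <- function(tsv_path, loci_a, loci_b) {
  raw <- read.delim(tsv_path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", colClasses = "character")
  if (ncol(raw) < 2L) stop("ortholog table must have two columns")
  raw <- raw[, 1:2]
  if (nrow(raw) > 0L &&
      !(raw[1, 1] %in% names(loci_a)) && !(raw[1, 2] %in% names(loci_b)) &&
      (nrow(raw) == 1L || all(raw[-1, 1] %in% names(loci_a))))
    raw <- raw[-1, , drop = FALSE]           # header row
  make_orthologs(raw[[1]], raw[[2]], loci_a, loci_b)
}

make_orthologs <- function(id_a, id_b, loci_a = NULL, loci_b = NULL) {
  if (!is.null(loci_a)) {
    bad <- setdiff(id_a, names(loci_a))
    if (length(bad)) stop("unknown species-A ids in ortholog table: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(id_b, names(loci_b))
    if (length(bad)) stop("unknown species-B ids in ortholog table: ",
                          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(id_a) || anyDuplicated(id_b))
    stop("ortholog table is not 1-to-1; repeated ids: ",
         paste(unique(c(id_a[duplicated(id_a)], id_b[duplicated(id_b)])),
               collapse = ", "))
  structure(data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                       hairpin_div = NA_real_, mature_div = NA_real_,
                       rate_class = rep("unset", length(id_a)),
                       stringsAsFactors = FALSE),
            class = c("mirna_orthologs", "data.frame"))
}

#' Write an ortholog table
#' @param pairs A `mirna_orthologs` data frame.
#' @param path Output TSV path.
#' @param divergence Include divergence / rate-class columns when present.
#' @return Invisibly, the path.
#' @export
write_ortholog_table <- function(pairs, path, divergence = TRUE) {
  out <- pairs[, c("id_a", "id_b")]
  if (divergence && any(!is.na(pairs$hairpin_div)))
    out <- cbind(out, pairs[, c("hairpin_div", "mature_div", "rate_class")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a library sample sheet
#'
#' TSV columns: `library_id`, `species`, `stage_label`, `time_start`,
#' `time_end`, `replicate_group`.  Symbolic stages (`larva`, `adult`,
#' `adult_male`, `adult_female`) may leave the time fields empty.
#'
#' @param sheet_path Sample sheet TSV path.
#' @return A `mirna_samples` data frame.
#' @export
load_samples <- function(sheet_path) {
  df <- read.delim(sheet_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("library_id", "species", "stage_label", "time_start",
            "time_end", "replicate_group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  mirna_samples(df[, need])
}

#' Construct a validated sample table
#' @param df Data frame with the sample sheet columns.
#' @return A `mirna_samples` data frame.
#' @export
mirna_samples <- function(df) {
  df$library_id <- as.character(df$library_id)
  df$time_start <- suppressWarnings(as.numeric(df$time_start))
  df$time_end <- suppressWarnings(as.numeric(df$time_end))
  if (anyDuplicated(df$library_id))
    stop("duplicate library ids: ",
         paste(unique(df$library_id[duplicated(df$library_id)]),
               collapse = ", "))
  symbolic <- c("larva", "adult", "adult_male", "adult_female")
  num <- !is.na(df$time_start) & !is.na(df$time_end)
  if (any(num & df$time_start >= df$time_end))
    stop("time_start >= time_end for libraries: ",
         paste(df$library_id[num & df$time_start >= df$time_end],
               collapse = ", "))
  if (any(!num & !df$stage_label %in% symbolic))
    stop("non-symbolic stage without a numeric time window: ",
         paste(df$library_id[!num & !df$stage_label %in% symbolic],
               collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("mirna_samples", "data.frame"))
}

#' Write a sample sheet
#' @param samples A `mirna_samples` data frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write expression matrices as TSV
#'
#' The TSV carries the unit in a `# unit:` comment line above the header.
#'
#' @param x A `mir_expr` matrix.
#' @param path TSV path.
#' @param species Optional species tag to re-attach on read.
#' @return `write_count_matrix` the path (invisibly); `read_count_matrix`
#'   a `mir_expr` matrix.
#' @export
write_count_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", expr_unit(x)), con)
  df <- data.frame(row_id = rownames(x),
                   format(unclass(x), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("row_id", colnames(x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, species = NULL) {
  first <- readLines(path, n = 1L)
  unit <- if (grepl("^# unit:", first))
    trimws(sub("^# unit:", "", first)) else "raw_fractional_count"
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, unit = unit, species = species)
}
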