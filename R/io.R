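# Readers and writers for the formats the pipeline touches. One coordinate
# convention internally (0-based half-open); GTF (1-based closed) and BED
# (0-based half-open) are converted exactly once, here.

#' Read transcript annotation
#'
#' @param path File path.
#' @param dialect `"gtf"` (1-based closed, attributes `transcript_id`,
#'   `gene_id`, `gene_biotype`, `tsl`, `mane`) or `"tsv"` (the package's own
#'   tabular dialect, written by [write_annotation()]).
#' @return Tibble of transcript models (0-based half-open coordinates; the
#'   TSS is `start` on the + strand and `end - 1` on the - strand).
#' @export
read_annotation <- function(path, dialect = c("gtf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tx <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
    assert_columns(tx, c("transcript_id", "gene_id", "group_id", "chrom",
                         "start", "end", "tss", "strand", "biotype",
                         "high_confidence"), "annotation TSV")
    return(tx)
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- stringr::str_split_fixed(lines, "\t", 9)
  bad <- which(apply(fields[, 1:8, drop = FALSE] == "", 1, any))
  assert_that(length(bad) == 0,
              sprintf("malformed GTF record at line %d", bad[1]))
  attr_of <- function(key) {
    m <- stringr::str_match(fields[, 9],
                            paste0(key, ' "([^"]*)"'))[, 2]
    m
  }
  tx_id <- attr_of("transcript_id")
  assert_that(!anyNA(tx_id), "GTF record without transcript_id")
  start1 <- as.integer(fields[, 4])
  end1 <- as.integer(fields[, 5])
  assert_that(!anyNA(start1) && !anyNA(end1) && all(start1 <= end1),
              "GTF has non-numeric or inverted coordinates")
  strand <- fields[, 7]
  assert_that(all(strand %in% c("+", "-")), "GTF strand must be + or -")
  tsl <- suppressWarnings(as.integer(attr_of("tsl")))
  mane <- attr_of("mane") %in% c("TRUE", "true", "1")
  tibble::tibble(
    transcript_id = tx_id,
    gene_id = attr_of("gene_id"),
    group_id = tx_id,
    chrom = fields[, 1],
    start = start1 - 1L, end = end1,
    tss = ifelse(strand == "+", start1 - 1L, end1 - 1L),
    strand = strand,
    biotype = attr_of("gene_biotype"),
    high_confidence = mane | (!is.na(tsl) & tsl <= 2)
  )
}

#' Write transcript annotation
#'
#' @param transcripts Transcript models tibble.
#' @param path Output path.
#' @param dialect `"gtf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path, dialect = c("gtf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    readr::write_tsv(transcripts, path, na = "NA")
    return(invisible(path))
  }
  attrs <- sprintf(
    'transcript_id "%s"; gene_id "%s"; gene_biotype "%s"; tsl "%s"; mane "%s";',
    transcripts$transcript_id, transcripts$gene_id, transcripts$biotype,
    ifelse(transcripts$high_confidence, "1", "5"),
    ifelse(transcripts$high_confidence, "TRUE", "FALSE")
  )
  lines <- paste(transcripts$chrom, "ifnkit", "transcript",
                 transcripts$start + 1L, transcripts$end, ".",
                 transcripts$strand, ".", attrs, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED file of regulatory elements
#'
#' BED3+name; 0-based half-open, kept as is.
#'
#' @param path File path.
#' @return Tibble `element_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  assert_that(ncol(bed) >= 3, "BED needs at least 3 columns")
  start <- as.integer(bed[[2]])
  end <- as.integer(bed[[3]])
  assert_that(!anyNA(start) && !anyNA(end) && all(start < end),
              "BED has non-numeric or inverted coordinates")
  tibble::tibble(
    element_id = if (ncol(bed) >= 4) as.character(bed[[4]]) else
      sprintf("el_%05d", seq_len(nrow(bed))),
    chrom = as.character(bed[[1]]), start = start, end = end
  )
}

#' Write elements or promoters as BED
#'
#' Elements are written as BED4; promoter tibbles (with a `transcript_ids`
#' list column) as BED6 with comma-joined transcript ids as the name, score 0
#' and strand ".".
#'
#' @param regions Tibble with `chrom`, `start`, `end` and either `element_id`
#'   or `transcript_ids`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if ("transcript_ids" %in% names(regions)) {
    name <- vapply(regions$transcript_ids, paste, character(1),
                   collapse = ",")
    lines <- paste(regions$chrom, regions$start, regions$end, name, 0, ".",
                   sep = "\t")
  } else {
    lines <- paste(regions$chrom, regions$start, regions$end,
                   regions$element_id, sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as an uppercase
#' named character vector restricted to A/C/G/T/N.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  assert_dna(seqs, "FASTA")
  seqs
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a JASPAR-style PFM text file
#'
#' Records look like `>ID name` followed by four rows `A [ 3 1 0 ]` (brackets
#' optional), in A/C/G/T order.
#'
#' @param path File path.
#' @return Named list of 4 x W count matrices (rows A/C/G/T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  assert_that(length(starts) >= 1, "no PFM records found")
  pwms <- list()
  for (s in starts) {
    id <- stringr::str_split(sub("^>", "", lines[[s]]), "\\s+")[[1]][1]
    assert_that(s + 4 <= length(lines),
                sprintf("truncated PFM record %s", id))
    rows <- lines[s + 1:4]
    bases <- substr(trimws(rows), 1, 1)
    assert_that(identical(bases, c("A", "C", "G", "T")),
                sprintf("PFM record %s must have rows A, C, G, T", id))
    counts <- lapply(rows, function(r) {
      nums <- stringr::str_extract_all(r, "[0-9.]+")[[1]]
      assert_that(length(nums) >= 1,
                  sprintf("malformed PFM row in record %s", id))
      as.numeric(nums)
    })
    assert_that(length(unique(lengths(counts))) == 1,
                sprintf("ragged PFM rows in record %s", id))
    mat <- do.call(rbind, counts)
    rownames(mat) <- bases
    assert_that(!(id %in% names(pwms)), sprintf("duplicate PFM id %s", id))
    pwms[[id]] <- mat
  }
  pwms
}

#' @rdname read_jaspar_pfm
#' @param pwms Named list of 4 x W count matrices.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  lines <- unlist(lapply(names(pwms), function(id) {
    m <- pwms[[id]]
    c(sprintf(">%s %s", id, id),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " "))
      }, character(1)))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a PWM cluster map
#'
#' @param path TSV with columns `pwm_id`, `cluster_id`.
#' @return Tibble `pwm_id`, `cluster_id`.
#' @export
read_cluster_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(x, c("pwm_id", "cluster_id"), "cluster map")
  assert_that(!anyDuplicated(x$pwm_id), "duplicate pwm_id in cluster map")
  x
}

#' @rdname read_cluster_map
#' @param clusters Tibble `pwm_id`, `cluster_id`.
#' @export
write_cluster_map <- function(clusters, path) {
  readr::write_tsv(clusters, path)
  invisible(path)
}

#' Read / write a single-cell count matrix (MatrixMarket trio)
#'
#' The matrix is genes x cells; `features.tsv` and `barcodes.tsv` carry the
#' row/column names and `cells.tsv` the cell metadata (`barcode`,
#' `cell_type`, `treatment`).
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   and `cells.tsv`.
#' @return List with `counts` (`dgCMatrix`) and `cells` (tibble).
#' @export
read_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = "feature_id",
                              show_col_types = FALSE)
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "barcode", show_col_types = FALSE)
  assert_that(nrow(features) == nrow(counts) &&
                nrow(barcodes) == ncol(counts),
              "MTX dimensions disagree with features/barcodes files")
  assert_that(!anyDuplicated(features$feature_id) &&
                !anyDuplicated(barcodes$barcode),
              "duplicate feature or barcode ids")
  dimnames(counts) <- list(features$feature_id, barcodes$barcode)
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path)) {
    x <- readr::read_tsv(cells_path, show_col_types = FALSE)
    assert_columns(x, c("barcode", "cell_type", "treatment"), "cells.tsv")
    assert_that(setequal(x$barcode, barcodes$barcode),
                "cells.tsv barcodes disagree with barcodes.tsv")
    x
  } else NULL
  list(counts = counts, cells = cells)
}

#' @rdname read_mtx
#' @param counts Genes x cells matrix.
#' @param cells Cell metadata tibble (`barcode`, `cell_type`, `treatment`).
#' @export
write_mtx <- function(counts, cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "features.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "barcodes.tsv"))
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a differential-expression or abundance TSV
#'
#' @param path File path.
#' @param required Columns that must be present.
#' @return Tibble.
#' @export
read_tsv_table <- function(path, required = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  if (!is.null(required)) assert_columns(x, required, basename(path))
  x
}
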