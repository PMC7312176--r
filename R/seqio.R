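#' Construct a sequence dataset
#'
#' A lightweight container pairing a named vector of DNA sequences with an
#' optional id-to-class label assignment.
#'
#' @param records Named character vector: record id -> uppercase DNA string.
#' @param labels Optional named character vector: record id -> class label.
#'   Every labeled id must exist among the records.
#' @return An object of class `pcnv_dataset`.
#' @export
pcnv_dataset <- function(records, labels = NULL) {
  ids <- names(records)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    abort_input("all records must have a nonempty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    abort_input("duplicate record ids: %s", paste(dup, collapse = ", "))
  if (any(nchar(records) == 0L))
    abort_input("empty sequence for record '%s'", ids[nchar(records) == 0L][1L])
  if (!is.null(labels)) {
    missing <- setdiff(names(labels), ids)
    if (length(missing) > 0L)
      abort_input("labeled ids absent from records: %s",
                  paste(missing, collapse = ", "))
  }
  structure(list(records = records, labels = labels), class = "pcnv_dataset")
}

#' @export
print.pcnv_dataset <- function(x, ...) {
  cat(sprintf("pcnv_dataset: %d sequences (lengths %d-%d)%s\n",
              length(x$records),
              min(nchar(x$records)), max(nchar(x$records)),
              if (is.null(x$labels)) ""
              else sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' Read a FASTA file into a dataset
#'
#' Accepts plain or gzip-compressed FASTA. The record id is the first
#' whitespace-delimited token of each header; wrapped sequence lines are
#' concatenated; sequences are uppercased.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A [pcnv_dataset] (without labels).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_input("cannot read FASTA '%s': %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0L) abort_input("no FASTA records in '%s'", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty) > 0L)
    abort_input("empty sequence for record '%s' in '%s'", empty[1L], path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    abort_input("duplicate record ids in '%s': %s", path,
                paste(dup, collapse = ", "))
  pcnv_dataset(seqs)
}

#' Write a dataset to FASTA
#'
#' @param dataset A [pcnv_dataset].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(dataset, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(dataset$records)) {
    s <- dataset$records[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts, starts + width - 1L)), con)
  }
  invisible(path)
}

# Guess the delimiter of a two-column table line: tab wins over comma.
detect_sep <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a two-column id/label table
#'
#' Tab- or comma-delimited, autodetected from the first data line. A header
#' line is skipped when its first field is one of `id`, `seqid`, `record`,
#' `name` (case-insensitive).
#'
#' @param path Path to the label table.
#' @return Named character vector: record id -> class label.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) abort_input("empty label file: %s", path)
  sep <- detect_sep(lines[keep[1L]])
  fields <- strsplit(lines[keep], sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad) > 0L)
    abort_input("line %d of '%s' has %d fields (expected 2)",
                keep[bad[1L]], path, nf[bad[1L]])
  tab <- do.call(rbind, fields)
  tab <- apply(tab, 2L, trimws)
  if (!is.matrix(tab)) tab <- matrix(tab, ncol = 2L)
  if (tolower(tab[1L, 1L]) %in% c("id", "seqid", "record", "name"))
    tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) abort_input("label file '%s' has no data rows", path)
  dup <- unique(tab[, 1L][duplicated(tab[, 1L])])
  if (length(dup) > 0L)
    abort_input("duplicate ids in label file '%s': %s", path,
                paste(dup, collapse = ", "))
  stats::setNames(tab[, 2L], tab[, 1L])
}

# Full-precision decimal formatting that round-trips through as.numeric.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  # prefer the shortest representation that still round-trips
  for (d in 1:16) {
    cand <- sprintf("%.*g", d, x)
    ok <- as.numeric(cand) == x
    out[ok & !is.na(ok)] <- cand[ok & !is.na(ok)]
  }
  out
}

#' Write a table of PCNVs
#'
#' One row per sequence: id, sequence length N, then the 18 components under
#' the fixed headers of [pcnv_components()]. Numbers are written with enough
#' digits to round-trip bit-exactly.
#'
#' @param vectors Numeric matrix from [compute_pcnv_matrix()] (rownames =
#'   ids), or a list of vectors from [compute_pcnv()].
#' @param path Output path.
#' @param lengths Optional named integer vector of sequence lengths; taken
#'   from `source_length` attributes when `vectors` is a list.
#' @param sep Field delimiter (default tab).
#' @return Invisibly, `path`.
#' @export
write_vectors <- function(vectors, path, lengths = NULL, sep = "\t") {
  if (is.list(vectors)) {
    ids <- vapply(vectors, function(v) {
      id <- attr(v, "source_id")
      if (is.null(id)) abort_input("vector without source_id") else id
    }, character(1L))
    lengths <- vapply(vectors, function(v) as.integer(attr(v, "source_length")),
                      integer(1L))
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
    rownames(vectors) <- ids
    colnames(vectors) <- pcnv_components()
  }
  if (is.null(dim(vectors)) || ncol(vectors) != 18L || nrow(vectors) < 1L)
    abort_input("expected a nonempty matrix with 18 columns")
  if (is.null(lengths)) lengths <- rowSums(vectors[, 1:4, drop = FALSE])
  body <- cbind(rownames(vectors), format_num(lengths),
                matrix(format_num(vectors), nrow = nrow(vectors)))
  header <- c("id", "N", pcnv_components())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(body, 1L, paste, collapse = sep), con)
  invisible(path)
}

#' Read a PCNV table written by [write_vectors()]
#'
#' @param path Path to the table.
#' @param sep Field delimiter.
#' @return Numeric matrix (rownames = ids, 18 named columns) with attribute
#'   `lengths`.
#' @export
read_vectors <- function(path, sep = "\t") {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "N", pcnv_components())
  if (!all(need %in% colnames(tab)))
    abort_input("'%s' is not a PCNV table (missing columns: %s)", path,
                paste(setdiff(need, colnames(tab)), collapse = ", "))
  mat <- as.matrix(tab[, pcnv_components(), drop = FALSE])
  rownames(mat) <- tab$id
  attr(mat, "lengths") <- stats::setNames(tab$N, tab$id)
  mat
}

#' Write a PHYLIP square distance matrix
#'
#' First line is the taxon count; each following line is a label and its full
#' row of distances. By default labels are written at full length (relaxed
#' dialect); `strict_phylip = TRUE` pads/truncates labels to the classic 10
#' characters.
#'
#' @param d Symmetric numeric matrix with identical row/column names.
#' @param path Output path.
#' @param strict_phylip Enforce 10-character labels.
#' @return Invisibly, `path`.
#' @export
write_distmat <- function(d, path, strict_phylip = FALSE) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels))
    abort_input("distance matrix labels must be present and unique")
  if (strict_phylip) labels <- sprintf("%-10s", substr(labels, 1L, 10L))
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(labels[i], format_num(d[i, ])), collapse = "  ")
  }, character(1L))
  writeLines(c(sprintf("%5d", nrow(d)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to the matrix file.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_distmat <- function(path) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || length(lines) != n + 1L)
    abort_input("'%s' is not a PHYLIP square distance matrix", path)
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(parts, `[`, character(1L), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}
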