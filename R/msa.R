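# Multiple sequence alignment container and coordinate maps, plus readers and
# writers for aligned FASTA, Clustal .aln, and the PHYLIP square matrix format.

#' Construct a multiple sequence alignment
#'
#' @param rows Named character vector (or named list) of equal-length gapped
#'   sequences; gap character is `-`.
#' @return An object of class `msa`: a named character vector with attribute
#'   `width`.
#' @export
msa <- function(rows) {
  rows <- unlist(rows)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("msa rows must be named")
  if (anyDuplicated(names(rows)))
    stop("duplicate msa row id: ", names(rows)[duplicated(names(rows))][1])
  rows[] <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("msa rows have unequal lengths: ", paste(w, collapse = ", "))
  if (w == 0L) stop("msa has zero columns")
  m <- do.call(rbind, strsplit(unname(rows), ""))
  if (any(colSums(m != "-") == 0L))
    stop("msa contains an all-gap column")
  structure(rows, width = w, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x), " sequences x ", attr(x, "width"), " columns\n",
      sep = "")
  invisible(x)
}

#' Number of columns in an alignment
#' @param x An `msa`.
#' @return Integer column count.
#' @export
msa_width <- function(x) attr(x, "width")

#' Remove gaps from one alignment row
#' @param x An `msa`.
#' @param id Row id.
#' @return Ungapped sequence string.
#' @export
degap <- function(x, id) {
  if (!id %in% names(x)) stop("no such row: ", id)
  gsub("-", "", x[[id]], fixed = TRUE)
}

#' Map residue positions of a row to alignment columns
#'
#' @param x An `msa`.
#' @param id Row id.
#' @return Integer vector `v` with `v[k]` = alignment column (1-based) holding
#'   the k-th residue (1-based, ungapped) of row `id`.
#' @export
residue_to_column <- function(x, id) {
  if (!id %in% names(x)) stop("no such row: ", id)
  which(strsplit(x[[id]], "")[[1]] != "-")
}

#' Map alignment columns to residue positions of a row
#'
#' @param x An `msa`.
#' @param id Row id.
#' @return Integer vector `v` of length `msa_width(x)`; `v[c]` is the 1-based
#'   ungapped residue position of row `id` at column `c`, or `NA` where the
#'   row has a gap.
#' @export
column_to_residue <- function(x, id) {
  chars <- strsplit(x[[id]], "")[[1]]
  out <- cumsum(chars != "-")
  out[chars == "-"] <- NA_integer_
  out
}

#' Character matrix view of an alignment
#' @param x An `msa`.
#' @param ... Unused.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @method as.matrix msa
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(unclass(x)), ""))
  rownames(m) <- names(x)
  m
}

#' Read an alignment from aligned FASTA
#' @param path Path to an aligned FASTA file (rows padded with `-`).
#' @return An `msa`.
#' @export
read_msa_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  msa(setNames(as.character(set), ids))
}

#' Write an alignment to aligned FASTA
#' @param x An `msa`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(x, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    body <- x[[id]]
    starts <- seq(1L, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1L, nchar(body))),
               con)
  }
  invisible(path)
}

#' Read a Clustal `.aln` alignment
#'
#' Accepts the interleaved CLUSTAL format: a header line containing
#' `CLUSTAL`, then blocks of `id  segment` lines separated by blank lines;
#' conservation lines (only `* : .` and spaces) are ignored.
#'
#' @param path Path to a `.aln` file.
#' @return An `msa`, rows in first-block order.
#' @export
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a CLUSTAL alignment: ", path)
  lines <- lines[-1]
  segs <- list()
  order_ids <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^[\\s*:.]+$", ln, perl = TRUE)) next  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.-]+)", ln))[[1]]
    if (length(m) < 3L) next
    id <- m[2]
    seg <- gsub(".", "-", m[3], fixed = TRUE)
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    segs[[id]] <- paste0(segs[[id]] %||% "", seg)
  }
  if (!length(order_ids)) stop("no sequence lines in ", path)
  msa(setNames(unlist(segs[order_ids]), order_ids))
}

#' Write a Clustal `.aln` alignment
#' @param x An `msa`.
#' @param path Output path.
#' @param block Block width.
#' @return `path`, invisibly.
#' @export
write_clustal <- function(x, path, block = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W multiple sequence alignment", con)
  writeLines("", con)
  w <- msa_width(x)
  name_w <- max(nchar(names(x))) + 4L
  for (start in seq(1L, w, by = block)) {
    for (id in names(x)) {
      seg <- substr(x[[id]], start, min(start + block - 1L, w))
      writeLines(sprintf("%-*s%s", name_w, id, seg), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# ---- PHYLIP square matrices ------------------------------------------------

#' Write a labeled square matrix in PHYLIP format
#'
#' Names are placed in a 10-character field (truncated or padded as PHYLIP
#' requires).
#'
#' @param m Square numeric matrix with row/col names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    nm <- substr(sprintf("%-10s", rownames(m)[i]), 1, 10)
    writeLines(paste0(nm, paste(sprintf("%10.6f", m[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a PHYLIP square matrix
#' @param path Path to a PHYLIP square (full) matrix file.
#' @return Numeric matrix with dimnames from the 10-character name fields
#'   (trailing whitespace stripped).
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP matrix: ", path)
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ln <- lines[i + 1L]
    labs[i] <- trimws(substr(ln, 1, 10))
    vals <- as.numeric(strsplit(trimws(substr(ln, 11, nchar(ln))), "\\s+")[[1]])
    if (length(vals) != n) stop("row ", i, " of ", path, " has ",
                                length(vals), " values, expected ", n)
    m[i, ] <- vals
  }
  dimnames(m) <- list(labs, labs)
  m
}
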