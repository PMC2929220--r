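# Sequence and structure I/O: FASTA, GenBank CDS extraction, CDS translation,
# PDB structures.  Residue numbering is 1-based inclusive everywhere
# user-facing.

#' Construct a protein sequence record
#'
#' @param id Sequence identifier (unique within a set).
#' @param residues Residue string over the 20-letter amino-acid alphabet
#'   (upper-cased on input). `X` is permitted but flagged via a warning.
#' @param description Free-text description.
#' @param numbering_origin Number of the first residue (default 1).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, description = "",
                             numbering_origin = 1L) {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("protein sequence '", id, "' is empty")
  if (grepl("-", residues, fixed = TRUE))
    stop("protein sequence '", id, "' contains gap characters")
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("protein sequence '", id, "' contains non-amino-acid characters: ",
         paste(unique(bad), collapse = ", "))
  if (grepl("X", residues, fixed = TRUE))
    warning("protein sequence '", id, "' contains ambiguous residue X")
  structure(list(id = id, description = description, residues = residues,
                 numbering_origin = as.integer(numbering_origin)),
            class = "protein_sequence")
}

#' Construct a nucleotide sequence record
#'
#' @inheritParams protein_sequence
#' @param residues Residue string over `{A,C,G,T,N}` (upper-cased on input).
#' @return An object of class `nucleotide_sequence`.
#' @export
nucleotide_sequence <- function(id, residues, description = "") {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("nucleotide sequence '", id, "' is empty")
  bad <- setdiff(strsplit(residues, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("nucleotide sequence '", id, "' contains invalid characters: ",
         paste(unique(bad), collapse = ", "))
  structure(list(id = id, description = description, residues = residues),
            class = "nucleotide_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence>", x$id, paste0("(", nchar(x$residues), " aa)"),
      if (nzchar(x$description)) x$description else "", "\n")
  invisible(x)
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  cat("<nucleotide_sequence>", x$id, paste0("(", nchar(x$residues), " nt)"), "\n")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parses with Biostrings and wraps each record as a [protein_sequence()] or
#' [nucleotide_sequence()]. Record order is preserved; whitespace and line
#' breaks inside sequence bodies are removed. The id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return A named list of sequence records, in file order.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- if (type == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1])
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    res <- as.character(set[[k]])
    out[[k]] <- if (type == "protein") {
      protein_sequence(ids[k], res, descs[k])
    } else {
      nucleotide_sequence(ids[k], res, descs[k])
    }
  }
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param seqs List of `protein_sequence` / `nucleotide_sequence` records.
#' @param path Output path.
#' @param width Line width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    header <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", header), con)
    body <- s$residues
    starts <- seq(1L, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1L, nchar(body))),
               con)
  }
  invisible(path)
}

#' Translate a coding region to protein
#'
#' Standard genetic code; translation starts at `orf_start` (which must be an
#' ATG) and stops at the first in-frame stop codon, which is not included.
#'
#' @param seq A [nucleotide_sequence()].
#' @param orf_start 1-based position of the initiator ATG.
#' @return A [protein_sequence()] with the same id.
#' @export
translate_cds <- function(seq, orf_start = 1L) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  nt <- seq$residues
  if (orf_start < 1L || orf_start + 5L > nchar(nt) + 1L)
    stop("ORF region from position ", orf_start, " is shorter than 6 nt")
  if (substr(nt, orf_start, orf_start + 2L) != "ATG")
    stop("no ATG at position ", orf_start, " of '", seq$id, "'")
  region <- substr(nt, orf_start, nchar(nt))
  region <- substr(region, 1L, 3L * (nchar(region) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(region),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at < 0L)
    stop("no in-frame stop codon from position ", orf_start,
         " of '", seq$id, "' (partial ORF)")
  protein_sequence(seq$id, substr(aa, 1L, stop_at - 1L),
                   description = paste0("translated from ", seq$id,
                                        " ORF at ", orf_start))
}

#' Locate the longest ATG-initiated open reading frame
#'
#' Scans the forward strand in all three frames and returns the start of the
#' longest ORF that begins with ATG and ends at an in-frame stop codon.
#'
#' @param seq A [nucleotide_sequence()].
#' @return 1-based start position of the longest complete ORF.
#' @export
find_longest_orf <- function(seq) {
  stopifnot(inherits(seq, "nucleotide_sequence"))
  nt <- seq$residues
  n <- nchar(nt)
  best_start <- NA_integer_
  best_len <- -1L
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    codons <- substring(nt, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at) && is_atg[k]) open_at <- k
      if (!is.na(open_at) && is_stop[k]) {
        len <- k - open_at # codons before the stop
        if (len > best_len) {
          best_len <- len
          best_start <- starts[open_at]
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.na(best_start)) stop("no complete ATG-initiated ORF in '", seq$id, "'")
  best_start
}

#' Extract the CDS from a GenBank flat file
#'
#' Minimal GenBank parsing: reads the ORIGIN sequence and the first `CDS`
#' feature's location (plain `a..b` or `join(a..b,c..d)` on the forward
#' strand), and returns the spliced coding sequence. Everything else in the
#' record is ignored.
#'
#' @param path Path to a GenBank flat file.
#' @return A [nucleotide_sequence()] holding the CDS (the record LOCUS name
#'   as id).
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else "genbank"
  cds_i <- grep("^\\s{5}CDS\\s", lines)
  if (!length(cds_i)) stop("no CDS feature in ", path)
  loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[cds_i[1]]))
  k <- cds_i[1] + 1L
  while (k <= length(lines) && !grepl("^\\s{21}/", lines[k]) &&
         grepl("^\\s{21}\\S", lines[k]) && !grepl("^\\s{5}\\S", lines[k])) {
    loc <- paste0(loc, trimws(lines[k]))
    k <- k + 1L
  }
  if (grepl("complement", loc))
    stop("complement-strand CDS not supported")
  spans <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1]]
  if (!length(spans)) stop("cannot parse CDS location: ", loc)
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("no ORIGIN section in ", path)
  body <- lines[(origin_i[1] + 1L):length(lines)]
  body <- body[!grepl("^//", body)]
  nt <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  pieces <- vapply(spans, function(sp) {
    ab <- as.integer(strsplit(sp, "..", fixed = TRUE)[[1]])
    substr(nt, ab[1], ab[2])
  }, character(1))
  nucleotide_sequence(id, paste(pieces, collapse = ""),
                      description = paste0("CDS ", loc))
}

# ---- PDB structures --------------------------------------------------------

STANDARD_AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a PDB-format structure
#'
#' Keeps `ATOM` records of standard amino-acid residues only (waters and
#' hetero-compounds excluded). Alternate locations are resolved per atom name
#' within a residue by keeping the highest-occupancy record (ties: first
#' encountered). Author residue numbering and insertion codes are retained.
#'
#' @param path Path to a PDB file.
#' @return An object of class `structure3d`: a list with `id` and `atoms`, a
#'   data frame with columns `chain`, `resnum`, `icode`, `resname`,
#'   `atom_name`, `altloc`, `element`, `occupancy`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^ATOM  ", lines)
  if (!any(sel)) stop("no ATOM records in ", path)
  ln <- lines[sel]
  lineno <- which(sel)
  fw <- function(a, b) trimws(substr(ln, a, b))
  xs <- suppressWarnings(as.numeric(fw(31, 38)))
  ys <- suppressWarnings(as.numeric(fw(39, 46)))
  zs <- suppressWarnings(as.numeric(fw(47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop("malformed coordinate field at line ", lineno[bad[1]], " of ", path)
  occ <- suppressWarnings(as.numeric(fw(55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    chain = substr(ln, 22, 22),
    resnum = as.integer(fw(23, 26)),
    icode = trimws(substr(ln, 27, 27)),
    resname = fw(18, 20),
    atom_name = fw(13, 16),
    altloc = trimws(substr(ln, 17, 17)),
    element = fw(77, 78),
    occupancy = occ,
    x = xs, y = ys, z = zs,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$resname %in% names(STANDARD_AA3), , drop = FALSE]
  if (!nrow(atoms)) stop("no standard-residue ATOM records in ", path)
  # element fallback from atom name (old PDB files leave columns 77-78 blank)
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$atom_name[blank]), 1, 1)
  # resolve altlocs: keep highest occupancy per (chain, resnum, icode, atom_name)
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom_name)
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resnum, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = sub("\\.[^.]*$", "", basename(path)), atoms = atoms),
            class = "structure3d")
}

#' Chains of a structure
#' @param s A `structure3d`.
#' @return Character vector of chain identifiers, in file order.
#' @export
structure_chains <- function(s) unique(s$atoms$chain)

#' One-letter sequence of a structure chain
#'
#' @param s A `structure3d`.
#' @param chain Chain identifier.
#' @return A [protein_sequence()] whose `numbering_origin` is the first author
#'   residue number of the chain (residue numbers are assumed consecutive
#'   within the chain for numbering purposes).
#' @export
structure_chain_sequence <- function(s, chain) {
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("unknown chain '", chain, "'")
  res <- unique(at[, c("resnum", "icode", "resname")])
  res <- res[order(res$resnum, res$icode), , drop = FALSE]
  protein_sequence(paste0(s$id, "_", chain),
                   paste(STANDARD_AA3[res$resname], collapse = ""),
                   description = paste0("chain ", chain),
                   numbering_origin = res$resnum[1])
}
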