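# Receptor-peptide contact detection in a crystal structure and mapping of
# contact positions onto a family alignment with conservation classification.

# ClustalW-style strong similarity groups
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                   "MILV", "MILF", "HY", "FYW")

#' Receptor residues in contact with a ligand chain
#'
#' A receptor residue is a contact when at least one of its heavy atoms lies
#' within `cutoff` of any heavy atom of the ligand chain. Hydrogens are
#' excluded; waters and hetero-compounds were already dropped at parse time.
#'
#' @param s A `structure3d` from [read_structure()].
#' @param receptor_chain,ligand_chain Chain identifiers.
#' @param cutoff Distance cutoff in Angstrom (default 4.0, a common
#'   heavy-atom interface convention).
#' @return Data frame sorted by author residue number with columns `chain`,
#'   `resnum`, `icode`, `resname`, `min_distance`, `n_atom_pairs`.
#' @export
find_contacts <- function(s, receptor_chain, ligand_chain, cutoff = 4.0) {
  stopifnot(inherits(s, "structure3d"), cutoff > 0)
  at <- s$atoms[toupper(s$atoms$element) != "H", , drop = FALSE]
  rec <- at[at$chain == receptor_chain, , drop = FALSE]
  lig <- at[at$chain == ligand_chain, , drop = FALSE]
  if (!nrow(rec)) stop("unknown chain '", receptor_chain, "'")
  if (!nrow(lig)) stop("unknown chain '", ligand_chain, "'")
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(rxyz^2), rep(1, nrow(lxyz))) +
    outer(rep(1, nrow(rxyz)), rowSums(lxyz^2)) - 2 * rxyz %*% t(lxyz)
  d2[d2 < 0] <- 0
  dmin_atom <- sqrt(d2)
  key <- paste(rec$resnum, rec$icode)
  hits <- dmin_atom <= cutoff
  res_keys <- unique(key[rowSums(hits) > 0])
  if (!length(res_keys))
    return(data.frame(chain = character(0), resnum = integer(0),
                      icode = character(0), resname = character(0),
                      min_distance = numeric(0), n_atom_pairs = integer(0)))
  out <- do.call(rbind, lapply(res_keys, function(k) {
    rows <- key == k
    data.frame(chain = receptor_chain,
               resnum = rec$resnum[rows][1],
               icode = rec$icode[rows][1],
               resname = rec$resname[rows][1],
               min_distance = min(dmin_atom[rows, , drop = FALSE]),
               n_atom_pairs = sum(hits[rows, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$resnum, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Auto-detect receptor and ligand chains
#'
#' Convention for receptor-peptide co-crystals: the receptor is the longest
#' protein chain, the ligand peptide the shortest.
#'
#' @param s A `structure3d`.
#' @return List with elements `receptor` and `ligand` (chain ids).
#' @export
auto_chains <- function(s) {
  chains <- structure_chains(s)
  if (length(chains) < 2L) stop("structure has fewer than 2 chains")
  nres <- vapply(chains, function(ch)
    nrow(unique(s$atoms[s$atoms$chain == ch, c("resnum", "icode")])),
    integer(1))
  list(receptor = chains[which.max(nres)], ligand = chains[which.min(nres)])
}

#' Map structure residue positions onto family alignment columns
#'
#' Globally aligns the structure chain sequence to one family member and
#' composes that pairwise alignment with the member's residue-to-column map.
#'
#' @param s_seq [protein_sequence()] of the structure chain (e.g. from
#'   [structure_chain_sequence()]).
#' @param x The family `msa`.
#' @param member_id Family member the structure corresponds to.
#' @param scheme A [scoring_scheme()] for the pairwise alignment.
#' @param min_identity Guard: minimum percent identity between structure and
#'   member sequences (default 50).
#' @return Integer vector of length `nchar(s_seq$residues)`: alignment column
#'   of each structure residue position (1-based in sequence order), `NA`
#'   where the position aligns to a gap in the member.
#' @export
map_structure_to_family <- function(s_seq, x, member_id,
                                    scheme = scoring_scheme(),
                                    min_identity = 50) {
  stopifnot(inherits(s_seq, "protein_sequence"), inherits(x, "msa"))
  if (!member_id %in% names(x)) stop("no such row: ", member_id)
  member <- protein_sequence(member_id, degap(x, member_id))
  aln <- global_align(s_seq, member, scheme)
  pid <- percent_identity(aln)
  if (pid < min_identity)
    stop("structure/sequence mismatch: ", round(pid, 1),
         "% identity to '", member_id, "' is below the ", min_identity,
         "% guard")
  ca <- strsplit(aln$a_aligned, "")[[1]]
  cb <- strsplit(aln$b_aligned, "")[[1]]
  apos <- cumsum(ca != "-")
  bpos <- cumsum(cb != "-")
  r2c <- residue_to_column(x, member_id)
  out <- rep(NA_integer_, nchar(s_seq$residues))
  both <- ca != "-" & cb != "-"
  out[apos[both]] <- r2c[bpos[both]]
  out
}

#' Corresponding residues across an alignment
#'
#' Given a residue position in one row, reports the residue letter and
#' ungapped position of every row at the alignment column holding that
#' residue (the "R106 in KPNA2 corresponds to ..." query).
#'
#' @param x An `msa`.
#' @param from_id Row the query position refers to.
#' @param from_pos 1-based ungapped residue position in `from_id`.
#' @return Data frame with columns `id`, `residue` (`"-"` for a gap),
#'   `position` (`NA` for a gap), plus the shared `column` as an attribute.
#' @export
correspond <- function(x, from_id, from_pos) {
  stopifnot(inherits(x, "msa"))
  r2c <- residue_to_column(x, from_id)
  if (from_pos < 1L || from_pos > length(r2c))
    stop("position ", from_pos, " out of range 1..", length(r2c),
         " for '", from_id, "'")
  col <- r2c[from_pos]
  m <- as.matrix(x)
  res <- m[, col]
  pos <- vapply(names(x), function(id) column_to_residue(x, id)[col],
                integer(1))
  out <- data.frame(id = names(x), residue = unname(res),
                    position = unname(pos), row.names = NULL)
  attr(out, "column") <- col
  out
}

#' Classify conservation of alignment columns
#'
#' Per column: `identical` when all non-gap residues are the same (and at
#' least one row has a residue); otherwise `gapped` when any row has a gap;
#' otherwise `conserved` when all residues fall into a single strong
#' similarity group; otherwise `different`. Summary counts fold `gapped`
#' into `different`, so `n_identical + n_conserved + n_different = n_total`.
#'
#' @param x An `msa`.
#' @param columns Integer vector of 1-based column indices (non-empty).
#' @param groups Character vector of similarity groups (each a string of
#'   residues); defaults to the ClustalW strong groups.
#' @return List with `records` (data frame `column`, `class`, `residues`) and
#'   `summary` (named counts `n_identical`, `n_conserved`, `n_different`,
#'   `n_total`).
#' @export
classify_conservation <- function(x, columns, groups = STRONG_GROUPS) {
  stopifnot(inherits(x, "msa"))
  if (!length(columns)) stop("empty column list")
  columns <- as.integer(columns)
  if (min(columns) < 1L || max(columns) > msa_width(x))
    stop("column index out of range 1..", msa_width(x))
  m <- as.matrix(x)
  gsets <- strsplit(groups, "")
  classify_one <- function(col) {
    res <- m[, col]
    nr <- res[res != "-"]
    if (length(unique(nr)) == 1L) return("identical")
    if (any(res == "-")) return("gapped")
    if (any(vapply(gsets, function(g) all(nr %in% g), logical(1))))
      return("conserved")
    "different"
  }
  cls <- vapply(columns, classify_one, character(1))
  records <- data.frame(
    column = columns,
    class = cls,
    residues = vapply(columns, function(col) paste(m[, col], collapse = ""),
                      character(1)),
    row.names = NULL)
  summary <- c(n_identical = sum(cls == "identical"),
               n_conserved = sum(cls == "conserved"),
               n_different = sum(cls %in% c("different", "gapped")),
               n_total = length(cls))
  list(records = records, summary = summary)
}

#' Columns where a majority of rows share the modal residue
#'
#' @param x An `msa`.
#' @param threshold Minimum count of the modal residue (gaps excluded).
#' @return Logical vector of length `msa_width(x)`.
#' @export
majority_identity_mask <- function(x, threshold) {
  stopifnot(inherits(x, "msa"), threshold >= 1L, threshold <= length(x))
  m <- as.matrix(x)
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(FALSE)
    max(table(col)) >= threshold
  })
}
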