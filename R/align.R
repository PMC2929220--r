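# Global pairwise alignment (Needleman-Wunsch/Gotoh, affine gaps),
# simplified progressive multiple alignment, and percent identity.

#' Alignment scoring scheme
#'
#' Defaults emulate ClustalW-like protein settings: BLOSUM62, gap opening 10,
#' gap extension 0.5. A gap run of length k costs
#' `gap_open + gap_extend * k`. Exact ClustalW behaviour (Gonnet series,
#' position-specific penalties) is not reproduced.
#'
#' @param submat Symmetric substitution matrix with amino-acid dimnames.
#'   Default: BLOSUM62 restricted to the 20 canonical residues plus `X`.
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative per-residue gap extension penalty.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(submat = NULL, gap_open = 10, gap_extend = 0.5) {
  if (is.null(submat)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    keep <- c(AA20, "X")
    submat <- BLOSUM62[keep, keep]
  }
  stopifnot(is.matrix(submat), nrow(submat) == ncol(submat),
            !is.null(rownames(submat)),
            isTRUE(all.equal(submat, t(submat))),
            gap_open >= 0, gap_extend >= 0)
  structure(list(submat = submat, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

encode_residues <- function(residues, alphabet) {
  codes <- match(strsplit(residues, "")[[1]], alphabet) - 1L
  if (anyNA(codes))
    stop("non-amino-acid character in sequence: ",
         strsplit(residues, "")[[1]][which(is.na(codes))[1]])
  codes
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh dynamic programming; the returned score is the
#' maximum over all global alignments of the pair. Traceback ties are broken
#' deterministically: match/mismatch is preferred over a gap in `a`, which is
#' preferred over a gap in `b`.
#'
#' @param a,b [protein_sequence()] records (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `pairwise_alignment` with fields `a_id`, `b_id`,
#'   `a_aligned`, `b_aligned` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  alphabet <- rownames(scheme$submat)
  ca <- encode_residues(a$residues, alphabet)
  cb <- encode_residues(b$residues, alphabet)
  res <- gotoh_align_cpp(ca, cb, scheme$submat, scheme$gap_open,
                         scheme$gap_extend)
  to_str <- function(codes) {
    out <- rep("-", length(codes))
    out[codes >= 0] <- alphabet[codes[codes >= 0] + 1L]
    paste(out, collapse = "")
  }
  structure(list(a_id = a$id, b_id = b$id,
                 a_aligned = to_str(res$a_aligned),
                 b_aligned = to_str(res$b_aligned),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$a_id, " / ", x$b_id,
      "  score ", format(x$score), "  length ", nchar(x$a_aligned), "\n",
      sep = "")
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' @param aln A `pairwise_alignment`, or any object with `a_aligned` and
#'   `b_aligned` fields (two equal-length gapped strings).
#' @param convention Denominator convention:
#'   * `"aligned_columns"` (default): identical columns / columns where at
#'     least one row has a residue (gap vs residue counts as non-identical);
#'   * `"shorter_seq"`: identical columns / length of the shorter ungapped
#'     sequence;
#'   * `"ungapped_columns"`: identical columns / columns where both rows have
#'     residues.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             convention = c("aligned_columns", "shorter_seq",
                                            "ungapped_columns")) {
  convention <- match.arg(convention)
  ra <- strsplit(aln$a_aligned, "")[[1]]
  rb <- strsplit(aln$b_aligned, "")[[1]]
  stopifnot(length(ra) == length(rb))
  keep <- !(ra == "-" & rb == "-")
  ra <- ra[keep]; rb <- rb[keep]
  ident <- sum(ra == rb & ra != "-")
  denom <- switch(convention,
    aligned_columns = length(ra),
    shorter_seq = min(sum(ra != "-"), sum(rb != "-")),
    ungapped_columns = sum(ra != "-" & rb != "-"))
  if (denom == 0L) stop("zero denominator for convention ", convention)
  100 * ident / denom
}

#' Pairwise percent-identity matrix of an alignment
#'
#' Each pair of rows is projected to the columns where not both are gaps, and
#' [percent_identity()] is applied under the chosen convention.
#'
#' @param x An `msa` with at least two rows.
#' @param convention Passed to [percent_identity()].
#' @return Symmetric numeric matrix (class `identity_matrix`) of percentages,
#'   diagonal 100, dimnames = row ids.
#' @export
identity_matrix <- function(x, convention = "aligned_columns") {
  stopifnot(inherits(x, "msa"), length(x) >= 2L)
  ids <- names(x)
  n <- length(ids)
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- list(a_aligned = x[[ids[i]]], b_aligned = x[[ids[j]]])
      m[i, j] <- m[j, i] <- percent_identity(aln, convention)
    }
  }
  class(m) <- c("identity_matrix", class(m))
  m
}

# frequency profile of a sub-alignment over the scheme's alphabet;
# gaps contribute nothing, so column sums equal the non-gap fraction
msa_profile <- function(rows, alphabet) {
  chars <- do.call(rbind, strsplit(unname(rows), ""))
  prof <- matrix(0, nrow = length(alphabet), ncol = ncol(chars))
  for (k in seq_along(alphabet)) {
    prof[k, ] <- colSums(chars == alphabet[k])
  }
  prof / length(rows)
}

merge_profiles <- function(rows_a, rows_b, scheme) {
  alphabet <- rownames(scheme$submat)
  pa <- msa_profile(rows_a, alphabet)
  pb <- msa_profile(rows_b, alphabet)
  path <- profile_align_cpp(pa, pb, scheme$submat, scheme$gap_open,
                            scheme$gap_extend)
  expand <- function(rows, use) {
    chars <- do.call(rbind, strsplit(unname(rows), ""))
    out <- matrix("-", nrow = nrow(chars), ncol = length(use))
    out[, use == 1L] <- chars
    setNames(apply(out, 1L, paste, collapse = ""), names(rows))
  }
  c(expand(rows_a, path$use_a), expand(rows_b, path$use_b))
}

#' Simplified progressive multiple alignment
#'
#' ClustalW-style strategy without its refinements: all pairwise global
#' alignments give p-distances, a neighbor-joining guide tree is built from
#' them (midpoint-rooted), and sub-alignments are merged by profile-profile
#' affine-gap alignment in guide-tree post-order. Output row order equals
#' input order.
#'
#' @param seqs List of two or more [protein_sequence()] records with unique
#'   ids.
#' @param scheme A [scoring_scheme()].
#' @return An `msa`.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme()) {
  if (length(seqs) < 2L) stop("progressive_align needs at least 2 sequences")
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  names(seqs) <- ids
  if (length(seqs) == 2L) {
    aln <- global_align(seqs[[1]], seqs[[2]], scheme)
    return(msa(setNames(c(aln$a_aligned, aln$b_aligned), ids)))
  }
  n <- length(seqs)
  pd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], scheme)
      pd[i, j] <- pd[j, i] <- p_distance(aln$a_aligned, aln$b_aligned)
    }
  }
  guide <- neighbor_joining(pd, clamp_negative = TRUE)
  guide <- phangorn::midpoint(guide)
  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    if (!length(kids)) {
      id <- guide$tip.label[node]
      return(setNames(seqs[[id]]$residues, id))
    }
    acc <- merge_node(kids[1])
    for (k in kids[-1]) acc <- merge_profiles(acc, merge_node(k), scheme)
    acc
  }
  root <- length(guide$tip.label) + 1L
  rows <- merge_node(root)
  msa(rows[ids])
}
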