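# Domain annotation on a reference sequence, alignment slicing, and
# per-domain divergence from an outgroup (IBB vs ARM-repeat analysis).

#' Domain map on an ungapped reference sequence
#'
#' @param reference_id Id of the reference sequence the coordinates refer to.
#' @param entries Data frame with columns `domain`, `start`, `end` (1-based
#'   inclusive, non-overlapping, unique names).
#' @param reference_length Optional known reference length for validation.
#' @return An object of class `domain_map`.
#' @export
domain_map <- function(reference_id, entries, reference_length = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("domain", "start", "end") %in% names(entries)))
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (anyDuplicated(entries$domain))
    stop("duplicate domain name: ",
         entries$domain[duplicated(entries$domain)][1])
  if (any(entries$start < 1L) || any(entries$start > entries$end))
    stop("invalid domain interval (need 1 <= start <= end)")
  if (!is.null(reference_length) && any(entries$end > reference_length))
    stop("domain interval exceeds reference length ", reference_length)
  o <- order(entries$start)
  e <- entries[o, ]
  if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
    stop("overlapping domain intervals")
  structure(list(reference_id = reference_id,
                 entries = entries[, c("domain", "start", "end")]),
            class = "domain_map")
}

#' Read a domain map from TSV
#'
#' Expected columns: `reference_id`, `domain`, `start`, `end` (tab-separated,
#' with header).
#'
#' @param path Path to the TSV file.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reference_id", "domain", "start", "end")
  if (!all(need %in% names(tab)))
    stop("domain TSV must have columns: ", paste(need, collapse = ", "))
  ref <- unique(tab$reference_id)
  if (length(ref) != 1L) stop("domain TSV must use a single reference_id")
  domain_map(ref, tab[, c("domain", "start", "end")])
}

#' Packaged KPNA2 domain annotation (estimate)
#'
#' IBB and ARM repeat intervals on human KPNA2, estimated from the canonical
#' domain architecture of importin alpha (IBB roughly residues 1-95, ten
#' ~42-residue ARM repeats tiling the body). These boundaries are an
#' estimate, not measured coordinates.
#'
#' @return A [domain_map()] with reference id `"KPNA2"`.
#' @export
kpna2_domain_map <- function() {
  read_domain_map(system.file("extdata", "kpna2_domains.tsv",
                              package = "karyofam", mustWork = TRUE))
}

#' Alignment columns covered by a domain
#'
#' Columns spanned by the domain interval on the (ungapped) reference row:
#' from the column holding residue `start` to the column holding residue
#' `end`, inclusive. Reference-gap columns inside that span belong to the
#' domain and are included.
#'
#' @param x An `msa` containing the reference row.
#' @param dmap A [domain_map()].
#' @param name Domain name(s); several names give the union of their columns.
#' @return Sorted integer vector of 1-based column indices.
#' @export
domain_columns <- function(x, dmap, name) {
  stopifnot(inherits(x, "msa"), inherits(dmap, "domain_map"))
  if (!dmap$reference_id %in% names(x))
    stop("reference row '", dmap$reference_id, "' not in alignment")
  r2c <- residue_to_column(x, dmap$reference_id)
  cols <- integer(0)
  for (nm in name) {
    e <- dmap$entries[dmap$entries$domain == nm, ]
    if (!nrow(e)) stop("no such domain: ", nm)
    if (e$end > length(r2c))
      stop("domain '", nm, "' exceeds reference length ", length(r2c))
    cols <- c(cols, seq(r2c[e$start], r2c[e$end]))
  }
  sort(unique(cols))
}

#' Restrict an alignment to a set of columns
#'
#' @param x An `msa`.
#' @param columns Integer vector of 1-based column indices (non-empty).
#' @return An `msa` over the selected columns, row order preserved. Rows left
#'   all-gap by the slice are kept but flagged with a warning.
#' @export
slice_msa <- function(x, columns) {
  stopifnot(inherits(x, "msa"))
  columns <- sort(unique(as.integer(columns)))
  if (!length(columns)) stop("empty column set")
  if (min(columns) < 1L || max(columns) > msa_width(x))
    stop("column index out of range 1..", msa_width(x))
  m <- as.matrix(x)[, columns, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  allgap <- !grepl("[^-]", rows)
  if (any(allgap))
    warning("all-gap row(s) after slicing: ",
            paste(names(x)[allgap], collapse = ", "))
  msa(setNames(rows, names(x)))
}

#' Per-domain divergence from an outgroup
#'
#' For each requested domain the alignment is sliced to the domain columns,
#' an ML distance matrix is computed, a neighbor-joining tree is built and
#' rooted at the outgroup, and each taxon's divergence is the branch-length
#' path from the outgroup to that taxon on the domain tree.
#'
#' @param x An `msa` containing the outgroup row.
#' @param dmap A [domain_map()] on a reference row of `x`.
#' @param domains List of domain selections; each element is a domain name or
#'   a character vector of names (union of their columns), and list names
#'   label the output rows (defaults to the collapsed domain names).
#' @param model A [substitution_model()].
#' @param outgroup Outgroup row id (e.g. the yeast importin alpha SRP1).
#' @param clamp_negative Clamp negative NJ branch lengths to 0 (default
#'   `TRUE`, so divergences are non-negative).
#' @return Data frame with columns `taxon`, `domain`, `divergence`.
#' @export
domain_divergence <- function(x, dmap, domains,
                              model = substitution_model("jtt"),
                              outgroup, clamp_negative = TRUE) {
  stopifnot(inherits(x, "msa"))
  if (!outgroup %in% names(x)) stop("outgroup '", outgroup, "' not in alignment")
  if (is.null(names(domains)))
    names(domains) <- vapply(domains, paste, character(1), collapse = "+")
  out <- list()
  for (dn in names(domains)) {
    cols <- domain_columns(x, dmap, domains[[dn]])
    sub <- slice_msa(x, cols)
    ncomp <- min(vapply(seq_along(sub), function(i)
      sum(strsplit(sub[[i]], "")[[1]] %in% AA20), integer(1)))
    if (ncomp < 10L)
      stop("domain '", dn, "' yields fewer than 10 comparable columns")
    dm <- tryCatch(distance_matrix(sub, model), error = function(e)
      stop("domain '", dn, "': ", conditionMessage(e), call. = FALSE))
    tr <- root_at(neighbor_joining(dm, clamp_negative = clamp_negative),
                  outgroup)
    taxa <- setdiff(names(x), outgroup)
    out[[dn]] <- data.frame(
      taxon = taxa,
      domain = dn,
      divergence = vapply(taxa, function(tx) path_length(tr, outgroup, tx),
                          numeric(1)),
      row.names = NULL)
  }
  do.call(rbind, out)
}
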