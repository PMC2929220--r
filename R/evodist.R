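# Pairwise evolutionary distances between aligned protein rows:
# p-distance and maximum-likelihood distances under a substitution model.

#' Proportion of differing residues between two aligned rows
#'
#' Gaps (and ambiguous residues) are excluded pairwise: only columns where
#' both rows carry a canonical residue are compared.
#'
#' @param row_a,row_b Equal-length gapped sequence strings.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(row_a, row_b) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  keep <- ca %in% AA20 & cb %in% AA20
  if (!any(keep)) stop("no comparable (both-residue) column")
  sum(ca[keep] != cb[keep]) / sum(keep)
}

pair_counts <- function(row_a, row_b) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  keep <- ca %in% AA20 & cb %in% AA20
  if (!any(keep)) stop("no comparable (both-residue) column")
  table(factor(ca[keep], levels = AA20), factor(cb[keep], levels = AA20))
}

#' Maximum-likelihood evolutionary distance between two aligned rows
#'
#' For empirical models the distance `d` maximises the reversible-pair
#' likelihood `sum over columns of log(pi[x] * P(d)[x, y])`, solved by
#' bracketed one-dimensional optimisation on `d` in `[1e-6, 10]`. For the
#' Poisson model the classical Poisson-correction closed form
#' `d = -log(1 - p)` is returned exactly.
#'
#' @param row_a,row_b Equal-length gapped sequence strings.
#' @param model A [substitution_model()].
#' @return Distance in expected substitutions per site.
#' @export
ml_distance <- function(row_a, row_b, model = substitution_model("jtt")) {
  stopifnot(inherits(model, "substitution_model"))
  p <- p_distance(row_a, row_b)
  if (p == 0) return(0)
  if (model$name == "poisson") {
    if (p >= 1) stop("distance saturated (p-distance = 1 under poisson model)")
    return(-log(1 - p))
  }
  N <- pair_counts(row_a, row_b)
  nz <- which(N > 0, arr.ind = TRUE)
  counts <- N[nz]
  lpi <- log(model$pi)[nz[, 1]]
  negll <- function(d) {
    P <- transition_matrix(model, d)
    -sum(counts * (lpi + log(P[nz])))
  }
  opt <- optimize(negll, interval = c(1e-6, 10), tol = 1e-10)
  d <- opt$minimum
  if (d >= 10 - 1e-3)
    stop("distance saturated (ML estimate at upper bound under ",
         model$name, " model)")
  d
}

#' Pairwise ML distance matrix of an alignment
#'
#' @param x An `msa` with at least two rows.
#' @param model A [substitution_model()].
#' @return Symmetric numeric matrix (substitutions/site), zero diagonal,
#'   dimnames = row ids.
#' @export
distance_matrix <- function(x, model = substitution_model("jtt")) {
  stopifnot(inherits(x, "msa"), length(x) >= 2L)
  ids <- names(x)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(ml_distance(x[[ids[i]]], x[[ids[j]]], model),
                    error = function(e) {
                      stop("pair (", ids[i], ", ", ids[j], "): ",
                           conditionMessage(e), call. = FALSE)
                    })
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}
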