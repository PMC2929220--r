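# Neighbor-joining trees, outgroup rooting, path-length queries, and
# reference-guided subfamily classification. Trees are ape "phylo" objects;
# Newick I/O goes through ape.

fmt_len <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion
#' (`Q_ij = (n-2) d_ij - r_i - r_j`). Ties in pair selection are broken
#' deterministically by the lexicographically lowest label pair, where a
#' merged node carries the lexicographically smaller label of its children.
#' For an additive matrix the tree's path metric reproduces the input
#' exactly. Negative branch lengths are kept by default (PHYLIP behaviour).
#'
#' @param D Symmetric distance matrix with dimnames; at least 3 taxa.
#' @param clamp_negative If `TRUE`, negative branch lengths are set to 0.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must have dimnames")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  cl <- function(x) if (clamp_negative) max(x, 0) else x
  # active nodes: newick fragment + tie-break label
  frag <- labs
  tielab <- labs
  d <- D
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      la <- tielab[cand[k, 1]]; lb <- tielab[cand[k, 2]]
      paste(min(la, lb), max(la, lb), sep = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- cl(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2)))
    vj <- cl(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt_len(vi), ",",
                      frag[j], ":", fmt_len(vj), ")")
    newlab <- min(tielab[i], tielab[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    tielab <- c(tielab[keep], newlab)
    d <- d2
  }
  # final three nodes joined at the central vertex (three-point formulas)
  va <- cl(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  vb <- cl(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  vc <- cl(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  nwk <- paste0("(", frag[1], ":", fmt_len(va), ",",
                frag[2], ":", fmt_len(vb), ",",
                frag[3], ":", fmt_len(vc), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on the pendant edge of an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge, so all
#' leaf-to-leaf path lengths are preserved and rooting is idempotent on the
#' path metric.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup_leaf Tip label to root on.
#' @return A rooted `ape::phylo` tree.
#' @export
root_at <- function(tree, outgroup_leaf) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup_leaf, tree$tip.label)
  if (is.na(tip)) stop("unknown leaf: ", outgroup_leaf)
  pend <- which(tree$edge[, 2] == tip)
  L <- tree$edge.length[pend]
  rooted <- ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
  rooted <- ape::reorder.phylo(rooted, "cladewise")
  root_node <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) != 2L) stop("rooting failed to produce a binary root")
  # redistribute the original pendant length half-and-half across the root
  tip2 <- match(outgroup_leaf, rooted$tip.label)
  og_edge <- kids[rooted$edge[kids, 2] == tip2]
  other <- setdiff(kids, og_edge)
  extra <- sum(rooted$edge.length[kids]) - L
  rooted$edge.length[og_edge] <- L / 2
  rooted$edge.length[other] <- L / 2 + extra
  rooted
}

#' Path length between two leaves
#'
#' Sum of branch lengths on the unique path between two tips.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param a,b Tip labels.
#' @return Path length in branch-length units; `path_length(t, x, x)` is 0.
#' @export
path_length <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown leaf: ", a)
  if (is.na(ib)) stop("unknown leaf: ", b)
  if (ia == ib) return(0)
  dm <- ape::dist.nodes(tree)
  dm[ia, ib]
}

#' All leaf-to-leaf path lengths
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
leaf_path_matrix <- function(tree) {
  n <- length(tree$tip.label)
  dm <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(dm) <- list(tree$tip.label, tree$tip.label)
  dm
}

#' Classify leaves into subfamilies by reference taxa
#'
#' Each non-reference leaf receives the label of the reference with which it
#' shares the smallest containing clade (most recent common ancestor),
#' excluding the root. If the smallest such clade is the root, or two
#' references with different labels tie at the same clade, the leaf is
#' `"unassigned"`. Reference leaves map to their own declared label.
#'
#' @param tree A rooted `ape::phylo` tree (root at the outgroup).
#' @param references Named character vector: names are reference tip labels,
#'   values their subfamily labels (e.g. `c(FlyA1 = "alpha1", ...)`).
#' @return Named character vector: tip label -> subfamily label.
#' @export
classify_subfamilies <- function(tree, references) {
  stopifnot(inherits(tree, "phylo"), length(references) >= 1L)
  miss <- setdiff(names(references), tree$tip.label)
  if (length(miss)) stop("reference leaf not in tree: ", miss[1])
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # clade size per internal node
  clade_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], clade_tips))
  }
  out <- setNames(rep("unassigned", ntip), tree$tip.label)
  out[names(references)] <- references
  for (leaf in setdiff(tree$tip.label, names(references))) {
    mrcas <- vapply(names(references), function(r) {
      ape::getMRCA(tree, c(leaf, r))
    }, integer(1))
    sizes <- vapply(mrcas, function(nd) length(clade_tips(nd)), integer(1))
    sizes[mrcas == root] <- NA_integer_
    if (all(is.na(sizes))) next
    best <- which(sizes == min(sizes, na.rm = TRUE))
    labs <- unique(unname(references[names(best)]))
    if (length(labs) == 1L) out[leaf] <- labs
  }
  out
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  tr
}

#' Write a Newick tree
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}
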