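# Shared fixtures: random sequences, random trees, a toy two-chain PDB file,
# and small independent oracles used across test files.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(id, len) {
  protein_sequence(id, paste(sample(AA, len, replace = TRUE), collapse = ""))
}

# random clock-free tree with uniform branch lengths
random_bl_tree <- function(n, min_bl = 0.05, max_bl = 1) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# independent path-length oracle: all-pairs shortest paths on the tree graph
igraph_path_matrix <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  dm <- igraph::distances(g, v = as.character(seq_len(n)),
                          to = as.character(seq_len(n)))
  dimnames(dm) <- list(tree$tip.label, tree$tip.label)
  dm
}

# minimal PDB writer for synthetic structures: atoms is a data frame with
# chain, resnum, resname, atom_name, element, x, y, z (+ optional altloc,
# occupancy)
write_toy_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$atom_name, a$altloc %||% "", a$resname, a$chain, a$resnum,
            a$x, a$y, a$z, a$occupancy %||% 1.0, 0.0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-chain toy complex: chain A = 4-residue receptor with CA+CB, chain B =
# 1-residue ligand placed at a controlled distance from residue 2 of A
toy_complex_pdb <- function(path, sep = 3.5) {
  atoms <- data.frame(
    chain = c(rep("A", 8), "B", "B"),
    resnum = c(rep(1:4, each = 2), 1, 1),
    resname = c(rep(c("ALA", "ARG", "GLY", "LEU"), each = 2), "LYS", "LYS"),
    atom_name = c(rep(c("CA", "CB"), 4), "CA", "NZ"),
    element = c(rep("C", 8), "C", "N"),
    x = c(0, 0.8, 5, 5.8, 10, 10.8, 15, 15.8, 5.8, 5.8),
    y = c(rep(0, 8), sep, sep + 2),
    z = 0,
    stringsAsFactors = FALSE)
  write_toy_pdb(atoms, path)
}

# stated-world simulated family used by several tests (small but non-trivial)
small_family <- function(seed = 11, len = 400, ibb_mult = 3) {
  cfg <- sim_config(kpna_like_tree(), root_length = len,
                    model = substitution_model("jtt"),
                    domain_multipliers = data.frame(
                      domain = "IBB", start = 1, end = max(40, len %/% 6),
                      multiplier = ibb_mult),
                    seed = seed)
  simulate_family(cfg)
}
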