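test_that("contacts are detected at the cutoff with correct min distance", {
  path <- withr::local_tempfile(fileext = ".pdb")
  toy_complex_pdb(path, sep = 3.5)
  s <- read_structure(path)
  hits <- find_contacts(s, "A", "B", cutoff = 4.0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$resnum, 2L)
  expect_equal(hits$min_distance, 3.5, tolerance = 1e-6)
  expect_gte(hits$n_atom_pairs, 1L)
  expect_equal(nrow(find_contacts(s, "A", "B", cutoff = 3.0)), 0L)
  expect_error(find_contacts(s, "Z", "B"), "unknown chain")
})

test_that("contacts equal an all-pairs brute-force scan and grow with cutoff", {
  set.seed(24)
  for (rep in 1:5) {
    nA <- 6; nB <- 3
    atoms <- data.frame(
      chain = rep(c("A", "B"), c(nA * 2, nB)),
      resnum = c(rep(seq_len(nA), each = 2), seq_len(nB)),
      resname = "ALA",
      atom_name = c(rep(c("CA", "CB"), nA), rep("CA", nB)),
      element = "C",
      x = runif(nA * 2 + nB, 0, 15), y = runif(nA * 2 + nB, 0, 15),
      z = runif(nA * 2 + nB, 0, 15), stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".pdb")
    write_toy_pdb(atoms, path)
    s <- read_structure(path)
    prev <- integer(0)
    for (cutoff in c(3, 5, 8, 12)) {
      hits <- find_contacts(s, "A", "B", cutoff)
      # brute-force oracle: nested loop over atom pairs
      at <- s$atoms
      recs <- at[at$chain == "A", ]; ligs <- at[at$chain == "B", ]
      expected <- sort(unique(unlist(lapply(seq_len(nrow(recs)), function(i) {
        for (j in seq_len(nrow(ligs))) {
          d <- sqrt((recs$x[i] - ligs$x[j])^2 + (recs$y[i] - ligs$y[j])^2 +
                      (recs$z[i] - ligs$z[j])^2)
          if (d <= cutoff) return(recs$resnum[i])
        }
        NULL
      }))))
      expect_equal(hits$resnum, as.integer(expected %||% integer(0)))
      expect_true(all(prev %in% hits$resnum))  # monotone in cutoff
      prev <- hits$resnum
    }
  }
})

test_that("auto chain detection picks longest receptor, shortest ligand", {
  path <- withr::local_tempfile(fileext = ".pdb")
  toy_complex_pdb(path)
  s <- read_structure(path)
  expect_equal(auto_chains(s), list(receptor = "A", ligand = "B"))
})

test_that("structure-to-family mapping composes alignments and coordinates", {
  x <- msa(c(K2 = "MKVLATRE", K1 = "MKVQATRE"))
  s_seq <- protein_sequence("struct", "MKVLATRE")
  map <- map_structure_to_family(s_seq, x, "K2")
  expect_equal(map, 1:8)
  # one extra N-terminal residue in the member shifts the mapping by one
  x2 <- msa(c(K2 = "GMKVLATRE", K1 = "GMKVQATRE"))
  map2 <- map_structure_to_family(s_seq, x2, "K2")
  expect_equal(map2, 2:9)
  expect_error(map_structure_to_family(
    protein_sequence("s", "WWWWFFFFYYYY"), x, "K2"), "mismatch")
})

test_that("indel-perturbed mappings stay consistent with the pairwise alignment", {
  set.seed(25)
  for (rep in 1:10) {
    base <- random_protein("member", 60)
    res <- strsplit(base$residues, "")[[1]]
    drop <- sort(sample(60, 5))
    s_seq <- protein_sequence("struct", paste(res[-drop], collapse = ""))
    x <- msa(setNames(c(base$residues, base$residues), c("member", "other")))
    map <- map_structure_to_family(s_seq, x, "member")
    aln <- global_align(s_seq, base)
    ca <- strsplit(aln$a_aligned, "")[[1]]
    cb <- strsplit(aln$b_aligned, "")[[1]]
    apos <- cumsum(ca != "-"); bpos <- cumsum(cb != "-")
    both <- ca != "-" & cb != "-"
    expect_equal(map[apos[both]], bpos[both])  # gap-free member: column = pos
  }
})

test_that("correspond reports residues and ungapped positions per row", {
  x <- msa(c(one = "MKVLAT"))
  got <- correspond(x, "one", 3)
  expect_equal(got$residue, "V")
  expect_equal(got$position, 3L)
  x2 <- msa(c(a = "MKV-LAT", b = "MK-QLAT", c = "M--QLAT"))
  got2 <- correspond(x2, "a", 3)   # the V column
  expect_equal(got2$residue, c("V", "-", "-"))
  expect_equal(got2$position, c(3L, NA, NA))
  got3 <- correspond(x2, "b", 3)   # the Q column
  expect_equal(got3$residue, c("-", "Q", "Q"))
  expect_equal(got3$position, c(NA, 3L, 2L))
  expect_error(correspond(x2, "a", 99), "out of range")
})

test_that("correspond is self-consistent across rows", {
  fam <- small_family(seed = 91, len = 80)
  x <- progressive_align(fam$sequences)
  set.seed(26)
  for (rep in 1:10) {
    id <- sample(names(x), 1)
    pos <- sample(nchar(degap(x, id)), 1)
    tab <- correspond(x, id, pos)
    col <- attr(tab, "column")
    for (k in which(!is.na(tab$position))) {
      back <- correspond(x, tab$id[k], tab$position[k])
      expect_equal(attr(back, "column"), col)
    }
  }
})

test_that("conservation classes follow the similarity groups", {
  x <- msa(c(a = "RKDAS", b = "RRDGT", c = "RRDVA"))
  got <- classify_conservation(x, 1:5)
  # col1 all R -> identical; col2 {K,R} -> conserved (QHRK);
  # col3 all D -> identical; col4 {A,G,V} -> different;
  # col5 {S,T,A} -> conserved (STA)
  expect_equal(got$records$class,
               c("identical", "conserved", "identical", "different",
                 "conserved"))
  s <- got$summary
  expect_equal(unname(s["n_identical"] + s["n_conserved"] + s["n_different"]),
               unname(s["n_total"]))
  expect_equal(unname(s["n_total"]), 5L)
  # {K,D} is different
  y <- msa(c(a = "K", b = "D"))
  expect_equal(classify_conservation(y, 1)$records$class, "different")
  expect_error(classify_conservation(y, integer(0)), "empty")
})

test_that("gapped columns are flagged but identity wins over gaps", {
  x <- msa(c(a = "R-K", b = "RRD", c = "RKX"))
  got <- classify_conservation(x, 1:3)
  expect_equal(got$records$class[1], "identical")
  expect_equal(got$records$class[2], "gapped")
  s <- got$summary
  expect_equal(unname(s["n_identical"] + s["n_conserved"] + s["n_different"]),
               unname(s["n_total"]))
})

test_that("majority-identity mask counts modal residues against a threshold", {
  x <- msa(c(a = "RKA", b = "RDC", c = "RKE", d = "RKW"))
  expect_equal(unname(majority_identity_mask(x, 4)), c(TRUE, FALSE, FALSE))
  expect_equal(unname(majority_identity_mask(x, 3)), c(TRUE, TRUE, FALSE))
  expect_equal(unname(majority_identity_mask(x, 2)), c(TRUE, TRUE, FALSE))
  set.seed(27)
  for (rep in 1:10) {
    rows <- setNames(vapply(1:5, function(i)
      paste(sample(c("A", "C", "-"), 12, replace = TRUE), collapse = ""),
      character(1)), paste0("r", 1:5))
    rows[1] <- gsub("-", "A", rows[1])
    x <- msa(rows)
    m <- as.matrix(x)
    thr <- sample(2:5, 1)
    oracle <- apply(m, 2, function(col) {
      col <- col[col != "-"]
      length(col) > 0 && max(table(col)) >= thr
    })
    expect_equal(unname(majority_identity_mask(x, thr)), unname(oracle))
  }
})
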