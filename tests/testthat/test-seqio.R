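test_that("FASTA reading preserves records, order and content", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first protein", "MK", ">b", "MSTV", "LLK"), path)
  recs <- read_fasta(path)
  expect_length(recs, 2L)
  expect_equal(names(recs), c("a", "b"))
  expect_equal(recs$a$residues, "MK")
  expect_equal(recs$a$description, "first protein")
  expect_equal(recs$b$residues, "MSTVLLK")
})

test_that("FASTA round-trip is the identity on records", {
  set.seed(101)
  seqs <- lapply(1:5, function(i) random_protein(paste0("s", i), 30 + i))
  names(seqs) <- vapply(seqs, `[[`, character(1), "id")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path, width = 17L)
  back <- read_fasta(path)
  expect_equal(lapply(back, `[[`, "residues"), lapply(seqs, `[[`, "residues"))
  expect_equal(names(back), names(seqs))
})

test_that("FASTA errors: empty file and duplicate ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), path)
  expect_error(read_fasta(path))
  writeLines(c(">x", "MK", ">x", "ML"), path)
  expect_error(read_fasta(path), "duplicate.*x")
})

test_that("sequence validation enforces the alphabets", {
  expect_error(protein_sequence("p", ""), "empty")
  expect_error(protein_sequence("p", "MK-L"), "gap")
  expect_error(protein_sequence("p", "MKZL"), "Z")
  expect_warning(protein_sequence("p", "MKXL"), "ambiguous")
  expect_error(nucleotide_sequence("n", "ACGU"), "U")
  expect_equal(nucleotide_sequence("n", "acgt")$residues, "ACGT")
})

test_that("translate_cds follows the standard code and stops at a stop", {
  nt <- nucleotide_sequence("x", "ATGGGCTAA")
  expect_equal(translate_cds(nt)$residues, "MG")
  expect_equal(translate_cds(nucleotide_sequence("x", "ATGTAA"))$residues, "M")
  # offset ORF
  nt2 <- nucleotide_sequence("y", "CCATGAAATTTTGAGG")
  expect_equal(translate_cds(nt2, orf_start = 3L)$residues, "MKF")
  expect_error(translate_cds(nt2, orf_start = 1L), "ATG")
  expect_error(translate_cds(nucleotide_sequence("z", "ATGAAAGGG")), "stop")
})

test_that("translated length times three plus the stop equals the ORF span", {
  set.seed(7)
  for (rep in 1:20) {
    ncod <- sample(2:40, 1)
    body <- paste(sample(setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")), ncod - 1, replace = TRUE), collapse = "")
    nt <- nucleotide_sequence("r", paste0("ATG", body, "TAA"))
    p <- translate_cds(nt)
    expect_equal(nchar(p$residues) * 3L + 3L, nchar(nt$residues))
  }
})

test_that("the longest ATG-initiated ORF is located across frames", {
  # short ORF in frame 1, longer ORF starting at position 8 (frame 2)
  nt <- nucleotide_sequence("o", paste0("ATGTAAG", "ATGAAACCCGGGTTTTAG", "AC"))
  expect_equal(find_longest_orf(nt), 8L)
  expect_equal(translate_cds(nt, find_longest_orf(nt))$residues, "MKPGF")
  expect_error(find_longest_orf(nucleotide_sequence("o2", "CCCCCCCCC")),
               "no complete")
})

test_that("GenBank CDS extraction handles plain and join() locations", {
  gb <- c(
    "LOCUS       TESTREC    60 bp    mRNA    linear   PRI 01-JAN-2008",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             join(4..9,13..21)",
    "                     /codon_start=1",
    "ORIGIN",
    "        1 cccatgaaag ggcccgggtt ttaacc",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  cds <- read_genbank_cds(path)
  expect_equal(cds$id, "TESTREC")
  # 4..9 = ATGAAA, 13..21 = CCCGGGTTT
  expect_equal(cds$residues, "ATGAAACCCGGGTTT")
  expect_error(read_genbank_cds(withr::local_tempfile(fileext = ".gb")),
               "no such file")
})

test_that("PDB parsing keeps standard residues and resolves altlocs", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    chain = "A", resnum = c(1, 1, 2), resname = c("ALA", "ALA", "GLY"),
    atom_name = c("CA", "CB", "CA"), element = "C",
    x = c(0, 1, 4), y = 0, z = 0, stringsAsFactors = FALSE)
  write_toy_pdb(atoms, path)
  s <- read_structure(path)
  expect_s3_class(s, "structure3d")
  expect_equal(structure_chains(s), "A")
  expect_equal(nrow(unique(s$atoms[, c("resnum", "icode")])), 2L)
  expect_equal(structure_chain_sequence(s, "A")$residues, "AG")
})

test_that("altLoc A/B keeps one atom per name, highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atoms <- data.frame(
    chain = "A", resnum = 1, resname = "ALA",
    atom_name = c("CA", "CA"), altloc = c("A", "B"), element = "C",
    occupancy = c(0.4, 0.6),
    x = c(0, 9), y = 0, z = 0, stringsAsFactors = FALSE)
  write_toy_pdb(atoms, path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 9)  # the 0.6-occupancy altloc
})

test_that("malformed PDB coordinates are reported with a line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  ln <- "ATOM      1 CA  ALA A   1       bad_x   0.000   0.000  1.00  0.00           C"
  writeLines(ln, path)
  expect_error(read_structure(path), "line 1")
})
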