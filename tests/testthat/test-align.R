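test_that("identical sequences align gap-free with the diagonal score", {
  set.seed(5)
  sch <- scoring_scheme()
  for (rep in 1:10) {
    s <- random_protein("s", sample(5:60, 1))
    aln <- global_align(s, protein_sequence("t", s$residues), sch)
    expect_false(grepl("-", aln$a_aligned, fixed = TRUE))
    expect_false(grepl("-", aln$b_aligned, fixed = TRUE))
    res <- strsplit(s$residues, "")[[1]]
    expect_equal(aln$score, sum(sch$submat[cbind(res, res)]))
  }
})

test_that("degapping an alignment recovers the inputs exactly", {
  set.seed(6)
  for (rep in 1:20) {
    a <- random_protein("a", sample(3:40, 1))
    b <- random_protein("b", sample(3:40, 1))
    aln <- global_align(a, b)
    expect_equal(nchar(aln$a_aligned), nchar(aln$b_aligned))
    expect_equal(gsub("-", "", aln$a_aligned), a$residues)
    expect_equal(gsub("-", "", aln$b_aligned), b$residues)
    # no column with two gaps
    ca <- strsplit(aln$a_aligned, "")[[1]]
    cb <- strsplit(aln$b_aligned, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("empty sequences are rejected before alignment", {
  expect_error(protein_sequence("e", ""), "empty")
})

test_that("DP score equals the exhaustive-enumeration oracle on short pairs", {
  set.seed(8)
  sch <- scoring_scheme()
  alphabet <- rownames(sch$submat)
  for (rep in 1:100) {
    a <- random_protein("a", sample(1:8, 1))
    b <- random_protein("b", sample(1:8, 1))
    dp <- global_align(a, b, sch)$score
    oracle <- karyofam:::enumerate_align_score_cpp(
      match(strsplit(a$residues, "")[[1]], alphabet) - 1L,
      match(strsplit(b$residues, "")[[1]], alphabet) - 1L,
      sch$submat, sch$gap_open, sch$gap_extend)
    expect_equal(dp, oracle, tolerance = 1e-9)
  }
})

test_that("percent identity follows the stated conventions", {
  expect_equal(percent_identity(list(a_aligned = "AAAA", b_aligned = "AAAT")),
               75)
  expect_equal(percent_identity(list(a_aligned = "MKV", b_aligned = "MKV")),
               100)
  expect_equal(percent_identity(list(a_aligned = "AA--", b_aligned = "AAGG")),
               50)
  expect_equal(percent_identity(list(a_aligned = "AA--", b_aligned = "AAGG"),
                                "ungapped_columns"), 100)
  expect_equal(percent_identity(list(a_aligned = "AAG-", b_aligned = "AA-G"),
                                "shorter_seq"), 100 * 2 / 3)
})

test_that("percent identity is symmetric and stable under identical columns", {
  set.seed(9)
  for (rep in 1:20) {
    len <- sample(4:30, 1)
    ra <- sample(c(AA, "-"), len, replace = TRUE, prob = c(rep(1, 20), 5))
    rb <- sample(c(AA, "-"), len, replace = TRUE, prob = c(rep(1, 20), 5))
    both_gap <- ra == "-" & rb == "-"
    ra[both_gap] <- "A"; rb[both_gap] <- "C"
    aln <- list(a_aligned = paste(ra, collapse = ""),
                b_aligned = paste(rb, collapse = ""))
    rev <- list(a_aligned = aln$b_aligned, b_aligned = aln$a_aligned)
    expect_equal(percent_identity(aln), percent_identity(rev))
    # appending identical both-residue columns moves identity toward 100 but
    # keeps 100 fixed; appending one identical column to an all-identical
    # pair is invariant
    same <- list(a_aligned = paste0(aln$a_aligned, "W"),
                 b_aligned = paste0(aln$b_aligned, "W"))
    expect_gte(percent_identity(same), percent_identity(aln))
  }
  expect_equal(percent_identity(list(a_aligned = "MKW", b_aligned = "MKW")),
               percent_identity(list(a_aligned = "MK", b_aligned = "MK")))
})

test_that("identity_matrix matches per-pair brute-force recomputation", {
  fam <- small_family(seed = 21, len = 120)
  x <- fam$alignment
  m <- identity_matrix(x)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(100, length(x)))
  ids <- names(x)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      ca <- strsplit(x[[ids[i]]], "")[[1]]
      cb <- strsplit(x[[ids[j]]], "")[[1]]
      keep <- !(ca == "-" & cb == "-")
      expect_equal(m[i, j],
                   100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") /
                     sum(keep))
    }
  }
})

test_that("identity matrix of duplicated sequences is all 100", {
  x <- msa(c(a = "MKVLAT", b = "MKVLAT", c = "MKVLAT"))
  expect_true(all(identity_matrix(x) == 100))
})

test_that("progressive alignment of two sequences reduces to the pairwise DP", {
  a <- protein_sequence("a", "MKVLATRE")
  b <- protein_sequence("b", "MKVATRE")
  aln <- global_align(a, b)
  x <- progressive_align(list(a, b))
  expect_equal(unname(x[["a"]]), aln$a_aligned)
  expect_equal(unname(x[["b"]]), aln$b_aligned)
})

test_that("progressive alignment of identical sequences is gap-free", {
  s <- "MKVLATREHQWFDNPGIC"
  seqs <- lapply(paste0("s", 1:5), function(id) protein_sequence(id, s))
  x <- progressive_align(seqs)
  expect_equal(msa_width(x), nchar(s))
  expect_false(any(grepl("-", unclass(x), fixed = TRUE)))
  expect_equal(names(x), paste0("s", 1:5))  # input order preserved
})

test_that("progressive alignment recovers a mostly gap-free simulated family", {
  fam <- small_family(seed = 31, len = 200)
  x <- progressive_align(fam$sequences)
  # substitution-only truth: the aligner should add few or no gap columns
  expect_lte(msa_width(x), 200 + 10)
  expect_equal(names(x), names(fam$sequences))
})
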