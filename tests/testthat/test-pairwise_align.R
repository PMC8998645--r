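test_that("identical sequences score the matrix diagonal with identity 1", {
  a <- global_align("AAA", "AAA", protein_scoring())
  expect_equal(a$score, 12)   # 3 x BLOSUM62 A/A = 4
  expect_equal(a$identity, 1)
  expect_equal(a$coverage_a, 1)
  b <- global_align("HEAGAWGHEE", "PAWHEAE", protein_scoring())
  ## score equals the independent Gotoh oracle
  expect_equal(b$score,
               gotoh_global_score("HEAGAWGHEE", "PAWHEAE",
                                  protein_scoring()$matrix, 10, 0.5))
})

test_that("global scores equal the exhaustive affine-gap oracle", {
  set.seed(7)
  ps <- protein_scoring(); ds <- dna_scoring()
  for (i in 1:60) {
    a <- random_protein(sample(1:12, 1)); b <- random_protein(sample(1:12, 1))
    expect_equal(global_align(a, b, ps)$score,
                 gotoh_global_score(a, b, ps$matrix, ps$gap_open,
                                    ps$gap_extend),
                 tolerance = 1e-9)
  }
  for (i in 1:40) {
    a <- random_dna_str(sample(1:12, 1)); b <- random_dna_str(sample(1:12, 1))
    expect_equal(global_align(a, b, ds)$score,
                 gotoh_global_score(a, b, ds$matrix, ds$gap_open,
                                    ds$gap_extend),
                 tolerance = 1e-9)
  }
})

test_that("swapping the sequences preserves the score", {
  set.seed(11)
  ps <- protein_scoring()
  for (i in 1:10) {
    a <- random_protein(8); b <- random_protein(10)
    expect_equal(global_align(a, b, ps)$score, global_align(b, a, ps)$score)
  }
})

test_that("score never decreases when identical residues are appended", {
  set.seed(13)
  ps <- protein_scoring()
  for (i in 1:10) {
    a <- random_protein(6); b <- random_protein(8)
    s0 <- global_align(a, b, ps)$score
    s1 <- global_align(paste0(a, "W"), paste0(b, "W"), ps)$score
    expect_gte(s1, s0)
  }
})

test_that("local alignment finds the shared core and allows empty alignments", {
  l <- local_align("TTTACGTTT", "GGGACGGGG", dna_scoring())
  expect_equal(l$score, 6)
  expect_equal(gsub("-", "", l$aligned_a), "ACG")
  ## disjoint content: empty alignment, score 0
  e <- local_align("AAAA", "TTTT", dna_scoring())
  expect_equal(e$score, 0)
  expect_equal(e$aligned_a, "")
  ## local dominates global clipped at zero
  set.seed(17)
  for (i in 1:10) {
    a <- random_dna_str(15); b <- random_dna_str(15)
    expect_gte(local_align(a, b, dna_scoring())$score,
               max(0, global_align(a, b, dna_scoring())$score))
  }
})

test_that("errors on empty input and mixed alphabets", {
  expect_error(global_align("", "AAA"), "non-empty")
  expect_error(global_align("ACGT", "MKWQ"), "alphabet")
})

test_that("exon spans map onto alignment columns", {
  ## two exons of 150 + 150 nt, gapless self-alignment: aa spans [0,50), [50,100)
  g <- gen_ancestral_gene(n_exons = 2L, exon_len_range = c(150L, 150L),
                          seed = 5)
  aln <- global_align(g$model$protein, g$model$protein, protein_scoring())
  sp <- map_exons_to_alignment(g$model, aln, "a")
  expect_equal(sp$aa_start, c(0L, 50L))
  expect_equal(sp$aa_end, c(50L, 100L))
  expect_equal(sp$col_start, c(1L, 51L))
  expect_equal(sp$col_end, c(50L, 100L))
  expect_false(any(sp$boundary_split))
})

test_that("a phase-1 exon boundary assigns the split residue to the 5' exon", {
  ## hand-built gene: exon1 = 7 nt, exon2 = 8 nt (codon split at the junction)
  cds <- "ATGGCTGCAGCTGCT"  # 15 nt, MAAAA
  intron <- strrep("T", 50)
  scaffold <- paste0(substring(cds, 1, 7), intron, substring(cds, 8, 15))
  gm <- gene_model("ph1", "s", "+", rbind(c(0, 7), c(57, 65)), scaffold)
  expect_equal(gm$protein, "MAAAA")
  aln <- global_align(gm$protein, gm$protein, protein_scoring())
  sp <- map_exons_to_alignment(gm, aln, "a")
  ## exon1 covers aa 0..2 (the split codon 2 goes to the 5' exon)
  expect_equal(sp$aa_end[1], 3L)
  expect_equal(sp$aa_start[2], 3L)
  expect_true(sp$boundary_split[2])
  expect_false(sp$boundary_split[1])
})

test_that("NCBI-format scoring matrices load", {
  tf <- tempfile()
  writeLines(c("# comment", "   A  C", "A  5 -4", "C -4  5"), tf)
  m <- read_scoring_matrix(tf)
  expect_equal(m["A", "A"], 5)
  expect_equal(m["A", "C"], -4)
})
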