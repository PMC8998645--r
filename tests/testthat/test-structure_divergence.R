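test_that("cherry extraction matches definitions on hand-built trees", {
  ## two same-species leaves under one ancestor: a paralog pair
  p <- extract_sibling_pairs(parse_newick("((spA_1:1,spA_2:1):1,spB_1:2);"))
  expect_length(p, 1L)
  expect_equal(p[[1]]$relation, "paralog")
  expect_setequal(c(p[[1]]$a, p[[1]]$b), c("spA_1", "spA_2"))
  ## caterpillar tree: a single cherry
  p2 <- extract_sibling_pairs(
    parse_newick("(((spA_1:1,spB_1:1):1,spC_1:2):1,spD_1:3);"))
  expect_length(p2, 1L)
  expect_equal(p2[[1]]$relation, "ortholog")
  ## empty genes_of_interest: empty result
  expect_length(extract_sibling_pairs(
    parse_newick("((spA_1:1,spA_2:1):1,spB_1:2);"),
    genes_of_interest = character(0)), 0L)
  ## a leaf without a species tag errors
  expect_error(extract_sibling_pairs(parse_newick("((x:1,spA_2:1):1,spB_1:2);")),
               "species tag")
})

test_that("cherry extraction agrees with brute-force MRCA enumeration", {
  set.seed(41)
  for (rep in 1:25) {
    tr <- ape::rtree(10)
    tr$tip.label <- sprintf("sp%d_g%d", sample(1:4, 10, replace = TRUE), 1:10)
    mine <- extract_sibling_pairs(tr)
    mine_sorted <- lapply(mine, function(p) sort(c(p$a, p$b)))
    brute <- brute_force_cherries(tr)
    expect_setequal(vapply(mine_sorted, paste, "", collapse = "|"),
                    vapply(brute, paste, "", collapse = "|"))
  }
})

test_that("identical gene structures match exon-by-exon with no orphans", {
  g <- gen_ancestral_gene(n_exons = 3L, seed = 51)
  corr <- pair_exon_homology(g$model, g$model)
  expect_equal(nrow(corr$matched), 3L)
  expect_equal(corr$matched$overlap_a, rep(1, 3))
  expect_length(corr$orphans_a, 0L)
  expect_length(corr$orphans_b, 0L)
  expect_false(is_structurally_divergent(corr, g$model, g$model))
})

test_that("an extra exon becomes an orphan; the rest still match", {
  sp <- gen_sibling_pair("GAIN_LOSS", divergence = 0.05, seed = 61)
  corr <- pair_exon_homology(sp$a$model, sp$b$model)
  carrier_n <- if (sp$truth$carrier == "a") length(corr$orphans_a)
               else length(corr$orphans_b)
  other_n <- if (sp$truth$carrier == "a") length(corr$orphans_b)
             else length(corr$orphans_a)
  expect_equal(carrier_n, 1L)
  expect_equal(other_n, 0L)
  expect_equal(nrow(corr$matched), 5L)
  expect_true(is_structurally_divergent(corr, sp$a$model, sp$b$model))
})

test_that("an exon split by an intron gain yields a flagged split candidate", {
  sp <- gen_sibling_pair("SPLIT", divergence = 0.05, seed = 71)
  corr <- pair_exon_homology(sp$a$model, sp$b$model)
  splits <- if (sp$truth$carrier == "a") corr$split_candidates_a
            else corr$split_candidates_b
  expect_length(splits, 1L)
  call <- classify_mechanisms(sp$a$model, sp$b$model, sp$a$scaffold_seq,
                              sp$b$scaffold_seq)
  expect_equal(call$mechanisms, "GAIN_LOSS")
  subtypes <- vapply(call$evidence,
                     function(e) if (is.null(e$subtype)) "" else e$subtype, "")
  expect_true("intron_gain_loss" %in% subtypes)
})

test_that("structural divergence rule: equal counts but unequal exon lengths", {
  g <- gen_ancestral_gene(n_exons = 3L, exon_len_range = c(300L, 300L),
                          seed = 81)
  ## shrink one exon by one codon on a copy
  ex2 <- g$model$exons
  ex2[2, 2] <- ex2[2, 2] - 3L
  gm2 <- gene_model("g2", "s", "+", ex2, g$scaffold_seq)
  corr <- pair_exon_homology(g$model, gm2)
  expect_equal(nrow(corr$matched), 3L)
  expect_true(is_structurally_divergent(corr, g$model, gm2))
})

test_that("planted mechanisms are classified correctly with evidence", {
  sp_ex <- gen_sibling_pair("EXONIZATION", divergence = 0.08, seed = 91)
  call_ex <- classify_mechanisms(sp_ex$a$model, sp_ex$b$model,
                                 sp_ex$a$scaffold_seq, sp_ex$b$scaffold_seq)
  expect_equal(call_ex$mechanisms, "EXONIZATION_PSEUDOEXONIZATION")
  ev <- call_ex$evidence[[1]]
  expect_gte(ev$identity, 0.40)
  expect_gte(ev$coverage, 0.60)

  sp_gl <- gen_sibling_pair("GAIN_LOSS", divergence = 0.08, seed = 92)
  call_gl <- classify_mechanisms(sp_gl$a$model, sp_gl$b$model,
                                 sp_gl$a$scaffold_seq, sp_gl$b$scaffold_seq)
  expect_equal(call_gl$mechanisms, "GAIN_LOSS")

  sp_in <- gen_sibling_pair("INTRAEXONIC_INDEL", divergence = 0.08, seed = 93)
  call_in <- classify_mechanisms(sp_in$a$model, sp_in$b$model,
                                 sp_in$a$scaffold_seq, sp_in$b$scaffold_seq)
  expect_equal(call_in$mechanisms, "INTRAEXONIC_INDEL")

  ## identical inputs: no divergence, no mechanisms
  sp_no <- gen_sibling_pair("NONE", divergence = 0, seed = 94)
  call_no <- classify_mechanisms(sp_no$a$model, sp_no$b$model,
                                 sp_no$a$scaffold_seq, sp_no$b$scaffold_seq)
  expect_false(call_no$structurally_divergent)
  expect_length(call_no$mechanisms, 0L)
})

test_that("classification is symmetric in the pair order", {
  mechs <- c("GAIN_LOSS", "EXONIZATION", "INTRAEXONIC_INDEL")
  for (mech in mechs) {
    sp <- gen_sibling_pair(mech, divergence = 0.08,
                           seed = 100 + match(mech, mechs))
    ab <- classify_mechanisms(sp$a$model, sp$b$model, sp$a$scaffold_seq,
                              sp$b$scaffold_seq)
    ba <- classify_mechanisms(sp$b$model, sp$a$model, sp$b$scaffold_seq,
                              sp$a$scaffold_seq)
    expect_equal(ab$mechanisms, ba$mechanisms)
  }
})

test_that("an orphan without genomic windows is an error naming the gene", {
  sp <- gen_sibling_pair("GAIN_LOSS", divergence = 0.05, seed = 111)
  carrier_gene <- if (sp$truth$carrier == "a") "spA_g1" else "spA_g2"
  expect_error(classify_mechanisms(sp$a$model, sp$b$model), carrier_gene)
})

test_that("the census counts pairs per mechanism, with overlaps allowed", {
  mk <- function(mechs) structure(
    list(structurally_divergent = length(mechs) > 0, mechanisms = mechs,
         evidence = list(), pair = c(a = "x", b = "y")),
    class = "divergence_call")
  cen <- mechanism_census(list(mk("GAIN_LOSS"),
                               mk(c("GAIN_LOSS",
                                    "EXONIZATION_PSEUDOEXONIZATION")),
                               mk("EXONIZATION_PSEUDOEXONIZATION")))
  expect_equal(unname(cen["GAIN_LOSS"]), 2L)
  expect_equal(unname(cen["EXONIZATION_PSEUDOEXONIZATION"]), 2L)
  expect_equal(unname(cen["INTRAEXONIC_INDEL"]), 0L)
  expect_equal(unname(cen["n_pairs"]), 3L)
  empty <- mechanism_census(list())
  expect_true(all(empty[rlrkit:::MECHANISMS] == 0L))
})
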