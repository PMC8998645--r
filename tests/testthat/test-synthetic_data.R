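test_that("ancestral genes are valid and deterministic under a seed", {
  g1 <- gen_ancestral_gene(n_exons = 4L, seed = 101)
  g2 <- gen_ancestral_gene(n_exons = 4L, seed = 101)
  expect_identical(g1$scaffold_seq, g2$scaffold_seq)
  expect_identical(g1$model$exons, g2$model$exons)
  expect_equal(nchar(g1$model$cds) %% 3L, 0L)
  expect_false(g1$model$internal_stop)
  ## single-exon gene: CDS equals the exon
  s <- gen_ancestral_gene(n_exons = 1L, seed = 5)
  expect_equal(nrow(s$model$exons), 1L)
  expect_equal(nchar(s$model$cds),
               unname(s$model$exons[1, 2] - s$model$exons[1, 1]))
})

test_that("generator output survives the GFF3/FASTA parser round trip", {
  sp <- gen_sibling_pair("EXONIZATION", divergence = 0.1, seed = 103)
  tf <- tempfile(fileext = ".gff3"); ff <- tempfile(fileext = ".fa")
  write_gff3(list(sp$a$model, sp$b$model), tf)
  write_fasta(c(setNames(sp$a$scaffold_seq, sp$a$model$scaffold_id),
                setNames(sp$b$scaffold_seq, sp$b$model$scaffold_id)), ff)
  back <- parse_gff3_gene_models(tf, ff)
  expect_length(back, 2L)
  expect_equal(back[[sp$a$model$gene_id]]$cds, sp$a$model$cds)
  expect_equal(back[[sp$b$model$gene_id]]$protein, sp$b$model$protein)
})

test_that("NONE at zero divergence gives identical models", {
  sp <- gen_sibling_pair("NONE", divergence = 0, seed = 107)
  expect_identical(sp$a$model$cds, sp$b$model$cds)
  expect_identical(sp$a$model$exons, sp$b$model$exons)
})

test_that("exonized exons align to the partner intron at the expected identity", {
  for (seed in c(109, 113)) {
    sp <- gen_sibling_pair("EXONIZATION", divergence = 0.1, seed = seed)
    carrier <- if (sp$truth$carrier == "a") sp$a else sp$b
    partner <- if (sp$truth$carrier == "a") sp$b else sp$a
    ## the planted exon is the one absent from the partner: find by count
    corr <- pair_exon_homology(carrier$model, partner$model)
    orphans <- if (sp$truth$carrier == "a") corr$orphans_a else corr$orphans_b
    ## run under classify to find the orphan's best non-exonic hit
    call <- classify_mechanisms(carrier$model, partner$model,
                                carrier$scaffold_seq, partner$scaffold_seq)
    ev <- Filter(function(e)
      e$mechanism == "EXONIZATION_PSEUDOEXONIZATION", call$evidence)
    expect_length(ev, 1L)
    ## by construction the pairwise identity is about (1 - divergence)^2
    expect_gte(ev[[1]]$identity, 1 - 2 * 0.1 - 0.08)
  }
})

test_that("novel gained exons have no partner-intron homology above chance", {
  sp <- gen_sibling_pair("GAIN_LOSS", divergence = 0.1, seed = 127)
  call <- classify_mechanisms(sp$a$model, sp$b$model, sp$a$scaffold_seq,
                              sp$b$scaffold_seq)
  ev <- Filter(function(e) !is.null(e$subtype) && e$subtype == "novel_exon",
               call$evidence)
  expect_length(ev, 1L)
  expect_lt(ev[[1]]$best_identity * ev[[1]]$best_coverage, 0.4 * 0.6)
})

test_that("Poisson counts have variance close to the mean", {
  gc <- gen_counts(n_genes = 10000L, n_a = 2L, n_b = 2L, dispersion = 0,
                   n_de = 0L, baseline_sdlog = 0, seed = 131)
  ## all genes share mean 100: pooled variance/mean ratio near 1
  x <- as.vector(gc$cm$counts)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.05)
  ## NB dispersion inflates variance: var = mu + phi mu^2
  gc2 <- gen_counts(n_genes = 10000L, n_a = 2L, n_b = 2L, dispersion = 0.2,
                    n_de = 0L, baseline_sdlog = 0, seed = 133)
  x2 <- as.vector(gc2$cm$counts)
  expect_equal(var(x2), mean(x2) + 0.2 * mean(x2)^2, tolerance = 0.1 * var(x2))
})

test_that("count generation is reproducible and truth-labelled", {
  a <- gen_counts(n_genes = 100L, n_de = 10L, seed = 137)
  b <- gen_counts(n_genes = 100L, n_de = 10L, seed = 137)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$de), 10L)
  expect_true(all(a$truth$true_log2fc[a$truth$de] == 3))
})

test_that("an exonization event too large for fixed introns errors", {
  expect_error(
    gen_sibling_pair("EXONIZATION", divergence = 0,
                     event_aa_range = c(300L, 300L),
                     intron_len_range = c(150L, 200L), fit_introns = FALSE,
                     seed = 139),
    "larger than available intron")
})
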