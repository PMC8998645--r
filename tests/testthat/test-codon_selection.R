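test_that("the GY94 generator has the required structure", {
  set.seed(3)
  for (rep in 1:3) {
    kappa <- runif(1, 0.5, 5); omega <- runif(1, 0.05, 3)
    pi <- runif(61); pi <- pi / sum(pi)
    Q <- gy94_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    ## detailed balance: pi_i q_ij = pi_j q_ji
    F <- sweep(Q, 1, pi, "*")
    expect_lt(max(abs(F - t(F))), 1e-12)
    ## scaled to one expected substitution per unit time
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  }
  ## kappa = omega = 1, uniform pi: all single-nt rates equal
  Q1 <- gy94_rate_matrix(1, 1, scale = FALSE)
  off <- Q1[Q1 > 0]
  expect_equal(length(unique(round(off, 12))), 1L)
  ## multi-nucleotide changes are zero
  expect_equal(Q1["AAA", "ACC"], 0)
  expect_error(gy94_rate_matrix(2, 0.5, pi = rep(1, 10)), "61")
})

test_that("two-taxon likelihood matches the closed form to 1e-8", {
  tr <- parse_newick("(a:0.3,b:0.2);")
  spec <- codon_model_spec("M0", kappa = 2.5, omega = 0.4)
  sim <- simulate_codon_alignment(tr, spec, 40, seed = 19)
  pi <- rep(1 / 61, 61)
  lnl <- as.numeric(log_likelihood(sim$alignment, tr, spec, pi = pi))
  ## independent route: series expm of Q(t1+t2), reversibility closed form
  Q <- gy94_rate_matrix(2.5, 0.4, pi)
  P <- expm_series(Q * 0.5)
  st <- sim$alignment$states
  closed <- sum(log(pi[st["a", ]] * P[cbind(st["a", ], st["b", ])]))
  expect_equal(lnl, closed, tolerance = 1e-8)
})

test_that("zero branch lengths on identical sequences give the stationary lnL", {
  tr <- parse_newick("(a:0,b:0,c:0);")
  seqs <- setNames(rep(strrep("ATGGCT", 10), 3), c("a", "b", "c"))
  ca <- codon_alignment(seqs)
  pi <- rep(1 / 61, 61)
  lnl <- as.numeric(log_likelihood(ca, tr, codon_model_spec("M0"), pi = pi))
  expect_equal(lnl, 20 * log(1 / 61), tolerance = 1e-6)
})

test_that("the likelihood is invariant under re-rooting (pulley principle)", {
  tr <- parse_newick("((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.08);")
  spec <- codon_model_spec("M1a", kappa = 2, omega0 = 0.2, p0 = 0.7)
  sim <- simulate_codon_alignment(tr, spec, 60, seed = 23)
  pi <- rep(1 / 61, 61)
  base <- as.numeric(log_likelihood(sim$alignment, tr, spec, pi = pi))
  for (node in c("a", "c", "d")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = FALSE)
    expect_equal(as.numeric(log_likelihood(sim$alignment, rerooted, spec,
                                           pi = pi)),
                 base, tolerance = 1e-8)
  }
  ## leaf order in the alignment is irrelevant
  ca2 <- sim$alignment
  perm <- rev(ca2$taxa)
  ca2$states <- ca2$states[perm, ]
  ca2$taxa <- perm
  expect_equal(as.numeric(log_likelihood(ca2, tr, spec, pi = pi)), base,
               tolerance = 1e-10)
})

test_that("gaps are treated as missing data", {
  tr <- parse_newick("(a:0.2,b:0.2);")
  seqs <- c(a = "ATGGCTAAA", b = "ATG---AAA")
  ca <- codon_alignment(seqs)
  lnl <- as.numeric(log_likelihood(ca, tr, codon_model_spec("M0"),
                                   pi = rep(1 / 61, 61)))
  ## dropping the gapped site entirely must give the other two sites' lnL
  ca2 <- codon_alignment(c(a = "ATGAAA", b = "ATGAAA"))
  lnl2 <- as.numeric(log_likelihood(ca2, tr, codon_model_spec("M0"),
                                    pi = rep(1 / 61, 61)))
  ## site 2 contributes log(pi) marginalised over b: exactly log pi_GCT
  expect_equal(lnl, lnl2 + log(1 / 61), tolerance = 1e-10)
})

test_that("taxa/leaf mismatches error", {
  tr <- parse_newick("(a:0.2,x:0.2);")
  ca <- codon_alignment(c(a = "ATG", b = "ATG"))
  expect_error(log_likelihood(ca, tr, codon_model_spec("M0")), "taxa")
  expect_error(codon_alignment(c(a = "ATGTAAATG", b = "ATGGCTATG")), "stop")
  expect_error(codon_alignment(c(a = "ATGG-TATG", b = "ATGGCTATG")),
               "whole-codon")
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  expect_equal(lrt(-100, -100, 2)$p_value, 1)
  expect_equal(lrt(-100, -100 + 5.99146 / 2, 2)$p_value, 0.05,
               tolerance = 1e-4)
  ## negative statistics clamp to zero
  expect_equal(lrt(-99, -100, 2)$statistic, 0)
})

test_that("M0 fits recover simulated kappa and omega", {
  tr <- parse_newick("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05,(e:0.1,f:0.15):0.02);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0", kappa = 2,
                                                       omega = 0.2),
                                  500, seed = 29)
  fit <- fit_codon_model(sim$alignment, tr, "M0", seed = 1)
  expect_lt(abs(fit$omegas[1] - 0.2) / 0.2, 0.2)
  expect_lt(abs(fit$kappa - 2) / 2, 0.25)
})

test_that("nesting: the alternative model never fits worse than its null", {
  tr <- parse_newick("((a:0.15,b:0.15):0.1,c:0.2,d:0.25);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M1a", kappa = 2,
                                                       omega0 = 0.1,
                                                       p0 = 0.8),
                                  80, seed = 31)
  f1 <- fit_codon_model(sim$alignment, tr, "M1a", n_starts = 1, seed = 1)
  f2 <- fit_codon_model(sim$alignment, tr, "M2a", n_starts = 1, init = f1,
                        seed = 1)
  expect_gte(f2$lnL, f1$lnL - 1e-2)
  f7 <- fit_codon_model(sim$alignment, tr, "M7", n_starts = 1, seed = 1)
  f8 <- fit_codon_model(sim$alignment, tr, "M8", n_starts = 1, init = f7,
                        seed = 1)
  expect_gte(f8$lnL, f7$lnL - 1e-2)
})

test_that("branch2 with all branches foreground matches M0", {
  tr <- parse_newick("((a:0.15,b:0.15):0.1,c:0.2,d:0.25);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0", kappa = 2,
                                                       omega = 0.3),
                                  100, seed = 37)
  f0 <- fit_codon_model(sim$alignment, tr, "M0", n_starts = 1, seed = 1)
  fb <- fit_codon_model(sim$alignment, tr, "branch2",
                        foreground = seq_len(nrow(ape::reorder.phylo(
                          tr, "postorder")$edge)),
                        n_starts = 1, seed = 1)
  expect_equal(fb$lnL, f0$lnL, tolerance = 1e-2)
})

test_that("a positively selected foreground clade is detected by branch2", {
  tr <- parse_newick("((a:0.2,b:0.2):0.1,c:0.2,d:0.25);")
  hits <- 0L
  nrep <- 6L
  for (r in seq_len(nrep)) {
    spec <- codon_model_spec("branch2", kappa = 2, omega_bg = 0.2,
                             omega_fg = 5, foreground = c("a", "b"))
    sim <- simulate_codon_alignment(tr, spec, 300, seed = 500 + r)
    fit <- fit_codon_model(sim$alignment, tr, "branch2",
                           foreground = c("a", "b"), n_starts = 1, seed = r)
    if (fit$omegas[2] > 1) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * nrep))
})

test_that("NEB flags sites in the positively selected class", {
  tr <- parse_newick("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1,(e:0.2,f:0.2):0.05);")
  spec <- codon_model_spec("M2a", kappa = 2, omega0 = 0.1, p0 = 0.75,
                           p1 = 0.15, omega2 = 5)
  sim <- simulate_codon_alignment(tr, spec, 200, seed = 43)
  fit <- fit_codon_model(sim$alignment, tr, "M2a", n_starts = 1, seed = 1)
  sites <- neb_sites(fit)
  planted <- which(sim$site_class == 3L)
  expect_gt(length(planted), 0L)
  ## the flagged set should be enriched for planted positively selected sites
  expect_gt(mean(sites$selected[planted]), mean(sites$selected[-planted]))
  expect_gte(mean(sites$selected[planted]), 0.5)
  ## models without an omega > 1 class refuse site identification
  f0 <- fit_codon_model(sim$alignment, tr, "M0", n_starts = 1, seed = 1)
  expect_error(neb_sites(f0), "M2a or M8")
})

test_that("simulation respects limits and seeds", {
  tr <- parse_newick("(a:0,b:0,c:0);")
  sim <- simulate_codon_alignment(tr, codon_model_spec("M0"), 30, seed = 5)
  st <- sim$alignment$states
  expect_true(all(st[1, ] == st[2, ]) && all(st[1, ] == st[3, ]))
  tr2 <- parse_newick("((a:0.1,b:0.2):0.1,c:0.3);")
  s1 <- simulate_codon_alignment(tr2, codon_model_spec("M1a"), 50, seed = 7)
  s2 <- simulate_codon_alignment(tr2, codon_model_spec("M1a"), 50, seed = 7)
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)
  expect_identical(s1$site_class, s2$site_class)
})

test_that("long simulations reproduce the stationary codon frequencies", {
  tr <- parse_newick("(a:0.05,b:0.05);")
  set.seed(9)
  pi <- runif(61, 0.5, 1.5); pi <- pi / sum(pi)
  spec <- codon_model_spec("M0", kappa = 2, omega = 0.5, pi = pi)
  sim <- simulate_codon_alignment(tr, spec, 10000, seed = 11)
  emp <- tabulate(sim$alignment$states, nbins = 61) / (2 * 10000)
  expect_lt(max(abs(emp - pi)), 0.01)
})
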