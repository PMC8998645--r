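## Goldman-Yang (GY94) codon substitution machinery: the 61-state rate
## matrix over sense codons, Felsenstein-pruning likelihoods with
## site-class mixtures, maximum-likelihood fits of M0, the two-ratio
## branch model, and the site models M1a/M2a/M7/M8, likelihood-ratio
## tests, naive-empirical-Bayes site identification, and a simulator.

## ---- codon bookkeeping -------------------------------------------------

codon_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    all64 <- names(gc_tab)
    sense <- all64[gc_tab != "*"]
    aa <- gc_tab[sense]
    n <- length(sense)  # 61
    ## substitution type: 0 none/multi-nt, 1 syn tv, 2 syn ts, 3 nonsyn tv,
    ## 4 nonsyn ts
    type <- matrix(0L, n, n, dimnames = list(sense, sense))
    ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
    sp <- strsplit(sense, "")
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(sp[[i]] != sp[[j]])
      if (length(diff) != 1L) next
      ts <- ts_pair(sp[[i]][diff], sp[[j]][diff])
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L else
        if (!syn && !ts) 3L else 4L
    }
    cache <<- list(codons = sense, aa = aa, type = type, n = n,
                   stops = all64[gc_tab == "*"])
    cache
  }
})

#' GY94 codon rate matrix
#'
#' Generator over the 61 sense codons of the standard genetic code.
#' Off-diagonal rates for single-nucleotide changes i -> j are
#' proportional to `pi_j`, multiplied by `kappa` for transitions and by
#' `omega` for nonsynonymous changes; multi-nucleotide changes have rate
#' 0. Rows sum to zero, and with `scale = TRUE` the matrix is normalised
#' so the expected number of substitutions per codon site is 1 at
#' stationarity.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS, > 0).
#' @param pi codon stationary frequencies (length 61, positive, sums
#'   to 1); default uniform.
#' @param scale normalise to one expected substitution per unit time.
#' @return 61 x 61 matrix with codon dimnames.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = NULL, scale = TRUE) {
  ct <- codon_tables()
  if (is.null(pi)) pi <- rep(1 / ct$n, ct$n)
  if (length(pi) != ct$n || any(pi <= 0))
    stop("pi must be ", ct$n, " positive frequencies")
  pi <- pi / sum(pi)
  Q <- gy94_Q_raw(kappa, omega, pi, ct)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    Q <- Q / rate
  }
  dimnames(Q) <- list(ct$codons, ct$codons)
  Q
}

gy94_Q_raw <- function(kappa, omega, pi, ct = codon_tables()) {
  PIJ <- matrix(pi, ct$n, ct$n, byrow = TRUE)
  Ty <- ct$type
  Q <- (Ty == 1L) * PIJ + kappa * (Ty == 2L) * PIJ +
    omega * (Ty == 3L) * PIJ + omega * kappa * (Ty == 4L) * PIJ
  diag(Q) <- -rowSums(Q)
  Q
}

## ---- codon alignments --------------------------------------------------

#' Construct a codon alignment
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (equal lengths divisible by 3; gaps in whole-codon units).
#' @return Object of class `codon_alignment`: `taxa`, `states` (taxa x
#'   sites integer matrix into the 61 sense codons, `NA` = gap/ambiguous),
#'   `nsites`, `sequences`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 2L)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  if (len %% 3L != 0L) stop("alignment length not divisible by 3")
  ct <- codon_tables()
  nsites <- len %/% 3L
  states <- matrix(NA_integer_, length(seqs), nsites,
                   dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cods <- substring(toupper(seqs[i]), 3L * seq_len(nsites) - 2L,
                      3L * seq_len(nsites))
    partial <- grepl("-", cods) & cods != "---"
    if (any(partial)) stop("taxon ", names(seqs)[i],
                           ": gaps must be whole-codon units")
    if (any(cods %in% ct$stops))
      stop("taxon ", names(seqs)[i], ": in-frame internal stop codon")
    states[i, ] <- match(cods, ct$codons)
  }
  structure(list(taxa = names(seqs), states = states, nsites = nsites,
                 sequences = seqs),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$nsites,
      " codon sites\n", sep = "")
  invisible(x)
}

#' Read a codon alignment from FASTA
#' @param path FASTA file of aligned coding sequences.
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  codon_alignment(setNames(as.character(x),
                           vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)))
}

#' Write a codon alignment as FASTA
#' @param ca a [codon_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(ca, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(ca$sequences), path)
  invisible(path)
}

#' F3x4 codon frequencies from an alignment
#'
#' Empirical nucleotide frequencies at each codon position; the frequency
#' of a sense codon is the product over its three positions, renormalised
#' after removing stop codons.
#'
#' @param ca a [codon_alignment].
#' @return Named vector of 61 codon frequencies.
#' @export
f3x4_frequencies <- function(ca) {
  ct <- codon_tables()
  obs <- ct$codons[ca$states[!is.na(ca$states)]]
  if (!length(obs)) return(setNames(rep(1 / ct$n, ct$n), ct$codons))
  posfreq <- lapply(1:3, function(p) {
    nt <- substring(obs, p, p)
    f <- table(factor(nt, levels = c("A", "C", "G", "T")))
    f <- f + 1  # light smoothing: keeps every sense codon reachable
    f / sum(f)
  })
  pi <- vapply(ct$codons, function(cd) {
    prod(vapply(1:3, function(p) posfreq[[p]][[substring(cd, p, p)]], 0))
  }, 0)
  pi / sum(pi)
}

## ---- model specs and class structure ----------------------------------

CODON_MODELS <- c("M0", "branch2", "M1a", "M2a", "M7", "M8")

#' Specify a codon substitution model
#'
#' @param model one of `"M0"`, `"branch2"` (two-ratio branch model),
#'   `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param kappa transition/transversion ratio.
#' @param omega single dN/dS (M0).
#' @param omega_bg,omega_fg background/foreground dN/dS (branch2).
#' @param foreground tip labels or edge indices of foreground branches
#'   (branch2).
#' @param omega0,p0 conserved-class dN/dS (< 1) and its weight
#'   (M1a/M2a; in M8 `p0` is the beta component's weight).
#' @param p1 neutral-class weight (M2a).
#' @param omega2 positively selected dN/dS (> 1; M2a).
#' @param p_beta,q_beta beta distribution shape parameters (M7/M8).
#' @param omega_s selected-class dN/dS (> 1; M8).
#' @param K_beta number of equal-probability beta discretisation
#'   categories (default 10).
#' @param pi codon frequencies (default F3x4 from the data at fit time,
#'   uniform for simulation).
#' @return Object of class `codon_model_spec`.
#' @export
codon_model_spec <- function(model, kappa = 2, omega = 0.5,
                             omega_bg = 0.2, omega_fg = 1.5,
                             foreground = NULL,
                             omega0 = 0.1, p0 = 0.7, p1 = 0.2, omega2 = 3,
                             p_beta = 0.5, q_beta = 1.5, omega_s = 3,
                             K_beta = 10L, pi = NULL) {
  model <- match.arg(model, CODON_MODELS)
  stopifnot(kappa > 0)
  spec <- list(model = model, kappa = kappa, K_beta = as.integer(K_beta),
               pi = pi)
  spec <- switch(model,
    M0 = c(spec, list(omega = omega)),
    branch2 = {
      c(spec, list(omega_bg = omega_bg, omega_fg = omega_fg,
                   foreground = foreground))
    },
    M1a = c(spec, list(omega0 = omega0, p0 = p0)),
    M2a = c(spec, list(omega0 = omega0, p0 = p0, p1 = p1, omega2 = omega2)),
    M7 = c(spec, list(p_beta = p_beta, q_beta = q_beta)),
    M8 = c(spec, list(p_beta = p_beta, q_beta = q_beta, p0 = p0,
                      omega_s = omega_s)))
  class(spec) <- "codon_model_spec"
  spec
}

## Site-class omegas and weights for a spec.
model_classes <- function(spec) {
  K <- spec$K_beta
  switch(spec$model,
    M0 = list(omegas = spec$omega, weights = 1),
    branch2 = list(omegas = NA, weights = 1),  # per-branch, handled separately
    M1a = list(omegas = c(spec$omega0, 1),
               weights = c(spec$p0, 1 - spec$p0)),
    M2a = list(omegas = c(spec$omega0, 1, spec$omega2),
               weights = c(spec$p0, spec$p1, 1 - spec$p0 - spec$p1)),
    M7 = list(omegas = qbeta((seq_len(K) - 0.5) / K, spec$p_beta, spec$q_beta),
              weights = rep(1 / K, K)),
    M8 = list(omegas = c(qbeta((seq_len(K) - 0.5) / K, spec$p_beta,
                               spec$q_beta), spec$omega_s),
              weights = c(rep(spec$p0 / K, K), 1 - spec$p0)))
}

## Build the scaled Q slices, per-edge/per-class slice index and weights
## for a spec on a tree with `nedge` edges.
build_model_matrices <- function(spec, nedge, pi, foreground_edges = NULL) {
  ct <- codon_tables()
  eps <- 1e-6
  if (spec$model == "branch2") {
    if (is.null(foreground_edges) || !length(foreground_edges))
      stop("branch2 requires a nonempty foreground branch set")
    Qb <- gy94_Q_raw(spec$kappa, max(spec$omega_bg, eps), pi, ct)
    Qf <- gy94_Q_raw(spec$kappa, max(spec$omega_fg, eps), pi, ct)
    ## each branch's Q scaled to one expected substitution per unit length
    Qb <- Qb / (-sum(pi * diag(Qb)))
    Qf <- Qf / (-sum(pi * diag(Qf)))
    Qcube <- array(c(Qb, Qf), dim = c(ct$n, ct$n, 2L))
    Qidx <- matrix(1L, nedge, 1L)
    Qidx[foreground_edges, 1L] <- 2L
    return(list(Qcube = Qcube, Qidx = Qidx, weights = 1,
                omegas = c(spec$omega_bg, spec$omega_fg)))
  }
  cls <- model_classes(spec)
  omegas <- pmax(cls$omegas, eps)
  K <- length(omegas)
  Qs <- lapply(omegas, function(w) gy94_Q_raw(spec$kappa, w, pi, ct))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  cbar <- sum(cls$weights * rates)   # mixture-average rate
  Qcube <- array(unlist(Qs), dim = c(ct$n, ct$n, K)) / cbar
  Qidx <- matrix(seq_len(K), nedge, K, byrow = TRUE)
  list(Qcube = Qcube, Qidx = Qidx, weights = cls$weights, omegas = omegas)
}

resolve_foreground <- function(tree, foreground) {
  if (is.null(foreground)) return(integer(0))
  if (is.numeric(foreground)) return(as.integer(foreground))
  idx <- match(foreground, tree$tip.label)
  if (anyNA(idx)) stop("unknown foreground tip(s): ",
                       paste(foreground[is.na(idx)], collapse = ", "))
  which(tree$edge[, 2L] %in% idx)
}

## ---- likelihood --------------------------------------------------------

## Per-site per-class log-likelihood matrix (K x nsites).
siteclass_loglik <- function(ca, tree, spec, pi, foreground_edges = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  if (!setequal(tr$tip.label, ca$taxa))
    stop("tree leaves and alignment taxa differ")
  states <- ca$states[tr$tip.label, , drop = FALSE]
  states[is.na(states)] <- 0L
  bm <- build_model_matrices(spec, nrow(tr$edge), pi, foreground_edges)
  ll <- codon_class_siteloglik(tr$edge, tr$edge.length, states - 1L,
                               bm$Qcube, bm$Qidx, pi)
  attr(ll, "weights") <- bm$weights
  attr(ll, "omegas") <- bm$omegas
  ll
}

#' Codon-model log-likelihood
#'
#' Felsenstein pruning over `P(t) = exp(Qt)` with site-class mixtures
#' averaged per site; alignment gaps are missing data (partial likelihood
#' 1 for all states). Branch lengths are expected substitutions per codon
#' site.
#'
#' @param ca a [codon_alignment].
#' @param tree [ape::phylo] with the alignment's taxa as leaves.
#' @param spec a [codon_model_spec].
#' @param pi codon frequencies; default F3x4 from the alignment.
#' @return Log-likelihood (scalar) with the per-site per-class matrix in
#'   `attr(, "siteclass")`.
#' @export
log_likelihood <- function(ca, tree, spec, pi = NULL) {
  pi <- pi %||% spec$pi %||% f3x4_frequencies(ca)
  fg <- if (spec$model == "branch2")
    resolve_foreground(tree, spec$foreground) else NULL
  ll <- siteclass_loglik(ca, tree, spec, pi, fg)
  w <- attr(ll, "weights")
  ## logsumexp over classes per site
  m <- apply(ll, 2L, max)
  lnl_site <- m + log(colSums(exp(sweep(ll, 2L, m, "-")) * w))
  structure(sum(lnl_site), siteclass = ll, site_loglik = lnl_site)
}

## ---- fitting -----------------------------------------------------------

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

## Transformed-parameter layout per model; all parameters live on an
## unconstrained-ish scale with wide box bounds for L-BFGS-B.
par_layout <- function(model) {
  switch(model,
    M0 = list(names = c("lkappa", "lomega"),
              lower = c(log(0.05), log(1e-4)),
              upper = c(log(50), log(999))),
    branch2 = list(names = c("lkappa", "lomega_bg", "lomega_fg"),
                   lower = c(log(0.05), log(1e-4), log(1e-4)),
                   upper = c(log(50), log(999), log(999))),
    M1a = list(names = c("lkappa", "lgt_omega0", "lgt_p0"),
               lower = c(log(0.05), -14, -14),
               upper = c(log(50), 14, 14)),
    M2a = list(names = c("lkappa", "lgt_omega0", "lgt_q0", "lgt_q1",
                         "lomega2m1"),
               lower = c(log(0.05), -14, -14, -14, log(1e-4)),
               upper = c(log(50), 14, 14, 14, log(998))),
    M7 = list(names = c("lkappa", "lp", "lq"),
              lower = c(log(0.05), log(0.005), log(0.005)),
              upper = c(log(50), log(99), log(99))),
    M8 = list(names = c("lkappa", "lp", "lq", "lgt_p0", "lomegasm1"),
              lower = c(log(0.05), log(0.005), log(0.005), -14, log(1e-4)),
              upper = c(log(50), log(99), log(99), 14, log(998))))
}

decode_spec <- function(model, th, K_beta, foreground) {
  switch(model,
    M0 = codon_model_spec("M0", kappa = exp(th[1L]), omega = exp(th[2L])),
    branch2 = codon_model_spec("branch2", kappa = exp(th[1L]),
                               omega_bg = exp(th[2L]), omega_fg = exp(th[3L]),
                               foreground = foreground),
    M1a = codon_model_spec("M1a", kappa = exp(th[1L]),
                           omega0 = inv_logit(th[2L]),
                           p0 = inv_logit(th[3L])),
    M2a = {
      q0 <- inv_logit(th[3L]); q1 <- inv_logit(th[4L])
      codon_model_spec("M2a", kappa = exp(th[1L]),
                       omega0 = inv_logit(th[2L]),
                       p0 = q0, p1 = (1 - q0) * q1,
                       omega2 = 1 + exp(th[5L]))
    },
    M7 = codon_model_spec("M7", kappa = exp(th[1L]), p_beta = exp(th[2L]),
                          q_beta = exp(th[3L]), K_beta = K_beta),
    M8 = codon_model_spec("M8", kappa = exp(th[1L]), p_beta = exp(th[2L]),
                          q_beta = exp(th[3L]), p0 = inv_logit(th[4L]),
                          omega_s = 1 + exp(th[5L]), K_beta = K_beta))
}

default_start <- function(model) {
  switch(model,
    M0 = c(log(2), log(0.4)),
    branch2 = c(log(2), log(0.3), log(0.8)),
    M1a = c(log(2), logit(0.2), logit(0.7)),
    M2a = c(log(2), logit(0.2), logit(0.65), logit(0.8), log(1.5)),
    M7 = c(log(2), log(0.5), log(1.2)),
    M8 = c(log(2), log(0.5), log(1.2), logit(0.9), log(1.5)))
}

## Starting parameters for `model` taken from a previous fit, typically the
## nested null (M0 -> branch2, M1a -> M2a, M7 -> M8): the extra positively
## selected class starts with near-zero weight, so the start point is
## likelihood-equivalent to the null optimum and the alternative fit can
## only improve on it.
encode_start <- function(model, fit) {
  sp <- fit$parameters
  clamp01 <- function(p) min(max(p, 1e-6), 1 - 1e-6)
  th <- switch(model,
    M0 = if (fit$model == "M0") c(log(sp$kappa), log(sp$omega)),
    branch2 = switch(fit$model,
      branch2 = c(log(sp$kappa), log(sp$omega_bg), log(sp$omega_fg)),
      M0 = c(log(sp$kappa), log(sp$omega), log(sp$omega)),
      NULL),
    M1a = if (fit$model == "M1a")
      c(log(sp$kappa), logit(clamp01(sp$omega0)), logit(clamp01(sp$p0))),
    M2a = switch(fit$model,
      M2a = {
        q0 <- clamp01(sp$p0); q1 <- clamp01(sp$p1 / max(1 - sp$p0, 1e-9))
        c(log(sp$kappa), logit(clamp01(sp$omega0)), logit(q0), logit(q1),
          log(max(sp$omega2 - 1, 1e-4)))
      },
      M1a = {
        q0 <- clamp01(sp$p0 * 0.9999)
        q1 <- clamp01(0.9999 * (1 - sp$p0) / max(1 - q0, 1e-9))
        c(log(sp$kappa), logit(clamp01(sp$omega0)), logit(q0), logit(q1),
          log(1))  # omega2 starts at 2
      },
      NULL),
    M7 = if (fit$model == "M7")
      c(log(sp$kappa), log(sp$p_beta), log(sp$q_beta)),
    M8 = switch(fit$model,
      M8 = c(log(sp$kappa), log(sp$p_beta), log(sp$q_beta),
             logit(clamp01(sp$p0)), log(max(sp$omega_s - 1, 1e-4))),
      M7 = c(log(sp$kappa), log(sp$p_beta), log(sp$q_beta),
             logit(0.995), log(1)),
      NULL))
  th
}

#' Fit a codon model by maximum likelihood
#'
#' Maximises the log-likelihood over kappa, the model's omega parameters
#' and all branch lengths by bounded quasi-Newton (L-BFGS-B) from
#' `n_starts` starting points (the first from standard defaults and the
#' input branch lengths, the rest jittered under seeds derived from
#' `seed`), keeping the best converged fit. Deterministic given `seed`.
#'
#' @param ca a [codon_alignment].
#' @param tree starting tree with branch lengths (expected substitutions
#'   per codon).
#' @param model one of `"M0"`, `"branch2"`, `"M1a"`, `"M2a"`, `"M7"`,
#'   `"M8"`.
#' @param foreground foreground branches (branch2 only): tip labels or
#'   edge indices.
#' @param pi codon frequencies; default F3x4 from the alignment.
#' @param n_starts number of optimisation starts (default 3).
#' @param init optional `codon_fit` of this model or its nested null
#'   (M0 for branch2, M1a for M2a, M7 for M8) providing the first start
#'   point; the extra class starts with near-zero weight so the start is
#'   likelihood-equivalent to the null optimum, which guarantees
#'   `lnL(alternative) >= lnL(null)`.
#' @param seed seed fixing the start jitter.
#' @param K_beta beta discretisation categories (default 10).
#' @param control passed to [stats::optim] (maxit default 300).
#' @return Object of class `codon_fit`: `lnL`, `kappa`, `parameters`
#'   (decoded spec), `omegas`, `weights`, `tree` (fitted branch lengths),
#'   `np` (free parameter count), `posterior` (site x class posterior
#'   matrix, site models), `trace` (per-start convergence records).
#' @export
fit_codon_model <- function(ca, tree, model = CODON_MODELS,
                            foreground = NULL, pi = NULL, n_starts = 3L,
                            init = NULL, seed = 1L, K_beta = 10L,
                            control = list()) {
  model <- match.arg(model)
  pi <- pi %||% f3x4_frequencies(ca)
  tr <- ape::reorder.phylo(tree, "postorder")
  if (!setequal(tr$tip.label, ca$taxa))
    stop("tree leaves and alignment taxa differ")
  fg <- if (model == "branch2") {
    fge <- resolve_foreground(tr, foreground)
    if (!length(fge)) stop("branch2 requires a nonempty foreground set")
    fge
  } else NULL
  lay <- par_layout(model)
  nedge <- nrow(tr$edge)
  npar <- length(lay$names)
  lower <- c(lay$lower, rep(log(1e-6), nedge))
  upper <- c(lay$upper, rep(log(20), nedge))
  states <- ca$states[tr$tip.label, , drop = FALSE]
  states[is.na(states)] <- 0L
  states <- states - 1L

  obj <- function(th) {
    spec <- decode_spec(model, th[seq_len(npar)], K_beta, foreground)
    bl <- exp(th[-seq_len(npar)])
    bm <- tryCatch(build_model_matrices(spec, nedge, pi, fg),
                   error = function(e) NULL)
    if (is.null(bm)) return(1e10)
    ll <- codon_class_siteloglik(tr$edge, bl, states, bm$Qcube, bm$Qidx, pi)
    m <- apply(ll, 2L, max)
    lnl <- sum(m + log(colSums(exp(sweep(ll, 2L, m, "-")) * bm$weights)))
    if (!is.finite(lnl)) return(1e10)
    -lnl
  }

  bl0 <- pmax(tr$edge.length, 1e-4)
  th_init <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "codon_fit"))
    th_init <- encode_start(model, init)
    if (is.null(th_init))
      stop("cannot initialise a ", model, " fit from a ", init$model, " fit")
    if (identical(init$tree$edge, tr$edge))
      bl0 <- pmax(init$tree$edge.length, 1e-6)
  }
  start0 <- c(th_init %||% default_start(model), log(bl0))
  start0 <- pmin(pmax(start0, lower), upper)
  ctl <- utils::modifyList(list(maxit = 300), control)
  best <- NULL
  trace <- list()
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1L) start0 else with_seed(
      derive_seed(seed, paste0(model, s)),
      pmin(pmax(start0 + rnorm(length(start0), 0, 0.5), lower), upper))
    fit <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) { trace[[s]] <- list(ok = FALSE); next }
    trace[[s]] <- list(ok = TRUE, value = -fit$value,
                       convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("codon model fit failed to converge after ", n_starts,
         " start(s); trace recorded")
  th <- best$par
  spec <- decode_spec(model, th[seq_len(npar)], K_beta, foreground)
  spec$pi <- pi
  tr$edge.length <- exp(th[-seq_len(npar)])
  bm <- build_model_matrices(spec, nedge, pi, fg)
  ll <- codon_class_siteloglik(tr$edge, tr$edge.length, states, bm$Qcube,
                               bm$Qidx, pi)
  posterior <- NULL
  if (length(bm$weights) > 1L) {
    wl <- exp(sweep(ll, 2L, apply(ll, 2L, max), "-")) * bm$weights
    posterior <- t(sweep(wl, 2L, colSums(wl), "/"))
    colnames(posterior) <- paste0("class", seq_along(bm$weights))
  }
  structure(
    list(model = model, lnL = -best$value, kappa = spec$kappa,
         parameters = spec, omegas = bm$omegas, weights = bm$weights,
         tree = tr, pi = pi, np = length(th), posterior = posterior,
         foreground = fg, trace = trace, convergence = best$convergence),
    class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> ", x$model, ": lnL = ", format(x$lnL, digits = 10),
      ", kappa = ", round(x$kappa, 3), "\n", sep = "")
  if (x$model == "branch2") {
    cat("  omega (background/foreground): ",
        round(x$omegas[1L], 4), " / ", round(x$omegas[2L], 4), "\n", sep = "")
  } else {
    cat("  site classes:\n")
    for (k in seq_along(x$weights))
      cat(sprintf("    omega = %8.4f  weight = %.4f\n",
                  x$omegas[k], x$weights[k]))
  }
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  sp <- object$parameters
  keep <- setdiff(names(sp), c("model", "K_beta", "pi", "foreground"))
  unlist(sp[keep])
}

#' Likelihood-ratio test between nested codon models
#'
#' `p` is the chi-square upper tail of `2 (lnL_alt - lnL_null)` with `df`
#' degrees of freedom; a negative statistic (numerical noise) is clamped
#' to zero.
#'
#' @param lnL_null,lnL_alt log-likelihoods (or `codon_fit` objects).
#' @param df degrees of freedom (2 for M1a-vs-M2a and M7-vs-M8, 1 for
#'   M0-vs-branch2).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(lnL_null, lnL_alt, df) {
  if (inherits(lnL_null, "codon_fit")) lnL_null <- lnL_null$lnL
  if (inherits(lnL_alt, "codon_fit")) lnL_alt <- lnL_alt$lnL
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Naive-empirical-Bayes positively selected sites
#'
#' Flags sites whose posterior probability of belonging to an `omega > 1`
#' class (at the fitted parameter values) exceeds `threshold`. Applies to
#' M2a and M8 fits; models without a positively selected class error.
#'
#' @param fit a [fit_codon_model] result under M2a or M8.
#' @param threshold posterior probability cutoff (default 0.9).
#' @return `data.frame`: `site`, `posterior_positive`, `selected`.
#' @export
neb_sites <- function(fit, threshold = 0.9) {
  if (!fit$model %in% c("M2a", "M8"))
    stop("site identification requires an M2a or M8 fit")
  pos_classes <- which(fit$omegas > 1)
  pp <- rowSums(fit$posterior[, pos_classes, drop = FALSE])
  data.frame(site = seq_along(pp), posterior_positive = pp,
             selected = pp > threshold)
}

## ---- simulation --------------------------------------------------------

#' Simulate a codon alignment under a GY94 model
#'
#' Evolves sequences root-to-tips: the root codon of each site is drawn
#' from `pi`, each site's omega class is drawn once and fixed across the
#' tree, and each branch applies `P(t) = exp(Qt)` with the same scaled
#' matrices the likelihood uses.
#'
#' @param tree [ape::phylo] with branch lengths (expected substitutions
#'   per codon).
#' @param spec a [codon_model_spec] (its `pi` is used; default uniform).
#' @param n_codons number of codon sites.
#' @param seed RNG seed.
#' @return list: `alignment` ([codon_alignment]), `site_class` (true
#'   class per site), `omegas`, `weights`, `spec`.
#' @export
simulate_codon_alignment <- function(tree, spec, n_codons, seed = 1L) {
  ct <- codon_tables()
  pi <- spec$pi %||% rep(1 / ct$n, ct$n)
  tr <- ape::reorder.phylo(tree, "postorder")
  fg <- if (spec$model == "branch2")
    resolve_foreground(tr, spec$foreground) else NULL
  bm <- build_model_matrices(spec, nrow(tr$edge), pi, fg)
  K <- length(bm$weights)
  with_seed(seed, {
    z <- sample.int(K, n_codons, replace = TRUE, prob = bm$weights)
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    seqs <- matrix(NA_integer_, nnode, n_codons)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(ct$n, n_codons, replace = TRUE, prob = pi)
    ## precompute P per (edge, class) via symmetric eigendecomposition
    d <- sqrt(pi)
    eigs <- lapply(seq_len(dim(bm$Qcube)[3L]), function(m) {
      S <- diag(d) %*% bm$Qcube[, , m] %*% diag(1 / d)
      eigen((S + t(S)) / 2, symmetric = TRUE)
    })
    Pmat <- function(m, t) {
      e <- eigs[[m]]
      P <- diag(1 / d) %*% (e$vectors %*% (exp(e$values * t) * t(e$vectors))) %*% diag(d)
      P[P < 0] <- 0
      P / rowSums(P)
    }
    ## preorder = reverse postorder: parents before children
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      t_e <- tr$edge.length[e]
      for (k in seq_len(K)) {
        sites_k <- which(z == k)
        if (!length(sites_k)) next
        P <- Pmat(bm$Qidx[e, k], t_e)
        from <- seqs[par, sites_k]
        seqs[ch, sites_k] <- vapply(from, function(x)
          sample.int(ct$n, 1L, prob = P[x, ]), 0L)
      }
    }
    tipseq <- vapply(seq_len(ntip), function(i)
      paste(ct$codons[seqs[i, ]], collapse = ""), "")
    names(tipseq) <- tr$tip.label
    list(alignment = codon_alignment(tipseq), site_class = z,
         omegas = bm$omegas, weights = bm$weights, spec = spec)
  })
}
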