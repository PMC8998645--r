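## FPKM computation, a conditional negative-binomial exact test for
## differential expression, and DEG calling at |log2FC| >= 1.5 and
## FDR <= 0.05. The NB exact test is a documented stand-in for an edgeR
## analysis: it uses a single moment-estimated common dispersion and
## conditions on the pooled per-gene sum; equivalence to edgeR is not
## claimed. Gene length is the spliced CDS length.

#' Compute FPKM from a count matrix
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (library_size[s] * gene_length_nt[g])`
#' (fragments per kilobase of transcript per million mapped fragments).
#'
#' @param cm a [count_matrix].
#' @param sample_labels optional named vector of tissue/condition labels.
#' @return Object of class `expression_profile`: `fpkm` matrix plus labels.
#' @export
compute_fpkm <- function(cm, sample_labels = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  fpkm <- sweep(sweep(cm$counts * 1e9, 2L, cm$library_size, "/"),
                1L, cm$gene_length_nt, "/")
  structure(list(fpkm = fpkm,
                 sample_labels = sample_labels %||%
                   setNames(colnames(cm$counts), colnames(cm$counts))),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", nrow(x$fpkm), " genes x ", ncol(x$fpkm),
      " samples\n", sep = "")
  invisible(x)
}

#' Long-format (heatmap-ready) expression table
#'
#' @param ep an [compute_fpkm] result.
#' @return `data.frame` with `gene_id`, `sample`, `label`, `fpkm`.
#' @export
expression_long <- function(ep) {
  data.frame(gene_id = rep(rownames(ep$fpkm), ncol(ep$fpkm)),
             sample = rep(colnames(ep$fpkm), each = nrow(ep$fpkm)),
             label = rep(unname(ep$sample_labels[colnames(ep$fpkm)]),
                         each = nrow(ep$fpkm)),
             fpkm = as.vector(ep$fpkm))
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' For equal-sized libraries the conditional likelihood of a gene's
#' replicate counts given their group sum is free of the gene's mean and
#' depends only on the dispersion; the common dispersion maximises the
#' summed conditional log-likelihood across genes and groups (the
#' standard qCML approach for a common dispersion). Returns 0 when the
#' data look Poisson or no group has replicates.
#'
#' @param counts genes x samples matrix.
#' @param group factor/vector of group memberships over columns.
#' @return Non-negative scalar dispersion.
#' @export
estimate_common_dispersion <- function(counts, group) {
  group <- as.factor(group)
  mats <- lapply(levels(group), function(g)
    counts[, group == g, drop = FALSE])
  mats <- Filter(function(m) ncol(m) >= 2L, mats)
  if (!length(mats)) return(0)
  cond_ll <- function(log_phi) {
    r <- exp(-log_phi)  # size = 1/phi
    tot <- 0
    for (m in mats) {
      n <- ncol(m)
      z <- rowSums(m)
      keep <- z > 0
      if (!any(keep)) next
      y <- m[keep, , drop = FALSE]
      zz <- z[keep]
      tot <- tot + sum(lgamma(y + r)) - length(zz) * n * lgamma(r) -
        sum(lgamma(zz + n * r)) + length(zz) * lgamma(n * r)
    }
    tot
  }
  opt <- optimize(cond_ll, interval = log(c(1e-6, 10)), maximum = TRUE)
  ## a maximum at the lower boundary means Poisson-like data
  if (opt$maximum <= log(1e-6) + 0.05 ||
      cond_ll(log(1e-6)) >= opt$objective) return(0)
  exp(opt$maximum)
}

#' Conditional NB exact test for one gene
#'
#' Two-sided exact test of equal means between two replicate groups,
#' conditioning on the pooled sum `t` under a negative binomial with
#' common dispersion `phi`: group sums are treated as
#' `NB(n_g * mu, phi / n_g)` and the conditional probability of each split
#' of `t` is computed; the p-value sums the probabilities of all splits no
#' more probable than the observed one. `phi = 0` reduces to the exact
#' binomial (Poisson) test. An all-zero gene returns p = 1 by convention.
#'
#' @param counts_a,counts_b replicate count vectors.
#' @param dispersion common NB dispersion (`>= 0`).
#' @param lib_a,lib_b optional library sizes per replicate; the expected
#'   split is proportional to the group totals (defaults to equal
#'   libraries).
#' @return p-value in `[0, 1]`.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0,
                          lib_a = NULL, lib_b = NULL) {
  stopifnot(length(counts_a) >= 1L, length(counts_b) >= 1L, dispersion >= 0)
  sa <- sum(counts_a); sb <- sum(counts_b)
  t <- sa + sb
  if (t == 0L) return(1)
  wa <- if (is.null(lib_a)) length(counts_a) else sum(lib_a)
  wb <- if (is.null(lib_b)) length(counts_b) else sum(lib_b)
  pr <- wa / (wa + wb)
  x <- 0:t
  logp <- if (dispersion == 0) {
    dbinom(x, t, pr, log = TRUE)
  } else {
    ## group-sum NB sizes: sum of n iid NB(mu, phi) is NB(n*mu, phi/n)
    size_a <- length(counts_a) / dispersion
    size_b <- length(counts_b) / dispersion
    mu <- t  # null expected total: group means t*pr and t*(1-pr)
    la <- dnbinom(x, size = size_a, mu = mu * pr, log = TRUE)
    lb <- dnbinom(t - x, size = size_b, mu = mu * (1 - pr), log = TRUE)
    lp <- la + lb
    lp - log(sum(exp(lp - max(lp)))) - max(lp)
  }
  obs <- logp[sa + 1L]
  p <- sum(exp(logp[logp <= obs + 1e-9]))
  min(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure (wraps [stats::p.adjust]).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return Adjusted FDR values.
#' @export
bh_adjust <- function(p_values) p.adjust(p_values, method = "BH")

#' Differential-expression test across a count matrix
#'
#' Per gene: conditional NB exact test between the two groups (common
#' dispersion moment-estimated across genes when not supplied), log2 fold
#' change from mean FPKM with pseudocount `c`:
#' `log2((mean FPKM_b + c) / (mean FPKM_a + c))`, and BH-adjusted FDR.
#'
#' @param cm a [count_matrix].
#' @param samples_a,samples_b column names (or indices) of the two groups.
#' @param dispersion optional common dispersion; estimated when `NULL`.
#' @param pseudocount FPKM pseudocount for the fold change (default 0.01).
#' @return `data.frame` of class `de_result`: `gene_id`, `log2fc`,
#'   `p_value`, `fdr`, `mean_fpkm_a`, `mean_fpkm_b`, with the dispersion
#'   used in `attr(, "dispersion")`.
#' @export
de_test <- function(cm, samples_a, samples_b, dispersion = NULL,
                    pseudocount = 0.01) {
  stopifnot(inherits(cm, "count_matrix"))
  A <- cm$counts[, samples_a, drop = FALSE]
  B <- cm$counts[, samples_b, drop = FALSE]
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(
      cbind(A, B), rep(c("a", "b"), c(ncol(A), ncol(B))))
  fpkm <- compute_fpkm(cm)$fpkm
  ma <- rowMeans(fpkm[, samples_a, drop = FALSE])
  mb <- rowMeans(fpkm[, samples_b, drop = FALSE])
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  p <- vapply(seq_len(nrow(A)), function(g)
    nb_exact_test(A[g, ], B[g, ], dispersion,
                  lib_a = cm$library_size[samples_a],
                  lib_b = cm$library_size[samples_b]),
    numeric(1))
  out <- data.frame(gene_id = rownames(cm$counts), log2fc = log2fc,
                    p_value = p, fdr = bh_adjust(p),
                    mean_fpkm_a = ma, mean_fpkm_b = mb)
  rownames(out) <- NULL
  attr(out, "dispersion") <- dispersion
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flag differentially expressed genes
#'
#' `significant_de` requires both `|log2FC| >= lfc_threshold` and
#' `FDR <= alpha`; `upregulated` additionally requires
#' `log2FC > lfc_threshold`. With `fc_only = TRUE` the FDR condition is
#' dropped (the fold-change-only upregulation rule used for infection
#' contrasts).
#'
#' @param de a [de_test] result (needs `log2fc` and `fdr` columns).
#' @param lfc_threshold log2 fold-change threshold (default 1.5).
#' @param alpha FDR threshold (default 0.05).
#' @param fc_only drop the FDR condition.
#' @return `de` with logical columns `significant_de` and `upregulated`
#'   appended.
#' @export
call_degs <- function(de, lfc_threshold = 1.5, alpha = 0.05, fc_only = FALSE) {
  fdr_ok <- if (fc_only) TRUE else de$fdr <= alpha
  de$significant_de <- abs(de$log2fc) >= lfc_threshold & fdr_ok
  de$upregulated <- de$log2fc > lfc_threshold & fdr_ok
  de
}
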