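## The core algorithm: compare the exon-intron structures of sibling
## paralog/ortholog gene pairs and classify the mechanism(s) of structural
## divergence into gain/loss of exon or intron, exonization/
## pseudoexonization, and intraexonic insertion/deletion. Mechanisms are
## not mutually exclusive; a pair may carry several. Pseudoexonization is
## reported under the same label as exonization: assigning polarity
## (exon -> non-exon vs non-exon -> exon) would require an outgroup.

MECHANISMS <- c("GAIN_LOSS", "EXONIZATION_PSEUDOEXONIZATION", "INTRAEXONIC_INDEL")

#' Thresholds for structure-divergence classification
#'
#' @param tau_overlap reciprocal alignment-column overlap for two exons to
#'   be called homologous (default 0.5).
#' @param min_indel_aa minimum gap-run length (aligned amino-acid columns)
#'   inside a matched exon pair to call an intraexonic indel (default 2).
#' @param exonization_id_min,exonization_cov_min identity and coverage
#'   required for an orphan exon to be aligned "with confidence" to the
#'   partner's non-exonic sequence (defaults 0.40 / 0.60; DNA local
#'   alignment).
#' @param min_orphan_aa orphan exons shorter than this are ignored as
#'   alignment noise (default 10 aa).
#' @param flank flanking sequence (nt) on each side of a gene counted as
#'   non-exonic search space (default 5000).
#' @param min_flank_aln minimum aligned non-gap columns on each side of an
#'   intraexonic gap run (default 5).
#' @return Named list of parameters.
#' @export
divergence_params <- function(tau_overlap = 0.5, min_indel_aa = 2L,
                              exonization_id_min = 0.40,
                              exonization_cov_min = 0.60,
                              min_orphan_aa = 10L, flank = 5000L,
                              min_flank_aln = 5L,
                              min_match_identity = 0.2,
                              rescue_identity = 0.3) {
  stopifnot(tau_overlap > 0, tau_overlap <= 1, min_indel_aa >= 1,
            exonization_id_min >= 0, exonization_id_min <= 1,
            exonization_cov_min >= 0, exonization_cov_min <= 1,
            min_orphan_aa >= 0, flank >= 0,
            min_match_identity >= 0, min_match_identity <= 1,
            rescue_identity >= 0, rescue_identity <= 1)
  list(tau_overlap = tau_overlap, min_indel_aa = as.integer(min_indel_aa),
       exonization_id_min = exonization_id_min,
       exonization_cov_min = exonization_cov_min,
       min_orphan_aa = as.integer(min_orphan_aa), flank = as.integer(flank),
       min_flank_aln = as.integer(min_flank_aln),
       min_match_identity = min_match_identity,
       rescue_identity = rescue_identity)
}

#' Extract sibling pairs (cherries) from a gene tree
#'
#' A sibling pair is a cherry: two leaves sharing an immediate ancestor.
#' These are the pairs of homologs with highest sequence similarity on the
#' tree, the unit of comparison for structure divergence. The relation is
#' `paralog` when both genes carry the same species tag and `ortholog`
#' otherwise.
#'
#' @param tree an [ape::phylo] gene tree (or newick text/path).
#' @param genes_of_interest optional id set; pairs are kept only when both
#'   members are in the set.
#' @param species_fun function mapping a leaf label to its species tag;
#'   the default takes the prefix before the first underscore and errors
#'   on labels without one.
#' @return List of `sibling_pair` objects: `a`, `b`, `relation`, `source`.
#' @export
extract_sibling_pairs <- function(tree, genes_of_interest = NULL,
                                  species_fun = default_species_tag) {
  if (!inherits(tree, "phylo")) tree <- parse_newick(tree)
  ntip <- length(tree$tip.label)
  pairs <- list()
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (node in names(children)) {
    ch <- children[[node]]
    tips <- ch[ch <= ntip]
    if (length(ch) == 2L && length(tips) == 2L) {
      a <- tree$tip.label[tips[1L]]; b <- tree$tip.label[tips[2L]]
      if (!is.null(genes_of_interest) &&
          !(a %in% genes_of_interest && b %in% genes_of_interest)) next
      rel <- if (identical(species_fun(a), species_fun(b))) "paralog" else "ortholog"
      pairs[[length(pairs) + 1L]] <- structure(
        list(a = a, b = b, relation = rel, source = "tree_cherry"),
        class = "sibling_pair")
    }
  }
  pairs
}

default_species_tag <- function(label) {
  if (!grepl("_", label))
    stop("leaf '", label, "' carries no species tag (expected 'species_gene')")
  sub("_.*$", "", label)
}

#' @export
print.sibling_pair <- function(x, ...) {
  cat("<sibling_pair> ", x$a, " - ", x$b, "  (", x$relation, ", ",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Match homologous exons between two gene models
#'
#' Exon spans are mapped onto the global protein alignment with
#' [map_exons_to_alignment]; exons are matched 1:1 when their column spans
#' overlap reciprocally by at least `tau_overlap` of each span, greedily in
#' 5'-to-3' order with crossing matches forbidden. Unmatched exons become
#' orphans; an orphan whose span lies mostly inside a *matched* partner
#' exon's span is flagged a split candidate (the intron gain/loss pattern,
#' where one exon corresponds to two).
#'
#' Two guards absorb the ambiguity of a single global alignment around
#' large insertions: a matched pair whose aligned residues show only
#' random-level identity (`< min_match_identity`) is demoted to orphans,
#' and two orphans whose exon sequences align directly with clear
#' homology (identity `>= rescue_identity`) are rescued into a match
#' (non-crossing order preserved).
#'
#' @param gm_a,gm_b [gene_model]s.
#' @param aln global protein `alignment_result` of `gm_a$protein` (as `a`)
#'   vs `gm_b$protein` (as `b`); computed if `NULL`.
#' @param tau_overlap reciprocal overlap threshold (default 0.5).
#' @param min_match_identity identity below which a matched pair is
#'   demoted (default 0.2, midway between random protein identity of
#'   about 0.07 and the most diverged homologous exons considered).
#' @param rescue_identity direct-alignment identity required to rescue an
#'   orphan pair (default 0.3).
#' @return Object of class `exon_correspondence`: `matched`
#'   (`data.frame` `exon_a`, `exon_b`, `overlap_a`, `overlap_b`,
#'   `identity`, `rescued`), `orphans_a`, `orphans_b` (exon indices),
#'   `split_candidates_a/b`, `spans_a`, `spans_b`, `aln`,
#'   `rescue_alignments` (direct alignments of rescued pairs).
#' @export
pair_exon_homology <- function(gm_a, gm_b, aln = NULL, tau_overlap = 0.5,
                               min_match_identity = 0.2,
                               rescue_identity = 0.3) {
  if (is.null(aln))
    aln <- global_align(gm_a$protein, gm_b$protein, protein_scoring())
  spans_a <- map_exons_to_alignment(gm_a, aln, "a")
  spans_b <- map_exons_to_alignment(gm_b, aln, "b")
  na <- nrow(spans_a); nb <- nrow(spans_b)
  ## per-column exon membership over residue columns only: overlap is
  ## counted on aligned residue pairs, so gap stretches inside an exon's
  ## interval do not dilute it
  ea <- column_exon_membership(aln$aligned_a, spans_a)
  eb <- column_exon_membership(aln$aligned_b, spans_b)
  n_res_a <- tabulate(ea[ea > 0L], na)
  n_res_b <- tabulate(eb[eb > 0L], nb)
  both <- ea > 0L & eb > 0L
  pair_counts <- matrix(0L, na, nb)
  if (any(both)) {
    tab <- table(factor(ea[both], seq_len(na)), factor(eb[both], seq_len(nb)))
    pair_counts[] <- as.integer(tab)
  }
  ## a pair qualifies when its reciprocal overlap reaches tau under either
  ## definition: aligned residue pairs (robust to gap scatter inside an
  ## exon's interval) or column intervals (robust to large intraexonic
  ## indels that leave few aligned pairs); the greedy non-crossing matcher
  ## below resolves any conflicts 5'->3'
  cand <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (n_res_a[i] == 0L || n_res_b[j] == 0L) next
    fa <- pair_counts[i, j] / n_res_a[i]
    fb <- pair_counts[i, j] / n_res_b[j]
    fiv <- c(0, 0)
    if (!is.na(spans_a$col_start[i]) && !is.na(spans_b$col_start[j])) {
      inter <- max(0L, min(spans_a$col_end[i], spans_b$col_end[j]) -
                     max(spans_a$col_start[i], spans_b$col_start[j]) + 1L)
      fiv <- c(inter / (spans_a$col_end[i] - spans_a$col_start[i] + 1L),
               inter / (spans_b$col_end[j] - spans_b$col_start[j] + 1L))
    }
    if ((fa >= tau_overlap && fb >= tau_overlap) ||
        (fiv[1L] >= tau_overlap && fiv[2L] >= tau_overlap))
      cand <- rbind(cand, c(i, j, max(fa, fiv[1L]), max(fb, fiv[2L])))
  }
  matched <- data.frame(exon_a = integer(0), exon_b = integer(0),
                        overlap_a = numeric(0), overlap_b = numeric(0),
                        identity = numeric(0), rescued = logical(0))
  ca_ch <- strsplit(aln$aligned_a, "")[[1L]]
  cb_ch <- strsplit(aln$aligned_b, "")[[1L]]
  pair_identity <- function(i, j) {
    cols <- which(ea == i & eb == j)
    if (!length(cols)) return(0)
    mean(ca_ch[cols] == cb_ch[cols])
  }
  if (!is.null(cand)) {
    ## greedy weighted matching: anchor on the candidate with the most
    ## aligned residue pairs first (ties 5'->3'), forbid crossings; this
    ## keeps a thin spurious interval overlap from displacing the
    ## residue-rich true pairing
    wt <- pair_counts[cand[, 1:2, drop = FALSE]]
    cand <- cand[order(-wt, cand[, 1L], cand[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (i %in% matched$exon_a || j %in% matched$exon_b) next
      if (any((matched$exon_a - i) * (matched$exon_b - j) < 0)) next
      id <- pair_identity(i, j)
      ## demote matches that are random-level or rest on too few aligned
      ## residue pairs to judge
      if (pair_counts[i, j] < 5L || id < min_match_identity) next
      matched <- rbind(matched, data.frame(
        exon_a = i, exon_b = j,
        overlap_a = cand[r, 3L], overlap_b = cand[r, 4L],
        identity = id, rescued = FALSE))
    }
    matched <- matched[order(matched$exon_a), , drop = FALSE]
  }
  orphans_a <- setdiff(seq_len(na), matched$exon_a)
  orphans_b <- setdiff(seq_len(nb), matched$exon_b)
  ## rescue orphan pairs that are directly alignable homologs misplaced by
  ## the global alignment
  rescue_alignments <- list()
  exon_prot <- function(gm, spans, i) {
    lo <- spans$aa_start[i] + 1L; hi <- spans$aa_end[i]
    if (hi < lo) return("")
    substring(gm$protein, lo, min(hi, nchar(gm$protein)))
  }
  for (i in orphans_a) {
    for (j in orphans_b) {
      pa <- exon_prot(gm_a, spans_a, i); pb <- exon_prot(gm_b, spans_b, j)
      if (nchar(pa) < 5L || nchar(pb) < 5L) next
      ## non-crossing with respect to the accepted matches
      before_a <- matched$exon_a < i; before_b <- matched$exon_b < j
      if (!identical(before_a, before_b)) next
      da <- global_align(pa, pb, protein_scoring())
      if (da$identity >= rescue_identity) {
        matched <- rbind(matched, data.frame(
          exon_a = i, exon_b = j, overlap_a = NA_real_, overlap_b = NA_real_,
          identity = da$identity, rescued = TRUE))
        rescue_alignments[[paste(i, j, sep = "_")]] <- da
        orphans_b <- setdiff(orphans_b, j)
        break
      }
    }
  }
  matched <- matched[order(matched$exon_a), , drop = FALSE]
  orphans_a <- setdiff(seq_len(na), matched$exon_a)
  orphans_b <- setdiff(seq_len(nb), matched$exon_b)
  ## split candidate: an orphan whose residues mostly align, at homolog-
  ## level identity, to residues of one matched partner exon (the
  ## one-exon-corresponds-to-two signature of intron gain/loss)
  split_a <- orphans_a[vapply(orphans_a, function(i) {
    if (n_res_a[i] == 0L || !length(matched$exon_b)) return(FALSE)
    j <- matched$exon_b[which.max(pair_counts[i, matched$exon_b])]
    pair_counts[i, j] / n_res_a[i] >= 0.5 &&
      pair_identity(i, j) >= min_match_identity
  }, logical(1))]
  split_b <- orphans_b[vapply(orphans_b, function(j) {
    if (n_res_b[j] == 0L || !length(matched$exon_a)) return(FALSE)
    i <- matched$exon_a[which.max(pair_counts[matched$exon_a, j])]
    pair_counts[i, j] / n_res_b[j] >= 0.5 &&
      pair_identity(i, j) >= min_match_identity
  }, logical(1))]
  structure(list(matched = matched, orphans_a = orphans_a,
                 orphans_b = orphans_b, split_candidates_a = split_a,
                 split_candidates_b = split_b, spans_a = spans_a,
                 spans_b = spans_b, aln = aln, tau_overlap = tau_overlap,
                 rescue_alignments = rescue_alignments),
            class = "exon_correspondence")
}

## Map each alignment column to the exon index whose residue occupies it
## (0 for gap columns / columns outside any exon).
column_exon_membership <- function(aligned, spans) {
  ch <- strsplit(aligned, "")[[1L]]
  out <- integer(length(ch))
  res_cols <- which(ch != "-")
  if (!length(res_cols)) return(out)
  ## residue r (1-based) belongs to exon i iff aa_start_i < r <= aa_end_i
  exon_of_res <- rep(0L, length(res_cols))
  for (i in seq_len(nrow(spans))) {
    lo <- spans$aa_start[i] + 1L; hi <- spans$aa_end[i]
    if (hi >= lo && lo <= length(res_cols))
      exon_of_res[lo:min(hi, length(res_cols))] <- i
  }
  out[res_cols] <- exon_of_res
  out
}

#' @export
print.exon_correspondence <- function(x, ...) {
  cat("<exon_correspondence> ", nrow(x$matched), " matched pair(s), ",
      length(x$orphans_a), "+", length(x$orphans_b), " orphan(s)",
      if (length(c(x$split_candidates_a, x$split_candidates_b)))
        paste0(" (", length(c(x$split_candidates_a, x$split_candidates_b)),
               " split candidate(s))") else "", "\n", sep = "")
  invisible(x)
}

#' Are two gene structures divergent?
#'
#' TRUE iff the exon counts differ, or the counts are equal but at least
#' one matched (homologous) exon pair has unequal nucleotide lengths.
#'
#' @param corr an [pair_exon_homology] result.
#' @param gm_a,gm_b the gene models the correspondence was computed on.
#' @return logical scalar.
#' @export
is_structurally_divergent <- function(corr, gm_a, gm_b) {
  len_a <- abs(gm_a$exons[, 2L] - gm_a$exons[, 1L])
  len_b <- abs(gm_b$exons[, 2L] - gm_b$exons[, 1L])
  if (length(len_a) != length(len_b)) return(TRUE)
  if (nrow(corr$matched) == 0L) return(length(len_a) != length(len_b))
  any(len_a[corr$matched$exon_a] != len_b[corr$matched$exon_b])
}

#' Classify the mechanisms of structural divergence for a gene pair
#'
#' Rules, applied to the exon correspondence of the pair's global protein
#' alignment:
#' \enumerate{
#'   \item \emph{Intraexonic insertion/deletion}: a gap run of at least
#'     `min_indel_aa` columns strictly inside a matched exon pair (not
#'     touching either exon's boundary columns), flanked by at least
#'     `min_flank_aln` aligned non-gap columns on each side.
#'   \item \emph{Exonization/pseudoexonization} vs \emph{gain/loss}: each
#'     orphan exon of at least `min_orphan_aa` residues is locally aligned
#'     (DNA) against the partner gene's non-exonic sequence (introns plus
#'     `flank` nt on each side). Identity at least `exonization_id_min`
#'     over coverage at least `exonization_cov_min` of the orphan means
#'     the partner carries the homologous sequence outside its exons:
#'     exonization/pseudoexonization. Otherwise the orphan is a genuine
#'     gain/loss of an exon.
#'   \item Split-candidate orphans (one exon corresponding to two) are
#'     gain/loss with subtype `intron_gain_loss`.
#' }
#'
#' @param gm_a,gm_b [gene_model]s.
#' @param genomic_a,genomic_b scaffold sequence windows covering each gene
#'   locus plus flank (character or `DNAString`). Required whenever an
#'   orphan exon exists.
#' @param aln optional precomputed global protein alignment.
#' @param corr optional precomputed [pair_exon_homology].
#' @param params a [divergence_params] list.
#' @return Object of class `divergence_call`: `structurally_divergent`,
#'   `mechanisms` (character subset of the three labels), `evidence`
#'   (list of per-mechanism records), `pair`, `params`.
#' @export
classify_mechanisms <- function(gm_a, gm_b, genomic_a = NULL, genomic_b = NULL,
                                aln = NULL, corr = NULL,
                                params = divergence_params()) {
  if (is.null(corr))
    corr <- pair_exon_homology(gm_a, gm_b, aln, params$tau_overlap,
                               params$min_match_identity,
                               params$rescue_identity)
  aln <- corr$aln
  mechanisms <- character(0)
  evidence <- list()

  ## (1) intraexonic indels within matched exon pairs; rescued pairs are
  ## scanned on their direct pairwise alignment. An indel changes the
  ## exon's length, so equal-length matched exons are skipped: alignment
  ## gaps there can only be compensating artifacts of diverged sequence.
  len_a_nt <- abs(gm_a$exons[, 2L] - gm_a$exons[, 1L])
  len_b_nt <- abs(gm_b$exons[, 2L] - gm_b$exons[, 1L])
  for (r in seq_len(nrow(corr$matched))) {
    i <- corr$matched$exon_a[r]; j <- corr$matched$exon_b[r]
    if (abs(len_a_nt[i] - len_b_nt[j]) < 3L * params$min_indel_aa) next
    runs <- if (corr$matched$rescued[r]) {
      da <- corr$rescue_alignments[[paste(i, j, sep = "_")]]
      direct_gap_runs(da, params)
    } else {
      intraexonic_gap_runs(aln, corr$spans_a[i, ], corr$spans_b[j, ], params)
    }
    if (nrow(runs)) {
      mechanisms <- union(mechanisms, "INTRAEXONIC_INDEL")
      evidence[[length(evidence) + 1L]] <- list(
        mechanism = "INTRAEXONIC_INDEL", exon_a = i, exon_b = j, runs = runs)
    }
  }

  ## (2)/(3) orphan exons
  orphan_sets <- list(
    list(side = "a", gm = gm_a, partner = gm_b, genome = genomic_a,
         partner_genome = genomic_b, orphans = corr$orphans_a,
         splits = corr$split_candidates_a),
    list(side = "b", gm = gm_b, partner = gm_a, genome = genomic_b,
         partner_genome = genomic_a, orphans = corr$orphans_b,
         splits = corr$split_candidates_b))
  for (os in orphan_sets) {
    len_aa <- abs(os$gm$exons[, 2L] - os$gm$exons[, 1L]) / 3
    for (i in os$orphans) {
      if (len_aa[i] < params$min_orphan_aa) next
      if (i %in% os$splits) {
        mechanisms <- union(mechanisms, "GAIN_LOSS")
        evidence[[length(evidence) + 1L]] <- list(
          mechanism = "GAIN_LOSS", subtype = "intron_gain_loss",
          side = os$side, exon = i)
        next
      }
      if (is.null(os$genome) || is.null(os$partner_genome))
        stop("orphan exon in gene ", os$gm$gene_id,
             " but genomic window(s) missing")
      hit <- best_nonexonic_hit(os$gm, i, os$genome, os$partner,
                                os$partner_genome, params)
      if (!is.null(hit) && hit$identity >= params$exonization_id_min &&
          hit$coverage >= params$exonization_cov_min) {
        mechanisms <- union(mechanisms, "EXONIZATION_PSEUDOEXONIZATION")
        evidence[[length(evidence) + 1L]] <- c(
          list(mechanism = "EXONIZATION_PSEUDOEXONIZATION", side = os$side,
               exon = i), hit)
      } else {
        mechanisms <- union(mechanisms, "GAIN_LOSS")
        evidence[[length(evidence) + 1L]] <- list(
          mechanism = "GAIN_LOSS", subtype = "novel_exon", side = os$side,
          exon = i,
          best_identity = if (is.null(hit)) 0 else hit$identity,
          best_coverage = if (is.null(hit)) 0 else hit$coverage)
      }
    }
  }

  divergent <- is_structurally_divergent(corr, gm_a, gm_b) ||
    length(mechanisms) > 0L
  structure(list(structurally_divergent = divergent,
                 mechanisms = sort(mechanisms), evidence = evidence,
                 pair = c(a = gm_a$gene_id, b = gm_b$gene_id),
                 correspondence = corr, params = params),
            class = "divergence_call")
}

## Gap runs >= min_indel_aa strictly inside the intersection of the two
## exon spans, with >= min_flank_aln aligned (both non-gap) columns on
## each side.
intraexonic_gap_runs <- function(aln, span_a, span_b, params) {
  out <- data.frame(col_start = integer(0), col_end = integer(0),
                    length = integer(0), side = character(0))
  if (is.na(span_a$col_start) || is.na(span_b$col_start)) return(out)
  lo <- max(span_a$col_start, span_b$col_start)
  hi <- min(span_a$col_end, span_b$col_end)
  if (hi - lo + 1L < 2L * params$min_flank_aln + params$min_indel_aa) return(out)
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  for (side in c("a", "b")) {
    gap <- (if (side == "a") ca else cb) == "-"
    both <- ca != "-" & cb != "-"
    r <- rle(gap[lo:hi])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_indel_aa)) {
      g1 <- lo + starts[k] - 1L; g2 <- lo + ends[k] - 1L
      ## strictly inside both spans
      if (g1 <= max(span_a$col_start, span_b$col_start) ||
          g2 >= min(span_a$col_end, span_b$col_end)) next
      left_ok <- sum(both[lo:(g1 - 1L)]) >= params$min_flank_aln
      right_ok <- sum(both[(g2 + 1L):hi]) >= params$min_flank_aln
      if (left_ok && right_ok)
        out <- rbind(out, data.frame(col_start = g1, col_end = g2,
                                     length = g2 - g1 + 1L, side = side))
    }
  }
  out
}

## Gap runs inside a direct pairwise alignment of a rescued exon pair:
## same criteria as intraexonic_gap_runs, with the alignment ends as the
## exon boundaries.
direct_gap_runs <- function(da, params) {
  out <- data.frame(col_start = integer(0), col_end = integer(0),
                    length = integer(0), side = character(0))
  ca <- strsplit(da$aligned_a, "")[[1L]]
  cb <- strsplit(da$aligned_b, "")[[1L]]
  n <- length(ca)
  both <- ca != "-" & cb != "-"
  for (side in c("a", "b")) {
    gap <- (if (side == "a") ca else cb) == "-"
    r <- rle(gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params$min_indel_aa)) {
      if (starts[k] <= 1L || ends[k] >= n) next
      if (sum(both[1:(starts[k] - 1L)]) < params$min_flank_aln) next
      if (sum(both[(ends[k] + 1L):n]) < params$min_flank_aln) next
      out <- rbind(out, data.frame(col_start = starts[k], col_end = ends[k],
                                   length = ends[k] - starts[k] + 1L,
                                   side = side))
    }
  }
  out
}

## Best local DNA hit of an orphan exon against the partner's non-exonic
## sequence (introns + flanks), all in transcription orientation.
best_nonexonic_hit <- function(gm, exon_i, genome, partner, partner_genome,
                               params) {
  orphan <- exon_sequence(gm, exon_i, genome)
  segs <- nonexonic_segments(partner, partner_genome, params$flank)
  ## sensitive scoring (break-even at 50% identity): the homologous
  ## non-coding copy may be far more diverged than coding sequence, and
  ## the +2/-3 default stops extending exactly at the 60% identity a
  ## deeply diverged pair still shows
  ## gaps are kept expensive: the homologous copy diverges by
  ## substitution, so a true hit is near-gapless, while cheap gaps would
  ## let meandering random alignments fake identity and coverage
  sens <- list(matrix = Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE),
    gap_open = 6, gap_extend = 1, alphabet = "dna")
  best <- NULL
  for (k in seq_along(segs)) {
    if (nchar(segs[[k]]) < 10L) next
    la <- local_align(orphan, segs[[k]], sens)
    if (la$score <= 0) next
    cand <- list(identity = la$identity, coverage = la$coverage_a,
                 score = la$score, segment = names(segs)[k])
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

## Non-exonic sequence segments of a gene: 5' flank, introns, 3' flank,
## each in transcription orientation.
nonexonic_segments <- function(gm, genome, flank) {
  genome <- as.character(genome)
  ex <- gm$exons[order(gm$exons[, 1L]), , drop = FALSE]
  g1 <- min(ex[, 1L]); g2 <- max(ex[, 2L])
  segs <- list()
  lo <- max(0L, g1 - flank)
  if (g1 > lo) segs[["flank_up"]] <- substring(genome, lo + 1L, g1)
  if (nrow(ex) > 1L)
    for (i in seq_len(nrow(ex) - 1L)) {
      s <- ex[i, 2L]; e <- ex[i + 1L, 1L]
      if (e > s) segs[[paste0("intron_", i)]] <- substring(genome, s + 1L, e)
    }
  hi <- min(nchar(genome), g2 + flank)
  if (hi > g2) segs[["flank_down"]] <- substring(genome, g2 + 1L, hi)
  if (gm$strand == "-") {
    segs <- lapply(segs, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
    segs <- rev(segs)
  }
  segs
}

#' @export
print.divergence_call <- function(x, ...) {
  cat("<divergence_call> ", x$pair[["a"]], " vs ", x$pair[["b"]], ": ",
      if (x$structurally_divergent) "divergent" else "not divergent", sep = "")
  if (length(x$mechanisms))
    cat(" [", paste(x$mechanisms, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Count how many pairs exhibit each mechanism
#'
#' A pair counts toward every mechanism in its call, so columns need not
#' sum to the number of pairs.
#'
#' @param calls list of [classify_mechanisms] results.
#' @return Named integer vector over the three mechanisms, plus
#'   `n_pairs` and `n_divergent`.
#' @export
mechanism_census <- function(calls) {
  counts <- setNames(integer(length(MECHANISMS)), MECHANISMS)
  for (cl in calls) for (m in cl$mechanisms) counts[m] <- counts[m] + 1L
  c(counts, n_pairs = length(calls),
    n_divergent = sum(vapply(calls, `[[`, TRUE, "structurally_divergent")))
}
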