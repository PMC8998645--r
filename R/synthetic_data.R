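## Generators for every input the pipeline consumes, with planted ground
## truth. Background divergence between siblings is i.i.d. nucleotide
## substitution with a 2:1 transition bias and no indels outside the
## planted event, so that the truth labels stay unambiguous. Exons are
## built from sense codons (no in-frame stops); the planted event sizes
## default to 100-300 aa, the size range of the large exon-gain events
## observed in real RLR sibling pairs.

SIB_MECHANISMS <- c("GAIN_LOSS", "EXONIZATION", "INTRAEXONIC_INDEL", "NONE",
                    "SPLIT")

random_sense_codons <- function(n_codons) {
  ct <- codon_tables()
  paste(sample(ct$codons, n_codons, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## i.i.d. substitutions at rate `rate`; transitions twice as likely as
## either transversion.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (!length(hit)) return(seq)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  u <- runif(length(hit))
  for (k in seq_along(hit)) {
    b <- ch[hit[k]]
    if (!b %in% names(transition)) next
    ch[hit[k]] <- if (u[k] < 0.5) transition[[b]] else
      tv[[b]][1L + (u[k] > 0.75)]
  }
  paste(ch, collapse = "")
}

#' Generate an ancestral multi-exon gene on a random scaffold window
#'
#' The CDS is drawn as random sense codons (optionally started with ATG)
#' and cut into `n_exons` pieces; introns and flanks are uniform random
#' DNA. With `phase0 = TRUE` (default) every exon boundary falls on a
#' codon boundary, which planted structural events require.
#'
#' @param n_exons number of coding exons (>= 1).
#' @param exon_len_range exon length range in nt (rounded to codons when
#'   `phase0`).
#' @param intron_len_range intron length range in nt.
#' @param flank flanking DNA on each side of the gene (nt).
#' @param phase0 force codon-aligned exon boundaries.
#' @param gene_id,scaffold_id identifiers.
#' @param seed RNG seed (`NULL` = use current stream).
#' @return list: `model` ([gene_model]), `scaffold_seq`, `truth`.
#' @export
gen_ancestral_gene <- function(n_exons = 5L, exon_len_range = c(120L, 300L),
                               intron_len_range = c(150L, 400L),
                               flank = 500L, phase0 = TRUE,
                               gene_id = "anc_g1", scaffold_id = "anc_s1",
                               seed = NULL) {
  stopifnot(n_exons >= 1L, all(exon_len_range > 0), all(intron_len_range > 0))
  with_seed(seed, {
    exon_len <- runif_int(n_exons, exon_len_range[1L], exon_len_range[2L])
    if (phase0) exon_len <- pmax(3L, (exon_len %/% 3L) * 3L)
    total <- sum(exon_len)
    if (total %% 3L != 0L) {  # pad the last exon to keep the frame
      pad <- 3L - total %% 3L
      exon_len[n_exons] <- exon_len[n_exons] + pad
      total <- total + pad
    }
    cds <- paste0("ATG", substring(random_sense_codons(total / 3L), 4L))
    intron_len <- if (n_exons > 1L)
      runif_int(n_exons - 1L, intron_len_range[1L], intron_len_range[2L])
    else integer(0)
    pieces <- character(0)
    exons <- matrix(0L, n_exons, 2L)
    pos <- flank
    cds_off <- 0L
    for (i in seq_len(n_exons)) {
      if (i > 1L) {
        pieces <- c(pieces, random_dna(intron_len[i - 1L]))
        pos <- pos + intron_len[i - 1L]
      }
      exons[i, ] <- c(pos, pos + exon_len[i])
      pieces <- c(pieces, substring(cds, cds_off + 1L, cds_off + exon_len[i]))
      pos <- pos + exon_len[i]
      cds_off <- cds_off + exon_len[i]
    }
    scaffold <- paste0(random_dna(flank), paste(pieces, collapse = ""),
                       random_dna(flank))
    model <- gene_model(gene_id, scaffold_id, "+", exons, scaffold)
    list(model = model, scaffold_seq = scaffold,
         truth = list(n_exons = n_exons, exon_len = exon_len,
                      intron_len = intron_len, flank = flank))
  })
}

## Insert `ins` into `scaffold` at 0-based position `pos`; shift exon
## coordinates accordingly.
insert_into_scaffold <- function(scaffold, exons, pos, ins) {
  n <- nchar(ins)
  scaffold <- paste0(substring(scaffold, 1L, pos), ins,
                     substring(scaffold, pos + 1L))
  ## intervals ending at pos stay; those starting at pos shift; an interval
  ## straddling pos widens (its end moves, its start does not)
  exons[exons[, 1L] >= pos, 1L] <- exons[exons[, 1L] >= pos, 1L] + n
  exons[exons[, 2L] > pos, 2L] <- exons[exons[, 2L] > pos, 2L] + n
  list(scaffold = scaffold, exons = exons)
}

delete_from_scaffold <- function(scaffold, exons, pos, len) {
  scaffold <- paste0(substring(scaffold, 1L, pos),
                     substring(scaffold, pos + len + 1L))
  exons[exons[, 1L] >= pos + len, 1L] <- exons[exons[, 1L] >= pos + len, 1L] - len
  exons[exons[, 2L] > pos, 2L] <- pmax(pos, exons[exons[, 2L] > pos, 2L] - len)
  list(scaffold = scaffold, exons = exons)
}

#' Generate a sibling gene pair with a planted structural event
#'
#' Both descendants of a common ancestral gene carry independent
#' background substitutions (per-branch rate `divergence`); the named
#' event is planted in exactly one descendant:
#' \describe{
#'   \item{GAIN_LOSS}{a novel-sequence exon inserted into an intron;}
#'   \item{EXONIZATION}{a stretch of the shared ancestral intron becomes a
#'     new exon in one descendant while remaining intronic in the other;}
#'   \item{INTRAEXONIC_INDEL}{a multiple-of-3 block inserted into (or
#'     deleted from) the middle of one exon;}
#'   \item{SPLIT}{an intron inserted into one exon (intron gain);}
#'   \item{NONE}{nothing planted.}
#' }
#'
#' @param mechanism one of `r paste(SIB_MECHANISMS, collapse = ", ")`.
#' @param divergence per-branch substitution rate in `[0, 0.5]`.
#' @param event_aa_range planted event size range (amino acids).
#' @param n_exons,exon_len_range,intron_len_range,flank ancestor geometry
#'   (see [gen_ancestral_gene]); intron range must accommodate
#'   EXONIZATION events.
#' @param ids gene id pair (character 2); scaffold ids derive from them.
#' @param fit_introns for EXONIZATION, enlarge the intron length range so
#'   one intron is guaranteed to host the event (default TRUE); with
#'   `FALSE` an event larger than every intron is an error.
#' @param seed RNG seed.
#' @return list: `a`, `b` (each `model` + `scaffold_seq`), `truth`
#'   (mechanism, carrier, event size/location), `ancestor`.
#' @export
gen_sibling_pair <- function(mechanism = "NONE", divergence = 0.05,
                             event_aa_range = c(100L, 300L),
                             n_exons = 5L, exon_len_range = c(150L, 300L),
                             intron_len_range = c(200L, 500L),
                             flank = 500L, ids = c("spA_g1", "spA_g2"),
                             fit_introns = TRUE, seed = NULL) {
  mechanism <- match.arg(mechanism, SIB_MECHANISMS)
  stopifnot(divergence >= 0, divergence <= 0.5, length(ids) == 2L,
            n_exons >= 2L)
  with_seed(seed, {
    event_aa <- runif_int(1L, event_aa_range[1L], event_aa_range[2L])
    event_nt <- 3L * event_aa
    if (mechanism == "EXONIZATION" && fit_introns) {
      ## guarantee by construction that one intron can host the event
      need <- event_nt + 2L * 40L + 20L
      intron_len_range <- pmax(intron_len_range, c(need, need + 200L))
    }
    anc <- gen_ancestral_gene(n_exons, exon_len_range, intron_len_range,
                              flank = flank, phase0 = TRUE,
                              gene_id = "ancestor", scaffold_id = "anc")
    exo_at <- exo_intron <- NULL
    if (mechanism == "EXONIZATION") {
      ## choose the stretch in the shared ancestor and overwrite it with
      ## sense codons: both descendants inherit it (one as an exon, the
      ## other as intron), and the exonized reading frame is stop-free
      margin <- 40L
      ex0 <- anc$model$exons
      introns <- cbind(ex0[-nrow(ex0), 2L], ex0[-1L, 1L])
      ok <- which(introns[, 2L] - introns[, 1L] >= event_nt + 2L * margin)
      if (!length(ok))
        stop("EXONIZATION event (", event_nt,
             " nt) larger than available intron")
      exo_intron <- ok[sample.int(length(ok), 1L)]
      exo_at <- introns[exo_intron, 1L] + margin
      anc$scaffold_seq <- paste0(
        substring(anc$scaffold_seq, 1L, exo_at),
        random_sense_codons(event_aa),
        substring(anc$scaffold_seq, exo_at + event_nt + 1L))
    }
    scafA <- scafB <- anc$scaffold_seq
    exA <- exB <- anc$model$exons
    carrier <- sample(c("a", "b"), 1L)
    truth <- list(mechanism = mechanism, carrier = carrier,
                  event_aa = if (mechanism %in% c("NONE")) NA_integer_
                  else event_aa)

    plant <- function(scaf, ex) {
      switch(mechanism,
        NONE = list(scaffold = scaf, exons = ex),
        GAIN_LOSS = {
          i <- sample.int(nrow(ex) - 1L, 1L)   # intron after exon i
          lo <- ex[i, 2L]; hi <- ex[i + 1L, 1L]
          at <- lo + (hi - lo) %/% 2L
          newex <- random_sense_codons(event_aa)
          r <- insert_into_scaffold(scaf, ex, at, newex)
          r$exons <- insert_exon_row(r$exons, i, c(at, at + event_nt))
          truth$event_intron <<- i
          r
        },
        EXONIZATION = {
          ## the stretch already exists in BOTH copies (planted in the
          ## shared ancestor); here it simply becomes an exon of this
          ## descendant
          r <- list(scaffold = scaf,
                    exons = insert_exon_row(ex, exo_intron,
                                            c(exo_at, exo_at + event_nt)))
          truth$event_intron <<- exo_intron
          truth$event_window <<- c(exo_at, exo_at + event_nt)
          r
        },
        INTRAEXONIC_INDEL = {
          margin <- 24L
          kind <- sample(c("insertion", "deletion"), 1L)
          if (kind == "deletion") {
            ok <- which(ex[, 2L] - ex[, 1L] >= event_nt + 2L * margin)
            if (!length(ok)) kind <- "insertion"
          }
          if (kind == "insertion") {
            ok <- which(ex[, 2L] - ex[, 1L] >= 2L * margin)
            i <- ok[sample.int(length(ok), 1L)]
            at <- codon_floor(ex[i, 1L] + margin +
                              sample.int(ex[i, 2L] - ex[i, 1L] - 2L * margin, 1L),
                              ex[i, 1L])
            ## exon i straddles `at`, so the insertion widens it in place
            r <- insert_into_scaffold(scaf, ex, at, random_sense_codons(event_aa))
          } else {
            i <- ok[sample.int(length(ok), 1L)]
            slack <- ex[i, 2L] - ex[i, 1L] - event_nt - 2L * margin
            at <- codon_floor(ex[i, 1L] + margin + runif_int(1L, 0L, slack),
                              ex[i, 1L])
            r <- delete_from_scaffold(scaf, ex, at, event_nt)
          }
          truth$event_exon <<- i
          truth$indel_kind <<- kind
          r
        },
        SPLIT = {
          ok <- which(ex[, 2L] - ex[, 1L] >= 120L)
          i <- ok[sample.int(length(ok), 1L)]
          at <- codon_floor(ex[i, 1L] + (ex[i, 2L] - ex[i, 1L]) %/% 2L,
                            ex[i, 1L])
          ilen <- runif_int(1L, intron_len_range[1L], intron_len_range[2L])
          r <- insert_into_scaffold(scaf, ex, at, random_dna(ilen))
          ## exon i becomes two exons around the new intron
          e1 <- c(ex[i, 1L], at)
          e2 <- c(at + ilen, ex[i, 2L] + ilen)
          r$exons <- r$exons[-i, , drop = FALSE]
          r$exons <- rbind(r$exons, e1, e2)
          r$exons <- r$exons[order(r$exons[, 1L]), , drop = FALSE]
          truth$event_exon <<- i
          r
        })
    }

    if (carrier == "a") {
      r <- plant(scafA, exA); scafA <- r$scaffold; exA <- r$exons
    } else {
      r <- plant(scafB, exB); scafB <- r$scaffold; exB <- r$exons
    }
    scafA <- mutate_sequence(scafA, divergence)
    scafB <- mutate_sequence(scafB, divergence)
    gmA <- gene_model(ids[1L], paste0(ids[1L], "_scaf"), "+", exA, scafA)
    gmB <- gene_model(ids[2L], paste0(ids[2L], "_scaf"), "+", exB, scafB)
    truth$divergence <- divergence
    list(a = list(model = gmA, scaffold_seq = scafA),
         b = list(model = gmB, scaffold_seq = scafB),
         truth = truth, ancestor = anc)
  })
}

insert_exon_row <- function(exons, after, interval) {
  out <- rbind(exons[seq_len(after), , drop = FALSE],
               matrix(as.integer(interval), 1L),
               if (after < nrow(exons))
                 exons[(after + 1L):nrow(exons), , drop = FALSE])
  out
}

## round `pos` down to the nearest codon boundary relative to exon start
codon_floor <- function(pos, exon_start) {
  exon_start + ((pos - exon_start) %/% 3L) * 3L
}

#' Generate a species repertoire: domain tables, scaffold orders, truth
#'
#' For each species, genes of the requested RLR types are emitted with
#' domain annotations consistent with the type's N-terminal pattern plus
#' the helicase core. Tandem arrays are placed on shared scaffolds with
#' interleaved non-RLR decoy genes; remaining RLRs are scattered among
#' decoys on a separate scaffold per species.
#'
#' @param species_spec named list: species tag -> named integer vector of
#'   counts per RLR type label (e.g. `list(sp1 = c(V1 = 2, V2 = 1))`).
#' @param tandem_spec optional named list: species tag -> list of arrays,
#'   each `list(n = members, intervening = decoys between neighbours)`.
#' @param seed RNG seed.
#' @return list: `domain_table`, `orders` (list of
#'   [scaffold_gene_order]), `truth` (`data.frame` gene/species/label/
#'   array id).
#' @export
gen_repertoire <- function(species_spec, tandem_spec = NULL, seed = NULL) {
  with_seed(seed, {
    dom_rows <- list()
    truth <- list()
    orders <- list()
    type_patterns <- list(
      A1 = "Death", V1 = c("CARD", "CARD"), V2 = character(0), C = "CARD",
      L1 = c("CARD", "CARD"), L2 = "DED", L3 = "CASc", L4 = "IG",
      L5 = "SAM", L6 = "Death", X = c("IG", "SAM"))
    for (sp in names(species_spec)) {
      counts <- species_spec[[sp]]
      gene_ids <- character(0)
      labels <- character(0)
      for (ty in names(counts)) {
        if (counts[[ty]] == 0L) next
        for (k in seq_len(counts[[ty]])) {
          gid <- sprintf("%s_g%03d", sp, length(gene_ids) + 1L)
          gene_ids <- c(gene_ids, gid)
          labels <- c(labels, ty)
          pos <- 10L
          for (dn in type_patterns[[ty]]) {
            w <- sample(60:100, 1L)
            dom_rows[[length(dom_rows) + 1L]] <- data.frame(
              gene_id = gid, domain_name = dn, aa_start = pos,
              aa_end = pos + w)
            pos <- pos + w + sample(10:30, 1L)
          }
          for (dn in c("DEXDc", "HELICc", "RD")) {
            w <- switch(dn, DEXDc = 170L, HELICc = 120L, RD = 90L)
            dom_rows[[length(dom_rows) + 1L]] <- data.frame(
              gene_id = gid, domain_name = dn, aa_start = pos,
              aa_end = pos + w)
            pos <- pos + w + sample(10:30, 1L)
          }
        }
      }
      ## scaffold placement
      arrays <- if (!is.null(tandem_spec)) tandem_spec[[sp]] else NULL
      placed <- character(0)
      arr_id <- 0L
      arr_of <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
      if (!is.null(arrays)) for (arr in arrays) {
        arr_id <- arr_id + 1L
        members <- setdiff(gene_ids, placed)[seq_len(arr$n)]
        if (anyNA(members)) stop("tandem_spec requests more RLRs than exist")
        placed <- c(placed, members)
        scafid <- sprintf("%s_scaf_arr%d", sp, arr_id)
        gid_seq <- character(0)
        rlr_seq <- logical(0)
        for (m in seq_along(members)) {
          if (m > 1L && arr$intervening > 0L) {
            dec <- sprintf("%s_dec_%d_%d", scafid, m, seq_len(arr$intervening))
            gid_seq <- c(gid_seq, dec)
            rlr_seq <- c(rlr_seq, rep(FALSE, arr$intervening))
          }
          gid_seq <- c(gid_seq, members[m])
          rlr_seq <- c(rlr_seq, TRUE)
        }
        orders[[scafid]] <- scaffold_gene_order(
          scafid, gid_seq, seq_along(gid_seq) * 1e4, rlr_seq)
        arr_of[members] <- sprintf("%s_arr%d", sp, arr_id)
      }
      rest <- setdiff(gene_ids, placed)
      if (length(rest)) {
        scafid <- sprintf("%s_scaf_rest", sp)
        gid_seq <- character(0); rlr_seq <- logical(0)
        for (g in rest) {
          ndec <- 8L  # scattered: always beyond any sensible max_intervening
          dec <- sprintf("%s_dec_%s_%d", scafid, g, seq_len(ndec))
          gid_seq <- c(gid_seq, dec, g)
          rlr_seq <- c(rlr_seq, rep(FALSE, ndec), TRUE)
        }
        gid_seq <- c(gid_seq, sprintf("%s_dec_tail_%d", scafid, 1:8))
        rlr_seq <- c(rlr_seq, rep(FALSE, 8L))
        orders[[scafid]] <- scaffold_gene_order(
          scafid, gid_seq, seq_along(gid_seq) * 1e4, rlr_seq)
      }
      if (length(gene_ids))
        truth[[sp]] <- data.frame(gene_id = gene_ids, species = sp,
                                  label = labels,
                                  array = unname(arr_of[gene_ids]))
    }
    domain_table <- if (length(dom_rows)) {
      dt <- do.call(rbind, dom_rows)
      dt$canonical <- dt$domain_name %in% rlr_domain_vocabulary()
      dt
    } else data.frame(gene_id = character(0), domain_name = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      canonical = logical(0))
    list(domain_table = domain_table, orders = orders,
         truth = if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
         else data.frame(gene_id = character(0), species = character(0),
                         label = character(0), array = character(0)))
  })
}

#' Generate an NB count matrix with planted differential expression
#'
#' Counts are `NB(mu_gs, dispersion)` with per-gene baseline means drawn
#' log-normally; planted genes have their group-B mean multiplied by
#' `2^log2fc`. `dispersion = 0` draws Poisson counts.
#'
#' @param n_genes number of genes.
#' @param n_a,n_b replicates per group.
#' @param dispersion common NB dispersion.
#' @param n_de number of planted differentially expressed genes.
#' @param log2fc planted log2 fold change (applied to group B).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean
#'   parameters (defaults give a median of ~100 counts).
#' @param gene_len_range per-gene length range (nt).
#' @param seed RNG seed.
#' @return list: `cm` ([count_matrix]), `truth` (`data.frame` gene_id /
#'   de / true_log2fc).
#' @export
gen_counts <- function(n_genes = 2000L, n_a = 3L, n_b = 3L, dispersion = 0.1,
                       n_de = 0L, log2fc = 3, baseline_meanlog = log(100),
                       baseline_sdlog = 1, gene_len_range = c(300L, 3000L),
                       seed = NULL) {
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    mu <- exp(rnorm(n_genes, baseline_meanlog, baseline_sdlog))
    de <- rep(FALSE, n_genes)
    if (n_de > 0L) de[sample.int(n_genes, n_de)] <- TRUE
    mu_b <- ifelse(de, mu * 2^log2fc, mu)
    draw <- function(m, n) {
      vapply(seq_len(n), function(i) {
        if (dispersion == 0) rpois(length(m), m)
        else rnbinom(length(m), size = 1 / dispersion, mu = m)
      }, numeric(length(m)))
    }
    counts <- cbind(draw(mu, n_a), draw(mu_b, n_b))
    colnames(counts) <- c(sprintf("a%d", seq_len(n_a)),
                          sprintf("b%d", seq_len(n_b)))
    rownames(counts) <- gene_ids
    len <- 3L * runif_int(n_genes, gene_len_range[1L] %/% 3L,
                          gene_len_range[2L] %/% 3L)
    cm <- count_matrix(counts, len, rep(1e6, ncol(counts)))
    list(cm = cm,
         truth = data.frame(gene_id = gene_ids, de = de,
                            true_log2fc = ifelse(de, log2fc, 0)))
  })
}
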