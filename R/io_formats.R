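## Readers/writers for the external formats the pipeline touches, and the
## gene-model container used throughout. Internal coordinates are 0-based
## half-open; all GFF3 I/O converts at the boundary (GFF3 is 1-based
## inclusive). Only CDS features define exons: the structures compared
## downstream are protein-coding exon diagrams, so UTR exons are ignored.

#' Controlled vocabulary of RLR-associated protein domains
#'
#' Domain names recognised by the architecture classifier: the helicase core
#' (DEXDc, HELICc), the C-terminal regulatory domain (RD), and the
#' N-terminal interaction/catalytic domains observed across metazoan RLRs.
#'
#' @return Character vector of canonical domain names.
#' @export
rlr_domain_vocabulary <- function() {
  c("CARD", "Death", "DED", "CASc", "IG", "SAM", "DEXDc", "HELICc", "RD")
}

#' Construct a gene model from exon coordinates and a scaffold sequence
#'
#' A gene model is a scaffold id, strand, and an ordered set of coding-exon
#' intervals (0-based half-open genomic coordinates, stored in transcription
#' order: ascending for `+`, descending for `-`). The spliced CDS and its
#' translation are derived from the scaffold sequence at construction time.
#' A terminal stop codon is trimmed from the protein; internal stops set the
#' `internal_stop` flag but do not reject the model (pseudoexonization can
#' legitimately create them).
#'
#' @param gene_id gene identifier.
#' @param scaffold_id scaffold the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of 0-based half-open `[start, end)`
#'   genomic intervals, one row per coding exon, in any order.
#' @param scaffold_seq the scaffold nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @return An object of class `gene_model` with fields `gene_id`,
#'   `scaffold_id`, `strand`, `exons` (transcription order), `cds`,
#'   `protein`, `internal_stop`.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, scaffold_seq) {
  stopifnot(is_string(gene_id), is_string(scaffold_id), strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L]) || any(exons < 0L))
    stop("gene ", gene_id, ": invalid exon interval")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": overlapping exons")
  seq <- as.character(scaffold_seq)
  if (max(exons[, 2L]) > nchar(seq))
    stop("gene ", gene_id, ": exon beyond scaffold end")
  cds <- splice_cds(seq, exons, strand)
  if (nchar(cds) %% 3L != 0L)
    stop("gene ", gene_id, ": CDS length ", nchar(cds), " not divisible by 3")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  prot <- translate_cds(cds)
  structure(
    list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
         exons = exons, cds = cds, protein = prot$protein,
         internal_stop = prot$internal_stop),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, "  ", x$scaffold_id, "(", x$strand, ")  ",
      nrow(x$exons), " exon(s), CDS ", nchar(x$cds), " nt, protein ",
      nchar(x$protein), " aa",
      if (x$internal_stop) "  [internal stop]" else "", "\n", sep = "")
  invisible(x)
}

## Spliced, strand-corrected CDS from ascending-sorted exon intervals.
splice_cds <- function(scaffold_seq, exons_ascending, strand) {
  pieces <- substring(scaffold_seq, exons_ascending[, 1L] + 1L, exons_ascending[, 2L])
  cds <- paste(pieces, collapse = "")
  if (strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  if (nchar(aa) > 0L && substring(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substring(aa, 1L, nchar(aa) - 1L)
  list(protein = aa, internal_stop = grepl("*", aa, fixed = TRUE))
}

## Per-exon CDS nucleotide offsets [start, end), 0-based, transcription order.
exon_cds_offsets <- function(gm) {
  len <- abs(gm$exons[, 2L] - gm$exons[, 1L])
  ends <- cumsum(len)
  cbind(start = c(0L, ends[-length(ends)]), end = ends)
}

## Exon nucleotide sequence in transcription orientation.
exon_sequence <- function(gm, i, scaffold_seq) {
  s <- substring(as.character(scaffold_seq), gm$exons[i, 1L] + 1L, gm$exons[i, 2L])
  if (gm$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Parse gene models from GFF3 and a genome FASTA
#'
#' Reads `gene`/`mRNA`/`CDS` features (GFF3, 1-based inclusive coordinates)
#' and builds one [gene_model] per mRNA from its CDS features. Minus-strand
#' CDS are reordered into transcription order and reverse-complemented
#' before splicing. Records whose total CDS length is not divisible by 3
#' are rejected with a warning naming the gene; a missing scaffold is a
#' hard error; an internal stop codon only flags the model.
#'
#' @param gff3 path to a GFF3 file, or GFF3 text.
#' @param genome path to a FASTA file, a named character vector, or a
#'   [Biostrings::DNAStringSet] keyed by scaffold id.
#' @return List of [gene_model] objects; rejected records are reported in
#'   `attr(, "rejected")` as a named character vector of messages.
#' @export
parse_gff3_gene_models <- function(gff3, genome) {
  path <- as_input_file(gff3, ".gff3")
  gr <- rtracklayer::import(path, format = "gff3")
  genome <- load_genome(genome)

  md <- S4Vectors::mcols(gr)
  is_cds <- tolower(as.character(md$type)) == "cds"
  if (!any(is_cds)) return(structure(list(), rejected = character(0)))
  cds <- gr[is_cds]
  cmd <- S4Vectors::mcols(cds)
  parent <- vapply(as.list(cmd$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  if (anyNA(parent)) {
    id <- cmd$ID
    parent[is.na(parent)] <- if (!is.null(id)) id[is.na(parent)] else
      paste0("cds", which(is.na(parent)))
  }

  ## mRNA id -> gene id, when mRNA features carry a Parent.
  is_mrna <- tolower(as.character(md$type)) %in% c("mrna", "transcript")
  mrna_gene <- character(0)
  if (any(is_mrna)) {
    mm <- S4Vectors::mcols(gr[is_mrna])
    gp <- vapply(as.list(mm$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
    mrna_gene <- setNames(gp, mm$ID)
  }

  models <- list()
  rejected <- character(0)
  for (tx in unique(parent)) {
    sel <- parent == tx
    scaf <- as.character(GenomicRanges::seqnames(cds))[sel][1L]
    strand <- as.character(GenomicRanges::strand(cds))[sel][1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    gid <- mrna_gene[tx]
    gid <- if (length(gid) == 1L && !is.na(gid)) gid else tx
    if (!scaf %in% names(genome))
      stop("scaffold '", scaf, "' referenced by gene '", gid,
           "' not found in genome")
    ## GFF3 1-based inclusive -> 0-based half-open.
    ex <- cbind(GenomicRanges::start(cds)[sel] - 1L, GenomicRanges::end(cds)[sel])
    gm <- tryCatch(gene_model(gid, scaf, strand, ex, genome[[scaf]]),
                   error = function(e) conditionMessage(e))
    if (is.character(gm)) rejected[gid] <- gm else models[[gid]] <- gm
  }
  if (length(rejected))
    warning("rejected ", length(rejected), " record(s): ",
            paste(names(rejected), collapse = ", "))
  structure(models, rejected = rejected)
}

load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    return(setNames(as.character(genome), names(genome)))
  if (is.character(genome) && (length(genome) > 1L || !is.null(names(genome))))
    return(genome)
  x <- Biostrings::readDNAStringSet(as_input_file(genome, ".fa"))
  ## FASTA headers may carry descriptions; key on the first word.
  setNames(as.character(x), vapply(strsplit(names(x), "\\s+"), `[`, "", 1L))
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features (1-based inclusive coordinates)
#' for each model, suitable for re-reading with [parse_gff3_gene_models].
#'
#' @param models list of [gene_model] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    ex <- gm$exons[order(gm$exons[, 1L]), , drop = FALSE]
    g1 <- min(ex[, 1L]) + 1L; g2 <- max(ex[, 2L])
    tx <- paste0(gm$gene_id, ".t1")
    lines <- c(lines,
      paste(gm$scaffold_id, "rlrkit", "gene", g1, g2, ".", gm$strand, ".",
            paste0("ID=", gm$gene_id), sep = "\t"),
      paste(gm$scaffold_id, "rlrkit", "mRNA", g1, g2, ".", gm$strand, ".",
            paste0("ID=", tx, ";Parent=", gm$gene_id), sep = "\t"))
    ## CDS phase: leading bases of this CDS completing the previous codon.
    off <- exon_cds_offsets(gm)
    phase <- (3L - off[, "start"] %% 3L) %% 3L
    ord <- if (gm$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    for (k in seq_len(nrow(ex))) {
      i <- ord[k]  # row of ascending-sorted ex corresponding to transcription index k
      lines <- c(lines,
        paste(gm$scaffold_id, "rlrkit", "CDS", ex[i, 1L] + 1L, ex[i, 2L], ".",
              gm$strand, phase[k],
              paste0("ID=cds-", tx, ";Parent=", tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write scaffold sequences as FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Parse a protein domain annotation table
#'
#' Expects TSV columns `gene_id`, `domain_name`, `aa_start`, `aa_end`
#' (1-based inclusive protein coordinates). Rows whose domain name is
#' outside [rlr_domain_vocabulary] are kept but flagged non-canonical
#' (they can still surface as X-type evidence). Rows with
#' `aa_start > aa_end` are rejected with a warning.
#'
#' @param tsv path or TSV text.
#' @return `data.frame` with columns `gene_id`, `domain_name`, `aa_start`,
#'   `aa_end`, `canonical`, sorted by gene then `aa_start`.
#' @export
parse_domain_table <- function(tsv) {
  df <- read.delim(as_input_file(tsv, ".tsv"), stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_name", "aa_start", "aa_end")
  if (!all(need %in% names(df)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$aa_start <- as.integer(df$aa_start); df$aa_end <- as.integer(df$aa_end)
  bad <- df$aa_start > df$aa_end | df$aa_start < 1L
  if (any(bad)) {
    warning("rejected ", sum(bad), " domain row(s) with invalid coordinates (",
            paste(df$gene_id[bad], collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
  }
  df$canonical <- df$domain_name %in% rlr_domain_vocabulary()
  df <- df[order(df$gene_id, df$aa_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse a newick tree
#'
#' Standard newick via [ape::read.tree]. Duplicate leaf labels are a hard
#' error; missing branch lengths default to 1 with a warning.
#'
#' @param text newick string or file path.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  tr <- if (is_string(text) && !grepl("[();]", text) && file.exists(text))
    ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("newick has no branch lengths; defaulting all to 1")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tr
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param gene_length_nt per-gene positive length in nucleotides.
#' @param library_size per-sample positive library size (total mapped
#'   fragments; may exceed the column sums).
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_length_nt, library_size) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("negative count")
  stopifnot(length(gene_length_nt) == nrow(counts),
            length(library_size) == ncol(counts))
  if (any(gene_length_nt <= 0)) stop("gene lengths must be positive")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts,
                 gene_length_nt = setNames(as.numeric(gene_length_nt), rownames(counts)),
                 library_size = setNames(as.numeric(library_size), colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Parse a read-count TSV
#'
#' First column `gene_id`; an optional `length` column gives per-gene
#' lengths; remaining columns are integer counts per sample. Library sizes
#' default to column sums when not supplied.
#'
#' @param tsv path or TSV text.
#' @param gene_lengths optional named vector overriding the `length` column.
#' @param library_sizes optional named per-sample vector.
#' @return A [count_matrix].
#' @export
parse_counts <- function(tsv, gene_lengths = NULL, library_sizes = NULL) {
  df <- read.delim(as_input_file(tsv, ".tsv"), stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(df)[1L] != "gene_id") names(df)[1L] <- "gene_id"
  len <- gene_lengths
  if ("length" %in% names(df)) {
    if (is.null(len)) len <- setNames(df$length, df$gene_id)
    df$length <- NULL
  }
  cnt <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cnt) <- df$gene_id
  if (any(cnt < 0)) stop("negative count for gene ",
                         df$gene_id[which(rowSums(cnt < 0) > 0)[1L]])
  if (is.null(len)) stop("gene lengths required (length column or gene_lengths=)")
  len <- len[rownames(cnt)]
  if (is.null(library_sizes)) library_sizes <- colSums(cnt)
  count_matrix(cnt, len, library_sizes[colnames(cnt)])
}

#' Write a count matrix as TSV
#'
#' @param cm a [count_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = cm$gene_length_nt,
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
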