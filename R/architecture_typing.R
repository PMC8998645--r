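## Screening for the RLR core (DEXDc + HELICc + RD, in that order) and
## classification of the ordered N-terminal domain architecture into the
## RLR type taxonomy (A1, V1, V2, C, L1-L6, X). The taxonomy is an
## editable pattern table: only the anchored labels (V1/V2/C/A1, L2=DED,
## L4=IG) are fixed by the field's usage; the unanchored L types ship as
## configurable defaults and every output records the taxonomy version.

RLR_TYPE_LABELS <- c("A1", "V1", "V2", "C", "L1", "L2", "L3", "L4", "L5", "L6", "X")

#' Default RLR type taxonomy table
#'
#' Maps an N-terminal domain pattern (domains preceding the helicase core,
#' `+`-joined; runs of a repeated domain collapse to one copy except CARD,
#' whose copy number is kept up to 2 because it separates the two-CARD
#' vertebrate-like type from the single-CARD cnidarian-like type) to a type
#' label. Rows may be restricted to a clade; clade-specific rows take
#' precedence over clade-agnostic ones. Unmatched patterns classify as X.
#'
#' @return `data.frame` with columns `pattern`, `clade` (`NA` = any),
#'   `label`, plus attribute `taxonomy_version`.
#' @export
default_taxonomy <- function() {
  df <- data.frame(
    pattern = c("",   "CARD", "CARD+CARD",    "CARD+CARD", "Death",    "Death",
                "DED", "CASc", "IG", "SAM"),
    clade   = c(NA,   NA,     "lophotrochozoa", NA,        "lophotrochozoa", NA,
                NA,   NA,     NA,   NA),
    label   = c("V2", "C",    "L1",           "V1",        "L6",       "A1",
                "L2", "L3",   "L4", "L5"),
    stringsAsFactors = FALSE)
  attr(df, "taxonomy_version") <- "rlrkit-default-1"
  df
}

#' Load a taxonomy table from TSV
#'
#' Columns `pattern`, `label` and optionally `clade`; empty `clade` means
#' clade-agnostic.
#'
#' @param tsv path or TSV text.
#' @param version identifier recorded in downstream outputs.
#' @return Taxonomy `data.frame` as in [default_taxonomy].
#' @export
read_taxonomy <- function(tsv, version = "user") {
  df <- read.delim(as_input_file(tsv, ".tsv"), stringsAsFactors = FALSE)
  if (!all(c("pattern", "label") %in% names(df)))
    stop("taxonomy needs columns pattern, label")
  if (is.null(df$clade)) df$clade <- NA_character_
  df$clade[!is.na(df$clade) & !nzchar(df$clade)] <- NA_character_
  df$pattern[is.na(df$pattern)] <- ""
  attr(df, "taxonomy_version") <- version
  df
}

#' Screen a gene's domains for the RLR core
#'
#' TRUE iff DEXDc, HELICc and RD are all present and occur in that relative
#' order along the protein (the screening rule for an RLR: an intermediate
#' DEAD/DEAH box helicase followed by a C-terminal regulatory domain).
#'
#' @param domains `data.frame` rows for one gene, as from
#'   [parse_domain_table].
#' @return logical scalar.
#' @export
is_rlr <- function(domains) {
  if (NROW(domains) == 0L) return(FALSE)
  nm <- domains$domain_name[order(domains$aa_start)]
  ## subsequence test: DEXDc before HELICc before RD
  i <- match("DEXDc", nm)
  if (is.na(i)) return(FALSE)
  j <- which(nm == "HELICc" & seq_along(nm) > i)[1L]
  if (is.na(j)) return(FALSE)
  any(nm == "RD" & seq_along(nm) > j)
}

#' Build an architecture from a gene's domain annotations
#'
#' @param domains `data.frame` rows for one gene.
#' @param gene_id optional id (defaults to the table's).
#' @return Object of class `architecture`: `gene_id`, `ordered_domains`,
#'   `n_terminal_domains` (the sublist preceding the helicase core),
#'   `n_terminal_pattern` (collapsed; see [default_taxonomy]), `copy_number`.
#' @export
architecture <- function(domains, gene_id = NULL) {
  stopifnot(NROW(domains) > 0L)
  gene_id <- gene_id %||% domains$gene_id[1L]
  domains <- domains[order(domains$aa_start), , drop = FALSE]
  nm <- domains$domain_name
  core_start <- match("DEXDc", nm)
  nterm <- if (is.na(core_start)) nm else nm[seq_len(core_start - 1L)]
  nterm <- setdiff_keep_order(nterm, c("DEXDc", "HELICc", "RD"))
  structure(
    list(gene_id = gene_id, ordered_domains = nm,
         n_terminal_domains = nterm,
         n_terminal_pattern = collapse_pattern(nterm),
         copy_number = table(nterm)),
    class = "architecture")
}

setdiff_keep_order <- function(x, drop) x[!x %in% drop]

## Collapse runs of a repeated domain to one copy; CARD copy number is
## retained up to 2 (distinguishes the two-CARD and one-CARD types).
collapse_pattern <- function(nterm) {
  if (length(nterm) == 0L) return("")
  r <- rle(nterm)
  out <- character(0)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    reps <- if (v == "CARD") min(r$lengths[k], 2L) else 1L
    out <- c(out, rep(v, reps))
  }
  paste(out, collapse = "+")
}

#' @export
print.architecture <- function(x, ...) {
  cat("<architecture> ", x$gene_id, ": ",
      paste(x$ordered_domains, collapse = "-"),
      "  [N-term: ", if (nzchar(x$n_terminal_pattern)) x$n_terminal_pattern
      else "(none)", "]\n", sep = "")
  invisible(x)
}

#' Classify an architecture into an RLR type
#'
#' Deterministic lookup of the collapsed N-terminal pattern against the
#' taxonomy table; clade-specific rows win over clade-agnostic rows; no
#' match yields X with the pattern kept as evidence.
#'
#' @param arch an [architecture] (or a gene's domain `data.frame`).
#' @param taxonomy taxonomy table; default [default_taxonomy].
#' @param clade optional clade tag of the species (e.g.
#'   `"lophotrochozoa"`).
#' @return Object of class `rlr_type`: `label`, `gene_id`, `evidence`
#'   (the pattern, for X), `taxonomy_version`.
#' @export
classify_rlr_type <- function(arch, taxonomy = default_taxonomy(), clade = NULL) {
  if (is.data.frame(arch)) arch <- architecture(arch)
  pat <- arch$n_terminal_pattern
  hit <- taxonomy$pattern == pat
  label <- NA_character_
  if (!is.null(clade)) {
    sp <- hit & !is.na(taxonomy$clade) & taxonomy$clade == clade
    if (any(sp)) label <- taxonomy$label[which(sp)[1L]]
  }
  if (is.na(label)) {
    ga <- hit & is.na(taxonomy$clade)
    if (any(ga)) label <- taxonomy$label[which(ga)[1L]]
  }
  evidence <- NULL
  if (is.na(label)) {
    label <- "X"
    evidence <- paste(arch$n_terminal_domains, collapse = "+")
  }
  structure(list(label = label, gene_id = arch$gene_id, evidence = evidence,
                 taxonomy_version = attr(taxonomy, "taxonomy_version") %||% "user"),
            class = "rlr_type")
}

#' @export
print.rlr_type <- function(x, ...) {
  cat("<rlr_type> ", x$gene_id, ": ", x$label,
      if (!is.null(x$evidence)) paste0(" (", x$evidence, ")") else "",
      "\n", sep = "")
  invisible(x)
}

#' Classify every gene in a domain table
#'
#' @param domain_table table from [parse_domain_table].
#' @param taxonomy,clade see [classify_rlr_type]; `clade` may be a named
#'   vector keyed by gene id or a single tag.
#' @param rlr_only drop genes failing the [is_rlr] screen (default TRUE).
#' @return `data.frame`: `gene_id`, `is_rlr`, `label`, `pattern`,
#'   `taxonomy_version`.
#' @export
classify_domain_table <- function(domain_table, taxonomy = default_taxonomy(),
                                  clade = NULL, rlr_only = TRUE) {
  ids <- unique(domain_table$gene_id)
  if (!length(ids))
    return(data.frame(gene_id = character(0), is_rlr = logical(0),
                      label = character(0), pattern = character(0),
                      taxonomy_version = character(0)))
  rows <- lapply(ids, function(g) {
    d <- domain_table[domain_table$gene_id == g, , drop = FALSE]
    ok <- is_rlr(d)
    if (!ok && rlr_only)
      return(data.frame(gene_id = g, is_rlr = FALSE, label = NA_character_,
                        pattern = NA_character_,
                        taxonomy_version = attr(taxonomy, "taxonomy_version") %||% "user"))
    cl <- if (length(clade) > 1L || !is.null(names(clade))) clade[[g]] else clade
    ty <- classify_rlr_type(architecture(d), taxonomy, clade = cl)
    data.frame(gene_id = g, is_rlr = ok, label = ty$label,
               pattern = architecture(d)$n_terminal_pattern,
               taxonomy_version = ty$taxonomy_version)
  })
  do.call(rbind, rows)
}

#' Summarize per-species RLR type repertoires
#'
#' @param typed `data.frame` with columns `species` and `label` (one row
#'   per classified gene), e.g. a [classify_domain_table] result joined
#'   with species tags.
#' @return `data.frame` of species x type counts plus a `total` column;
#'   counts sum to the number of classified genes per species.
#' @export
summarize_repertoire <- function(typed) {
  stopifnot(all(c("species", "label") %in% names(typed)))
  species <- sort(unique(typed$species))
  typed <- typed[!is.na(typed$label), , drop = FALSE]
  out <- matrix(0L, nrow = length(species), ncol = length(RLR_TYPE_LABELS),
                dimnames = list(species, RLR_TYPE_LABELS))
  if (nrow(typed)) {
    tab <- table(factor(typed$species, levels = species),
                 factor(typed$label, levels = RLR_TYPE_LABELS))
    out[] <- as.integer(tab)
  }
  df <- as.data.frame.matrix(out)
  df <- cbind(species = species, df, total = rowSums(out))
  rownames(df) <- NULL
  df
}
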