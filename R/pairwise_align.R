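## Deterministic affine-gap pairwise alignment used for sibling-pair
## comparison, exon homology mapping, and exonization detection. The
## dynamic programming engine is Biostrings::pairwiseAlignment; a gap of
## length L costs gap_open + L * gap_extend under this convention.

#' Default protein alignment scoring (BLOSUM62, affine gaps)
#' @return list with `matrix`, `gap_open`, `gap_extend`, `alphabet`.
#' @export
protein_scoring <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  list(matrix = e$BLOSUM62, gap_open = 10, gap_extend = 0.5,
       alphabet = "protein")
}

#' Default DNA alignment scoring (match +2 / mismatch -3, affine gaps)
#' @return list with `matrix`, `gap_open`, `gap_extend`, `alphabet`.
#' @export
dna_scoring <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = TRUE)
  list(matrix = m, gap_open = 5, gap_extend = 2, alphabet = "dna")
}

#' Read an NCBI-format substitution matrix file
#'
#' Plain whitespace-separated matrix with a header row of residues and
#' `#` comment lines, as distributed by NCBI.
#'
#' @param path matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(m) <- list(vapply(rows, `[`, "", 1L), header)
  m
}

guess_alphabet <- function(x) {
  if (grepl("^[ACGTNacgtn]+$", x)) "dna" else "protein"
}

align_engine <- function(a, b, scoring, type) {
  if (!is_string(a) || !is_string(b) || !nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty strings")
  if (is.null(scoring)) {
    ## the alphabet guess is only needed to pick a default scoring; short
    ## protein fragments over ACGT letters are indistinguishable from DNA,
    ## so explicit scoring always wins
    if (guess_alphabet(a) != guess_alphabet(b))
      stop("sequences appear to be over different alphabets; ",
           "pass an explicit scoring")
    scoring <- if (guess_alphabet(a) == "dna") dna_scoring() else
      protein_scoring()
  }
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  sc <- Biostrings::score(pa)
  if (type == "local" && (sc <= 0 || nchar(al_a) == 0L)) {
    return(new_alignment_result("", "", 0, scoring, type,
                                a, b, start_a = NA, start_b = NA))
  }
  start_a <- if (type == "local") Biostrings::start(Biostrings::pattern(pa)) else 1L
  start_b <- if (type == "local") Biostrings::start(Biostrings::subject(pa)) else 1L
  new_alignment_result(al_a, al_b, sc, scoring, type, a, b, start_a, start_b)
}

new_alignment_result <- function(al_a, al_b, score, scoring, type, a, b,
                                 start_a, start_b) {
  ca <- strsplit(al_a, "")[[1L]]
  cb <- strsplit(al_b, "")[[1L]]
  both <- ca != "-" & cb != "-"
  denom <- sum(ca != "-" | cb != "-")
  identity <- if (denom > 0L) sum(both & ca == cb) / denom else 0
  similarity <- if (denom > 0L) {
    pos <- mapply(function(x, y)
      x %in% rownames(scoring$matrix) && y %in% colnames(scoring$matrix) &&
        scoring$matrix[x, y] > 0, ca[both], cb[both])
    sum(pos) / denom
  } else 0
  la <- sum(ca != "-"); lb <- sum(cb != "-")
  structure(
    list(aligned_a = al_a, aligned_b = al_b, score = score,
         identity = identity, similarity = similarity,
         coverage_a = la / nchar(a), coverage_b = lb / nchar(b),
         start_a = start_a, start_b = start_b, type = type,
         alphabet = scoring$alphabet %||% "protein"),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$type, " score=", format(x$score),
      " identity=", round(x$identity, 3),
      " similarity=", round(x$similarity, 3),
      " coverage=", round(x$coverage_a, 2), "/", round(x$coverage_b, 2),
      "\n", sep = "")
  invisible(x)
}

#' Global (Needleman-Wunsch) affine-gap alignment
#'
#' Optimal global alignment under affine gap costs: a gap of length L costs
#' `gap_open + L * gap_extend`. Defaults: BLOSUM62 with gap open 10 /
#' extend 0.5 for protein; match +2 / mismatch -3 with gap open 5 /
#' extend 2 for DNA. Identity is matches over aligned columns excluding
#' double-gap columns; similarity counts positively scoring substitutions.
#'
#' @param a,b sequences over a shared alphabet (auto-detected).
#' @param scoring optional scoring list as from [protein_scoring].
#' @return An `alignment_result` with fields `aligned_a`, `aligned_b`,
#'   `score`, `identity`, `similarity`, `coverage_a`, `coverage_b`.
#' @export
global_align <- function(a, b, scoring = NULL) align_engine(a, b, scoring, "global")

#' Local (Smith-Waterman) affine-gap alignment
#'
#' Optimal local alignment; an empty alignment (score 0) is allowed when no
#' positively scoring segment exists. `start_a`/`start_b` give the 1-based
#' positions of the aligned substrings in the inputs.
#'
#' @inheritParams global_align
#' @return An `alignment_result`; `coverage_a`/`coverage_b` are the aligned
#'   fractions of each input.
#' @export
local_align <- function(a, b, scoring = NULL) align_engine(a, b, scoring, "local")

#' Map a gene model's exons onto alignment columns
#'
#' Exon `e` covering CDS nucleotides `[s, e)` maps to protein positions
#' `[floor(s/3), ceil(e/3))`; a residue split by a codon-phase boundary is
#' assigned to the 5' exon and the boundary is flagged. Protein positions
#' map to alignment columns by skipping gap columns in the requested
#' aligned string.
#'
#' @param gm a [gene_model] whose protein was aligned.
#' @param aln an `alignment_result` over `gm$protein`.
#' @param which `"a"` if `gm` was the first sequence, `"b"` otherwise.
#' @return `data.frame` with one row per exon: `exon`, `aa_start`, `aa_end`
#'   (0-based half-open protein coords), `col_start`, `col_end` (1-based
#'   inclusive alignment columns; `NA` for exons wholly outside a local
#'   alignment), and `boundary_split`.
#' @export
map_exons_to_alignment <- function(gm, aln, which = c("a", "b")) {
  which <- match.arg(which)
  aligned <- if (which == "a") aln$aligned_a else aln$aligned_b
  ch <- strsplit(aligned, "")[[1L]]
  res_cols <- which(ch != "-")
  n_res <- length(res_cols)
  offset <- if (identical(aln$type, "local")) {
    st <- if (which == "a") aln$start_a else aln$start_b
    if (is.na(st)) 0L else st - 1L
  } else {
    if (n_res != nchar(gm$protein))
      stop("alignment does not match protein length of ", gm$gene_id)
    0L
  }
  off <- exon_cds_offsets(gm)
  aa_start <- off[, "start"] %/% 3L
  aa_end <- (off[, "end"] + 2L) %/% 3L  # ceiling
  split5 <- off[, "start"] %% 3L != 0L  # shares its first residue with 5' exon
  aa_start[split5] <- aa_start[split5] + 1L
  n <- nrow(off)
  col_start <- col_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ## residues of this exon are protein positions aa_start..aa_end-1 (0-based),
    ## i.e. residue indices aa_start+1 .. aa_end (1-based), minus local offset
    lo <- aa_start[i] + 1L - offset
    hi <- aa_end[i] - offset
    lo2 <- max(lo, 1L); hi2 <- min(hi, n_res)
    if (lo2 <= hi2) {
      col_start[i] <- res_cols[lo2]
      col_end[i] <- res_cols[hi2]
    }
  }
  data.frame(exon = seq_len(n), aa_start = aa_start, aa_end = aa_end,
             col_start = col_start, col_end = col_end,
             boundary_split = split5)
}
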