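## Detection of local tandem duplication arrays of RLR genes from scaffold
## gene orders. An array is a maximal run of RLR genes on one scaffold in
## which consecutive RLRs are separated by at most `max_intervening`
## non-RLR genes; the default of 3 reflects that tandem duplicates are
## typically interleaved with a few unrelated genes rather than strictly
## adjacent.

#' Construct a scaffold gene order
#'
#' @param scaffold_id scaffold identifier.
#' @param gene_id gene ids on the scaffold.
#' @param start per-gene start coordinates (any consistent unit).
#' @param is_rlr logical flag per gene.
#' @return `data.frame` of class `scaffold_gene_order`, sorted by `start`.
#' @export
scaffold_gene_order <- function(scaffold_id, gene_id, start, is_rlr) {
  stopifnot(length(gene_id) == length(start), length(gene_id) == length(is_rlr))
  if (anyDuplicated(gene_id)) stop("duplicate gene ids on ", scaffold_id)
  df <- data.frame(scaffold_id = scaffold_id, gene_id = gene_id,
                   start = as.numeric(start), is_rlr = as.logical(is_rlr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scaffold_gene_order", "data.frame")
  df
}

#' Detect tandem arrays of RLR genes
#'
#' @param orders one [scaffold_gene_order] or a list of them (or a single
#'   `data.frame` with a `scaffold_id` column covering several scaffolds).
#' @param max_intervening maximum number of non-RLR genes allowed between
#'   consecutive array members (default 3).
#' @return List of `tandem_array` objects, each with `scaffold_id`,
#'   `members` (RLR gene ids in genomic order, at least 2) and
#'   `intervening` (non-RLR gene counts between consecutive members).
#' @export
detect_tandem_arrays <- function(orders, max_intervening = 3L) {
  stopifnot(max_intervening >= 0L)
  if (is.data.frame(orders)) orders <- split(orders, orders$scaffold_id)
  out <- list()
  for (ord in orders) {
    ord <- ord[order(ord$start), , drop = FALSE]
    idx <- which(ord$is_rlr)
    if (length(idx) < 2L) next
    gaps <- diff(idx) - 1L          # non-RLR genes between consecutive RLRs
    groups <- split(seq_along(idx), cumsum(c(0L, gaps > max_intervening)))
    for (g in groups) {
      if (length(g) < 2L) next
      out[[length(out) + 1L]] <- structure(
        list(scaffold_id = ord$scaffold_id[1L],
             members = ord$gene_id[idx[g]],
             intervening = gaps[g[-length(g)]]),
        class = "tandem_array")
    }
  }
  out
}

#' @export
print.tandem_array <- function(x, ...) {
  cat("<tandem_array> ", x$scaffold_id, ": ",
      paste(x$members, collapse = " - "),
      "  (intervening: ", paste(x$intervening, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Tabulate tandem arrays
#'
#' @param arrays result of [detect_tandem_arrays].
#' @return `data.frame` with one row per array: scaffold, size, members.
#' @export
tandem_array_table <- function(arrays) {
  if (!length(arrays))
    return(data.frame(scaffold_id = character(0), n_members = integer(0),
                      members = character(0)))
  data.frame(
    scaffold_id = vapply(arrays, `[[`, "", "scaffold_id"),
    n_members = vapply(arrays, function(a) length(a$members), 0L),
    members = vapply(arrays, function(a) paste(a$members, collapse = ","), ""))
}
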