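## Alignment deduplication: identical sequences produce zero-length terminal
## branches in a clock tree and would make the model over-partition, so they
## are collapsed before tree estimation and re-expanded afterwards.

#' Collapse an alignment to unique sequences
#'
#' Collapses exact-duplicate sequences to a single representative (the first
#' occurrence in file order) and records the membership map so delimitation
#' results can be expanded back to specimens. Matching is exact and
#' case-insensitive; sequences differing only by an ambiguity code (e.g. `N`
#' vs `A`) are **not** collapsed unless `collapse_ambiguous = TRUE`, which
#' treats positions as compatible when their IUPAC sets intersect.
#'
#' @param x a `DNAbin` matrix, a character matrix/vector of sequences, or a
#'   path to a FASTA file.
#' @param collapse_ambiguous also merge sequences that are compatible at
#'   every position through IUPAC ambiguity codes (greedy, first-match).
#' @return a list with `alignment` (unique sequences, `DNAbin`), `map`
#'   (named list: representative -> member ids) and `table` (data frame
#'   `id`, `representative`).
#' @export
dedupe_alignment <- function(x, collapse_ambiguous = FALSE) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- ape::read.FASTA(x)
  if (inherits(x, "DNAbin")) x <- as.character(as.matrix(x))
  if (is.null(dim(x))) {
    if (length(unique(nchar(x))) > 1L)
      stop("sequences must all have equal length (aligned)")
    x <- do.call(rbind, strsplit(toupper(x), ""))
  }
  if (nrow(x) == 0L) stop("empty alignment")
  seqs <- toupper(apply(x, 1L, paste0, collapse = ""))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("sequences must all have equal length (aligned)")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))

  if (!collapse_ambiguous) {
    rep_idx <- match(seqs, seqs)           # first occurrence
  } else {
    iupac <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"), "-" = "-", "?" = c("A", "C", "G", "T"))
    compat <- function(a, b) {
      ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
      all(mapply(function(u, v)
        length(intersect(iupac[[u]], iupac[[v]])) > 0, ca, cb))
    }
    rep_idx <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      hit <- 0L
      for (j in seq_len(i - 1L)) {
        if (rep_idx[j] != j) next
        if (seqs[i] == seqs[j] || compat(seqs[i], seqs[j])) { hit <- j; break }
      }
      rep_idx[i] <- if (hit) hit else i
    }
  }
  keep <- sort(unique(rep_idx))
  map <- lapply(keep, function(k) ids[rep_idx == k])
  names(map) <- ids[keep]
  aln <- ape::as.DNAbin(x[keep, , drop = FALSE])
  rownames(aln) <- ids[keep]
  list(alignment = aln, map = map,
       table = data.frame(id = ids, representative = ids[rep_idx],
                          stringsAsFactors = FALSE))
}

#' Expand a partition of representatives back to specimens
#'
#' @param partition a `gmyc_partition` on deduplicated representatives.
#' @param map the membership map from [dedupe_alignment()].
#' @return a data frame (`tip`, `entity`) covering every original specimen.
#' @export
expand_partition <- function(partition, map) {
  df <- as.data.frame(partition)
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    members <- map[[df$tip[i]]]
    if (is.null(members)) members <- df$tip[i]
    data.frame(tip = members, entity = df$entity[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
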