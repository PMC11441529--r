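# Sequence comparison utilities supporting homology-model validation:
# global alignment plus identity/similarity percentages.

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment through Biostrings, BLOSUM62 by
#' default with gap open 10 / extend 0.5.  The alignment method and
#' penalties behind published identity figures are often unstated, so
#' reproduction of third-party percentages can differ by a few percent;
#' the parameters are therefore explicit arguments.
#'
#' @param a,b Protein sequences (plain strings, no gaps).
#' @param substitution_matrix Name of a Biostrings-shipped matrix.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A `pairwise_alignment`: gapped `aligned_a`, `aligned_b`, and
#'   the substitution matrix name.
#' @export
pairwise_align <- function(a, b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
              aligned_b = as.character(Biostrings::alignedSubject(aln)),
              substitution_matrix = substitution_matrix)
  if (nchar(out$aligned_a) != nchar(out$aligned_b))
    stopf("internal error: gapped lengths differ")
  class(out) <- "pairwise_alignment"
  out
}

#' Percent identity and similarity of an alignment
#'
#' Identity counts columns where both rows carry the same residue;
#' similarity additionally counts columns whose substitution score is
#' positive.  Both are percentages of the columns where neither row is a
#' gap.  Swapping the two rows leaves both values unchanged.
#'
#' @param aln A `pairwise_alignment` from [pairwise_align()], or any list
#'   with gapped `aligned_a`/`aligned_b` and a `substitution_matrix`
#'   name.
#' @return List with `identity` and `similarity` (percent, unrounded;
#'   round to integer for reporting).
#' @export
#' @examples
#' identity_similarity(pairwise_align("AAAA", "AATT"))$identity  # 50
identity_similarity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (length(ca) != length(cb)) stopf("gapped lengths differ")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stopf("alignment has no residue-residue columns")
  mat <- get_substitution_matrix(aln$substitution_matrix %||% "BLOSUM62")
  ia <- ca[both]; ib <- cb[both]
  ok <- ia %in% rownames(mat) & ib %in% colnames(mat)
  scores <- rep(NA_real_, sum(both))
  scores[ok] <- mat[cbind(ia[ok], ib[ok])]
  list(identity = 100 * mean(ia == ib),
       similarity = 100 * mean(!is.na(scores) & scores > 0))
}

get_substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  pc <- identity_similarity(x)
  cat(sprintf("pairwise_alignment (%s): %d columns, identity %.0f%%, similarity %.0f%%\n",
              x$substitution_matrix, nchar(x$aligned_a),
              pc$identity, pc$similarity))
  invisible(x)
}
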