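# Global pairwise sequence comparison (identity / similarity).

#' Global pairwise sequence identity and similarity
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]) and reports percent identity and
#' percent similarity over the aligned columns, excluding terminal gaps.
#' A column counts as similar when the substitution-matrix score of the
#' aligned pair is positive (identities included); gap columns are counted
#' in the denominator and are never identical or similar.
#'
#' @param seq_a,seq_b amino-acid strings (standard one-letter alphabet)
#' @param matrix substitution matrix name, default `"BLOSUM62"`
#' @param gap_opening,gap_extension affine gap penalties (positive costs)
#' @return named numeric vector `c(identity = , similarity = )` in percent
#' @export
pairwise_identity <- function(seq_a, seq_b, matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 4) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  submat <- get(matrix, envir = env)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  alignment_percentages(a, b, submat)
}

#' Identity/similarity from two aligned character vectors
#'
#' Shared between the alignment wrapper and any externally supplied
#' alignment. Terminal gap columns (leading/trailing gap runs of either
#' row) are excluded.
#' @noRd
alignment_percentages <- function(a, b, submat) {
  stopifnot(length(a) == length(b))
  gap <- a == "-" | b == "-"
  first <- 1L
  while (first <= length(a) && gap[first]) first <- first + 1L
  last <- length(a)
  while (last >= 1L && gap[last]) last <- last - 1L
  if (first > last) stop("alignment has no aligned columns")
  a <- a[first:last]
  b <- b[first:last]
  gap <- a == "-" | b == "-"
  ncol <- length(a)
  ident <- sum(!gap & a == b)
  sim <- sum(vapply(which(!gap), function(i) submat[a[i], b[i]] > 0, logical(1)))
  c(identity = 100 * ident / ncol, similarity = 100 * sim / ncol)
}
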