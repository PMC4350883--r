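# Global alignment with affine gaps, used for mapping domains onto the
# packaged reference set.  The dynamic program lives in src/align.cpp.

#' BLOSUM62 substitution table
#'
#' The standard BLOSUM62 matrix over the 20 amino acids plus X, shipped as
#' a plain TSV data file.
#'
#' @return Numeric matrix with residue dimnames.
#' @export
blosum62 <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      df <- utils::read.delim(
        system.file("extdata", "blosum62.tsv", package = "wrkyr"),
        check.names = FALSE)
      m <- as.matrix(df[, -1])
      rownames(m) <- df$residue
      val <<- m
    }
    val
  }
})

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`.  Traceback
#' is deterministic: on ties the diagonal move is preferred, then the gap
#' in the second sequence ("up"), then the gap in the first ("left").
#'
#' @param a,b Non-empty ungapped residue strings.
#' @param substitution Square substitution matrix with residue dimnames;
#'   defaults to [blosum62()].
#' @param gap_open,gap_extend Gap penalties (non-positive).
#' @return A list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
align_global <- function(a, b, substitution = blosum62(),
                         gap_open = -10, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) {
    stop_precondition("alignment inputs must be non-empty")
  }
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE)) {
    stop_precondition("alignment inputs must be ungapped")
  }
  alphabet <- rownames(substitution)
  known <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]])
  bad <- setdiff(known, alphabet)
  if (length(bad) > 0) {
    stop_precondition(sprintf("unknown residue(s): %s",
                              paste(bad, collapse = ", ")))
  }
  nw_affine_cpp(a, b, substitution, alphabet, gap_open, gap_extend)
}
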