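#' Scoring parameters for global DNA alignment
#'
#' Defaults replicate the EMBOSS needle DNA defaults: match +5, mismatch -4
#' (the EDNAFULL values for canonical bases), gap open 10, gap extend 0.5.
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param match,mismatch Substitution scores for identical / differing
#'   bases.
#' @param gap_open,gap_extend Non-negative gap penalties with
#'   `gap_extend <= gap_open`.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(match = 5, mismatch = -4, gap_open = 10,
                           gap_extend = 0.5) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  if (gap_extend > gap_open) {
    stop("'gap_extend' must not exceed 'gap_open'", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_params")
}

#' Needleman-Wunsch global pairwise DNA alignment
#'
#' Optimal global alignment under affine gap penalties (end gaps are
#' penalized), with percent identity in the needle convention: exact base
#' matches divided by the full alignment length including gap columns.
#'
#' @param a,b DNA [seq_record()]s or plain strings; non-empty.
#' @param params A [scoring_params()] object.
#' @return An `alignment_result`: `aligned_a`, `aligned_b` (gapped strings
#'   of equal length), `score`, `matches`, `alignment_length`,
#'   `identity_pct`, plus the input `ids`.
#' @examples
#' global_align("AAAA", "AAA",
#'              scoring_params(1, -1, gap_open = 1, gap_extend = 1))
#' @export
global_align <- function(a, b, params = scoring_params()) {
  ra <- .as_record(a, "dna", id = "a")
  rb <- .as_record(b, "dna", id = "b")
  if (!inherits(params, "scoring_params")) {
    stop("'params' must be a scoring_params object", call. = FALSE)
  }
  if (nchar(ra$seq) == 0L || nchar(rb$seq) == 0L) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  # Canonicalize the argument order so that identity(a, b) == identity(b, a)
  # exactly: among co-optimal alignments the traceback depends on which
  # sequence is the pattern, so the pair is always aligned in lexicographic
  # sequence order and transposed back.
  swapped <- ra$seq > rb$seq
  p1 <- if (swapped) rb$seq else ra$seq
  p2 <- if (swapped) ra$seq else rb$seq
  # our gap convention open + (L-1)*ext maps to Biostrings opening = open-ext
  pa <- Biostrings::pairwiseAlignment(
    p1, p2, type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend)
  al_1 <- as.character(Biostrings::alignedPattern(pa))
  al_2 <- as.character(Biostrings::alignedSubject(pa))
  al_a <- if (swapped) al_2 else al_1
  al_b <- if (swapped) al_1 else al_2
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  len <- length(ca)
  structure(
    list(aligned_a = al_a, aligned_b = al_b,
         score = as.numeric(Biostrings::score(pa)),
         matches = as.integer(matches), alignment_length = as.integer(len),
         identity_pct = 100 * matches / len,
         ids = c(ra$id, rb$id)),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, width = 60, ...) {
  cat("# Global alignment (Needleman-Wunsch, affine gaps)\n")
  cat(sprintf("# 1: %s\n# 2: %s\n", x$ids[1], x$ids[2]))
  cat(sprintf("# Length: %d\n# Identity: %d/%d (%.1f%%)\n# Score: %g\n",
              x$alignment_length, x$matches, x$alignment_length,
              x$identity_pct, x$score))
  for (off in seq(1L, x$alignment_length, by = width)) {
    to <- min(off + width - 1L, x$alignment_length)
    sa <- substr(x$aligned_a, off, to)
    sb <- substr(x$aligned_b, off, to)
    bars <- paste0(ifelse(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]] &
                            strsplit(sa, "")[[1]] != "-", "|", " "),
                   collapse = "")
    cat(sa, "\n", bars, "\n", sb, "\n\n", sep = "")
  }
  invisible(x)
}

#' All-vs-all percent-identity matrix
#'
#' Symmetric matrix of needle-convention percent identities from pairwise
#' global alignments; the diagonal is 100. Full precision is retained in
#' the returned matrix; round for display.
#'
#' @param seqs List of >= 2 DNA [seq_record()]s with unique ids.
#' @param params A [scoring_params()] object.
#' @return A symmetric numeric matrix with the record ids as dimnames.
#' @export
identity_matrix <- function(seqs, params = scoring_params()) {
  if (!is.list(seqs) || length(seqs) < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  seqs <- lapply(seqs, .as_record, alphabet = "dna")
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- global_align(seqs[[i]], seqs[[j]], params)$identity_pct
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}

#' Write an identity matrix as labeled TSV
#'
#' Values are written rounded to one decimal (the display convention);
#' the matrix object itself keeps full precision.
#'
#' @param m Matrix from [identity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], sprintf("%.1f", m[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
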