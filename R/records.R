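#' Create a sequence record
#'
#' The universal I/O unit of the package: an identifier plus an upper-case
#' DNA or protein sequence. DNA records may be supplied with `U` (mRNA
#' accessions are a common source); `U` is converted to `T` on ingest.
#' Protein records use the 20 canonical one-letter codes with an optional
#' terminal `*` stop symbol.
#'
#' @param id Character identifier (non-empty).
#' @param seq Sequence text; coerced to upper case.
#' @param alphabet `"dna"` or `"protein"`.
#' @param desc Optional free-text description (FASTA header remainder).
#' @return An object of class `seq_record` with fields `id`, `seq`,
#'   `alphabet`, `desc`.
#' @examples
#' seq_record("YlSQE_frag", "ATGGCTAAA", "dna")
#' seq_record("pep", "MKV*", "protein")
#' @export
seq_record <- function(id, seq, alphabet = c("dna", "protein"), desc = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a non-empty string", call. = FALSE)
  }
  if (!is.character(seq) || length(seq) != 1L) {
    stop("'seq' must be a single string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (alphabet == "dna") {
    if (grepl("U", seq, fixed = TRUE)) {
      message("record '", id, "': converted U to T on ingest")
      seq <- gsub("U", "T", seq, fixed = TRUE)
    }
    bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T"))
    if (length(bad) > 0) {
      stop("record '", id, "': non-ACGT characters in DNA sequence: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    body <- sub("\\*$", "", seq)
    bad <- setdiff(unique(strsplit(body, "")[[1]]), .AA20)
    if (length(bad) > 0) {
      stop("record '", id, "': invalid protein characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(id = id, seq = seq, alphabet = alphabet, desc = desc),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  shown <- if (nchar(x$seq) > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<seq_record> %s [%s, %d %s]\n  %s\n",
              x$id, x$alphabet, nchar(x$seq),
              if (x$alphabet == "dna") "nt" else "aa", shown))
  invisible(x)
}

.as_record <- function(x, alphabet = "dna", id = "seq") {
  if (inherits(x, "seq_record")) {
    if (x$alphabet != alphabet) {
      stop("expected a ", alphabet, " record, got ", x$alphabet, call. = FALSE)
    }
    x
  } else if (is.character(x) && length(x) == 1L) {
    seq_record(id, x, alphabet)
  } else {
    stop("expected a seq_record or a single string", call. = FALSE)
  }
}

.protein_body <- function(rec) sub("\\*$", "", rec$seq)

#' Translate a coding sequence
#'
#' Translates an in-frame DNA record with the standard nuclear genetic code
#' (translation table 1, used by *Y. lipolytica*). A terminal stop codon
#' becomes the terminal `*` symbol. Internal stop codons are an error unless
#' `allow_internal_stops = TRUE`, in which case the raw amino-acid string
#' (with internal `*`) is returned instead of a record.
#'
#' @param cds A DNA `seq_record` (or plain string); length must be a
#'   multiple of 3.
#' @param allow_internal_stops Return the raw translation string even if it
#'   contains internal stops.
#' @param code Optional named character vector mapping the 64 codons to
#'   amino-acid letters (an alternative genetic code).
#' @return A protein `seq_record`, or a plain string when
#'   `allow_internal_stops = TRUE`.
#' @export
translate_cds <- function(cds, allow_internal_stops = FALSE, code = NULL) {
  rec <- .as_record(cds, "dna")
  if (nchar(rec$seq) %% 3L != 0L) {
    stop("record '", rec$id, "': length not divisible by 3", call. = FALSE)
  }
  aa <- .translate_str(rec$seq, code)
  if (allow_internal_stops) return(aa)
  if (grepl("\\*", sub("\\*$", "", aa))) {
    stop("record '", rec$id, "': internal stop codon in translation",
         call. = FALSE)
  }
  seq_record(rec$id, aa, "protein", desc = rec$desc)
}
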