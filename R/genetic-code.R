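# Standard nuclear genetic code (NCBI translation table 1) and IUPAC helpers.
# The default host here is Yarrowia lipolytica, which uses the standard code;
# an alternative code can be supplied to compute_usage_table()/translate_cds().

.CODONS <- sort(names(Biostrings::GENETIC_CODE))

.AA_OF <- Biostrings::GENETIC_CODE[.CODONS]

# codon families keyed by amino acid (incl. "*" for the three stops)
.FAMILIES <- split(.CODONS, .AA_OF)

.AA20 <- setdiff(sort(unique(unname(.AA_OF))), "*")

.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# IUPAC motif -> regular expression over A/C/G/T
.iupac_regex <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad) > 0) {
    stop("motif '", motif, "' contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  paste0(vapply(letters, function(l) {
    opts <- .IUPAC[[l]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# translate a DNA string; returns an AA string possibly containing '*'
.translate_str <- function(seq, code = NULL) {
  if (is.null(code)) {
    codons <- .split_codons(seq)
    paste0(unname(.AA_OF[codons]), collapse = "")
  } else {
    codons <- .split_codons(seq)
    paste0(unname(code[codons]), collapse = "")
  }
}

.gc_content <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0L) return(NA_real_)
  mean(chars %in% c("G", "C"))
}
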