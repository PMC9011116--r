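#' N-terminal truncation of a protein
#'
#' Removes residues `delete_from..delete_to` (1-based, inclusive), the
#' standard way to strip an N-terminal transmembrane anchor. With
#' `keep_initial_met = TRUE` and `delete_from = 1` the initial methionine is
#' preserved (the deletion effectively starts at residue 2), mirroring the
#' distinction between a Delta-1-k truncation (used as the downstream
#' partner of a fusion, where the upstream part supplies the start codon)
#' and a Delta-2-k truncation expressed on its own. The output id is
#' suffixed with the effective deletion range.
#'
#' @param protein A protein [seq_record()].
#' @param delete_from,delete_to 1-based inclusive residue range to delete;
#'   must satisfy `1 <= delete_from <= delete_to < length` (removing the
#'   C-terminus is refused).
#' @param keep_initial_met Preserve residue 1 when `delete_from` is 1 or 2.
#' @return A protein `seq_record`, id suffixed `_d<from>-<to>`.
#' @examples
#' p <- seq_record("YlSQE", paste(rep("MKVLSTAGDE", 4), collapse = ""),
#'                 "protein")
#' nchar(truncate_n(p, 1, 37)$seq)                           # 3
#' nchar(truncate_n(p, 1, 37, keep_initial_met = TRUE)$seq)  # 4
#' @export
truncate_n <- function(protein, delete_from, delete_to,
                       keep_initial_met = FALSE) {
  rec <- .as_record(protein, "protein")
  body <- .protein_body(rec)
  stop_sym <- if (endsWith(rec$seq, "*")) "*" else ""
  len <- nchar(body)
  delete_from <- as.integer(delete_from)
  delete_to <- as.integer(delete_to)
  if (is.na(delete_from) || is.na(delete_to) || delete_from < 1L ||
      delete_from > delete_to) {
    stop("invalid deletion range [", delete_from, ", ", delete_to, "]",
         call. = FALSE)
  }
  if (delete_to >= len) {
    stop("record '", rec$id, "': deletion range [", delete_from, ", ",
         delete_to, "] reaches the C-terminus of a ", len,
         "-residue protein", call. = FALSE)
  }
  if (keep_initial_met) {
    if (delete_from > 2L) {
      stop("keep_initial_met only applies when delete_from is 1 or 2",
           call. = FALSE)
    }
    delete_from <- 2L
  }
  kept <- paste0(substr(body, 1L, delete_from - 1L),
                 substr(body, delete_to + 1L, len))
  seq_record(sprintf("%s_d%d-%d", rec$id, delete_from, delete_to),
             paste0(kept, stop_sym), "protein", desc = rec$desc)
}

#' Translational fusion of two proteins through a linker
#'
#' Joins an upstream and a downstream protein through `repeats` copies of a
#' linker motif (Gly-Ser-Gly by default). A terminal stop symbol on the
#' upstream partner is removed before fusion; the downstream sequence is
#' used exactly as given — whether it should retain its initial methionine
#' is the caller's choice (a Delta-1-k truncated partner has none).
#'
#' @param upstream,downstream Protein [seq_record()]s.
#' @param linker_motif Linker peptide text (default `"GSG"`).
#' @param repeats Number of linker copies (>= 0; 0 gives a direct fusion).
#' @return A protein `seq_record` of length
#'   `|up| + repeats * |motif| + |down|`.
#' @examples
#' up <- seq_record("GgBAS", strrep("MAKVLSTGDE", 10), "protein")
#' dn <- seq_record("trYlSQE", strrep("VLSTAGDEKF", 5), "protein")
#' nchar(fuse(up, dn)$seq)               # 153
#' nchar(fuse(up, dn, repeats = 4)$seq)  # 162
#' @export
fuse <- function(upstream, downstream, linker_motif = "GSG", repeats = 1L) {
  up <- .as_record(upstream, "protein")
  dn <- .as_record(downstream, "protein")
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 0L) {
    stop("'repeats' must be a non-negative integer", call. = FALSE)
  }
  linker_motif <- toupper(linker_motif)
  if (repeats > 0L) {
    bad <- setdiff(unique(strsplit(linker_motif, "")[[1]]), .AA20)
    if (length(bad) > 0) {
      stop("linker motif contains invalid residues: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  linker <- strrep(linker_motif, repeats)
  label <- if (repeats == 0L) NULL else
    if (repeats == 1L) linker_motif else
      sprintf("%sx%d", linker_motif, repeats)
  id <- paste(c(up$id, label, dn$id), collapse = "-")
  seq_record(id, paste0(.protein_body(up), linker, dn$seq), "protein")
}

#' Swap the N-terminal membrane-anchor domain between two coding sequences
#'
#' Builds a chimeric CDS whose 5' segment (encoding the N-terminal
#' transmembrane, NTM, domain) comes from a donor gene and whose catalytic
#' body comes from a recipient gene. The splice is at exact codon
#' boundaries derived from the residue boundaries (residue *r* maps to
#' nucleotide `3*r`), so the reading frame is preserved by construction and
#' the chimera translation is the donor NTM peptide followed by the
#' recipient body peptide. Domain boundaries (the 1-based index of the last
#' NTM residue, e.g. from a transmembrane-domain prediction) are inputs.
#'
#' @param recipient_cds,donor_cds DNA [seq_record()]s; lengths must be
#'   multiples of 3.
#' @param recipient_boundary,donor_boundary 1-based index of the last NTM
#'   residue in the respective protein (must be < protein length).
#' @param id Output id; default `"<donor>NTM-<recipient>"`.
#' @return A `design_result`: `record` (chimeric DNA), `translation`,
#'   `trace` (splice coordinates in nt and residues); CAI fields are `NA`.
#' @export
swap_ntm <- function(recipient_cds, donor_cds, recipient_boundary,
                     donor_boundary, id = NULL) {
  rcp <- .as_record(recipient_cds, "dna")
  don <- .as_record(donor_cds, "dna")
  for (r in list(rcp, don)) {
    if (nchar(r$seq) %% 3L != 0L) {
      stop("record '", r$id, "': CDS length not divisible by 3", call. = FALSE)
    }
  }
  rb <- as.integer(recipient_boundary)
  db <- as.integer(donor_boundary)
  rcp_len <- nchar(rcp$seq) %/% 3L  # codons incl. any stop
  don_len <- nchar(don$seq) %/% 3L
  rcp_aa_len <- nchar(sub("\\*+$", "", .translate_str(rcp$seq)))
  don_aa_len <- nchar(sub("\\*+$", "", .translate_str(don$seq)))
  if (is.na(db) || db < 1L || db >= don_aa_len) {
    stop("donor boundary ", db, " outside protein length ", don_aa_len,
         call. = FALSE)
  }
  if (is.na(rb) || rb < 1L || rb >= rcp_aa_len) {
    stop("recipient boundary ", rb, " outside protein length ", rcp_aa_len,
         call. = FALSE)
  }
  ntm <- substr(don$seq, 1L, 3L * db)
  body <- substr(rcp$seq, 3L * rb + 1L, nchar(rcp$seq))
  chimera <- paste0(ntm, body)
  aa <- .translate_str(chimera)
  input_internal <- grepl("\\*", sub("\\*+$", "", .translate_str(rcp$seq))) ||
    grepl("\\*", sub("\\*+$", "", .translate_str(don$seq)))
  if (grepl("\\*", sub("\\*+$", "", aa)) && !input_internal) {
    stop("internal stop codon created at the chimera junction", call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("%sNTM-%s", don$id, rcp$id)
  trace <- data.frame(
    position = c(0L, db),
    from = c(don$id, rcp$id),
    to = c(sprintf("residues 1-%d (nt [0,%d))", db, 3L * db),
           sprintf("residues %d-%d (nt [%d,%d))", rb + 1L, rcp_aa_len,
                   3L * rb, nchar(rcp$seq))),
    reason = c("donor NTM segment", "recipient body segment"),
    stringsAsFactors = FALSE)
  structure(
    list(record = seq_record(id, chimera, "dna"),
         translation = seq_record(id, sub("\\*+$", "", aa), "protein"),
         trace = trace, cai_before = NA_real_, cai_after = NA_real_),
    class = "design_result"
  )
}
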