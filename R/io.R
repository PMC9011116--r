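#' Read sequence records from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; the rest is
#' kept as the description. The alphabet is inferred per file: sequences
#' whose letters all fall in A/C/G/T/U are treated as DNA (with U converted
#' to T and a notice logged) unless `alphabet = "protein"` is given — a
#' peptide consisting only of Ala/Cys/Gly/Thr is indistinguishable from DNA,
#' so such inputs need the explicit flag.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `NULL` (infer) or one of `"dna"`, `"protein"`.
#' @return List of [seq_record()]s.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  records <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ab <- alphabet
    if (is.null(ab)) {
      chars <- unique(strsplit(seqs[[i]], "")[[1]])
      ab <- if (all(chars %in% c("A", "C", "G", "T", "U"))) "dna" else "protein"
    }
    records[[i]] <- seq_record(ids[i], seqs[[i]], ab, desc = descs[i])
  }
  records
}

#' Write sequence records to a FASTA file
#'
#' Headers are `id description`; sequence lines wrap at 60 columns.
#'
#' @param records Non-empty list of [seq_record()]s (a single record is
#'   accepted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (!is.list(records) || length(records) == 0L) {
    stop("'records' must be a non-empty list of seq_records", call. = FALSE)
  }
  seqs <- vapply(records, `[[`, character(1), "seq")
  ids <- vapply(records, `[[`, character(1), "id")
  descs <- vapply(records, `[[`, character(1), "desc")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ifelse(nzchar(descs), paste(ids, descs), ids)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# ---- GenBank flat-file CDS extraction -------------------------------------
# Minimal parser for the subset needed to pull annotated CDS features out of
# a GenBank record: LOCUS / FEATURES / ORIGIN sections, locations of the
# forms n..m, complement(...), join(...), complement(join(...)).

.parse_location <- function(loc, seq_len) {
  loc <- gsub("\\s", "", loc)
  comp <- FALSE
  if (grepl("^complement\\(", loc)) {
    comp <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("[<>]|order\\(|:", loc)) {
    stop("unsupported-location: '", loc, "'", call. = FALSE)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ranges <- lapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      stop("unsupported-location: '", p, "'", call. = FALSE)
    }
  })
  for (r in ranges) {
    if (r[1] > r[2] || r[1] < 1L || r[2] > seq_len) {
      stop("unsupported-location: range ", r[1], "..", r[2],
           " outside sequence of length ", seq_len, call. = FALSE)
    }
  }
  list(ranges = ranges, complement = comp)
}

#' Extract coding sequences from a GenBank flat file
#'
#' Returns one DNA record per annotated CDS feature, spliced across
#' `join()` exons and strand-resolved (`complement()` features are
#' reverse-complemented). Record ids use `/locus_tag`, then `/protein_id`,
#' then `/gene`, then a positional fallback.
#'
#' @param path Path to a GenBank flat file.
#' @return List of DNA [seq_record()]s (empty, with a warning, if the file
#'   has no CDS features).
#' @export
extract_cds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1",
               grep("^LOCUS", lines, value = TRUE)[1])
  if (is.na(locus)) locus <- "record"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("no ORIGIN section in ", path, call. = FALSE)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  end <- grep("^//", seq_lines)
  if (length(end) > 0L) seq_lines <- seq_lines[seq_len(end[1] - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0L) {
    warning("no FEATURES section in ", path, call. = FALSE)
    return(list())
  }
  feat_lines <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
  # feature key lines have the key at column 6; qualifier/continuation
  # lines are indented to column 22
  key_idx <- grep("^ {5}\\S", feat_lines)
  cds <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    key <- sub("^ {5}(\\S+).*$", "\\1", feat_lines[i])
    if (key != "CDS") next
    to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(feat_lines)
    block <- feat_lines[i:to]
    block[1] <- sub("^ {5}\\S+\\s*", "", block[1])
    block <- trimws(block)
    qual_at <- grep("^/", block)
    loc_end <- if (length(qual_at) > 0L) qual_at[1] - 1L else length(block)
    loc <- paste0(block[seq_len(loc_end)], collapse = "")
    quals <- block[grepl("^/", block)]
    getq <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub('^[^=]+="?|"$', "", hit[1])
    }
    parsed <- .parse_location(loc, nchar(seq))
    pieces <- vapply(parsed$ranges, function(r) {
      substr(seq, r[1], r[2])
    }, character(1))
    dna <- paste0(pieces, collapse = "")
    if (parsed$complement) dna <- .revcomp(dna)
    id <- getq("locus_tag")
    if (is.na(id)) id <- getq("protein_id")
    if (is.na(id)) id <- getq("gene")
    if (is.na(id)) id <- sprintf("%s_CDS%d", locus, length(cds) + 1L)
    cds[[length(cds) + 1L]] <- seq_record(id, dna, "dna")
  }
  if (length(cds) == 0L) {
    warning("no CDS features found in ", path, call. = FALSE)
  }
  cds
}

#' Read a constraint configuration file
#'
#' A flat YAML document mirroring [constraint_set()]: `forbidden_motifs`
#' (map of name to motif), `max_homopolymer`, `gc_window`
#' (`width`/`min_gc`/`max_gc`), optional `global_gc` (`min`/`max`).
#'
#' @param path Path to the YAML file.
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  motifs <- if (is.null(cfg$forbidden_motifs)) character(0) else
    unlist(cfg$forbidden_motifs)
  gc_window <- if (is.null(cfg$gc_window)) NULL else
    c(width = cfg$gc_window$width, min_gc = cfg$gc_window$min_gc,
      max_gc = cfg$gc_window$max_gc)
  global_gc <- if (is.null(cfg$global_gc)) NULL else
    c(min = cfg$global_gc$min, max = cfg$global_gc$max)
  constraint_set(
    forbidden_motifs = motifs,
    max_homopolymer = if (is.null(cfg$max_homopolymer)) 8 else
      cfg$max_homopolymer,
    gc_window = gc_window, global_gc = global_gc)
}
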