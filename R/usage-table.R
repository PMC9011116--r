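#' Read a gene-expression ranking table
#'
#' Two columns — gene id and a non-negative expression value in arbitrary
#' units — separated by tabs or commas; a header line is auto-detected (the
#' second field of the first row is non-numeric).
#'
#' @param path Path to the delimited text file.
#' @return A data.frame with columns `gene` and `expression`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty expression table: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("malformed expression table: rows must have two fields", call. = FALSE)
  }
  first_val <- suppressWarnings(as.numeric(trimws(fields[[1]][2])))
  if (is.na(first_val)) fields <- fields[-1]  # header row
  if (length(fields) == 0L) stop("expression table has no data rows", call. = FALSE)
  tab <- data.frame(
    gene = vapply(fields, function(f) trimws(f[1]), character(1)),
    expression = vapply(fields, function(f) {
      suppressWarnings(as.numeric(trimws(f[2])))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  .validate_expression_table(tab)
  tab
}

.validate_expression_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("gene", "expression") %in% names(tab)))
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene ids in expression table", call. = FALSE)
  }
  if (any(!is.finite(tab$expression)) || any(tab$expression < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  invisible(tab)
}

#' Select the most highly expressed genes
#'
#' Returns the ids of the `n` genes with the highest expression, the
#' reference set from which a host-specific codon-usage table is built
#' (canonically the 100 most highly expressed genes). Ordering is
#' deterministic: descending expression, ties broken by lexicographic gene
#' id, including at the rank-`n` boundary (so the output always has exactly
#' `n` elements).
#'
#' @param table A data.frame with columns `gene` and `expression`
#'   (see [read_expression_table()]).
#' @param n Positive number of genes to return; must not exceed the number
#'   of rows.
#' @return Character vector of `n` gene ids.
#' @examples
#' tab <- data.frame(gene = c("g1", "g2", "g3"), expression = c(10, 5, 10))
#' rank_top_genes(tab, 2)  # "g1" "g3"
#' @export
rank_top_genes <- function(table, n) {
  .validate_expression_table(table)
  if (nrow(table) == 0L) stop("empty expression table", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  if (n > nrow(table)) {
    stop("requested ", n, " genes but table has only ", nrow(table), " rows",
         call. = FALSE)
  }
  ord <- order(-table$expression, table$gene, method = "radix")
  table$gene[ord][seq_len(n)]
}

#' Build a codon-usage table from a set of coding sequences
#'
#' Counts codon occurrences across all CDSs, then derives per-synonym-family
#' frequencies (normalised within each amino acid) and relative-adaptiveness
#' weights (frequency divided by the family maximum, so the most-used codon
#' of every observed family has weight 1). Stop-codon counts are tracked but
#' stops are never optimization targets. Zero-count codons within an
#' observed family get the conventional 0.01 weight floor; families with
#' zero observations get uniform frequency and weight 1/|family| and are
#' flagged as unobserved — either way CAI never hits log(0).
#'
#' @param cds List of DNA [seq_record()]s (a single record is accepted).
#' @param frame_check Require every CDS length to be divisible by 3
#'   (default `TRUE`).
#' @param source Provenance text stored with the table (e.g. the gene-set
#'   id); defaults to a summary of the input.
#' @param code Optional alternative genetic code (named codon -> amino-acid
#'   vector); defaults to the standard nuclear code.
#' @return An object of class `codon_usage_table` with fields `counts`,
#'   `freq`, `weight` (named numeric vectors over the 64 codons), `aa`
#'   (codon -> amino acid), `unobserved` (amino-acid letters of unobserved
#'   families) and `source`.
#' @examples
#' tab <- compute_usage_table(list(seq_record("x", "ATGAAAAAATAA", "dna")))
#' tab$counts[["AAA"]]  # 2
#' @export
compute_usage_table <- function(cds, frame_check = TRUE, source = NULL,
                                code = NULL) {
  if (inherits(cds, "seq_record")) cds <- list(cds)
  if (!is.list(cds) || length(cds) == 0L) {
    stop("'cds' must be a non-empty list of seq_records", call. = FALSE)
  }
  aa_of <- if (is.null(code)) .AA_OF else code[.CODONS]
  counts <- stats::setNames(numeric(length(.CODONS)), .CODONS)
  notes <- character(0)
  for (rec in cds) {
    rec <- .as_record(rec, "dna")
    if (nchar(rec$seq) %% 3L != 0L) {
      if (frame_check) {
        stop("record '", rec$id, "': length ", nchar(rec$seq),
             " not divisible by 3", call. = FALSE)
      }
      rec$seq <- substr(rec$seq, 1L, 3L * (nchar(rec$seq) %/% 3L))
    }
    codons <- .split_codons(rec$seq)
    aa <- aa_of[codons]
    n_cod <- length(codons)
    if (n_cod > 1L && any(aa[-n_cod] == "*")) {
      warning("record '", rec$id, "': internal stop codon; counting continues",
              call. = FALSE)
      notes <- c(notes, paste0("internal stop in ", rec$id))
    }
    tl <- table(codons)
    counts[names(tl)] <- counts[names(tl)] + as.numeric(tl)
  }
  families <- split(.CODONS, aa_of)
  freq <- weight <- stats::setNames(numeric(length(.CODONS)), .CODONS)
  unobserved <- character(0)
  for (aa in names(families)) {
    fam <- families[[aa]]
    tot <- sum(counts[fam])
    if (tot > 0) {
      freq[fam] <- counts[fam] / tot
      # zero-count codons in an observed family get the conventional 0.01
      # floor so weights stay positive and CAI never hits log(0)
      weight[fam] <- pmax(freq[fam] / max(freq[fam]), 0.01)
    } else {
      freq[fam] <- 1 / length(fam)
      weight[fam] <- 1 / length(fam)
      unobserved <- c(unobserved, aa)
    }
  }
  if (is.null(source)) {
    source <- sprintf("computed from %d CDS records", length(cds))
  }
  if (length(notes) > 0) {
    source <- paste(c(source, notes), collapse = "; ")
  }
  structure(
    list(counts = counts, freq = freq, weight = weight,
         aa = stats::setNames(unname(aa_of), .CODONS),
         unobserved = sort(unobserved), source = source),
    class = "codon_usage_table"
  )
}

.validate_usage_table <- function(table) {
  if (!inherits(table, "codon_usage_table")) {
    stop("'table' must be a codon_usage_table", call. = FALSE)
  }
  invisible(table)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  n_obs <- length(setdiff(unique(x$aa), x$unobserved))
  cat(sprintf(
    "<codon_usage_table> %d codons counted, %d/%d families observed\n  source: %s\n",
    sum(x$counts), n_obs, length(unique(x$aa)), x$source))
  if (length(x$unobserved) > 0) {
    cat("  unobserved families:", paste(x$unobserved, collapse = " "), "\n")
  }
  invisible(x)
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative-adaptiveness weights of a sequence's
#' codons against a reference codon-usage table; a score of 1 means every
#' codon is the most-used codon of its family in the reference gene set.
#' Following the standard CAI convention, the single-codon Met and Trp
#' families and stop codons are excluded from the mean.
#'
#' @param seq A DNA [seq_record()] (or plain string); length must be a
#'   multiple of 3.
#' @param table A `codon_usage_table`.
#' @return A number in (0, 1].
#' @examples
#' tab <- compute_usage_table(list(seq_record("x", "ATGAAAAAATAA", "dna")))
#' cai("ATGAAAAAA", tab)  # 1: both Lys codons are family-maximal
#' @export
cai <- function(seq, table) {
  rec <- .as_record(seq, "dna")
  .validate_usage_table(table)
  codons <- .split_codons(rec$seq)
  aa <- table$aa[codons]
  include <- !(aa %in% c("*", "M", "W"))
  codons <- codons[include]
  if (length(codons) == 0L) {
    stop("record '", rec$id,
         "': no includable codons (only Met/Trp/stop); CAI undefined",
         call. = FALSE)
  }
  exp(mean(log(table$weight[codons])))
}

#' Write a codon-usage table to tab-separated text
#'
#' One row per codon over all 64 codons, columns
#' `codon<TAB>amino_acid<TAB>count<TAB>freq<TAB>weight`, with `#`-prefixed
#' provenance header lines. Frequencies and weights are written to six
#' decimals; [read_usage_table()] inverts the format.
#'
#' @param table A `codon_usage_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path) {
  .validate_usage_table(table)
  header <- c(
    paste0("# source: ", table$source),
    paste0("# unobserved: ",
           if (length(table$unobserved) > 0) {
             paste(table$unobserved, collapse = ",")
           } else "-")
  )
  rows <- sprintf("%s\t%s\t%d\t%.6f\t%.6f",
                  .CODONS, table$aa[.CODONS],
                  as.integer(table$counts[.CODONS]),
                  table$freq[.CODONS], table$weight[.CODONS])
  writeLines(c(header, "codon\tamino_acid\tcount\tfreq\tweight", rows), path)
  invisible(path)
}

#' Read a codon-usage table written by [write_usage_table()]
#'
#' Validates completeness (all 64 codons, nothing outside the codon
#' alphabet) and the normalization invariant (family frequencies sum to 1).
#'
#' @param path Path to the tab-separated table.
#' @return A `codon_usage_table`.
#' @export
read_usage_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  source <- sub("^# source: ", "", grep("^# source: ", hdr, value = TRUE)[1])
  if (is.na(source)) source <- "read from file"
  unobs_line <- sub("^# unobserved: ", "",
                    grep("^# unobserved: ", hdr, value = TRUE)[1])
  unobserved <- if (is.na(unobs_line) || unobs_line == "-") character(0) else
    strsplit(unobs_line, ",", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  body <- body[!grepl("^codon\t", body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 5L)) {
    stop("malformed usage table: expected 5 tab-separated fields per row",
         call. = FALSE)
  }
  codon <- toupper(vapply(fields, `[`, character(1), 1L))
  bad <- setdiff(codon, .CODONS)
  if (length(bad) > 0) {
    stop("codons outside the 64-codon alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(codon)) stop("duplicate codon rows", call. = FALSE)
  if (length(codon) != 64L) {
    stop("usage table must list all 64 codons; found ", length(codon),
         call. = FALSE)
  }
  count <- as.numeric(vapply(fields, `[`, character(1), 3L))
  freq <- as.numeric(vapply(fields, `[`, character(1), 4L))
  weight <- as.numeric(vapply(fields, `[`, character(1), 5L))
  if (any(is.na(count)) || any(is.na(freq)) || any(is.na(weight))) {
    stop("malformed numeric fields in usage table", call. = FALSE)
  }
  ord <- match(.CODONS, codon)
  counts <- stats::setNames(count[ord], .CODONS)
  freq <- stats::setNames(freq[ord], .CODONS)
  weight <- stats::setNames(weight[ord], .CODONS)
  for (aa in names(.FAMILIES)) {
    s <- sum(freq[.FAMILIES[[aa]]])
    if (abs(s - 1) > 1e-3) {
      stop(sprintf(
        "normalization error: family '%s' frequencies sum to %.4f, not 1",
        aa, s), call. = FALSE)
    }
  }
  if (any(weight <= 0) || any(weight > 1 + 1e-9)) {
    stop("weights must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(counts = counts, freq = freq, weight = weight,
         aa = stats::setNames(unname(.AA_OF), .CODONS),
         unobserved = unobserved, source = source),
    class = "codon_usage_table"
  )
}
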