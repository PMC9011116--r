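# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning/alignment/scoring code paths: plain loops, string
# enumeration and closed forms only. The standard genetic code itself is a
# fixed constant and is taken from Biostrings.

GC_CODE <- Biostrings::GENETIC_CODE
CODONS64 <- sort(names(GC_CODE))
FAMILIES64 <- split(CODONS64, GC_CODE[CODONS64])
AA20 <- setdiff(sort(unique(unname(GC_CODE))), "*")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n, first_met = TRUE) {
  body <- sample(AA20, if (first_met) n - 1L else n, replace = TRUE)
  paste(c(if (first_met) "M", body), collapse = "")
}

# ---- naive O(n*m) constraint rescanner ------------------------------------
# character-by-character loops; reports (kind, start, end) triples with the
# same 0-based half-open coordinate convention as scan_violations()

naive_scan <- function(seq, constraints) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  rows <- list()
  add <- function(kind, start, end) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, start = start,
                                             end = end)
  }
  matches_at <- function(motif_chars, pos) {
    w <- length(motif_chars)
    if (pos + w - 1L > n) return(FALSE)
    for (k in seq_len(w)) {
      if (!(chars[pos + k - 1L] %in% IUPAC_SETS[[motif_chars[k]]])) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (motif in constraints$forbidden_motifs) {
    w <- nchar(motif)
    hits <- integer(0)
    for (strand_motif in unique(c(motif, revcomp_chr(motif)))) {
      mc <- strsplit(strand_motif, "")[[1]]
      for (pos in seq_len(max(0L, n - w + 1L))) {
        if (matches_at(mc, pos)) hits <- c(hits, pos)
      }
    }
    # scan_violations drops a '-' strand hit only when the expanded pattern
    # is identical to the '+' strand pattern; for concrete ACGT motifs the
    # unique() above reproduces that
    for (pos in hits) add("motif", pos - 1L, pos - 1L + w)
  }
  if (is.finite(constraints$max_homopolymer) && n > 0L) {
    run_start <- 1L
    for (i in 2:(n + 1L)) {
      if (i > n || chars[i] != chars[run_start]) {
        len <- i - run_start
        if (len > constraints$max_homopolymer) {
          add("homopolymer", run_start - 1L, i - 1L)
        }
        run_start <- i
      }
    }
  }
  if (!is.null(constraints$gc_window)) {
    w <- as.integer(constraints$gc_window[["width"]])
    if (n >= w) {
      for (i in seq_len(n - w + 1L)) {
        gc <- sum(chars[i:(i + w - 1L)] %in% c("G", "C")) / w
        if (gc < constraints$gc_window[["min_gc"]] - 1e-12 ||
            gc > constraints$gc_window[["max_gc"]] + 1e-12) {
          add("gc_window", i - 1L, i - 1L + w)
        }
      }
    }
  }
  if (!is.null(constraints$global_gc) && n > 0L) {
    gc <- sum(chars %in% c("G", "C")) / n
    if (gc < constraints$global_gc[["min"]] - 1e-12 ||
        gc > constraints$global_gc[["max"]] + 1e-12) {
      add("global_gc", 0L, n)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$kind, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

report_triples <- function(rep) {
  out <- data.frame(kind = as.character(rep$kind), start = rep$start,
                    end = rep$end)
  out <- unique(out[order(out$kind, out$start, out$end), , drop = FALSE])
  rownames(out) <- NULL
  out
}

# ---- brute-force global alignment optimum ---------------------------------
# Exhaustive enumeration over all monotone matchings of residue pairs; each
# maximal unmatched block contributes one contiguous gap run per sequence
# (contiguous runs are optimal because gap_extend <= gap_open). Matched
# pairs score match/mismatch, so every global alignment is covered.

brute_force_score <- function(a, b, params) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  gap <- function(L) if (L <= 0L) 0 else
    params$gap_open + (L - 1L) * params$gap_extend
  best <- -Inf
  recurse <- function(i, j, acc) {
    tail_score <- acc - gap(n - i) - gap(m - j)
    if (tail_score > best) best <<- tail_score
    if (i < n && j < m) {
      for (ii in (i + 1L):n) {
        for (jj in (j + 1L):m) {
          s <- if (A[ii] == B[jj]) params$match else params$mismatch
          recurse(ii, jj, acc + s - gap(ii - i - 1L) - gap(jj - j - 1L))
        }
      }
    }
  }
  recurse(0L, 0L, 0)
  best
}

# longest common subsequence length via the edit-distance identity
# d_indel = n + m - 2*LCS (substitutions priced out at cost 2)
lcs_length <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
  (nchar(a) + nchar(b) - d) / 2
}

# ---- exhaustive synonymous-encoding search --------------------------------
# All synonymous encodings of a short protein (body codons from each
# residue's family, fixed stop codon appended); compliance checked by motif
# presence on either strand with base-R grepl; CAI recomputed as a direct
# product of table weights (Met/Trp/stop excluded).

best_compliant_cai <- function(protein, table, motif, stop_codon) {
  residues <- strsplit(protein, "")[[1]]
  combos <- expand.grid(FAMILIES64[residues], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  bodies <- do.call(paste0, combos)
  dna <- paste0(bodies, stop_codon)
  rc <- revcomp_chr(motif)
  ok <- !grepl(motif, dna, fixed = TRUE) & !grepl(rc, dna, fixed = TRUE)
  if (!any(ok)) return(NULL)
  log_cai <- vapply(which(ok), function(r) {
    codons <- as.character(unlist(combos[r, ]))
    keep <- !(residues %in% c("M", "W"))
    if (!any(keep)) return(NA_real_)
    mean(log(table$weight[codons[keep]]))
  }, numeric(1))
  list(best = exp(max(log_cai, na.rm = TRUE)), n_compliant = sum(ok))
}

# usage table built from a generated CDS set with randomized family bias;
# every family observed with probability ~1 at these sizes
random_usage_table <- function(seed, n_genes = 60) {
  freqs <- lapply(FAMILIES64, function(fam) {
    p <- stats::rexp(length(fam)) + 0.05
    stats::setNames(p / sum(p), fam)
  })
  spec <- bias_spec(freqs = freqs, n_genes = n_genes,
                    length_range = c(80, 150), seed = seed)
  compute_usage_table(generate_cds_set(spec))
}
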