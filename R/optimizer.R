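#' Sequence constraints for codon optimization
#'
#' The constraint vocabulary of the optimizer: forbidden motifs (restriction
#' sites, checked on both strands since the enzymes cut double-stranded
#' DNA), a cap on homopolymer run length, a sliding GC-content window and an
#' optional global GC band. The default motif set covers BsaI, EcoRI, BamHI
#' and NotI — NotI because integrative plasmids are typically NotI-digested
#' before transformation, so inserts must not carry a site.
#'
#' @param forbidden_motifs Named character vector of DNA motifs (IUPAC
#'   letters allowed); names are used in violation reports. May be empty.
#' @param max_homopolymer Longest allowed single-nucleotide run (positive;
#'   `Inf` disables the check).
#' @param gc_window `c(width, min_gc, max_gc)`: window width in nt
#'   (>= 10) and the allowed GC fraction band; `NULL` disables the check.
#' @param global_gc Optional `c(min, max)` GC band over the whole sequence.
#' @return An object of class `constraint_set`.
#' @examples
#' constraint_set(forbidden_motifs = c(EcoRI = "GAATTC"), max_homopolymer = 6)
#' @export
constraint_set <- function(forbidden_motifs = c(BsaI = "GGTCTC",
                                                EcoRI = "GAATTC",
                                                BamHI = "GGATCC",
                                                NotI = "GCGGCCGC"),
                           max_homopolymer = 8,
                           gc_window = c(width = 50, min_gc = 0.30,
                                         max_gc = 0.65),
                           global_gc = NULL) {
  forbidden_motifs <- toupper(forbidden_motifs)
  if (length(forbidden_motifs) > 0) {
    if (any(!nzchar(forbidden_motifs))) {
      stop("motifs must be non-empty strings", call. = FALSE)
    }
    if (is.null(names(forbidden_motifs))) {
      names(forbidden_motifs) <- forbidden_motifs
    }
    lapply(forbidden_motifs, .iupac_regex)  # validates the alphabet
  }
  if (!(is.numeric(max_homopolymer) && length(max_homopolymer) == 1L &&
        max_homopolymer >= 1)) {
    stop("'max_homopolymer' must be a positive number", call. = FALSE)
  }
  if (!is.null(gc_window)) {
    gc_window <- stats::setNames(as.numeric(gc_window),
                                 c("width", "min_gc", "max_gc"))
    if (gc_window[["width"]] < 10) {
      stop("gc_window width must be >= 10 nt", call. = FALSE)
    }
    if (!(gc_window[["min_gc"]] >= 0 &&
          gc_window[["min_gc"]] < gc_window[["max_gc"]] &&
          gc_window[["max_gc"]] <= 1)) {
      stop("gc_window requires 0 <= min_gc < max_gc <= 1", call. = FALSE)
    }
  }
  if (!is.null(global_gc)) {
    global_gc <- stats::setNames(as.numeric(global_gc), c("min", "max"))
    if (!(global_gc[["min"]] >= 0 && global_gc[["min"]] < global_gc[["max"]] &&
          global_gc[["max"]] <= 1)) {
      stop("global_gc requires 0 <= min < max <= 1", call. = FALSE)
    }
  }
  structure(list(forbidden_motifs = forbidden_motifs,
                 max_homopolymer = max_homopolymer,
                 gc_window = gc_window, global_gc = global_gc),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>\n")
  if (length(x$forbidden_motifs) > 0) {
    cat("  motifs:",
        paste(sprintf("%s(%s)", names(x$forbidden_motifs), x$forbidden_motifs),
              collapse = " "), "(both strands)\n")
  }
  cat("  max homopolymer:", x$max_homopolymer, "\n")
  if (!is.null(x$gc_window)) {
    cat(sprintf("  GC window: %g nt in [%.2f, %.2f]\n",
                x$gc_window[["width"]], x$gc_window[["min_gc"]],
                x$gc_window[["max_gc"]]))
  }
  if (!is.null(x$global_gc)) {
    cat(sprintf("  global GC in [%.2f, %.2f]\n",
                x$global_gc[["min"]], x$global_gc[["max"]]))
  }
  invisible(x)
}

.empty_report <- function() {
  structure(
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               detail = character(0), stringsAsFactors = FALSE),
    class = c("violation_report", "data.frame")
  )
}

.overlapping_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a DNA sequence for constraint violations
#'
#' Reports every occurrence of a forbidden motif (forward and
#' reverse-complement strand), every maximal homopolymer run longer than the
#' cap, every step-1 sliding window whose GC fraction falls outside the
#' allowed band (one row per violating window), and a global GC breach if
#' configured. Intervals are 0-based, half-open, in nucleotides, sorted by
#' start. An empty report means the sequence is compliant; an empty sequence
#' yields an empty report.
#'
#' @param seq A DNA [seq_record()] or plain string.
#' @param constraints A [constraint_set()].
#' @return A `violation_report` data.frame with columns `kind` (one of
#'   `motif`, `homopolymer`, `gc_window`, `global_gc`), `start`, `end`,
#'   `detail`.
#' @examples
#' scan_violations("GAATTC", constraint_set(c(EcoRI = "GAATTC"),
#'                                          gc_window = NULL))
#' @export
scan_violations <- function(seq, constraints) {
  if (!inherits(constraints, "constraint_set")) {
    stop("'constraints' must be a constraint_set", call. = FALSE)
  }
  s <- if (inherits(seq, "seq_record")) .as_record(seq, "dna")$seq else
    toupper(as.character(seq))
  n <- nchar(s)
  if (n == 0L) return(.empty_report())
  kinds <- character(0); starts <- integer(0); ends <- integer(0)
  details <- character(0)
  add <- function(kind, start, end, detail) {
    kinds[length(kinds) + 1L] <<- kind
    starts[length(starts) + 1L] <<- as.integer(start)
    ends[length(ends) + 1L] <<- as.integer(end)
    details[length(details) + 1L] <<- detail
  }
  for (i in seq_along(constraints$forbidden_motifs)) {
    motif <- constraints$forbidden_motifs[[i]]
    name <- names(constraints$forbidden_motifs)[i]
    w <- nchar(motif)
    if (w > n) next
    fwd <- .iupac_regex(motif)
    for (st in .overlapping_starts(s, fwd)) {
      add("motif", st - 1L, st - 1L + w,
          sprintf("%s (%s) + strand", name, motif))
    }
    rc <- .revcomp(motif)
    rev_re <- .iupac_regex(rc)
    if (rev_re != fwd) {
      for (st in .overlapping_starts(s, rev_re)) {
        add("motif", st - 1L, st - 1L + w,
            sprintf("%s (%s) - strand", name, motif))
      }
    }
  }
  if (is.finite(constraints$max_homopolymer)) {
    r <- rle(strsplit(s, "")[[1]])
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths
    over <- which(r$lengths > constraints$max_homopolymer)
    for (k in over) {
      add("homopolymer", run_starts[k], run_ends[k],
          sprintf("run of %d x %s exceeds cap %g", r$lengths[k], r$values[k],
                  constraints$max_homopolymer))
    }
  }
  if (!is.null(constraints$gc_window)) {
    w <- as.integer(constraints$gc_window[["width"]])
    if (n >= w) {
      is_gc <- as.integer(strsplit(s, "")[[1]] %in% c("G", "C"))
      cs <- c(0L, cumsum(is_gc))
      win_gc <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
      bad <- which(win_gc < constraints$gc_window[["min_gc"]] - 1e-12 |
                   win_gc > constraints$gc_window[["max_gc"]] + 1e-12)
      for (i in bad) {
        add("gc_window", i - 1L, i - 1L + w,
            sprintf("window GC %.3f outside [%.2f, %.2f]", win_gc[i],
                    constraints$gc_window[["min_gc"]],
                    constraints$gc_window[["max_gc"]]))
      }
    }
  }
  if (!is.null(constraints$global_gc)) {
    g <- .gc_content(s)
    if (g < constraints$global_gc[["min"]] - 1e-12 ||
        g > constraints$global_gc[["max"]] + 1e-12) {
      add("global_gc", 0L, n,
          sprintf("global GC %.3f outside [%.2f, %.2f]", g,
                  constraints$global_gc[["min"]], constraints$global_gc[["max"]]))
    }
  }
  if (length(kinds) == 0L) return(.empty_report())
  rep <- data.frame(kind = kinds, start = starts, end = ends,
                    detail = details, stringsAsFactors = FALSE)
  rep <- rep[order(rep$start, rep$end, rep$kind, rep$detail), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("violation_report", "data.frame"))
}

# family-maximal codon for each amino acid under a table (tie: lexicographic;
# .CODONS is sorted, so the first max within a family is the lexicographic one)
.maximal_codons <- function(table) {
  vapply(.FAMILIES[.AA20], function(fam) {
    w <- table$weight[fam]
    fam[which.max(w)]
  }, character(1))
}

.best_stop <- function(table) {
  stops <- .FAMILIES[["*"]]
  stops[order(-table$counts[stops], stops)][1]
}

#' Strict most-abundant-codon back-translation
#'
#' Encodes every residue with the maximal-weight codon of its synonym family
#' (ties broken lexicographically by codon text) and appends the
#' highest-count stop codon from the table. This is the "strict codon
#' usage" starting point of the optimizer: against a fully observed table
#' the result has CAI exactly 1.
#'
#' @param protein A protein [seq_record()] (or string); a terminal `*` is
#'   allowed and ignored.
#' @param table A `codon_usage_table`.
#' @return A DNA `seq_record` (same id), length `3 * (n_residues + 1)`.
#' @examples
#' tab <- compute_usage_table(list(seq_record("x", "ATGAAAAAATAA", "dna")))
#' back_translate_strict("MK", tab)$seq  # "ATGAAATAA"
#' @export
back_translate_strict <- function(protein, table) {
  rec <- .as_record(protein, "protein")
  .validate_usage_table(table)
  body <- .protein_body(rec)
  residues <- strsplit(body, "")[[1]]
  bad <- setdiff(unique(residues), .AA20)
  if (length(bad) > 0) {
    stop("record '", rec$id, "': residues outside the canonical alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  maximal <- .maximal_codons(table)
  dna <- paste0(paste0(maximal[residues], collapse = ""), .best_stop(table))
  seq_record(rec$id, dna, "dna", desc = rec$desc)
}

.report_keys <- function(rep) {
  if (nrow(rep) == 0L) character(0) else
    paste(rep$kind, rep$start, rep$end, rep$detail, sep = "|")
}

# candidate synonymous substitutions at codon positions overlapping [s, e)
# (0-based nt interval). Returns a data.frame ordered by weight loss, then
# position, then codon text. Stop codon (last position) is never touched.
.candidates_for <- function(codons, table, s, e, n_editable) {
  first <- max(0L, s %/% 3L)
  last <- min(n_editable - 1L, (e - 1L) %/% 3L)
  if (last < first) return(NULL)
  out <- list()
  for (p in first:last) {
    cur <- codons[p + 1L]
    fam <- .FAMILIES[[table$aa[[cur]]]]
    alts <- setdiff(fam, cur)
    for (alt in alts) {
      out[[length(out) + 1L]] <- data.frame(
        pos = p, from = cur, to = alt,
        loss = table$weight[[cur]] - table$weight[[alt]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  cand <- do.call(rbind, out)
  cand[order(cand$loss, cand$pos, cand$to), , drop = FALSE]
}

#' Constraint-aware codon optimization
#'
#' Back-translates a protein with strict most-abundant-codon assignment,
#' then deterministically repairs constraint violations. The repair is a
#' depth-first search over substitution moves: at each step the leftmost
#' violation is attacked with synonymous codon substitutions at positions
#' overlapping its interval — single substitutions first, then combinations
#' of up to `backtrack_depth` substitutions — ordered by smallest weight
#' loss (then leftmost position, then lexicographic codon text). A move is
#' admissible if it removes the violation without creating a new one that
#' ends earlier. The first admissible move at every step yields the greedy
#' repair; within a bounded rescan budget the search then backtracks over
#' alternative admissible moves, keeping the compliant result with the
#' highest CAI, with branches that cannot beat the incumbent pruned by
#' their accumulated weight loss. Small instances are explored
#' exhaustively, which is what makes the optimizer's small-instance
#' optimality testable; on large instances the budget keeps the procedure
#' near-greedy. The translation is preserved by construction and the whole
#' procedure is deterministic — identical inputs give byte-identical
#' outputs.
#'
#' @param protein A protein [seq_record()] or string.
#' @param table A `codon_usage_table`.
#' @param constraints A [constraint_set()]; defaults to the package default
#'   (BsaI/EcoRI/BamHI/NotI sites, homopolymer cap 8, 50-nt GC window
#'   0.30-0.65).
#' @param backtrack_depth Maximum number of simultaneous substitutions tried
#'   for a single violation (default 3).
#' @param search_budget Total number of trial rescans the search may spend
#'   beyond completing its first (greedy) repair path.
#' @param max_combos Cap on the number of multi-substitution combinations
#'   examined per violation.
#' @return A `design_result`: `record` (optimized DNA, id suffixed
#'   `_IhOP`), `translation` (the input protein), `trace` (data.frame of
#'   edits: 0-based codon `position`, `from`, `to`, `reason`), `cai_before`,
#'   `cai_after`.
#' @seealso [scan_violations()], [back_translate_strict()]
#' @export
optimize_codons <- function(protein, table,
                            constraints = constraint_set(),
                            backtrack_depth = 3,
                            search_budget = 250,
                            max_combos = 5000) {
  rec <- .as_record(protein, "protein")
  .validate_usage_table(table)
  strict <- back_translate_strict(rec, table)
  codons0 <- .split_codons(strict$seq)
  n_editable <- length(codons0) - 1L  # terminal stop is never substituted
  cai_before <- cai(strict, table)
  rep0 <- scan_violations(strict$seq, constraints)

  st <- new.env(parent = emptyenv())
  st$best_cai <- -Inf
  st$best_cum <- -Inf
  st$best_codons <- NULL
  st$best_trace <- NULL
  st$budget <- search_budget
  st$first_found <- FALSE
  st$residual <- rep0
  st$trials <- 0L
  st$aborted <- FALSE
  max_trials <- 20000L  # hard cap so infeasible instances terminate
  max_depth <- 20L + 4L * length(codons0)

  rescan <- function(codons) {
    scan_violations(paste0(codons, collapse = ""), constraints)
  }

  search <- function(codons, rep, cum, trace, depth) {
    if (nrow(rep) == 0L) {
      final <- cai(paste0(codons, collapse = ""), table)
      if (final > st$best_cai + 1e-12) {
        st$best_cai <- final
        st$best_cum <- cum
        st$best_codons <- codons
        st$best_trace <- trace
      }
      st$first_found <- TRUE
      return(invisible(NULL))
    }
    if (depth > max_depth) return(invisible(NULL))
    v <- rep[1L, ]
    old_keys <- .report_keys(rep)
    v_key <- paste(v$kind, v$start, v$end, v$detail, sep = "|")
    # GC violations can only be repaired by substitutions moving GC content
    # toward the band; restricting candidates to that direction prunes the
    # combinatorics without losing any single-handedly useful move
    gc_dir <- 0L
    if (v$kind %in% c("gc_window", "global_gc")) {
      win <- paste0(substr(paste0(codons, collapse = ""), v$start + 1L,
                           v$end), collapse = "")
      band <- if (v$kind == "gc_window") {
        c(constraints$gc_window[["min_gc"]], constraints$gc_window[["max_gc"]])
      } else {
        c(constraints$global_gc[["min"]], constraints$global_gc[["max"]])
      }
      gc_dir <- if (.gc_content(win) < band[1]) 1L else -1L
    }
    moves <- .moves_for(codons, table, v$start, v$end, n_editable,
                        backtrack_depth, max_combos, gc_dir)
    if (is.null(moves)) {
      if (!st$first_found && nrow(rep) > nrow(st$residual)) st$residual <- rep
      return(invisible(NULL))
    }
    for (m in moves) {
      if (st$aborted) break
      # until a first compliant solution exists the greedy descent is free;
      # afterwards every trial draws on the search budget
      if (st$first_found) {
        if (st$budget <= 0L) break
        st$budget <- st$budget - 1L
      } else {
        st$trials <- st$trials + 1L
        if (st$trials > max_trials) {
          st$aborted <- TRUE
          break
        }
      }
      # prune: cum tracks the product of weight ratios relative to the
      # strict encoding; the number of CAI-includable codons is fixed, so
      # a branch whose accumulated ratio cannot exceed the incumbent's
      # cannot yield a higher CAI (further moves only multiply by <= 1
      # ratios except for rare re-raises, which always follow a dominated
      # down-substitution at the same position)
      ratio <- prod(table$weight[m$to] / table$weight[codons[m$pos + 1L]])
      if (st$first_found && cum * ratio <= st$best_cum + 1e-15) next
      trial <- codons
      trial[m$pos + 1L] <- m$to
      rep2 <- rescan(trial)
      if (!.repair_ok(rep2, v, v_key, old_keys)) next
      new_trace <- rbind(trace, data.frame(
        position = m$pos, from = codons[m$pos + 1L], to = m$to,
        reason = sprintf("%s [%d,%d) %s", v$kind, v$start, v$end, v$detail),
        stringsAsFactors = FALSE))
      had_first <- st$first_found
      search(trial, rep2, cum * ratio, new_trace, depth + 1L)
      # after the greedy path completes, only explore alternatives while
      # budget remains
      if (had_first && st$budget <= 0L) break
      if (!had_first && st$first_found && st$budget <= 0L) break
    }
    invisible(NULL)
  }

  empty_trace <- data.frame(position = integer(0), from = character(0),
                            to = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  search(codons0, rep0, 1, empty_trace, 0L)
  if (is.null(st$best_codons)) .infeasible(rec$id, st$residual)

  dna <- seq_record(paste0(rec$id, "_IhOP"),
                    paste0(st$best_codons, collapse = ""), "dna",
                    desc = rec$desc)
  structure(
    list(record = dna,
         translation = seq_record(rec$id, .protein_body(rec), "protein"),
         trace = st$best_trace,
         cai_before = cai_before,
         cai_after = cai(dna, table)),
    class = "design_result"
  )
}

# admissible moves for one violation: single substitutions, then
# combinations of 2..depth substitutions at distinct positions, ordered by
# total weight loss (ties: leftmost position, lexicographic codon text).
# Each move is a list(pos = 0-based codon indices, to = replacement codons).
.moves_for <- function(codons, table, s, e, n_editable, depth, max_combos,
                       gc_dir = 0L) {
  cand <- .candidates_for(codons, table, s, e, n_editable)
  if (is.null(cand)) return(NULL)
  if (gc_dir != 0L) {
    n_gc <- function(x) {
      vapply(strsplit(x, ""), function(ch) sum(ch %in% c("G", "C")), 0L)
    }
    delta <- n_gc(cand$to) - n_gc(cand$from)
    cand <- cand[sign(delta) == gc_dir, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
  }
  moves <- lapply(seq_len(nrow(cand)), function(k) {
    list(pos = cand$pos[k], to = cand$to[k], loss = cand$loss[k])
  })
  if (depth >= 2 && nrow(cand) >= 2) {
    for (k in 2:min(depth, nrow(cand))) {
      combos <- utils::combn(nrow(cand), k, simplify = FALSE)
      keep <- vapply(combos, function(ix) {
        !anyDuplicated(cand$pos[ix])
      }, logical(1))
      combos <- combos[keep]
      if (length(combos) == 0L) next
      tot <- vapply(combos, function(ix) sum(cand$loss[ix]), numeric(1))
      ord <- order(tot)
      if (length(ord) > max_combos) ord <- ord[seq_len(max_combos)]
      moves <- c(moves, lapply(ord, function(i) {
        ix <- combos[[i]]
        list(pos = cand$pos[ix], to = cand$to[ix], loss = tot[i])
      }))
    }
  }
  moves[order(vapply(moves, `[[`, numeric(1), "loss"),
              vapply(moves, function(m) min(m$pos), numeric(1)),
              vapply(moves, function(m) paste(m$to, collapse = ","),
                     character(1)))]
}

.repair_ok <- function(rep2, v, v_key, old_keys) {
  keys2 <- .report_keys(rep2)
  if (v_key %in% keys2) return(FALSE)           # violation not removed
  if (nrow(rep2) == 0L) return(TRUE)
  earlier <- rep2$end < v$end
  if (!any(earlier)) return(TRUE)
  all(keys2[earlier] %in% old_keys)             # earlier-ending must pre-exist
}

.infeasible <- function(id, rep) {
  stop(errorCondition(
    paste0("record '", id, "': constraints infeasible within backtracking ",
           "budget; ", nrow(rep), " residual violation(s)"),
    class = c("constraint_infeasible", "error"),
    report = rep))
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %s (%d nt)\n", x$record$id, nchar(x$record$seq)))
  if (!is.null(x$cai_before) && !is.na(x$cai_before)) {
    cat(sprintf("  CAI %.4f -> %.4f, %d edit(s)\n",
                x$cai_before, x$cai_after, nrow(x$trace)))
  }
  if (nrow(x$trace) > 0) {
    print(utils::head(x$trace, 10))
    if (nrow(x$trace) > 10) cat("  ...", nrow(x$trace) - 10, "more edits\n")
  }
  invisible(x)
}
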