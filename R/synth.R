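# Fixture generation: seeded CDS sets with controlled codon bias and
# sequences carrying a requested constraint violation. All randomness flows
# from the seed stored in the spec; the caller's RNG state is untouched.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# default skewed per-family codon frequencies: within each family, codons in
# lexicographic order get probability proportional to 0.5^(rank-1) — a
# realistic strength of bias for a highly expressed gene set
.default_bias_freqs <- function() {
  lapply(.FAMILIES, function(fam) {
    p <- 0.5 ^ (seq_along(fam) - 1L)
    stats::setNames(p / sum(p), fam)
  })
}

#' Specification for a biased synthetic CDS set
#'
#' Describes the generating distribution for [generate_cds_set()]: one
#' codon-frequency vector per synonym family (including the stop family
#' `"*"`), a gene count, a body-length range in codons, and the seed that
#' makes generation fully reproducible. The default frequencies are skewed
#' (geometric decay 0.5 across each family in lexicographic codon order),
#' emulating the biased usage of a highly expressed gene set.
#'
#' @param freqs Named list: amino-acid letter (and `"*"`) to a named
#'   frequency vector over that family's codons, each summing to 1. `NULL`
#'   uses the default skew.
#' @param n_genes Number of CDSs to generate.
#' @param length_range `c(min, max)` body length in codons (min >= 10),
#'   excluding the start and stop codons.
#' @param seed Integer seed.
#' @param composition Optional named probability vector over the 20 amino
#'   acids for residue sampling; uniform when `NULL`.
#' @return An object of class `bias_spec`.
#' @export
bias_spec <- function(freqs = NULL, n_genes = 100, length_range = c(100, 400),
                      seed = 1, composition = NULL) {
  if (is.null(freqs)) freqs <- .default_bias_freqs()
  missing_fams <- setdiff(names(.FAMILIES), names(freqs))
  if (length(missing_fams) > 0) {
    defaults <- .default_bias_freqs()
    freqs[missing_fams] <- defaults[missing_fams]
  }
  for (aa in names(.FAMILIES)) {
    fam <- .FAMILIES[[aa]]
    f <- freqs[[aa]]
    if (is.null(names(f)) && length(f) == length(fam)) names(f) <- fam
    if (!setequal(names(f), fam)) {
      stop("frequency vector for family '", aa,
           "' must cover exactly its codons", call. = FALSE)
    }
    f <- f[fam]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      stop("frequencies for family '", aa,
           "' must be non-negative and sum to 1", call. = FALSE)
    }
    if (sum(f) <= 0) stop("zero-probability family '", aa, "'", call. = FALSE)
    freqs[[aa]] <- f
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 10L ||
      length_range[1] > length_range[2]) {
    stop("'length_range' must be c(min, max) with min >= 10 codons",
         call. = FALSE)
  }
  if (!is.null(composition)) {
    if (!setequal(names(composition), .AA20) || any(composition < 0)) {
      stop("'composition' must be a non-negative vector over the 20 amino acids",
           call. = FALSE)
    }
    composition <- composition[.AA20] / sum(composition)
  }
  structure(list(freqs = freqs, n_genes = as.integer(n_genes),
                 length_range = length_range, seed = as.integer(seed),
                 composition = composition),
            class = "bias_spec")
}

#' Generate a synthetic CDS set with controlled codon bias
#'
#' Each CDS starts with ATG, ends with a stop codon drawn from the spec's
#' stop-family frequencies, and has no internal stops; body codons are drawn
#' per residue from the spec's family frequency vectors. Deterministic:
#' the same spec (including seed) yields byte-identical records.
#'
#' @param spec A [bias_spec()].
#' @return List of DNA [seq_record()]s (ids `synth_001`, ...).
#' @export
generate_cds_set <- function(spec) {
  if (!inherits(spec, "bias_spec")) {
    stop("'spec' must be a bias_spec", call. = FALSE)
  }
  comp <- if (is.null(spec$composition)) {
    stats::setNames(rep(1 / length(.AA20), length(.AA20)), .AA20)
  } else spec$composition
  .with_seed(spec$seed, {
    lens <- if (spec$length_range[1] == spec$length_range[2]) {
      rep.int(spec$length_range[1], spec$n_genes)
    } else {
      sample(spec$length_range[1]:spec$length_range[2], spec$n_genes,
             replace = TRUE)
    }
    gene_of <- rep.int(seq_len(spec$n_genes), lens)
    residues <- sample(.AA20, sum(lens), replace = TRUE, prob = comp[.AA20])
    residues[cumsum(c(1L, lens[-spec$n_genes]))] <- "M"
    # one bulk draw per family keeps generation fast at large n
    codons <- character(length(residues))
    for (aa in unique(residues)) {
      idx <- which(residues == aa)
      f <- spec$freqs[[aa]]
      codons[idx] <- sample(names(f), length(idx), replace = TRUE, prob = f)
    }
    stop_f <- spec$freqs[["*"]]
    stops <- sample(names(stop_f), spec$n_genes, replace = TRUE,
                    prob = stop_f)
    bodies <- vapply(split(codons, gene_of), paste0, character(1),
                     collapse = "")
    lapply(seq_len(spec$n_genes), function(i) {
      seq_record(sprintf("synth_%03d", i), paste0(bodies[[i]], stops[i]),
                 "dna")
    })
  })
}

# low-risk codon background: ~50% GC, no homopolymer seeds, no common
# restriction sites, cycled to fill a CDS body
.NEUTRAL_CODONS <- c("GCT", "GAA", "ACT", "CTG", "GAC", "TCC", "ATC", "CAG")

.neutral_body <- function(n_codons) {
  paste0(rep_len(.NEUTRAL_CODONS, n_codons), collapse = "")
}

#' Generate a CDS carrying one requested constraint violation
#'
#' Builds a well-formed CDS (ATG start, stop end, no internal stops) on a
#' neutral, constraint-compliant background and embeds exactly the
#' requested violation class: a forbidden motif, a homopolymer run of a
#' stated length, or a GC-window breach. The construction is verified
#' internally with [scan_violations()], and the translation is returned
#' alongside so the optimizer can be round-tripped on the encoded protein.
#'
#' @param kind One of `"motif"`, `"homopolymer"`, `"gc_window"`.
#' @param params List of class-specific parameters: `motif` (default
#'   `"GAATTC"`); `run` (homopolymer length, default 12) and `cap` (the cap
#'   it must exceed, default 8); `width` (GC window, default 50).
#' @param seed Integer seed (placement jitter).
#' @param constraints The [constraint_set()] the violation is asserted
#'   against; defaults to `constraint_set()` with the relevant parameters
#'   substituted.
#' @return List with `record` (DNA [seq_record()]), `translation` (protein
#'   record) and `constraints` (the constraint set used for verification).
#' @export
generate_violating_sequence <- function(kind = c("motif", "homopolymer",
                                                 "gc_window"),
                                        params = list(), seed = 1,
                                        constraints = NULL) {
  kind <- match.arg(kind)
  n_flank <- 15L  # codons on each side of the inserted segment
  insert <- switch(kind,
    motif = {
      motif <- toupper(if (is.null(params$motif)) "GAATTC" else params$motif)
      if (grepl("[^ACGT]", motif)) {
        stop("violation fixtures need a concrete ACGT motif", call. = FALSE)
      }
      .pad_to_frame(motif)
    },
    homopolymer = {
      run <- if (is.null(params$run)) 12L else as.integer(params$run)
      cap <- if (is.null(params$cap)) 8L else as.integer(params$cap)
      if (run <= cap) {
        stop("impossible request: run ", run, " does not exceed cap ", cap,
             call. = FALSE)
      }
      .pad_to_frame(strrep("A", run), pad = "G")
    },
    gc_window = {
      # GC-rich but repairable: Arg/Leu/Ile codons all have AT-rich synonyms
      width <- if (is.null(params$width)) 50L else as.integer(params$width)
      .pad_to_frame(strrep("CGCCTCATC", ceiling(width / 9) + 2L))
    })
  if (is.null(constraints)) {
    constraints <- switch(kind,
      homopolymer = constraint_set(
        max_homopolymer = if (is.null(params$cap)) 8 else params$cap),
      constraint_set())
  }
  dna <- .with_seed(seed, {
    lead <- n_flank + sample(0:4, 1L)
    paste0("ATG", .neutral_body(lead), insert, .neutral_body(n_flank), "TAA")
  })
  rep <- scan_violations(dna, constraints)
  if (!(kind %in% rep$kind)) {
    stop("internal error: constructed sequence lacks a ", kind, " violation",
         call. = FALSE)
  }
  aa <- .translate_str(dna)
  if (grepl("\\*", sub("\\*$", "", aa))) {
    stop("internal error: fixture contains an internal stop", call. = FALSE)
  }
  record <- seq_record(paste0("viol_", kind), dna, "dna")
  list(record = record,
       translation = seq_record(paste0("viol_", kind), sub("\\*$", "", aa),
                                "protein"),
       constraints = constraints)
}

# pad a DNA segment to a codon multiple, avoiding in-frame stop codons
.pad_to_frame <- function(segment, pad = "C") {
  for (lead in c("", pad, strrep(pad, 2))) {
    for (trail_n in 0:2) {
      s <- paste0(lead, segment, strrep(pad, trail_n))
      if (nchar(s) %% 3L != 0L) next
      aa <- .translate_str(s)
      if (!grepl("\\*", aa)) return(s)
    }
  }
  stop("cannot embed segment without creating a stop codon", call. = FALSE)
}
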