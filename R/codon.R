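# Frame-constrained codon design: recode a protein so that the CDS carries
# no stop triplet (TAA/TAG/TGA) in any of the three reading frames and no
# forbidden motif (by default the Esp3I recognition site on either strand).
# Because out-of-frame stops span at most two adjacent codons and a 6-nt
# motif at most three, a dynamic programme over adjacent-codon-pair states
# is exact; it maximizes the summed log usage weight with a deterministic
# lexicographic tie-break.

#' Build a codon table
#'
#' Standard genetic code with per-codon usage weights. With uniform weights
#' every synonymous codon of an amino acid gets weight 1/degeneracy.
#'
#' @param weights `"uniform"`, or a data.frame with columns `aa`, `codon`,
#'   `weight` (weights are renormalized per amino acid).
#' @return A list of class `codon_table` mapping one-letter amino-acid
#'   codes to data.frames of `codon`, `weight`.
#' @export
codon_table <- function(weights = "uniform") {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  tab <- split(names(gc), unname(gc))
  tab <- lapply(tab, function(cods) {
    cods <- sort(cods)
    data.frame(codon = cods, weight = rep(1 / length(cods), length(cods)),
               stringsAsFactors = FALSE)
  })
  if (is.data.frame(weights)) {
    stopifnot(all(c("aa", "codon", "weight") %in% names(weights)))
    for (aa in names(tab)) {
      w <- weights[weights$aa == aa, ]
      m <- match(tab[[aa]]$codon, w$codon)
      if (anyNA(m)) next
      wt <- w$weight[m]
      if (any(wt <= 0)) stop("codon weights must be positive", call. = FALSE)
      tab[[aa]]$weight <- wt / sum(wt)
    }
  }
  structure(tab, class = "codon_table")
}

#' Read a codon table from TSV
#'
#' Expected columns: `aa`, `codon`, `weight`.
#'
#' @param path Path to a tab-separated file.
#' @return A `codon_table`.
#' @export
read_codon_table <- function(path) {
  codon_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Count stop codons in each reading frame
#'
#' @param seq DNA string (length >= 3).
#' @return Integer vector of length 3: complete stop triplets read at
#'   offsets 0, 1 and 2; incomplete terminal triplets are ignored.
#' @export
stops_by_frame <- function(seq) {
  check_dna(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  vapply(0:2, function(f) {
    if (1L + f > nchar(seq) - 2L) return(0L)
    starts <- seq.int(1L + f, nchar(seq) - 2L, by = 3L)
    sum(substring(seq, starts, starts + 2L) %in% STOP_CODONS)
  }, integer(1))
}

# constraint helpers for the DP ------------------------------------------

junction_stop_free <- function(a, b) {
  six <- paste0(a, b)
  !(substr(six, 2L, 4L) %in% STOP_CODONS) &&
    !(substr(six, 3L, 5L) %in% STOP_CODONS)
}

contains_motif <- function(seq, motifs) {
  any(vapply(motifs, function(m) grepl(m, seq, fixed = TRUE), logical(1)))
}

# does any motif occurrence in `ctx` overlap the final `tail_len` bases?
motif_overlaps_tail <- function(ctx, motifs, tail_len) {
  n <- nchar(ctx)
  for (m in motifs) {
    q <- nchar(m)
    from <- max(1L, n - tail_len - q + 2L)
    if (from > n - q + 1L) next
    win <- substr(ctx, from, n)
    if (grepl(m, win, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Recode a protein into a stop-free, motif-free CDS
#'
#' Finds the codon assignment with zero stop triplets in all three reading
#' frames and no forbidden motif (checked across codon junctions) that
#' maximizes the summed log codon-usage weight. Exact dynamic programme
#' over adjacent-codon-pair states; ties resolve to the lexicographically
#' smallest CDS, so output is deterministic for a fixed table.
#'
#' @param protein Amino-acid string (one-letter codes, no internal stops).
#' @param table A [codon_table].
#' @param forbid_motifs DNA motifs (each at most 7 nt for exact in-DP
#'   screening; longer motifs are verified on the assembled CDS) that must
#'   not occur anywhere in the CDS. Default: Esp3I recognition site on both
#'   strands.
#' @return List of class `optimization_result` with `cds`, `protein`,
#'   `score` (sum of log weights), `feasible`, and `infeasible_at` (first
#'   residue index, 1-based, at which no assignment survives; `NA` when
#'   feasible).
#' @export
optimize_cds <- function(protein, table = codon_table(),
                         forbid_motifs = c(ESP3I_PLUS, ESP3I_MINUS)) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    stop("precondition error: empty protein", call. = FALSE)
  }
  aas <- strsplit(protein, "")[[1L]]
  if (any(aas == "*")) stop("precondition error: internal stop symbol", call. = FALSE)
  unknown <- setdiff(aas, names(table))
  if (length(unknown)) {
    stop("unknown amino acid(s): ", paste(unknown, collapse = ","), call. = FALSE)
  }
  L <- length(aas)
  cods <- lapply(aas, function(a) table[[a]]$codon)
  lw <- lapply(aas, function(a) log(table[[a]]$weight))
  short_motifs <- forbid_motifs[nchar(forbid_motifs) <= 7L]
  long_motifs <- forbid_motifs[nchar(forbid_motifs) > 7L]
  # drop codons that themselves contain a motif
  for (i in seq_len(L)) {
    keep <- !vapply(cods[[i]], contains_motif, logical(1), motifs = short_motifs)
    cods[[i]] <- cods[[i]][keep]
    lw[[i]] <- lw[[i]][keep]
    if (!length(cods[[i]])) {
      return(optimization_failure(protein, i))
    }
  }
  fail <- function(i) optimization_failure(protein, i)
  if (L == 1L) {
    best <- which.max(lw[[1L]])
    ties <- which(abs(lw[[1L]] - lw[[1L]][best]) < 1e-12)
    pick <- ties[order(cods[[1L]][ties])][1L]
    return(optimization_success(cods[[1L]][pick], protein, lw[[1L]][pick]))
  }
  # pair states: list per position i >= 2 of data.frame(prev, cur) indices
  # V[[i]][a, b]: best suffix score for codons (i+1..L) given state
  # (c_{i-1} = cods[[i-1]][a], c_i = cods[[i]][b]); NA means dead state.
  trans_ok <- function(i, a, b, cc) {
    # transition (a at i-1, b at i) -> cc at i+1
    if (!junction_stop_free(cods[[i]][b], cods[[i + 1L]][cc])) return(FALSE)
    ctx <- paste0(cods[[i - 1L]][a], cods[[i]][b], cods[[i + 1L]][cc])
    !motif_overlaps_tail(ctx, short_motifs, 3L)
  }
  n_i <- vapply(cods, length, integer(1))
  # initial states (c1, c2)
  init_ok <- matrix(FALSE, n_i[1L], n_i[2L])
  for (a in seq_len(n_i[1L])) {
    for (b in seq_len(n_i[2L])) {
      six <- paste0(cods[[1L]][a], cods[[2L]][b])
      init_ok[a, b] <- junction_stop_free(cods[[1L]][a], cods[[2L]][b]) &&
        !contains_motif(six, short_motifs)
    }
  }
  if (!any(init_ok)) return(fail(2L))
  # forward reachability to report first infeasible residue
  reach <- vector("list", L)
  reach[[2L]] <- init_ok
  if (L >= 3L) {
    for (i in 2L:(L - 1L)) {
      nxt <- matrix(FALSE, n_i[i], n_i[i + 1L])
      for (b in seq_len(n_i[i])) {
        for (cc in seq_len(n_i[i + 1L])) {
          for (a in seq_len(n_i[i - 1L])) {
            if (reach[[i]][a, b] && trans_ok(i, a, b, cc)) {
              nxt[b, cc] <- TRUE
              break
            }
          }
        }
      }
      if (!any(nxt)) return(fail(i + 1L))
      reach[[i + 1L]] <- nxt
    }
  }
  # backward DP for optimal suffix score
  V <- vector("list", L)
  V[[L]] <- matrix(0, n_i[L - 1L], n_i[L])
  V[[L]][!reach[[L]]] <- NA_real_
  if (L >= 3L) {
    for (i in (L - 1L):2L) {
      v <- matrix(NA_real_, n_i[i - 1L], n_i[i])
      for (a in seq_len(n_i[i - 1L])) {
        for (b in seq_len(n_i[i])) {
          if (!reach[[i]][a, b]) next
          best <- NA_real_
          for (cc in seq_len(n_i[i + 1L])) {
            if (is.na(V[[i + 1L]][b, cc])) next
            if (!trans_ok(i, a, b, cc)) next
            cand <- lw[[i + 1L]][cc] + V[[i + 1L]][b, cc]
            if (is.na(best) || cand > best + 1e-12) best <- cand
          }
          v[a, b] <- best
        }
      }
      V[[i]] <- v
    }
  }
  # choose (c1, c2): maximize lw1 + lw2 + V[[2]], lexicographic tie-break
  best_score <- -Inf; pick <- NULL
  ord1 <- order(cods[[1L]]); ord2 <- order(cods[[2L]])
  for (a in ord1) {
    for (b in ord2) {
      if (!init_ok[a, b] || is.na(V[[2L]][a, b])) next
      sc <- lw[[1L]][a] + lw[[2L]][b] + V[[2L]][a, b]
      if (sc > best_score + 1e-12) { best_score <- sc; pick <- c(a, b) }
    }
  }
  if (is.null(pick)) return(fail(2L))
  choice <- integer(L)
  choice[1:2] <- pick
  if (L >= 3L) {
    for (i in 2L:(L - 1L)) {
      a <- choice[i - 1L]; b <- choice[i]
      target <- V[[i]][a, b]
      nxt <- NA_integer_; nxt_sc <- -Inf
      for (cc in order(cods[[i + 1L]])) {
        if (is.na(V[[i + 1L]][b, cc])) next
        if (!trans_ok(i, a, b, cc)) next
        sc <- lw[[i + 1L]][cc] + V[[i + 1L]][b, cc]
        if (sc > nxt_sc + 1e-12) { nxt_sc <- sc; nxt <- cc }
      }
      choice[i + 1L] <- nxt
    }
  }
  cds <- paste(vapply(seq_len(L), function(i) cods[[i]][choice[i]], character(1)),
               collapse = "")
  score <- sum(vapply(seq_len(L), function(i) lw[[i]][choice[i]], numeric(1)))
  if (length(long_motifs) && contains_motif(cds, long_motifs)) {
    return(fail(NA_integer_))
  }
  optimization_success(cds, protein, score)
}

optimization_success <- function(cds, protein, score) {
  structure(list(cds = cds, protein = protein, score = score,
                 feasible = TRUE, infeasible_at = NA_integer_),
            class = "optimization_result")
}

optimization_failure <- function(protein, at) {
  structure(list(cds = NA_character_, protein = protein, score = -Inf,
                 feasible = FALSE, infeasible_at = at),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<optimization_result> feasible, %d aa, score %.4f\n  %s\n",
                nchar(x$protein), x$score, x$cds))
  } else {
    cat(sprintf("<optimization_result> infeasible (first dead residue: %s)\n",
                x$infeasible_at))
  }
  invisible(x)
}

#' Verify a recoded CDS against its protein
#'
#' @param cds DNA string, length 3x the protein length.
#' @param protein Amino-acid string.
#' @param forbid_motifs Motifs that must be absent.
#' @return `TRUE` iff translation matches, no stop triplet occurs in any
#'   frame, and no forbidden motif is present.
#' @export
verify_recoding <- function(cds, protein,
                            forbid_motifs = c(ESP3I_PLUS, ESP3I_MINUS)) {
  if (nchar(cds) != 3L * nchar(protein)) {
    stop("precondition error: CDS length is not 3x protein length", call. = FALSE)
  }
  translate_cds(cds) == protein &&
    all(stops_by_frame(cds) == 0L) &&
    !contains_motif(cds, forbid_motifs)
}
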