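# Amplicon editing-outcome classification: quality trim, pair merging,
# alignment to the reporter reference, event calling over a guide window,
# and haplotype counting with per-class fractions (unedited,
# substitution-only, N-1, N-2, in-frame, HDR).

#' Analysis window on the reporter reference
#'
#' @param name Window name.
#' @param start,end 0-based half-open coordinates on the reference.
#' @param region Reporter region the window covers (`"mCherry"`, `"SOI"`
#'   or `"other"`); drives phenotype interpretation.
#' @return List of class `analysis_window`.
#' @export
analysis_window <- function(name, start, end, region = "other") {
  stopifnot(end - start >= 20L, start >= 0L)
  structure(list(name = name, start = as.integer(start), end = as.integer(end),
                 region = region),
            class = "analysis_window")
}

#' Read / write analysis windows as TSV
#'
#' Columns: `name`, `start`, `end` (0-based half-open), optional `region`.
#'
#' @param path File path.
#' @return `read_windows`: list of [analysis_window].
#' @export
read_windows <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(x)))
  if (is.null(x$region)) x$region <- "other"
  lapply(seq_len(nrow(x)), function(i) {
    analysis_window(x$name[i], x$start[i], x$end[i], x$region[i])
  })
}

#' @rdname read_windows
#' @param windows List of [analysis_window].
#' @export
write_windows <- function(windows, path) {
  df <- do.call(rbind, lapply(windows, function(w) {
    data.frame(name = w$name, start = w$start, end = w$end, region = w$region,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-trim reads with a 3' sliding window
#'
#' Scanning 5' to 3', the read is truncated just before the first window
#' of `window` bases whose mean Phred quality falls below `min_q`
#' (Trimmomatic-style); trimmed reads shorter than 40 nt are dropped.
#' The operation is idempotent.
#'
#' @param reads FASTQ data.frame (`id`, `seq`, `qual`, Phred+33).
#' @param min_q Mean-quality threshold.
#' @param window Window width in bases.
#' @return Trimmed FASTQ data.frame.
#' @export
quality_trim <- function(reads, min_q = 20L, window = 4L) {
  keep_len <- vapply(reads$qual, function(q) {
    s <- as.integer(charToRaw(q)) - 33L
    n <- length(s)
    if (n < window) return(n)
    cs <- cumsum(c(0L, s))
    means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    bad <- which(means < min_q)
    if (!length(bad)) n else bad[1L] - 1L
  }, numeric(1), USE.NAMES = FALSE)
  out <- reads
  out$seq <- substr(out$seq, 1L, keep_len)
  out$qual <- substr(out$qual, 1L, keep_len)
  out <- out[nchar(out$seq) >= 40L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge read pairs by overlap
#'
#' Read 2 is reverse-complemented; the overlap length (at least
#' `min_overlap`) minimizing the mismatch fraction is chosen and the pair
#' merged when that fraction is at most `max_mismatch_frac`, taking the
#' higher-quality base at conflicting positions.
#'
#' @param r1,r2 Mate FASTQ data.frames (index-matched).
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return List: `merged` FASTQ data.frame, `unmerged` list of the
#'   original pairs that failed to merge.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.25) {
  if (nrow(r1) != nrow(r2)) {
    stop("pairing error: mate counts differ", call. = FALSE)
  }
  n <- nrow(r1)
  seqs <- character(n)
  quals <- character(n)
  ok <- logical(n)
  r2rc <- revcomp(r2$seq)
  r2q <- vapply(r2$qual, function(q) {
    paste(rev(strsplit(q, "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  for (i in seq_len(n)) {
    s1 <- r1$seq[i]; s2 <- r2rc[i]
    ov <- .best_overlap_cpp(s1, s2, as.integer(min_overlap))
    if (ov$len < min_overlap || is.na(ov$frac) || ov$frac > max_mismatch_frac) next
    L <- ov$len
    n1 <- nchar(s1)
    head_seq <- substr(s1, 1L, n1 - L)
    head_q <- substr(r1$qual[i], 1L, n1 - L)
    tail_seq <- substr(s2, L + 1L, nchar(s2))
    tail_q <- substr(r2q[i], L + 1L, nchar(s2))
    o1 <- strsplit(substr(s1, n1 - L + 1L, n1), "")[[1L]]
    o2 <- strsplit(substr(s2, 1L, L), "")[[1L]]
    q1 <- as.integer(charToRaw(substr(r1$qual[i], n1 - L + 1L, n1))) - 33L
    q2 <- as.integer(charToRaw(substr(r2q[i], 1L, L))) - 33L
    take2 <- o1 != o2 & q2 > q1
    cons <- ifelse(take2, o2, o1)
    consq <- ifelse(o1 == o2, pmax(q1, q2), pmax(q1, q2))
    seqs[i] <- paste0(head_seq, paste(cons, collapse = ""), tail_seq)
    quals[i] <- paste0(head_q, rawToChar(as.raw(consq + 33L)), tail_q)
    ok[i] <- TRUE
  }
  merged <- data.frame(id = r1$id[ok], seq = seqs[ok], qual = quals[ok],
                       stringsAsFactors = FALSE)
  list(merged = merged,
       unmerged = list(r1 = r1[!ok, , drop = FALSE],
                       r2 = r2[!ok, , drop = FALSE]))
}

#' Align a read to a reference
#'
#' Affine-gap alignment, global in the read with free end gaps on the
#' reference (the read may start anywhere on the reference). Scoring and
#' tie-breaking are fixed, so alignments are deterministic: ties prefer
#' deletions over insertions, then the leftmost placement; indels are
#' subsequently left-aligned within homopolymers by [call_events].
#'
#' @param read Read sequence (length >= 40).
#' @param reference Reference sequence.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param min_score_frac Reads scoring below this fraction of the perfect
#'   match score are flagged unaligned (`unclassified`).
#' @return List of class `read_alignment`: `score`, `ref_start` (0-based),
#'   `ops` (data.frame `op` in `=`/`X`/`I`/`D`, `len`), `read`,
#'   `reference`, `unaligned`.
#' @export
align_to_reference <- function(read, reference, match = 2L, mismatch = -3L,
                               gap_open = -6L, gap_extend = -1L,
                               min_score_frac = 0.4) {
  check_dna(read, allow_n = TRUE, what = "read")
  if (nchar(read) < 40L) stop("read shorter than 40 nt", call. = FALSE)
  a <- .affine_align_cpp(read, reference, as.integer(match),
                         as.integer(mismatch), as.integer(gap_open),
                         as.integer(gap_extend))
  structure(list(score = a$score, ref_start = a$ref_start,
                 ops = data.frame(op = a$op, len = a$len,
                                  stringsAsFactors = FALSE),
                 read = read, reference = reference,
                 unaligned = a$score < min_score_frac * match * nchar(read)),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cigar <- paste0(x$ops$len, x$ops$op, collapse = "")
  cat(sprintf("<read_alignment> score %d, ref_start %d, %s%s\n", x$score,
              x$ref_start, cigar, if (x$unaligned) " (unaligned)" else ""))
  invisible(x)
}

# left-align an indel within a homopolymer context on the reference;
# returns list(position, inserted) with the leftmost representation
left_align_indel <- function(reference, position, inserted, deleted_len) {
  if (deleted_len > 0L && nchar(inserted) == 0L) {
    while (position > 0L &&
           substr(reference, position, position) ==
           substr(reference, position + deleted_len, position + deleted_len)) {
      position <- position - 1L
    }
  } else if (deleted_len == 0L && nchar(inserted) > 0L) {
    while (position > 0L &&
           substr(reference, position, position) ==
           substr(inserted, nchar(inserted), nchar(inserted))) {
      last <- substr(inserted, nchar(inserted), nchar(inserted))
      inserted <- paste0(last, substr(inserted, 1L, nchar(inserted) - 1L))
      position <- position - 1L
    }
  }
  list(position = position, inserted = inserted)
}

#' Call edit events over an analysis window
#'
#' Walks the alignment, reports indel ops intersecting the window as
#' [edit_event]s (left-aligned within homopolymers), counts in-window
#' substitutions, and reconstructs the read sequence spanning the window.
#' When the repaired reference window is supplied, a haplotype whose
#' windowed sequence aligns to it without any indel is flagged HDR (the
#' repair restored the template's indel structure; substitutions are
#' treated as sequencing error).
#'
#' @param alignment A [align_to_reference] result.
#' @param window An [analysis_window].
#' @param repaired_window Repaired-reference window sequence, or `NULL`.
#' @param hdr_max_mismatch Maximum substitutions tolerated against the
#'   repaired window for an HDR call (default unlimited: class membership
#'   is decided by indel structure alone and substitutions are read as
#'   sequencing error; set to 0 for byte-exact template matching).
#' @return List of class `window_call`: `covered`, `reason`, `events`,
#'   `n_subst`, `window_seq`, `is_hdr`, `fclass`.
#' @export
call_events <- function(alignment, window, repaired_window = NULL,
                        hdr_max_mismatch = Inf) {
  stopifnot(inherits(alignment, "read_alignment"),
            inherits(window, "analysis_window"))
  if (alignment$unaligned) {
    return(window_call(FALSE, "unaligned"))
  }
  ref <- alignment$reference
  rpos <- alignment$ref_start  # 0-based ref cursor
  qpos <- 0L                   # 0-based read cursor
  ops <- alignment$ops
  events <- list()
  n_subst <- 0L
  win_parts <- character(0)
  covered_from <- rpos
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("=", "X")) {
      # overlap of [rpos, rpos+len) with the window
      lo <- max(rpos, window$start); hi <- min(rpos + len, window$end)
      if (lo < hi) {
        win_parts <- c(win_parts,
                       substr(alignment$read, qpos + (lo - rpos) + 1L,
                              qpos + (hi - rpos)))
        if (op == "X") n_subst <- n_subst + (hi - lo)
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      if (rpos < window$end && rpos + len > window$start) {
        la <- left_align_indel(ref, rpos, "", len)
        events[[length(events) + 1L]] <-
          edit_event(window$region, position = la$position, deleted_len = len)
      }
      rpos <- rpos + len
    } else {  # I
      ins <- substr(alignment$read, qpos + 1L, qpos + len)
      if (rpos > window$start && rpos < window$end) {
        la <- left_align_indel(ref, rpos, ins, 0L)
        events[[length(events) + 1L]] <-
          edit_event(window$region, position = la$position, inserted = la$inserted)
        win_parts <- c(win_parts, ins)
      }
      qpos <- qpos + len
    }
  }
  if (covered_from > window$start || rpos < window$end) {
    return(window_call(FALSE, "partial_window_coverage"))
  }
  window_seq <- paste(win_parts, collapse = "")
  has_indel <- length(events) > 0L
  is_hdr <- FALSE
  if (!is.null(repaired_window) && has_indel) {
    cmp <- indel_free_vs(window_seq, repaired_window)
    is_hdr <- cmp$indel_free && cmp$mismatches <= hdr_max_mismatch
  }
  fclass <- if (is_hdr) {
    "HDR"
  } else if (!has_indel) {
    if (n_subst > 0L) "SUBSTITUTION_ONLY" else "UNEDITED"
  } else {
    net <- sum(vapply(events, function(e) nchar(e$inserted) - e$deleted_len,
                      numeric(1)))
    switch(as.character(net %% 3L),
           "2" = "N1", "1" = "N2", "0" = "N3_INFRAME")
  }
  window_call(TRUE, NA_character_, events = events, n_subst = n_subst,
              window_seq = window_seq, is_hdr = is_hdr, fclass = fclass)
}

window_call <- function(covered, reason, events = list(), n_subst = 0L,
                        window_seq = NA_character_, is_hdr = FALSE,
                        fclass = NA_character_) {
  structure(list(covered = covered, reason = reason, events = events,
                 n_subst = n_subst, window_seq = window_seq, is_hdr = is_hdr,
                 fclass = fclass),
            class = "window_call")
}

# does `seq` align to `ref_seq` without insertions or deletions?
indel_free_vs <- function(seq, ref_seq) {
  if (nchar(seq) != nchar(ref_seq)) {
    return(list(indel_free = FALSE, mismatches = NA_integer_))
  }
  a <- .affine_align_cpp(seq, ref_seq, 2L, -3L, -6L, -1L)
  list(indel_free = all(a$op %in% c("=", "X")) && a$ref_start == 0L,
       mismatches = sum(a$len[a$op == "X"]))
}

#' Window sequence of the repaired reference
#'
#' Maps a window given in defective-reference coordinates onto the
#' repaired reference (which differs by the restored segment) and extracts
#' the corresponding sequence.
#'
#' @param reference Defective reference sequence.
#' @param repaired Repaired reference sequence.
#' @param window An [analysis_window] on `reference`.
#' @return The repaired-reference window sequence.
#' @export
repaired_window_seq <- function(reference, repaired, window) {
  a <- .affine_align_cpp(repaired, reference, 2L, -3L, -6L, -1L)
  rpos <- a$ref_start; qpos <- 0L
  parts <- character(0)
  for (k in seq_along(a$op)) {
    op <- a$op[k]; len <- a$len[k]
    if (op %in% c("=", "X")) {
      lo <- max(rpos, window$start); hi <- min(rpos + len, window$end)
      if (lo < hi) {
        parts <- c(parts, substr(repaired, qpos + (lo - rpos) + 1L,
                                 qpos + (hi - rpos)))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else {
      if (rpos > window$start && rpos < window$end) {
        parts <- c(parts, substr(repaired, qpos + 1L, qpos + len))
      }
      qpos <- qpos + len
    }
  }
  paste(parts, collapse = "")
}

#' Classify merged reads into a haplotype table
#'
#' Deduplicates reads into unique haplotypes, aligns each haplotype to the
#' reference, calls events over the window and tabulates per-class read
#' fractions.
#'
#' @param reads Merged FASTQ (or plain `seq`) data.frame.
#' @param reference Reference sequence (defective construct).
#' @param window An [analysis_window].
#' @param repaired Repaired reference sequence, or `NULL` when no HDR
#'   template applies.
#' @param hdr_max_mismatch See [call_events].
#' @return A `haplotype_table`: list with `window`, `haplotypes`
#'   (data.frame `seq`, `count`, `fclass`, `net`), `fractions` (named,
#'   summing to 1 over classified reads), `n_reads`, `n_excluded`,
#'   `exclusion_reasons`.
#' @export
summarize_haplotypes <- function(reads, reference, window, repaired = NULL,
                                 hdr_max_mismatch = Inf) {
  if (!nrow(reads)) stop("empty-table error: no classifiable reads", call. = FALSE)
  rep_win <- if (!is.null(repaired)) {
    repaired_window_seq(reference, repaired, window)
  } else {
    NULL
  }
  tab <- table(reads$seq)
  uniq <- names(tab)
  counts <- as.integer(tab)
  fclass <- character(length(uniq))
  net <- integer(length(uniq))
  winseq <- character(length(uniq))
  excl <- character(0)
  for (i in seq_along(uniq)) {
    aln <- align_to_reference(uniq[i], reference)
    wc <- call_events(aln, window, rep_win, hdr_max_mismatch)
    if (!wc$covered) {
      fclass[i] <- NA_character_
      excl <- c(excl, wc$reason)
      next
    }
    fclass[i] <- wc$fclass
    net[i] <- sum(vapply(wc$events, function(e) nchar(e$inserted) - e$deleted_len,
                         numeric(1)), 0L)
    winseq[i] <- wc$window_seq
  }
  keep <- !is.na(fclass)
  if (!any(keep)) stop("empty-table error: no classifiable reads", call. = FALSE)
  # haplotypes are unique windowed sequences; collapse read-level dupes
  hap <- data.frame(seq = winseq[keep], count = counts[keep],
                    fclass = fclass[keep], net = net[keep],
                    stringsAsFactors = FALSE)
  hap <- stats::aggregate(count ~ seq + fclass + net, data = hap, FUN = sum)
  hap <- hap[order(-hap$count), c("seq", "count", "fclass", "net")]
  rownames(hap) <- NULL
  total <- sum(hap$count)
  fractions <- vapply(FRAME_CLASSES, function(cl) {
    sum(hap$count[hap$fclass == cl]) / total
  }, numeric(1))
  structure(list(window = window, haplotypes = hap, fractions = fractions,
                 n_reads = total, n_excluded = sum(counts[!keep]),
                 exclusion_reasons = table(excl)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> window %s [%d,%d): %d reads, %d haplotypes, %d excluded\n",
              x$window$name, x$window$start, x$window$end, x$n_reads,
              nrow(x$haplotypes), x$n_excluded))
  fr <- x$fractions[x$fractions > 0]
  for (cl in names(fr)) cat(sprintf("  %-17s %6.2f%%\n", cl, 100 * fr[cl]))
  invisible(x)
}

#' Full amplicon classification pipeline
#'
#' Trim, merge, deduplicate and classify paired amplicon reads over one
#' analysis window.
#'
#' @param r1,r2 FASTQ data.frames (or file paths).
#' @param reference Reference construct sequence (or a
#'   `reporter_cassette`).
#' @param window An [analysis_window].
#' @param repaired Repaired reference sequence, `TRUE` to take it from the
#'   cassette's `meta`, or `NULL`.
#' @param min_q,trim_window Quality-trim parameters.
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param hdr_max_mismatch See [call_events].
#' @return A `haplotype_table`.
#' @export
classify_amplicons <- function(r1, r2, reference, window, repaired = NULL,
                               min_q = 20L, trim_window = 4L,
                               min_overlap = 10L, max_mismatch_frac = 0.25,
                               hdr_max_mismatch = Inf) {
  if (is.character(r1) && length(r1) == 1L) r1 <- read_fastq(r1)
  if (is.character(r2) && length(r2) == 1L) r2 <- read_fastq(r2)
  if (inherits(reference, "reporter_cassette")) {
    if (isTRUE(repaired)) repaired <- reference$meta$repaired_seq
    reference <- reference$record$seq
  }
  t1 <- quality_trim(r1, min_q, trim_window)
  t2 <- quality_trim(r2, min_q, trim_window)
  common <- intersect(t1$id, t2$id)
  t1 <- t1[match(common, t1$id), , drop = FALSE]
  t2 <- t2[match(common, t2$id), , drop = FALSE]
  m <- merge_pairs(t1, t2, min_overlap, max_mismatch_frac)
  summarize_haplotypes(m$merged, reference, window, repaired,
                       hdr_max_mismatch)
}
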