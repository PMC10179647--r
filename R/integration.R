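# Transgene integration-site mapping from junction reads: a terminal-k-mer
# edit-distance filter retains transgene-bearing reads, the genomic flank
# beyond the matched transgene end is located in the reference by exact
# seeding with mismatch-tolerant verification, and junction hits are
# clustered into orientation-aware integration calls.

#' Terminal k-mers of a transgene
#'
#' @param transgene A [seq_record] (or DNA string).
#' @param k K-mer length (default 15).
#' @param max_edit Maximum Levenshtein distance for a filter hit.
#' @return List of class `transgene_ends`: `left_kmer`, `right_kmer`, `k`,
#'   `max_edit`.
#' @export
transgene_ends <- function(transgene, k = 15L, max_edit = 2L) {
  seq <- if (inherits(transgene, "seq_record")) transgene$seq else transgene
  stopifnot(k >= 8L, max_edit < k / 3)
  check_dna(seq)
  structure(list(left_kmer = substr(seq, 1L, k),
                 right_kmer = substr(seq, nchar(seq) - k + 1L, nchar(seq)),
                 k = as.integer(k), max_edit = as.integer(max_edit)),
            class = "transgene_ends")
}

# best infix edit distance of any of the 4 oriented terminal k-mers in a
# read; returns list(dist, end=left/right, rc, start, stop) or NULL
best_end_match <- function(read, ends) {
  kmers <- list(
    list(seq = ends$left_kmer, end = "left", rc = FALSE),
    list(seq = ends$right_kmer, end = "right", rc = FALSE),
    list(seq = revcomp(ends$left_kmer), end = "left", rc = TRUE),
    list(seq = revcomp(ends$right_kmer), end = "right", rc = TRUE))
  best <- NULL
  for (km in kmers) {
    h <- .infix_edit_cpp(km$seq, read)
    if (is.null(best) || h$dist < best$dist) {
      best <- list(dist = h$dist, end = km$end, rc = km$rc,
                   start = h$start, stop = h$end)
    }
  }
  best
}

#' Filter reads for transgene terminal k-mers
#'
#' A read (or pair: at least one mate) passes when it contains a substring
#' within Levenshtein distance `max_edit` of either terminal k-mer of the
#' transgene, on either strand.
#'
#' @param reads FASTQ data.frame, or list `list(r1 =, r2 =)` for pairs.
#' @param ends A [transgene_ends].
#' @return The passing reads, same shape as the input.
#' @export
terminal_kmer_filter <- function(reads, ends) {
  stopifnot(inherits(ends, "transgene_ends"))
  hit <- function(seqs) {
    vapply(seqs, function(s) {
      best_end_match(s, ends)$dist <= ends$max_edit
    }, logical(1), USE.NAMES = FALSE)
  }
  if (is.data.frame(reads)) {
    out <- reads[hit(reads$seq), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  keep <- hit(reads$r1$seq) | hit(reads$r2$seq)
  list(r1 = reads$r1[keep, , drop = FALSE], r2 = reads$r2[keep, , drop = FALSE])
}

# locate a flank in the genome by exact seeding from the junction-proximal
# end + mismatch-verification of the remainder; returns
# data.frame(contig, jpos, strand) of unique junction placements
locate_flank <- function(flank, genome, junction_side, max_mismatch = 3L) {
  # junction_side: "end" (junction at the flank's 3' end; left transgene
  # end follows) or "start" (junction at the flank's 5' start)
  hits <- NULL
  fl <- nchar(flank)
  seed_len <- min(20L, fl)
  for (strand in c("+", "-")) {
    for (ci in seq_len(nrow(genome))) {
      gseq <- if (strand == "+") genome$seq[ci] else revcomp(genome$seq[ci])
      glen <- nchar(gseq)
      seed <- if (junction_side == "end") {
        substr(flank, fl - seed_len + 1L, fl)
      } else {
        substr(flank, 1L, seed_len)
      }
      for (p in find_all_fixed(gseq, seed)) {  # 0-based seed start
        fstart <- if (junction_side == "end") p - (fl - seed_len) else p
        if (fstart < 0L || fstart + fl > glen) next
        cand <- substr(gseq, fstart + 1L, fstart + fl)
        mm <- sum(strsplit(cand, "")[[1L]] != strsplit(flank, "")[[1L]])
        if (mm > max_mismatch) next
        # junction coordinate on the strand-local sequence
        jloc <- if (junction_side == "end") fstart + fl else fstart
        # map to plus-strand coordinates
        jpos <- if (strand == "+") jloc else glen - jloc
        hits <- rbind(hits, data.frame(contig = genome$id[ci], jpos = jpos,
                                       strand = strand,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  unique(hits)
}

#' Call transgene integration sites from junction reads
#'
#' Filters reads by terminal k-mer, masks the transgene-matching segment,
#' aligns the remaining genomic flank (at least 20 nt) to the reference by
#' seeded search, and clusters junction hits within `cluster_window` into
#' orientation-aware calls supported by at least `min_support` reads.
#'
#' @param reads FASTQ data.frame of junction reads.
#' @param genome Reference contigs (data.frame `id`, `seq`; original,
#'   without the transgene).
#' @param ends A [transgene_ends].
#' @param min_support Minimum supporting reads per call.
#' @param cluster_window Maximum distance (nt) merged into one call.
#' @return data.frame of calls: `contig`, `position` (0-based insertion
#'   point), `orientation`, `end` (which transgene end the junction
#'   involves), `supporting_reads`.
#' @export
call_integration_sites <- function(reads, genome, ends, min_support = 2L,
                                   cluster_window = 10L) {
  stopifnot(nrow(genome) >= 1L)
  genome <- as_record_df(genome)
  passing <- terminal_kmer_filter(reads, ends)
  raw <- NULL
  for (i in seq_len(nrow(passing))) {
    read <- passing$seq[i]
    m <- best_end_match(read, ends)
    if (m$dist > ends$max_edit) next
    if (m$rc) {  # canonicalize: transgene on the plus strand of the read
      read <- revcomp(read)
      m <- best_end_match(read, ends)
    }
    if (m$end == "left") {
      flank <- substr(read, 1L, m$start)      # genomic side before tg start
      side <- "end"
    } else {
      flank <- substr(read, m$stop + 1L, nchar(read))  # after tg end
      side <- "start"
    }
    if (nchar(flank) < 20L) next  # flank too short, skipped
    hits <- locate_flank(flank, genome, side)
    if (is.null(hits) || nrow(hits) != 1L) next  # ambiguous or absent
    # orientation: transgene plus strand when the flank matched the plus
    # strand of the genome, minus otherwise
    ori <- if (hits$strand == "+") "+" else "-"
    raw <- rbind(raw, data.frame(contig = hits$contig, position = hits$jpos,
                                 orientation = ori, end = m$end,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(raw)) {
    return(data.frame(contig = character(0), position = integer(0),
                      orientation = character(0), end = character(0),
                      supporting_reads = integer(0), stringsAsFactors = FALSE))
  }
  calls <- NULL
  for (key in unique(paste(raw$contig, raw$orientation, raw$end))) {
    grp <- raw[paste(raw$contig, raw$orientation, raw$end) == key, ]
    pos <- sort(grp$position)
    cl_start <- 1L
    brk <- c(which(diff(pos) > cluster_window), length(pos))
    for (b in brk) {
      members <- pos[cl_start:b]
      calls <- rbind(calls, data.frame(
        contig = grp$contig[1L],
        position = as.integer(stats::median(members)),
        orientation = grp$orientation[1L], end = grp$end[1L],
        supporting_reads = length(members), stringsAsFactors = FALSE))
      cl_start <- b + 1L
    }
  }
  calls <- calls[calls$supporting_reads >= min_support, , drop = FALSE]
  calls <- calls[order(calls$contig, calls$position), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Collapse per-end junction calls into integration sites
#'
#' Left- and right-end calls at the same position (within
#' `cluster_window`) on one contig with one orientation describe a single
#' insertion.
#'
#' @param calls Output of [call_integration_sites].
#' @param cluster_window Merge distance (nt).
#' @return data.frame: `contig`, `position`, `orientation`,
#'   `supporting_reads` (summed over ends).
#' @export
integration_sites <- function(calls, cluster_window = 10L) {
  if (!nrow(calls)) {
    return(data.frame(contig = character(0), position = integer(0),
                      orientation = character(0), supporting_reads = integer(0),
                      stringsAsFactors = FALSE))
  }
  sites <- NULL
  for (key in unique(paste(calls$contig, calls$orientation))) {
    grp <- calls[paste(calls$contig, calls$orientation) == key, ]
    grp <- grp[order(grp$position), , drop = FALSE]
    cl_start <- 1L
    brk <- c(which(diff(grp$position) > cluster_window), nrow(grp))
    for (b in brk) {
      members <- grp[cl_start:b, , drop = FALSE]
      sites <- rbind(sites, data.frame(
        contig = members$contig[1L],
        position = as.integer(stats::median(members$position)),
        orientation = members$orientation[1L],
        supporting_reads = sum(members$supporting_reads),
        stringsAsFactors = FALSE))
      cl_start <- b + 1L
    }
  }
  sites <- sites[order(sites$contig, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Write integration calls as TSV / BED
#'
#' @param calls Calls data.frame.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$contig, start = calls$position,
                    end = calls$position + 1L,
                    name = paste0(calls$end, "_junction"),
                    score = calls$supporting_reads, strand = calls$orientation)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
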