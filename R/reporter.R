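# Data model for bivalent traffic-light reporter cassettes.  The construct
# carries one main ORF (mCherry - P2A - exchangeable SOI) followed by a
# P2A-linked blue-fluorophore cassette encoded in the -2 frame and a
# T2A-linked luciferase cassette in the -1 frame, so the net reading-frame
# change produced by an indel selects which downstream reporter is
# translated.  The SOI sits between two Type IIS (Esp3I) sites with
# distinct overhangs and must be free of stop codons in all three frames.

FEATURE_NAMES <- c("promoter", "mCherry", "P2A_1", "SOI", "P2A_2",
                   "mTagBFP2_cassette", "T2A_NanoLuc_cassette", "other")
FRAME_CLASSES <- c("UNEDITED", "N1", "N2", "N3_INFRAME", "HDR",
                   "SUBSTITUTION_ONLY")

#' Construct a reporter cassette object
#'
#' @param record A [seq_record] holding the full construct sequence.
#' @param features data.frame with columns `name` (one of
#'   `r paste(FEATURE_NAMES, collapse = ", ")`), `start`/`end` (0-based
#'   half-open), `frame_shift` (declared reading-frame offset of a
#'   downstream cassette: 0, -1 or -2) and `strand`.
#' @param validate Run [validate_cassette] and stop on violations.
#' @return An object of class `reporter_cassette`.
#' @export
reporter_cassette <- function(record, features, validate = TRUE) {
  stopifnot(inherits(record, "seq_record"), is.data.frame(features))
  req <- c("name", "start", "end", "frame_shift", "strand")
  stopifnot(all(req %in% names(features)))
  features <- features[order(features$start), req, drop = FALSE]
  rownames(features) <- NULL
  x <- structure(list(record = record, features = features),
                 class = "reporter_cassette")
  if (validate) {
    v <- validate_cassette(x)
    if (length(v)) stop("invalid cassette:\n  ", paste(v, collapse = "\n  "),
                        call. = FALSE)
  }
  x
}

#' @export
print.reporter_cassette <- function(x, ...) {
  cat(sprintf("<reporter_cassette> %s (%d nt, %d features)\n",
              x$record$id, nchar(x$record$seq), nrow(x$features)))
  print(x$features)
  invisible(x)
}

feature_of <- function(cassette, name) {
  f <- cassette$features[cassette$features$name == name, , drop = FALSE]
  if (nrow(f) != 1L) return(NULL)
  f
}

feature_seq <- function(cassette, name) {
  f <- feature_of(cassette, name)
  if (is.null(f)) return(NULL)
  substr(cassette$record$seq, f$start + 1L, f$end)
}

#' Scan a sequence for Esp3I recognition sites
#'
#' Finds every occurrence (including overlapping ones) of the recognition
#' hexamer `CGTCTC` on the plus strand and `GAGACG` (its reverse
#' complement, i.e. a minus-strand site) on the plus-strand text.
#'
#' @param seq DNA string over A/C/G/T.
#' @return data.frame with `position` (0-based first base of the hexamer)
#'   and `strand`, ordered by position.
#' @export
scan_esp3i <- function(seq) {
  check_dna(seq, what = "sequence")
  hit <- function(motif, strand) {
    m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(position = as.integer(m) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(hit(ESP3I_PLUS, "+"), hit(ESP3I_MINUS, "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 4-nt overhang generated by Esp3I cutting at a recognition site; the
# enzyme cuts one base downstream of CGTCTC on the top strand, leaving a
# 4-nt 5' overhang (mirrored for minus-strand sites).
esp3i_overhang <- function(seq, position, strand) {
  if (strand == "+") {
    from <- position + 8L
    if (from + 3L > nchar(seq)) return(NA_character_)
    substr(seq, from, from + 3L)
  } else {
    from <- position - 4L
    if (from < 1L) return(NA_character_)
    substr(seq, from, from + 3L)
  }
}

#' Esp3I overhangs of a cassette
#'
#' @param cassette A `reporter_cassette`.
#' @return Character vector of the 4-nt overhangs at each Esp3I site, in
#'   site order.
#' @export
esp3i_overhangs <- function(cassette) {
  seq <- cassette$record$seq
  sites <- scan_esp3i(seq)
  vapply(seq_len(nrow(sites)),
         function(i) esp3i_overhang(seq, sites$position[i], sites$strand[i]),
         character(1))
}

#' Validate a reporter cassette
#'
#' Checks every structural invariant of the cassette model; violations are
#' returned as data (a character vector naming the invariant and its
#' location), never raised.
#'
#' @param cassette A `reporter_cassette`.
#' @return Character vector of violation descriptors; empty iff valid.
#' @export
validate_cassette <- function(cassette) {
  v <- character(0)
  seq <- cassette$record$seq
  f <- cassette$features
  if (!grepl("^[ACGT]+$", seq)) {
    v <- c(v, "record: sequence contains characters outside {A,C,G,T}")
  }
  bad_names <- setdiff(f$name, FEATURE_NAMES)
  if (length(bad_names)) {
    v <- c(v, paste0("features: unknown feature name(s) ",
                     paste(bad_names, collapse = ",")))
  }
  n <- nchar(seq)
  for (i in seq_len(nrow(f))) {
    if (!(f$start[i] >= 0L && f$start[i] < f$end[i] && f$end[i] <= n)) {
      v <- c(v, sprintf("feature %s: coordinates [%d,%d) outside [0,%d)",
                        f$name[i], f$start[i], f$end[i], n))
    }
  }
  if (nrow(f) >= 2L) {
    for (i in 2:nrow(f)) {
      if (f$start[i] < f$end[i - 1L]) {
        v <- c(v, sprintf("features %s/%s overlap", f$name[i - 1L], f$name[i]))
      }
    }
  }
  chk_shift <- function(name, want) {
    ft <- feature_of(cassette, name)
    if (is.null(ft)) return(sprintf("feature %s: missing", name))
    if (ft$frame_shift != want) {
      return(sprintf("feature %s: declared frame shift %d, expected %d",
                     name, ft$frame_shift, want))
    }
    NULL
  }
  v <- c(v, chk_shift("mTagBFP2_cassette", -2L), chk_shift("T2A_NanoLuc_cassette", -1L),
         chk_shift("SOI", 0L))
  soi <- feature_of(cassette, "SOI")
  if (!is.null(soi)) {
    soi_seq <- substr(seq, soi$start + 1L, soi$end)
    if (nchar(soi_seq) %% 3L != 0L) {
      v <- c(v, sprintf("SOI: length %d not a multiple of 3", nchar(soi_seq)))
    }
    if (grepl("^[ACGT]+$", soi_seq) && nchar(soi_seq) >= 3L) {
      st <- stops_by_frame(soi_seq)
      for (fr in which(st > 0L)) {
        off <- stop_offsets(soi_seq, fr - 1L)
        v <- c(v, sprintf("SOI: stop codon in frame +%d at SOI offset %d",
                          fr - 1L, off[1L]))
      }
    }
    sites <- scan_esp3i(seq)
    if (nrow(sites) != 2L) {
      v <- c(v, sprintf("Esp3I: found %d recognition sites, expected exactly 2",
                        nrow(sites)))
    } else {
      up <- sites$position < soi$start
      dn <- sites$position >= soi$end
      if (!(sum(up) == 1L && sum(dn) == 1L)) {
        v <- c(v, "Esp3I: the two sites do not flank the SOI")
      }
      oh <- esp3i_overhangs(cassette)
      if (anyNA(oh)) {
        v <- c(v, "Esp3I: overhang extends outside the sequence")
      } else if (oh[1L] == oh[2L]) {
        v <- c(v, sprintf("Esp3I: overhangs identical (%s); must differ", oh[1L]))
      }
    }
    # main ORF mCherry -> P2A_1 -> SOI contiguous and in one frame
    mch <- feature_of(cassette, "mCherry")
    p2a <- feature_of(cassette, "P2A_1")
    if (!is.null(mch) && !is.null(p2a)) {
      if (!(mch$end == p2a$start && p2a$end == soi$start)) {
        v <- c(v, "main ORF: mCherry, P2A_1 and SOI are not contiguous")
      } else if ((soi$end - mch$start) %% 3L != 0L ||
                 (p2a$start - mch$start) %% 3L != 0L ||
                 (soi$start - mch$start) %% 3L != 0L) {
        v <- c(v, "main ORF: segment boundaries break the reading frame")
      }
      # declared shifts must match the actual frame offset of each cassette:
      # a cassette reached after a net -s indel sits at offset -s mod 3
      for (nm in c("mTagBFP2_cassette", "T2A_NanoLuc_cassette")) {
        ft <- feature_of(cassette, nm)
        if (is.null(ft)) next
        want <- (-ft$frame_shift) %% 3L
        got <- (ft$start - mch$start) %% 3L
        if (got != want) {
          v <- c(v, sprintf("%s: start offset %d mod 3 = %d inconsistent with declared shift %d",
                            nm, ft$start - mch$start, got, ft$frame_shift))
        }
      }
    }
  }
  v
}

# 0-based offsets of stop triplets in a given frame (0/1/2)
stop_offsets <- function(seq, frame) {
  starts <- seq.int(1L + frame, nchar(seq) - 2L, by = 3L)
  starts <- starts[starts + 2L <= nchar(seq)]
  starts[substring(seq, starts, starts + 2L) %in% STOP_CODONS] - 1L
}

#' Exchange the SOI of a cassette
#'
#' Models the Esp3I-mediated swap: the sequence between the unchanged
#' flanks is replaced and all downstream feature coordinates shift by the
#' length difference. The incoming SOI must satisfy the same design rules
#' as the resident one.
#'
#' @param cassette A valid `reporter_cassette`.
#' @param new_soi A [seq_record] with the replacement SOI.
#' @return A new, valid `reporter_cassette`.
#' @export
swap_soi <- function(cassette, new_soi) {
  stopifnot(inherits(cassette, "reporter_cassette"), inherits(new_soi, "seq_record"))
  s <- new_soi$seq
  check_dna(s, what = "new SOI")
  if (nchar(s) %% 3L != 0L) {
    stop(sprintf("design error: SOI length %d is not a multiple of 3", nchar(s)),
         call. = FALSE)
  }
  st <- stops_by_frame(s)
  if (any(st > 0L)) {
    fr <- which(st > 0L)[1L] - 1L
    stop(sprintf("design error: stop codon in frame +%d at SOI offset %d",
                 fr, stop_offsets(s, fr)[1L]), call. = FALSE)
  }
  if (nrow(scan_esp3i(s)) > 0L) {
    stop("design error: new SOI contains an internal Esp3I site", call. = FALSE)
  }
  soi <- feature_of(cassette, "SOI")
  if (is.null(soi)) stop("cassette has no SOI feature", call. = FALSE)
  old <- cassette$record$seq
  delta <- nchar(s) - (soi$end - soi$start)
  seq2 <- paste0(substr(old, 1L, soi$start), s,
                 substr(old, soi$end + 1L, nchar(old)))
  f <- cassette$features
  for (i in seq_len(nrow(f))) {
    if (f$name[i] == "SOI") {
      f$end[i] <- f$start[i] + nchar(s)
    } else if (f$start[i] >= soi$end) {
      f$start[i] <- f$start[i] + delta
      f$end[i] <- f$end[i] + delta
    }
  }
  rec <- seq_record(cassette$record$id, seq2,
                    paste0(cassette$record$description, " [SOI=", new_soi$id, "]"))
  reporter_cassette(rec, f, validate = TRUE)
}

# --- edit events and frame classes --------------------------------------

#' Create an edit event
#'
#' A located indel or HDR incorporation on a reporter region.
#'
#' @param region `"mCherry"`, `"SOI"` or `"other"`.
#' @param position 0-based leftmost affected base.
#' @param inserted Inserted bases (possibly empty).
#' @param deleted_len Number of deleted bases.
#' @param is_hdr Template-directed repair event.
#' @param n_subst Number of recorded substitutions (for
#'   substitution-only haplotypes).
#' @return List of class `edit_event`.
#' @export
edit_event <- function(region, position = 0L, inserted = "", deleted_len = 0L,
                       is_hdr = FALSE, n_subst = 0L) {
  stopifnot(region %in% c("mCherry", "SOI", "other"))
  if (!is_hdr && nchar(inserted) == 0L && deleted_len == 0L && n_subst == 0L) {
    stop("empty edit event: no insertion, deletion, HDR or substitution",
         call. = FALSE)
  }
  structure(list(region = region, position = as.integer(position),
                 inserted = inserted, deleted_len = as.integer(deleted_len),
                 is_hdr = is_hdr, n_subst = as.integer(n_subst)),
            class = "edit_event")
}

#' Reading-frame class of an edit event
#'
#' The class is defined by the net indel length modulo 3: `N1` (net = -1
#' mod 3) brings the -1-frame luciferase cassette into frame, `N2` (net =
#' -2 mod 3) the -2-frame blue-fluorophore cassette, and `N3_INFRAME` is a
#' frame-preserving indel. Insertions and deletions with the same net
#' residue share a class.
#'
#' @param event An [edit_event].
#' @return One of `r paste(FRAME_CLASSES, collapse = ", ")`.
#' @export
frame_class <- function(event) {
  stopifnot(inherits(event, "edit_event"))
  if (isTRUE(event$is_hdr)) return("HDR")
  net <- nchar(event$inserted) - event$deleted_len
  if (net == 0L && event$deleted_len == 0L) {
    return(if (event$n_subst > 0L) "SUBSTITUTION_ONLY" else "UNEDITED")
  }
  switch(as.character(net %% 3L),
         "2" = "N1", "1" = "N2", "0" = "N3_INFRAME")
}

#' Predict the reporter phenotype of one integrant
#'
#' Maps an edited region and frame class to the four boolean readouts.
#' An in-frame indel in mCherry is assumed to disrupt the fluorophore
#' (controlled by `inframe_disrupts_function`); an in-frame indel in the
#' SOI leaves mCherry intact because the upstream P2A has already released
#' it.
#'
#' @param region `"mCherry"` or `"SOI"`.
#' @param fclass A frame class string (see [frame_class]).
#' @param inframe_disrupts_function Treat in-frame indels in mCherry as
#'   destroying fluorescence.
#' @return Named logical vector `mCherry`, `moxGFP`, `mTagBFP2`, `NanoLuc`.
#' @export
predict_phenotype <- function(region, fclass, inframe_disrupts_function = TRUE) {
  if (!region %in% c("mCherry", "SOI")) {
    stop("unsupported region: ", region, call. = FALSE)
  }
  stopifnot(fclass %in% FRAME_CLASSES)
  ph <- function(mch, gfp, bfp, nluc) {
    c(mCherry = mch, moxGFP = gfp, mTagBFP2 = bfp, NanoLuc = nluc)
  }
  if (fclass %in% c("UNEDITED", "SUBSTITUTION_ONLY")) {
    return(ph(TRUE, FALSE, FALSE, FALSE))
  }
  if (fclass == "HDR") return(ph(TRUE, TRUE, FALSE, FALSE))
  if (region == "mCherry") {
    switch(fclass,
           N1 = ph(FALSE, FALSE, FALSE, TRUE),
           N2 = ph(FALSE, FALSE, TRUE, FALSE),
           N3_INFRAME = if (inframe_disrupts_function) {
             ph(FALSE, FALSE, FALSE, FALSE)
           } else {
             ph(TRUE, FALSE, FALSE, FALSE)
           })
  } else {
    switch(fclass,
           N1 = ph(TRUE, FALSE, FALSE, TRUE),
           N2 = ph(TRUE, FALSE, TRUE, FALSE),
           N3_INFRAME = ph(TRUE, FALSE, FALSE, FALSE))
  }
}

#' Combine integrant phenotypes into a cell phenotype
#'
#' Cells with several reporter integrants light up for every readout any
#' integrant produces: the cell phenotype is the elementwise OR.
#'
#' @param integrant_phenotypes Non-empty list of phenotype vectors.
#' @return Named logical vector.
#' @export
cell_phenotype <- function(integrant_phenotypes) {
  if (!length(integrant_phenotypes)) {
    stop("precondition error: no integrant phenotypes", call. = FALSE)
  }
  Reduce(`|`, integrant_phenotypes)
}
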