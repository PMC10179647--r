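# Bundled synthetic reporter construct.  The sequence is generated in code
# (no real fluorophore or luciferase CDS is shipped): each protein segment
# is a synthetic stand-in recoded with the package's own codon optimizer so
# the architecture -- main ORF, Esp3I-flanked stop-free SOI, -2 and -1
# frame cassettes -- is exact while the residues are arbitrary.  The SOI is
# a "defective" target carrying a 39-bp in-frame deletion whose restored
# segment defines the HDR template, mirroring the published reporter's
# design.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# run code under a temporary RNG state
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(n) {
  # no internal Met: ATG is methionine's only codon and is followed by a
  # frame+1 TGA whenever the next codon starts with A, which makes many
  # Met-containing proteins impossible to recode stop-free in all frames
  paste(c("M", sample(setdiff(AA20, "M"), n - 1L, replace = TRUE)),
        collapse = "")
}

# random DNA free of Esp3I motifs
random_dna_clean <- function(n) {
  repeat {
    s <- random_dna(n)
    if (nrow(scan_esp3i(s)) == 0L) return(s)
  }
}

# P2A-like linkers carrying the two Esp3I sites (distinct overhangs TTGG /
# CCTC); 24 nt each, stop-free in frame 0
P2A_ESP3I_UP <- "GGAAGCGGACGTCTCATTGGAGCC"
P2A_ESP3I_DOWN <- "GGAAGCGGAACCTCAGAGACGGCC"

#' Build the bundled synthetic traffic-light reporter
#'
#' Deterministically constructs a reporter cassette with the bivalent
#' traffic-light architecture: promoter, mCherry-like CDS, P2A linker with
#' an Esp3I site, an exchangeable SOI (a defective target CDS carrying a
#' 39-bp in-frame deletion, stop-free in all three frames), a second
#' P2A/Esp3I linker, a -2-frame blue-fluorophore cassette and a -1-frame
#' luciferase cassette, closed by an in-frame stop. All protein segments
#' are synthetic stand-ins recoded by [optimize_cds].
#'
#' The returned cassette carries a `meta` element with: `junction`
#' (0-based construct coordinate of the SOI deletion site), `restored`
#' (the missing 39-mer), `repaired_seq` (the full construct with the
#' segment restored) and `soi_full_cds`.
#'
#' @param seed Integer base seed for the deterministic construction.
#' @return A validated `reporter_cassette`.
#' @export
synthetic_reporter <- function(seed = 104729L) {
  for (k in 0:49) {
    cas <- try(local_seed(seed + k, build_reporter_once()), silent = TRUE)
    if (!inherits(cas, "try-error")) return(cas)
  }
  stop("failed to assemble a valid synthetic reporter", call. = FALSE)
}

build_reporter_once <- function() {
  cds_mch <- optimize_cds(random_protein(80L))$cds
  cds_bfp <- optimize_cds(random_protein(60L))$cds
  cds_nluc <- optimize_cds(random_protein(60L))$cds
  full_soi <- optimize_cds(random_protein(100L))$cds
  if (anyNA(c(cds_mch, cds_bfp, cds_nluc, full_soi))) stop("infeasible protein")
  # carve the 39-bp (13-codon) deletion out of the SOI, keeping it
  # stop-free in all frames and Esp3I-free at the new junction
  del <- NA_integer_
  for (cstart in 35:60) {  # codon index, 1-based
    from <- (cstart - 1L) * 3L + 1L
    cand <- paste0(substr(full_soi, 1L, from - 1L),
                   substr(full_soi, from + 39L, nchar(full_soi)))
    if (all(stops_by_frame(cand) == 0L) && nrow(scan_esp3i(cand)) == 0L) {
      del <- from
      delta_soi <- cand
      break
    }
  }
  if (is.na(del)) stop("no clean deletion window")
  restored <- substr(full_soi, del, del + 38L)
  promoter <- random_dna_clean(150L)
  tail <- random_dna_clean(30L)
  parts <- list(promoter = promoter, mCherry = cds_mch, P2A_1 = P2A_ESP3I_UP,
                SOI = delta_soi, P2A_2 = P2A_ESP3I_DOWN,
                sp1 = "CA", mTagBFP2_cassette = cds_bfp,
                sp2 = "GA", T2A_NanoLuc_cassette = cds_nluc,
                close = paste0("CATAA", tail))
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  seq <- paste(unlist(parts), collapse = "")
  feat_names <- c("promoter", "mCherry", "P2A_1", "SOI", "P2A_2",
                  "mTagBFP2_cassette", "T2A_NanoLuc_cassette")
  shifts <- c(promoter = 0L, mCherry = 0L, P2A_1 = 0L, SOI = 0L, P2A_2 = 0L,
              mTagBFP2_cassette = -2L, T2A_NanoLuc_cassette = -1L)
  features <- data.frame(
    name = feat_names,
    start = unname(starts[feat_names]),
    end = unname(ends[feat_names]),
    frame_shift = unname(shifts[feat_names]),
    strand = "+", stringsAsFactors = FALSE)
  rec <- seq_record("synthetic_tlr", seq,
                    "synthetic bivalent traffic-light reporter construct")
  cas <- reporter_cassette(rec, features, validate = TRUE)
  junction <- unname(starts["SOI"]) + del - 1L  # 0-based construct coord
  repaired <- paste0(substr(seq, 1L, junction), restored,
                     substr(seq, junction + 1L, nchar(seq)))
  cas$meta <- list(junction = junction, restored = restored,
                   repaired_seq = repaired, soi_full_cds = full_soi)
  cas
}

#' Assemble an HDR template for the reporter's deleted segment
#'
#' Two homology arms copied from the construct around the deletion
#' junction flank the restored segment; with the defaults this yields the
#' canonical 80 + 39 + 80 = 199-nt single-stranded template.
#'
#' @param cassette A cassette from [synthetic_reporter] (needs `meta`).
#' @param arm Homology-arm length in nt.
#' @return A [seq_record] of length `2 * arm + nchar(restored)`.
#' @export
build_hdr_template <- function(cassette, arm = 80L) {
  stopifnot(!is.null(cassette$meta))
  j <- cassette$meta$junction
  seq <- cassette$record$seq
  stopifnot(j - arm >= 0L, j + arm <= nchar(seq))
  tpl <- paste0(substr(seq, j - arm + 1L, j), cassette$meta$restored,
                substr(seq, j + 1L, j + arm))
  seq_record("hdr_template", tpl,
             sprintf("%d-nt arms flanking the %d-nt restored segment",
                     arm, nchar(cassette$meta$restored)))
}

#' Design a guide for a reporter region
#'
#' Picks the protospacer whose predicted cut site lies closest to the
#' region's target point (the SOI deletion junction, or the centre of
#' mCherry) with a valid PAM and a unique target match.
#'
#' @param cassette A cassette from [synthetic_reporter].
#' @param region `"SOI"` or `"mCherry"`.
#' @param enzyme `"spCas9"`, `"saCas9"` or `"asCas12a"`.
#' @return A [cut_site_model].
#' @export
design_guide <- function(cassette, region = c("SOI", "mCherry"),
                         enzyme = "spCas9") {
  region <- match.arg(region)
  seq <- cassette$record$seq
  target <- if (region == "SOI") {
    cassette$meta$junction
  } else {
    f <- feature_of(cassette, "mCherry")
    (f$start + f$end) %/% 2L
  }
  geom <- enzyme_geometry(enzyme)
  n <- nchar(seq)
  best <- NULL
  for (p in order(abs(seq_len(n) - 1L - target))) {
    p0 <- p - 1L  # candidate protospacer start, 0-based
    if (geom$pam_side == "3p") {
      pam_at <- p0 + geom$proto_len
      if (pam_at + nchar(geom$pam) > n) next
      pam_seq <- substr(seq, pam_at + 1L, pam_at + nchar(geom$pam))
      cut <- p0 + geom$proto_len + geom$cut_from_pam
    } else {
      if (p0 - nchar(geom$pam) < 0L || p0 + geom$proto_len > n) next
      pam_seq <- substr(seq, p0 - nchar(geom$pam) + 1L, p0)
      cut <- p0 + geom$cut_top
    }
    if (!iupac_match(pam_seq, geom$pam)) next
    proto <- substr(seq, p0 + 1L, p0 + geom$proto_len)
    model <- cut_site_model(enzyme, proto, pam_seq)
    loc <- try(locate_cut(model, seq), silent = TRUE)
    if (inherits(loc, "try-error")) next
    if (abs(cut - target) > 40L) next
    best <- model
    break
  }
  if (is.null(best)) stop("no unique guide near the target site", call. = FALSE)
  best
}

#' Analysis window centred on a guide's cut site
#'
#' @param cassette A reporter cassette.
#' @param model A [cut_site_model] targeting the cassette.
#' @param width Window width in nt.
#' @param name Window name.
#' @return An [analysis_window] in construct coordinates.
#' @export
guide_window <- function(cassette, model, width = 100L, name = NULL) {
  cut <- locate_cut(model, cassette$record$seq)
  start <- cut - width %/% 2L
  f <- cassette$features
  hit <- f$name[f$start <= cut & f$end > cut]
  region <- if (length(hit) && hit[1L] %in% c("mCherry", "SOI")) hit[1L] else "other"
  analysis_window(name %||% paste0(region, "_window"), start, start + width,
                  region = region)
}

#' Design amplicon primers bracketing a window
#'
#' @param cassette A reporter cassette.
#' @param window An [analysis_window] on the construct.
#' @param amplicon_len Target amplicon length (nt).
#' @param primer_len Primer length (nt).
#' @return Character vector `c(forward, reverse)`; the reverse primer is
#'   given 5'->3' on the minus strand, as ordered for synthesis.
#' @export
design_primers <- function(cassette, window, amplicon_len = 430L,
                           primer_len = 24L) {
  seq <- cassette$record$seq
  centre <- (window$start + window$end) %/% 2L
  a0 <- max(0L, centre - amplicon_len %/% 2L)
  b0 <- min(nchar(seq), a0 + amplicon_len)
  stopifnot(a0 + primer_len < window$start, b0 - primer_len > window$end)
  fwd <- substr(seq, a0 + 1L, a0 + primer_len)
  rev <- revcomp(substr(seq, b0 - primer_len + 1L, b0))
  c(forward = fwd, reverse = rev)
}
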