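# Shared fixtures (built once per run) and independent oracles used to
# freeze expected values.

fix_cassette <- synthetic_reporter()
fix_guide_soi <- design_guide(fix_cassette, "SOI")
fix_guide_mch <- design_guide(fix_cassette, "mCherry")
fix_win_soi <- guide_window(fix_cassette, fix_guide_soi)
fix_win_mch <- guide_window(fix_cassette, fix_guide_mch)
fix_primers_soi <- design_primers(fix_cassette, fix_win_soi)
fix_primers_mch <- design_primers(fix_cassette, fix_win_mch)
fix_template <- build_hdr_template(fix_cassette)

# brute-force sliding-window motif scan
oracle_scan_esp3i <- function(seq) {
  out <- NULL
  for (i in seq_len(nchar(seq) - 5L)) {
    hex <- substr(seq, i, i + 5L)
    if (hex == "CGTCTC") out <- rbind(out, data.frame(position = i - 1L,
                                                      strand = "+"))
    if (hex == "GAGACG") out <- rbind(out, data.frame(position = i - 1L,
                                                      strand = "-"))
  }
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out$strand <- as.character(out$strand)
  out
}

# frame-class oracle via the construct's geometry: apply the net length
# change upstream of the downstream cassettes and see which one lands in
# the main reading frame
oracle_frame_class <- function(ins_len, del_len, cassette = fix_cassette) {
  if (ins_len == 0L && del_len == 0L) return("UNEDITED")
  net <- ins_len - del_len
  f <- cassette$features
  orf <- f$start[f$name == "mCherry"]
  nluc <- f$start[f$name == "T2A_NanoLuc_cassette"]
  bfp <- f$start[f$name == "mTagBFP2_cassette"]
  if ((nluc + net - orf) %% 3L == 0L) return("N1")
  if ((bfp + net - orf) %% 3L == 0L) return("N2")
  "N3_INFRAME"
}

# plain-R affine-gap fitting alignment, score only (Gotoh)
oracle_align_score <- function(read, ref, match = 2, mismatch = -3,
                               gap_open = -6, gap_extend = -1) {
  m <- nchar(read); n <- nchar(ref)
  rd <- strsplit(read, "")[[1L]]
  rf <- strsplit(ref, "")[[1L]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L)
  Y <- matrix(NEG, m + 1L, n + 1L)
  M[1L, ] <- 0
  for (i in 2L:(m + 1L)) X[i, 1L] <- gap_open + (i - 1L) * gap_extend
  for (i in 2L:(m + 1L)) {
    for (j in 2L:(n + 1L)) {
      s <- if (rd[i - 1L] == rf[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] + gap_open + gap_extend,
                     Y[i - 1L, j] + gap_open + gap_extend,
                     X[i - 1L, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1L] + gap_open + gap_extend,
                     X[i, j - 1L] + gap_open + gap_extend,
                     Y[i, j - 1L] + gap_extend)
    }
  }
  max(M[m + 1L, ], X[m + 1L, ], Y[m + 1L, ])
}

# exhaustive codon-assignment search: feasibility and best score
oracle_optimize <- function(protein, tab = codon_table(),
                            motifs = c("CGTCTC", "GAGACG")) {
  aas <- strsplit(protein, "")[[1L]]
  cods <- lapply(aas, function(a) tab[[a]]$codon)
  lw <- lapply(aas, function(a) stats::setNames(log(tab[[a]]$weight),
                                                tab[[a]]$codon))
  grid <- do.call(expand.grid, c(cods, list(stringsAsFactors = FALSE,
                                            KEEP.OUT.ATTRS = FALSE)))
  cds <- do.call(paste0, grid)
  L <- 3L * length(aas)
  ok <- rep(TRUE, length(cds))
  for (i in seq_len(L - 2L)) {
    ok <- ok & !(substr(cds, i, i + 2L) %in% c("TAA", "TAG", "TGA"))
  }
  for (m in motifs) ok <- ok & !grepl(m, cds, fixed = TRUE)
  if (!any(ok)) return(list(feasible = FALSE, score = -Inf))
  sc <- rep(0, length(cds))
  for (k in seq_along(aas)) sc <- sc + lw[[k]][grid[[k]]]
  sc[!ok] <- -Inf
  list(feasible = TRUE, score = max(sc),
       best_cds = min(cds[ok & abs(sc - max(sc)) < 1e-9]))
}

# deterministic non-uniform codon table (rank-skewed weights) so score
# comparisons exercise the optimizer's objective
skewed_codon_table <- function() {
  tab <- codon_table()
  for (aa in names(tab)) {
    w <- seq_len(nrow(tab[[aa]]))
    tab[[aa]]$weight <- w / sum(w)
  }
  tab
}

# infix edit distance oracle (independent implementation)
oracle_infix_dist <- function(pattern, text) {
  drop(utils::adist(pattern, text, partial = TRUE))
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
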