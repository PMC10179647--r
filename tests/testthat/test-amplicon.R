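make_fastq <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("?", nchar(seqs))  # Q30
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

test_that("quality trimming cuts low-quality tails and is idempotent", {
  q30 <- strrep("?", 100)
  good <- make_fastq(random_dna(100), q30)
  expect_identical(quality_trim(good, 20, 4), good)
  # 80 good bases then a Q2 tail of 20 nt
  tail_q <- paste0(strrep("?", 80), strrep("#", 20))
  read <- make_fastq(random_dna(100), tail_q)
  trimmed <- quality_trim(read, 20, 4)
  # first window with mean < 20 starts at base 79 ((30+30+2+2)/4 = 16),
  # so 78 bases survive
  expect_equal(nchar(trimmed$seq), 78L)
  expect_identical(quality_trim(trimmed, 20, 4), trimmed)
  # reads collapsing below 40 nt are dropped
  short <- make_fastq(random_dna(50), paste0(strrep("?", 30), strrep("#", 20)))
  expect_equal(nrow(quality_trim(short, 20, 4)), 0L)
})

test_that("pair merging reconstructs the amplicon and resolves conflicts by quality", {
  set.seed(51)
  amplicon <- random_dna(400)
  r1 <- make_fastq(substr(amplicon, 1, 250))
  r2 <- make_fastq(revcomp(substr(amplicon, 151, 400)))
  m <- merge_pairs(r1, r2, min_overlap = 10, max_mismatch_frac = 0.25)
  expect_equal(nrow(m$merged), 1L)
  expect_equal(m$merged$seq, amplicon)
  expect_equal(nchar(m$merged$qual), 400L)

  # amplicon longer than both reads: no overlap, pair stays unmerged
  long_amp <- random_dna(600)
  r1l <- make_fastq(substr(long_amp, 1, 250))
  r2l <- make_fastq(revcomp(substr(long_amp, 351, 600)))
  ml <- merge_pairs(r1l, r2l, min_overlap = 10, max_mismatch_frac = 0.02)
  expect_equal(nrow(ml$merged), 0L)
  expect_equal(nrow(ml$unmerged$r1), 1L)

  # conflicting base in the overlap: the higher-quality read wins
  amp <- random_dna(300)
  s1 <- substr(amp, 1, 200)
  mism_pos <- 180L
  old <- substr(s1, mism_pos, mism_pos)
  substr(s1, mism_pos, mism_pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  q1 <- paste0(strrep("I", 200))  # Q40 on read 1
  r1c <- make_fastq(s1, q1)
  r2c <- make_fastq(revcomp(substr(amp, 101, 300)), strrep("+", 200))  # Q10
  mc <- merge_pairs(r1c, r2c, min_overlap = 10, max_mismatch_frac = 0.25)
  expect_equal(substr(mc$merged$seq, mism_pos, mism_pos),
               substr(s1, mism_pos, mism_pos))

  expect_error(merge_pairs(r1, make_fastq(c("A", "C"))), "pairing error")
})

test_that("alignment scores match a plain-R DP oracle on random string pairs", {
  set.seed(52)
  for (i in 1:100) {
    ref <- random_dna(sample(45:60, 1))
    read <- if (i %% 3 == 0) {
      random_dna(sample(40:55, 1))
    } else {
      # mutated subsequence of the reference
      r <- substr(ref, 1, sample(44:nchar(ref), 1))
      if (i %% 2 == 0) r <- paste0(substr(r, 1, 20), substr(r, 24, nchar(r)))
      ch <- strsplit(r, "")[[1]]
      p <- sample(length(ch), 2)
      ch[p] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      paste(ch, collapse = "")
    }
    got <- align_to_reference(read, ref)
    expect_equal(got$score, oracle_align_score(read, ref), label = i)
    # ops must reconstruct the read length and the reference span
    qlen <- sum(got$ops$len[got$ops$op %in% c("=", "X", "I")])
    expect_equal(qlen, nchar(read))
  }
})

test_that("alignment recovers planted indels as single ops", {
  set.seed(53)
  ref <- random_dna(300)
  read <- substr(ref, 51, 250)
  expect_equal(align_to_reference(read, ref)$ops$op, "=")

  del2 <- paste0(substr(read, 1, 100), substr(read, 103, 200))
  ops <- align_to_reference(del2, ref)$ops
  expect_equal(ops$op[ops$op == "D"], "D")
  expect_equal(ops$len[ops$op == "D"], 2L)
  expect_equal(nrow(ops[ops$op == "D", ]), 1L)

  # the 39-nt restored segment aligns as one insertion against the
  # defective reference
  cassette_seq <- fix_cassette$record$seq
  j <- fix_cassette$meta$junction
  hdr_read <- substr(fix_cassette$meta$repaired_seq, j - 150, j + 189)
  ops39 <- align_to_reference(hdr_read, cassette_seq)$ops
  ins <- ops39[ops39$op == "I", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$len, 39L)
})

test_that("event calling left-aligns homopolymer indels and respects window coverage", {
  # reference with an A6 homopolymer (0-based 80..85); delete one A
  set.seed(59)
  ref <- paste0(random_dna(79), "C", "AAAAAA", "G", random_dna(79))
  drop_base <- function(s, p) {  # delete 1-based position p
    paste0(substr(s, 1, p - 1), substr(s, p + 1, nchar(s)))
  }
  read <- substr(drop_base(ref, 84), 21, 145)
  win <- analysis_window("w", 40, 120, region = "SOI")
  aln <- align_to_reference(read, ref)
  wc <- call_events(aln, win)
  expect_true(wc$covered)
  expect_equal(length(wc$events), 1L)
  ev <- wc$events[[1]]
  expect_equal(ev$deleted_len, 1L)
  # oracle by exhaustive shift: the deletion positions equivalent to the
  # observed molecule are exactly the homopolymer, so the leftmost
  # representation is its first base (1-based 81 = 0-based 80)
  edited <- drop_base(ref, 84)
  equiv <- vapply(78:88, function(p) drop_base(ref, p) == edited, logical(1))
  expect_equal(min((78:88)[equiv]), 81L)
  expect_equal(ev$position, 80L)

  # all-match alignment yields no events
  clean <- call_events(align_to_reference(substr(ref, 21, 140), ref), win)
  expect_equal(length(clean$events), 0L)
  expect_equal(clean$fclass, "UNEDITED")

  # reads not spanning the window are excluded with a reason
  shorty <- call_events(align_to_reference(substr(ref, 60, 110), ref), win)
  expect_false(shorty$covered)
  expect_equal(shorty$reason, "partial_window_coverage")
})

test_that("haplotype summaries recover constructed class mixtures exactly", {
  seq <- fix_cassette$record$seq
  cut <- as.integer(locate_cut(fix_guide_soi, seq))
  win <- fix_win_soi
  a0 <- win$start - 120
  b0 <- win$end + 120
  ref_mol <- substr(seq, a0 + 1, b0)
  del2 <- paste0(substr(seq, a0 + 1, cut - 1), substr(seq, cut + 2, b0))
  reads <- make_fastq(c(rep(ref_mol, 50), rep(del2, 50)))
  tab <- summarize_haplotypes(reads, seq, win)
  expect_s3_class(tab, "haplotype_table")
  expect_equal(sum(tab$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(tab$fractions["UNEDITED"]), 0.5)
  expect_equal(unname(tab$fractions["N2"]), 0.5)
  expect_equal(tab$n_reads, 100L)
  expect_error(summarize_haplotypes(make_fastq(character(0)), seq, win),
               "empty-table")
})

test_that("substitution errors alone never masquerade as indel classes", {
  mols <- rep(fix_cassette$record$seq, 5)
  reads <- simulate_amplicon_reads(
    mols, fix_primers_soi,
    read_sim_params(n_pairs = 2000, substitution_error = 0.005, seed = 54))
  tab <- classify_amplicons(reads$r1, reads$r2, fix_cassette$record$seq,
                            fix_win_soi)
  no_indel <- tab$fractions["UNEDITED"] + tab$fractions["SUBSTITUTION_ONLY"]
  expect_gte(unname(no_indel), 0.999)
})

test_that("the classification pipeline recovers a known mixture within 3 SD", {
  sp <- condition_spectrum(default_indel_spectrum(), 2L)  # net = -1 class
  mols <- simulate_molecules(fix_cassette, fix_guide_soi, 600, spectrum = sp,
                             edit_frac = 0.3, seed = 55)
  reads <- simulate_amplicon_reads(
    mols, fix_primers_soi,
    read_sim_params(n_pairs = 5000, substitution_error = 0.001, seed = 56))
  tab <- classify_amplicons(reads$r1, reads$r2, fix_cassette$record$seq,
                            fix_win_soi)
  truth <- mean(nchar(mols) != nchar(fix_cassette$record$seq))
  sd3 <- 3 * sqrt(truth * (1 - truth) / 5000)
  expect_lt(abs(unname(tab$fractions["N1"]) - truth), sd3)
  expect_equal(sum(tab$fractions), 1, tolerance = 1e-9)
})

test_that("HDR haplotypes are called only against the repaired reference", {
  mols <- simulate_molecules(fix_cassette, fix_guide_soi, 50, hdr_frac = 1,
                             seed = 57)
  reads <- simulate_amplicon_reads(
    mols, fix_primers_soi,
    read_sim_params(n_pairs = 400, substitution_error = 0.001, seed = 58))
  with_tpl <- classify_amplicons(reads$r1, reads$r2, fix_cassette,
                                 fix_win_soi, repaired = TRUE)
  expect_equal(unname(with_tpl$fractions["HDR"]), 1)
  # without the repaired reference the same reads are in-frame insertions
  without <- classify_amplicons(reads$r1, reads$r2, fix_cassette$record$seq,
                                fix_win_soi)
  expect_equal(unname(without$fractions["N3_INFRAME"]), 1)

  # byte-exact template matching demotes haplotypes whose sequencing
  # errors fall inside the window to the in-frame class
  strict <- classify_amplicons(reads$r1, reads$r2, fix_cassette,
                               fix_win_soi, repaired = TRUE,
                               hdr_max_mismatch = 0L)
  expect_lt(unname(strict$fractions["HDR"]), 1)
  expect_equal(unname(strict$fractions["HDR"] +
                        strict$fractions["N3_INFRAME"]), 1)
})
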