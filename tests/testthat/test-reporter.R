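test_that("scan_esp3i finds placed motifs and matches a brute-force scan", {
  expect_equal(scan_esp3i("AACGTCTCA"),
               data.frame(position = 2L, strand = "+",
                          stringsAsFactors = FALSE))
  expect_equal(scan_esp3i("GAGACG"),
               data.frame(position = 0L, strand = "-",
                          stringsAsFactors = FALSE))
  # overlapping occurrences must all be reported
  expect_equal(scan_esp3i("CGTCTCGTCTC")$position, c(0L, 5L))
  expect_error(scan_esp3i("ACGTN"), "alphabet")
  set.seed(11)
  for (i in 1:200) {
    s <- random_dna(120)
    expect_identical(scan_esp3i(s), oracle_scan_esp3i(s))
  }
  # denser motif content: seed fragments into random backbones
  set.seed(12)
  for (i in 1:100) {
    s <- paste0(random_dna(30), "CGTCTC", random_dna(10), "GAGACG",
                random_dna(sample(0:30, 1)))
    expect_identical(scan_esp3i(s), oracle_scan_esp3i(s))
  }
})

test_that("the bundled synthetic construct validates and violations are reported as data", {
  expect_length(validate_cassette(fix_cassette), 0)
  oh <- esp3i_overhangs(fix_cassette)
  expect_length(oh, 2)
  expect_false(oh[1] == oh[2])

  # force a frame +1 stop inside the SOI
  broken <- fix_cassette
  soi <- broken$features[broken$features$name == "SOI", ]
  seq <- broken$record$seq
  # find a frame+1 codon start inside the SOI and plant TAA there
  pos <- soi$start + 13L  # offset 13 -> frame (13 mod 3) = 1
  substr(seq, pos + 1L, pos + 3L) <- "TAA"
  broken$record$seq <- seq
  v <- validate_cassette(broken)
  expect_true(any(grepl("frame \\+1", v)))

  # identical overhangs must be flagged
  twin <- fix_cassette
  seq2 <- twin$record$seq
  sites <- scan_esp3i(seq2)
  minus <- sites[sites$strand == "-", ]
  oh1 <- oh[1]
  substr(seq2, minus$position - 4L, minus$position - 1L) <- oh1
  twin$record$seq <- seq2
  v2 <- validate_cassette(twin)
  expect_true(any(grepl("overhang", v2)))
})

test_that("swap_soi shifts downstream coordinates and round-trips validation", {
  soi30 <- optimize_cds(strrep("G", 10))$cds
  old_len <- with(fix_cassette$features,
                  end[name == "SOI"] - start[name == "SOI"])
  swapped <- swap_soi(fix_cassette, seq_record("mini", soi30))
  delta <- 30L - old_len
  f0 <- fix_cassette$features
  f1 <- swapped$features
  for (nm in c("mTagBFP2_cassette", "T2A_NanoLuc_cassette")) {
    expect_equal(f1$start[f1$name == nm], f0$start[f0$name == nm] + delta)
  }
  expect_equal(f1$start[f1$name == "mCherry"], f0$start[f0$name == "mCherry"])
  expect_length(validate_cassette(swapped), 0)

  expect_error(swap_soi(fix_cassette, seq_record("stop", "ATGTAACAT")),
               "design error.*stop")
  expect_error(swap_soi(fix_cassette, seq_record("site", "CGTCTCATT")),
               "design error.*Esp3I")
  expect_error(swap_soi(fix_cassette, seq_record("len", "ATGC")),
               "design error.*multiple of 3")

  # round-trip safety over random accepted SOIs
  set.seed(21)
  for (i in 1:8) {
    p <- paste0("M", random_aa(sample(8:25, 1),
                               alphabet = setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "M")))
    res <- optimize_cds(p)
    if (!res$feasible) next
    expect_length(validate_cassette(swap_soi(fix_cassette,
                                             seq_record(p, res$cds))), 0)
  }
})

test_that("frame_class matches the construct-geometry oracle over [0,9]^2 indels", {
  for (ins in 0:9) {
    for (del in 0:9) {
      if (ins == 0 && del == 0) next
      ev <- edit_event("SOI", 10L, inserted = strrep("A", ins),
                       deleted_len = del)
      expect_identical(frame_class(ev), oracle_frame_class(ins, del),
                       label = sprintf("ins=%d del=%d", ins, del))
    }
  }
  expect_identical(frame_class(edit_event("SOI", 0L, deleted_len = 1L)), "N1")
  expect_identical(frame_class(edit_event("SOI", 0L, inserted = "A")), "N2")
  expect_identical(frame_class(edit_event("SOI", 0L, deleted_len = 39L)),
                   "N3_INFRAME")
  expect_identical(frame_class(edit_event("SOI", 0L, is_hdr = TRUE,
                                          inserted = "AAA")), "HDR")
  expect_identical(frame_class(edit_event("SOI", 0L, n_subst = 2L)),
                   "SUBSTITUTION_ONLY")
  expect_error(edit_event("SOI", 0L), "empty edit event")
})

test_that("phenotype prediction follows the traffic-light logic", {
  ph <- function(...) c(mCherry = ..1, moxGFP = ..2, mTagBFP2 = ..3,
                        NanoLuc = ..4)
  expect_equal(predict_phenotype("mCherry", "UNEDITED"),
               ph(TRUE, FALSE, FALSE, FALSE))
  expect_equal(predict_phenotype("mCherry", "N1"), ph(FALSE, FALSE, FALSE, TRUE))
  expect_equal(predict_phenotype("mCherry", "N2"), ph(FALSE, FALSE, TRUE, FALSE))
  expect_equal(predict_phenotype("mCherry", "N3_INFRAME"),
               ph(FALSE, FALSE, FALSE, FALSE))
  expect_equal(predict_phenotype("mCherry", "N3_INFRAME",
                                 inframe_disrupts_function = FALSE),
               ph(TRUE, FALSE, FALSE, FALSE))
  expect_equal(predict_phenotype("SOI", "N1"), ph(TRUE, FALSE, FALSE, TRUE))
  expect_equal(predict_phenotype("SOI", "N2"), ph(TRUE, FALSE, TRUE, FALSE))
  expect_equal(predict_phenotype("SOI", "N3_INFRAME"),
               ph(TRUE, FALSE, FALSE, FALSE))
  expect_equal(predict_phenotype("SOI", "HDR"), ph(TRUE, TRUE, FALSE, FALSE))
  expect_equal(predict_phenotype("SOI", "SUBSTITUTION_ONLY"),
               ph(TRUE, FALSE, FALSE, FALSE))
  expect_error(predict_phenotype("other", "N1"), "unsupported region")
})

test_that("cell phenotype is the elementwise OR over integrants", {
  hdr <- predict_phenotype("SOI", "HDR")
  n2 <- predict_phenotype("SOI", "N2")
  combo <- cell_phenotype(list(hdr, n2))
  expect_true(combo["moxGFP"] && combo["mTagBFP2"])
  expect_equal(cell_phenotype(list(n2)), n2)
  zero <- c(mCherry = FALSE, moxGFP = FALSE, mTagBFP2 = FALSE, NanoLuc = FALSE)
  expect_equal(cell_phenotype(list(zero, zero, zero)), zero)
  expect_error(cell_phenotype(list()), "precondition")
})

test_that("the HDR template assembles arms around the restored segment", {
  expect_equal(nchar(fix_template$seq), 199L)
  expect_equal(nchar(fix_cassette$meta$restored), 39L)
  # template = 80-nt left arm + 39-nt segment + 80-nt right arm
  expect_equal(substr(fix_template$seq, 81, 119), fix_cassette$meta$restored)
  j <- fix_cassette$meta$junction
  seq <- fix_cassette$record$seq
  expect_equal(substr(fix_template$seq, 1, 80), substr(seq, j - 79, j))
  expect_equal(substr(fix_template$seq, 120, 199), substr(seq, j + 1, j + 80))
  # repaired construct carries the template's central segment seamlessly
  expect_true(grepl(fix_template$seq, fix_cassette$meta$repaired_seq,
                    fixed = TRUE))
})
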