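test_that("locate_cut follows enzyme geometry on both strands", {
  set.seed(41)
  flank1 <- random_dna(50)
  flank2 <- random_dna(50)
  proto <- random_dna(20)
  target <- paste0(flank1, proto, "TGG", flank2)
  m <- cut_site_model("spCas9", proto, "TGG")
  cut <- locate_cut(m, target)
  # blunt cut 3 nt 5' of the PAM: protospacer ends at 69 (0-based), PAM at
  # 70; cut between protospacer positions 17 and 18
  expect_equal(as.integer(cut), 67L)
  expect_equal(attr(cut, "strand"), "+")
  # strand symmetry: the same guide on the reverse complement mirrors
  cut_rc <- locate_cut(m, revcomp(target))
  expect_equal(attr(cut_rc, "strand"), "-")
  expect_equal(as.integer(cut_rc), nchar(target) - as.integer(cut))

  expect_error(locate_cut(m, paste0(flank1, flank2)), "target-site error")
  twice <- paste0(target, target)
  expect_error(locate_cut(m, twice), "target-site error")

  p23 <- random_dna(23)
  t2 <- paste0(flank1, "TTTA", p23, flank2)
  m2 <- cut_site_model("asCas12a", p23, "TTTA")
  c2 <- locate_cut(m2, t2)
  expect_equal(as.integer(c2), 54L + 18L)
  expect_equal(attr(c2, "cut_bottom"), 54L + 23L)
})

test_that("indel spectra normalize and condition on net residue classes", {
  sp <- default_indel_spectrum()
  expect_equal(sum(sp$prob), 1, tolerance = 1e-12)
  for (res in 0:2) {
    cs <- condition_spectrum(sp, res)
    expect_equal(sum(cs$prob), 1, tolerance = 1e-12)
    expect_true(all((cs$inserted_len - cs$deleted_len) %% 3 == res))
  }
  tmp <- tempfile(fileext = ".tsv")
  write_spectrum(sp, tmp)
  expect_equal(read_spectrum(tmp)$prob, sp$prob, tolerance = 1e-9)
})

test_that("population simulation respects degenerate probabilities and seeds", {
  sp <- default_indel_spectrum()
  pop <- simulate_population(fix_cassette, fix_guide_soi, sp, 50,
                             edit_prob = 0, seed = 42)
  for (cell in pop) {
    expect_equal(unname(cell$phenotype),
                 c(TRUE, FALSE, FALSE, FALSE))
    expect_true(all(vapply(cell$integrant_events, is.null, logical(1))))
  }
  expect_error(
    simulate_population(fix_cassette, fix_guide_soi, sp, 5, hdr_prob = 0.5),
    "config error")
  a <- simulate_population(fix_cassette, fix_guide_soi, sp, 30, 2L,
                           edit_prob = 0.7, seed = 7)
  b <- simulate_population(fix_cassette, fix_guide_soi, sp, 30, 2L,
                           edit_prob = 0.7, seed = 7)
  expect_identical(a, b)
})

test_that("molecule pools follow the spectrum's class masses", {
  sp <- default_indel_spectrum()
  mols <- simulate_molecules(fix_cassette, fix_guide_soi, 4000,
                             spectrum = sp, edit_frac = 1, seed = 43)
  ref_len <- nchar(fix_cassette$record$seq)
  net <- nchar(mols) - ref_len
  class_mass <- vapply(0:2, function(r) sum(sp$prob[(sp$inserted_len -
                                                       sp$deleted_len) %% 3 == r]),
                       numeric(1))
  obs <- vapply(0:2, function(r) mean(net %% 3 == r), numeric(1))
  for (r in 1:3) {
    sd3 <- 3 * sqrt(class_mass[r] * (1 - class_mass[r]) / 4000)
    expect_lt(abs(obs[r] - class_mass[r]), sd3 + 1e-9)
  }
})

test_that("HDR molecules carry the exact 39-nt restored segment", {
  mols <- simulate_molecules(fix_cassette, fix_guide_soi, 5, hdr_frac = 1,
                             seed = 44)
  expect_true(all(mols == fix_cassette$meta$repaired_seq))
  aln <- align_to_reference(
    substr(mols[1], fix_cassette$meta$junction - 150,
           fix_cassette$meta$junction + 190),
    fix_cassette$record$seq)
  ins <- aln$ops[aln$ops$op == "I", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$len, 39L)
})

test_that("amplicon read simulation is seeded, primer-anchored and error-calibrated", {
  mols <- rep(fix_cassette$record$seq, 3)
  params <- read_sim_params(n_pairs = 2000, substitution_error = 0.001,
                            seed = 45)
  reads <- simulate_amplicon_reads(mols, fix_primers_soi, params)
  reads_again <- simulate_amplicon_reads(mols, fix_primers_soi, params)
  expect_identical(reads, reads_again)
  # byte-identical FASTQ under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(reads$r1, f1)
  write_fastq(reads_again$r1, f2)
  expect_identical(readLines(f1), readLines(f2))

  # error-free reads match the amplicon ends exactly
  clean <- simulate_amplicon_reads(
    mols[1], fix_primers_soi,
    read_sim_params(n_pairs = 20, substitution_error = 0, seed = 46))
  seq <- fix_cassette$record$seq
  a <- regexpr(fix_primers_soi[1], seq, fixed = TRUE)
  rc2 <- revcomp(fix_primers_soi[2])
  b <- regexpr(rc2, seq, fixed = TRUE) + nchar(rc2) - 1L
  amplicon <- substr(seq, a, b)
  expect_true(all(clean$r1$seq == substr(amplicon, 1, 250)))
  expect_true(all(clean$r2$seq ==
                    revcomp(substr(amplicon, nchar(amplicon) - 249,
                                   nchar(amplicon)))))

  # observed mismatch rate within 3 SD of the configured rate
  n_bases <- sum(nchar(reads$r1$seq))
  ref_r1 <- substr(amplicon, 1, 250)
  mm <- sum(vapply(reads$r1$seq, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(ref_r1, "")[[1]])
  }, numeric(1)))
  rate <- mm / n_bases
  sd3 <- 3 * sqrt(0.001 * 0.999 / n_bases)
  expect_lt(abs(rate - 0.001), sd3)

  expect_error(
    simulate_amplicon_reads("ACGTACGT", fix_primers_soi, params),
    "amplification error.*molecule 1")
})

test_that("integration simulation places the requested sites with truth records", {
  set.seed(47)
  genome <- data.frame(id = c("c1", "c2", "c3"),
                       seq = vapply(c(30000L, 25000L, 20000L), random_dna,
                                    character(1)))
  tg <- seq_record("tg", fix_cassette$record$seq)
  one <- simulate_integrations(genome, tg, 1, seed = 48)
  expect_equal(nrow(one$truth), 1L)
  extra <- sum(nchar(one$genome$seq)) - sum(nchar(genome$seq))
  expect_equal(extra, nchar(tg$seq))

  five <- simulate_integrations(genome, tg, 5, seed = 49)
  expect_equal(nrow(five$truth), 5L)
  # the transgene (possibly reverse-complemented) sits at each mod_start
  for (r in seq_len(5)) {
    contig <- five$genome$seq[five$genome$id == five$truth$contig[r]]
    placed <- substr(contig, five$truth$mod_start[r] + 1L,
                     five$truth$mod_end[r])
    want <- if (five$truth$orientation[r] == "+") tg$seq else revcomp(tg$seq)
    expect_equal(placed, want)
  }
  # minus orientation places the reverse complement at the junction
  ori <- five$truth$orientation
  expect_true(length(unique(ori)) >= 1)
  expect_error(simulate_integrations(genome[1, ][, ], seq_record("big",
                                                                 random_dna(5000)),
                                     1, seed = 1),
               "capacity error")
})
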