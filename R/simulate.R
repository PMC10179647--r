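# In-silico Cas editing and read simulation: cut-site location for the
# three supported enzymes, indel spectra, edited-molecule populations with
# per-integrant NHEJ/HDR outcomes, amplicon read pairs with i.i.d.
# substitution error, and transgene-bearing toy genomes with junction
# reads for integration mapping.

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(pat) {
  paste(IUPAC_MAP[strsplit(pat, "")[[1L]]], collapse = "")
}

iupac_match <- function(seq, pat) {
  nchar(seq) == nchar(pat) && grepl(paste0("^", iupac_regex(pat), "$"), seq)
}

enzyme_geometry <- function(enzyme) {
  switch(enzyme,
         spCas9 = list(proto_len = 20L, pam = "NGG", pam_side = "3p",
                       cut_from_pam = -3L, staggered = FALSE),
         saCas9 = list(proto_len = 21L, pam = "NNGRRT", pam_side = "3p",
                       cut_from_pam = -3L, staggered = FALSE),
         # Cas12a: 5' TTTV PAM, staggered cut after protospacer
         # positions 18 (non-target strand) and 23 (target strand) --
         # documented convention, not measured here
         asCas12a = list(proto_len = 23L, pam = "TTTV", pam_side = "5p",
                         cut_top = 18L, cut_bottom = 23L, staggered = TRUE),
         stop("unknown enzyme: ", enzyme, call. = FALSE))
}

#' Describe a Cas cut site
#'
#' @param enzyme `"spCas9"`, `"saCas9"` or `"asCas12a"`.
#' @param protospacer Protospacer sequence (plus-strand of the guide
#'   match).
#' @param pam PAM sequence actually present at the site (IUPAC allowed).
#' @return List of class `cut_site_model`.
#' @export
cut_site_model <- function(enzyme, protospacer, pam) {
  geom <- enzyme_geometry(enzyme)
  check_dna(protospacer, what = "protospacer")
  if (nchar(protospacer) != geom$proto_len) {
    stop(sprintf("%s protospacer must be %d nt", enzyme, geom$proto_len),
         call. = FALSE)
  }
  structure(list(enzyme = enzyme, protospacer = protospacer, pam = pam,
                 geometry = geom),
            class = "cut_site_model")
}

find_all_fixed <- function(text, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Locate the cut position of a guide on a target
#'
#' The protospacer+PAM must occur exactly once across both strands.
#' spCas9/saCas9 cut blunt 3 nt 5' of the PAM; asCas12a cuts staggered
#' after protospacer positions 18/23 (the returned position is the
#' top-strand cut; the bottom-strand cut is attached as an attribute).
#'
#' @param model A [cut_site_model].
#' @param target DNA string.
#' @return 0-based cut position (number of bases 5' of the cut on the
#'   strand carrying the protospacer, mapped to plus-strand coordinates),
#'   with attributes `strand` and (Cas12a) `cut_bottom`.
#' @export
locate_cut <- function(model, target) {
  check_dna(target)
  geom <- model$geometry
  pat <- if (geom$pam_side == "3p") {
    paste0(model$protospacer, iupac_regex(model$pam))
  } else {
    paste0(iupac_regex(model$pam), model$protospacer)
  }
  plus <- find_all_fixed(target, pat)
  rc <- revcomp(target)
  minus <- find_all_fixed(rc, pat)
  total <- length(plus) + length(minus)
  if (total != 1L) {
    stop(sprintf("target-site error: %d matches for protospacer+PAM", total),
         call. = FALSE)
  }
  cut_in <- function(p0) {
    proto_start <- if (geom$pam_side == "3p") p0 else p0 + nchar(model$pam)
    if (geom$staggered) {
      top <- proto_start + geom$cut_top
      attr(top, "cut_bottom_local") <- proto_start + geom$cut_bottom
      top
    } else {
      proto_start + geom$proto_len + geom$cut_from_pam
    }
  }
  if (length(plus)) {
    cut <- cut_in(plus)
    out <- as.integer(cut)
    attr(out, "strand") <- "+"
    if (geom$staggered) attr(out, "cut_bottom") <- as.integer(attr(cut, "cut_bottom_local"))
  } else {
    cut <- cut_in(minus)
    n <- nchar(target)
    out <- n - as.integer(cut)
    attr(out, "strand") <- "-"
    if (geom$staggered) attr(out, "cut_bottom") <- n - as.integer(attr(cut, "cut_bottom_local"))
  }
  out
}

# --- indel spectra ------------------------------------------------------

#' Default indel spectrum
#'
#' Geometric-tailed deletions (success probability `p_del`, lengths 1 to
#' `max_del`) mixed with 1-nt insertions at `ins_frac` of events. A
#' fixture for simulation, configurable via TSV ([read_spectrum]).
#'
#' @param p_del Geometric parameter for deletion lengths.
#' @param max_del Maximum deletion length.
#' @param ins_frac Probability mass on the 1-nt insertion.
#' @return data.frame of class `indel_spectrum` with `deleted_len`,
#'   `inserted_len`, `prob` (summing to 1).
#' @export
default_indel_spectrum <- function(p_del = 0.5, max_del = 30L, ins_frac = 0.2) {
  dl <- seq_len(max_del)
  pd <- p_del * (1 - p_del)^(dl - 1L)
  pd <- pd / sum(pd) * (1 - ins_frac)
  out <- rbind(
    data.frame(deleted_len = dl, inserted_len = 0L, prob = pd),
    data.frame(deleted_len = 0L, inserted_len = 1L, prob = ins_frac))
  structure(out, class = c("indel_spectrum", "data.frame"))
}

#' Condition an indel spectrum on a net-length residue class
#'
#' Restricts to events whose net length (insertions minus deletions) is
#' congruent to `net_mod3` modulo 3 and renormalizes.
#'
#' @param spectrum An `indel_spectrum`.
#' @param net_mod3 Residue in `{0, 1, 2}`; the N-1 class is residue 2, the
#'   N-2 class residue 1.
#' @return Conditioned `indel_spectrum`.
#' @export
condition_spectrum <- function(spectrum, net_mod3) {
  net <- spectrum$inserted_len - spectrum$deleted_len
  keep <- (net %% 3L) == net_mod3 & !(net == 0L & spectrum$deleted_len == 0L)
  out <- spectrum[keep, , drop = FALSE]
  if (!nrow(out)) stop("spectrum has no mass in that class", call. = FALSE)
  out$prob <- out$prob / sum(out$prob)
  rownames(out) <- NULL
  structure(out, class = c("indel_spectrum", "data.frame"))
}

#' Read / write an indel spectrum as TSV
#'
#' @param path File path.
#' @return `read_spectrum`: an `indel_spectrum`.
#' @export
read_spectrum <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("deleted_len", "inserted_len", "prob") %in% names(x)))
  if (abs(sum(x$prob) - 1) > 1e-6) stop("spectrum probabilities must sum to 1",
                                        call. = FALSE)
  structure(x, class = c("indel_spectrum", "data.frame"))
}

#' @rdname read_spectrum
#' @param spectrum An `indel_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(spectrum, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# apply one indel (deletion centred on the cut, insertion at the cut) to a
# sequence; returns list(seq, event)
apply_indel <- function(seq, cut, deleted_len, inserted, region = "other") {
  start <- cut - deleted_len %/% 2L  # 0-based leftmost deleted base
  start <- max(0L, min(start, nchar(seq) - deleted_len))
  out <- paste0(substr(seq, 1L, start), inserted,
                substr(seq, start + deleted_len + 1L, nchar(seq)))
  list(seq = out,
       event = edit_event(region, position = start, inserted = inserted,
                          deleted_len = deleted_len))
}

random_insertion <- function(len) {
  if (len == 0L) return("")
  random_dna(len)
}

#' Simulate an edited cell population
#'
#' Every integrant of every cell is independently unedited (probability
#' `1 - edit_prob`) or edited; edited integrants undergo HDR with
#' probability `hdr_prob` (template required) and otherwise acquire one
#' indel drawn from the spectrum at the guide's cut site.
#'
#' @param cassette Reporter cassette (defines the target and regions).
#' @param model A [cut_site_model] for the guide.
#' @param spectrum An `indel_spectrum`.
#' @param n_cells Number of cells.
#' @param integrants_per_cell Reporter copies per cell.
#' @param edit_prob Per-integrant editing probability.
#' @param hdr_template A [seq_record] HDR template, or `NULL`.
#' @param hdr_prob Probability that an edited integrant takes HDR.
#' @param seed RNG seed.
#' @return List of `simulated_cell` objects: `integrant_events` (list,
#'   `NULL` for unedited) and `phenotype`.
#' @export
simulate_population <- function(cassette, model, spectrum, n_cells,
                                integrants_per_cell = 1L, edit_prob = 1,
                                hdr_template = NULL, hdr_prob = 0,
                                seed = 1L) {
  stopifnot(n_cells >= 1L, edit_prob >= 0, edit_prob <= 1,
            hdr_prob >= 0, hdr_prob <= 1)
  if (hdr_prob > 0 && is.null(hdr_template)) {
    stop("config error: hdr_prob > 0 requires an HDR template", call. = FALSE)
  }
  seq <- cassette$record$seq
  cut <- as.integer(locate_cut(model, seq))
  f <- cassette$features
  hit <- f$name[f$start <= cut & f$end > cut]
  region <- if (length(hit) && hit[1L] %in% c("mCherry", "SOI")) hit[1L] else "other"
  restored <- cassette$meta$restored
  local_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      events <- lapply(seq_len(integrants_per_cell), function(j) {
        if (stats::runif(1) >= edit_prob) return(NULL)
        if (!is.null(hdr_template) && stats::runif(1) < hdr_prob) {
          return(edit_event(region, position = cassette$meta$junction,
                            inserted = restored, is_hdr = TRUE))
        }
        row <- sample.int(nrow(spectrum), 1L, prob = spectrum$prob)
        apply_indel(seq, cut, spectrum$deleted_len[row],
                    random_insertion(spectrum$inserted_len[row]),
                    region = region)$event
      })
      phen <- cell_phenotype(lapply(events, function(ev) {
        if (is.null(ev)) {
          c(mCherry = TRUE, moxGFP = FALSE, mTagBFP2 = FALSE, NanoLuc = FALSE)
        } else {
          predict_phenotype(region, frame_class(ev))
        }
      }))
      structure(list(integrant_events = events, phenotype = phen),
                class = "simulated_cell")
    })
  })
}

#' Build an edited molecule pool
#'
#' Convenience generator for amplicon simulations: draws `n` molecules
#' from a mixture of outcome classes applied to the cassette sequence.
#'
#' @param cassette Reporter cassette.
#' @param model Guide [cut_site_model].
#' @param n Number of molecules.
#' @param spectrum Indel spectrum for edited molecules (`NULL` for none).
#' @param edit_frac Fraction of molecules carrying an indel.
#' @param hdr_frac Fraction of molecules carrying the exact template
#'   repair.
#' @param seed RNG seed.
#' @return Character vector of molecule sequences.
#' @export
simulate_molecules <- function(cassette, model, n, spectrum = NULL,
                               edit_frac = 0, hdr_frac = 0, seed = 1L) {
  stopifnot(edit_frac + hdr_frac <= 1 + 1e-12)
  seq <- cassette$record$seq
  cut <- as.integer(locate_cut(model, seq))
  local_seed(seed, {
    kind <- sample(c("indel", "hdr", "ref"), n, replace = TRUE,
                   prob = c(edit_frac, hdr_frac, 1 - edit_frac - hdr_frac))
    vapply(kind, function(kd) {
      if (kd == "ref") return(seq)
      if (kd == "hdr") return(cassette$meta$repaired_seq)
      row <- sample.int(nrow(spectrum), 1L, prob = spectrum$prob)
      apply_indel(seq, cut, spectrum$deleted_len[row],
                  random_insertion(spectrum$inserted_len[row]))$seq
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Read-simulation parameters
#'
#' @param read_len Read length (nt).
#' @param paired Paired-end output.
#' @param substitution_error Per-base i.i.d. substitution rate.
#' @param n_pairs Number of read pairs (reads if unpaired) drawn uniformly
#'   over molecules.
#' @param seed RNG seed.
#' @param base_quality Constant Phred quality assigned to simulated bases.
#' @return List of class `read_sim_params`.
#' @export
read_sim_params <- function(read_len = 250L, paired = TRUE,
                            substitution_error = 0.001, n_pairs = 5000L,
                            seed = 1L, base_quality = 30L) {
  stopifnot(substitution_error >= 0, substitution_error < 0.1,
            read_len >= 50L, n_pairs >= 1L)
  structure(list(read_len = as.integer(read_len), paired = paired,
                 substitution_error = substitution_error,
                 n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                 base_quality = as.integer(base_quality)),
            class = "read_sim_params")
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate amplicon read pairs from a molecule pool
#'
#' Each molecule is amplified between the primer pair (the reverse primer
#' matching as its reverse complement); read 1 starts at the forward
#' primer, read 2 is the reverse complement of the amplicon's other end.
#' Substitution errors are i.i.d. at the configured rate; qualities are a
#' constant Phred score.
#'
#' @param molecules Character vector of molecule sequences.
#' @param primers `c(forward, reverse)`; reverse given 5'->3' on the minus
#'   strand.
#' @param params A [read_sim_params].
#' @return List with `r1` and `r2` FASTQ data.frames (plus `truncated`,
#'   a logical flag per molecule for amplicons shorter than the read
#'   length). Unpaired parameters return `r1` only.
#' @export
simulate_amplicon_reads <- function(molecules, primers, params = read_sim_params()) {
  stopifnot(length(primers) == 2L)
  fwd <- primers[[1L]]
  rev_rc <- revcomp(primers[[2L]])
  amplicons <- vapply(seq_along(molecules), function(i) {
    mol <- molecules[i]
    a <- regexpr(fwd, mol, fixed = TRUE)
    b <- regexpr(rev_rc, mol, fixed = TRUE)
    if (a == -1L || b == -1L) {
      stop(sprintf("amplification error: primer absent from molecule %d", i),
           call. = FALSE)
    }
    substr(mol, a, b + nchar(rev_rc) - 1L)
  }, character(1))
  truncated <- nchar(amplicons) < params$read_len
  local_seed(params$seed, {
    pick <- sample.int(length(amplicons), params$n_pairs, replace = TRUE)
    amp <- amplicons[pick]
    r1 <- substr(amp, 1L, params$read_len)
    r1 <- inject_errors(r1, params$substitution_error)
    q <- vapply(nchar(r1), function(L) {
      strrep(rawToChar(as.raw(params$base_quality + 33L)), L)
    }, character(1))
    ids <- sprintf("read_%d", seq_len(params$n_pairs))
    out <- list(r1 = data.frame(id = ids, seq = r1, qual = q,
                                stringsAsFactors = FALSE),
                truncated = truncated)
    if (params$paired) {
      r2 <- revcomp(substr(amp, pmax(1L, nchar(amp) - params$read_len + 1L),
                           nchar(amp)))
      r2 <- inject_errors(r2, params$substitution_error)
      q2 <- vapply(nchar(r2), function(L) {
        strrep(rawToChar(as.raw(params$base_quality + 33L)), L)
      }, character(1))
      out$r2 <- data.frame(id = ids, seq = r2, qual = q2,
                           stringsAsFactors = FALSE)
    }
    out
  })
}

# --- transgene integration ----------------------------------------------

#' Insert a transgene into a toy genome
#'
#' Sites are drawn uniformly over the genome (contigs weighted by length)
#' with random orientation; sites closer than 5x the transgene length on
#' one contig are re-drawn so junctions stay resolvable.
#'
#' @param genome data.frame of contigs (`id`, `seq`).
#' @param transgene A [seq_record].
#' @param n_sites Number of insertions.
#' @param seed RNG seed.
#' @return List: `genome` (modified contigs), `truth` (data.frame
#'   `contig`, `position` 0-based insertion point in original coordinates,
#'   `orientation`, `mod_start`/`mod_end` transgene span in modified
#'   coordinates).
#' @export
simulate_integrations <- function(genome, transgene, n_sites, seed = 1L) {
  stopifnot(n_sites >= 1L)
  genome <- as_record_df(genome)
  tg <- transgene$seq
  total <- sum(nchar(genome$seq))
  if (total < 10L * nchar(tg)) {
    stop("capacity error: genome must be >= 10x the transgene length",
         call. = FALSE)
  }
  min_gap <- 5L * nchar(tg)
  local_seed(seed, {
    sites <- NULL
    for (attempt in 1:200) {
      ci <- sample.int(nrow(genome), 1L, prob = nchar(genome$seq))
      pos <- sample.int(nchar(genome$seq[ci]) - 1L, 1L)
      if (pos < 200L || pos > nchar(genome$seq[ci]) - 200L) next
      if (!is.null(sites) &&
          any(sites$ci == ci & abs(sites$pos - pos) < min_gap)) next
      ori <- sample(c("+", "-"), 1L)
      sites <- rbind(sites, data.frame(ci = ci, pos = pos, ori = ori))
      if (nrow(sites) == n_sites) break
    }
    if (is.null(sites) || nrow(sites) < n_sites) {
      stop("capacity error: could not place all insertions", call. = FALSE)
    }
    sites <- sites[order(sites$ci, sites$pos), , drop = FALSE]
    truth <- data.frame(contig = genome$id[sites$ci], position = sites$pos,
                        orientation = sites$ori,
                        mod_start = NA_integer_, mod_end = NA_integer_,
                        stringsAsFactors = FALSE)
    mod <- genome
    for (ci in unique(sites$ci)) {
      rows <- which(sites$ci == ci)
      offset <- 0L
      s <- genome$seq[ci]
      for (r in rows) {
        ins <- if (sites$ori[r] == "+") tg else revcomp(tg)
        p <- sites$pos[r] + offset
        s <- paste0(substr(s, 1L, p), ins, substr(s, p + 1L, nchar(s)))
        truth$mod_start[r] <- p
        truth$mod_end[r] <- p + nchar(ins)
        offset <- offset + nchar(ins)
      }
      mod$seq[ci] <- s
    }
    list(genome = mod, truth = truth)
  })
}

#' Simulate junction-anchored reads over integration sites
#'
#' Tagmentation-style enrichment: single-end reads spanning each
#' transgene-genome junction, with at least `min_tg` transgene bases and
#' at least `min_flank` genomic bases, on a random sequencing strand.
#'
#' @param modified_genome Modified contigs from [simulate_integrations].
#' @param truth Truth records from [simulate_integrations].
#' @param n_per_site Reads per junction side per site.
#' @param read_len Read length.
#' @param error Substitution error rate.
#' @param min_tg,min_flank Minimum bases on the transgene / genome side.
#' @param seed RNG seed.
#' @return FASTQ data.frame.
#' @export
simulate_junction_reads <- function(modified_genome, truth, n_per_site = 100L,
                                    read_len = 150L, error = 0.001,
                                    min_tg = 20L, min_flank = 25L, seed = 1L) {
  local_seed(seed, {
    reads <- character(0)
    for (r in seq_len(nrow(truth))) {
      contig_seq <- modified_genome$seq[modified_genome$id == truth$contig[r]]
      for (junc in c(truth$mod_start[r], truth$mod_end[r])) {
        # read window must contain the junction with margins on both sides
        lo <- junc - (read_len - min_tg)
        hi <- junc - min_flank
        starts <- sample(seq.int(max(0L, lo), max(0L, hi)), n_per_site,
                         replace = TRUE)
        frag <- substring(contig_seq, starts + 1L, starts + read_len)
        flip <- stats::runif(n_per_site) < 0.5
        frag[flip] <- revcomp(frag[flip])
        reads <- c(reads, frag)
      }
    }
    reads <- inject_errors(reads, error)
    data.frame(id = sprintf("junc_%d", seq_along(reads)), seq = reads,
               qual = strrep("?", nchar(reads)), stringsAsFactors = FALSE)
  })
}
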