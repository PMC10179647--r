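# Readers and writers for the formats the toolkit exchanges: FASTA
# (Biostrings), FASTQ (Phred+33, validated record-by-record so malformed
# input reports a line number) and a minimal GenBank flat-file subset for
# annotated cassettes.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  data.frame(id = id, seq = toupper(as.character(x)), description = desc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTA file
#'
#' @param records data.frame with `id`, `seq` and optional `description`,
#'   or a single [seq_record].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(records, path) {
  records <- as_record_df(records)
  nm <- ifelse(nzchar(records$description %||% ""),
               paste(records$id, records$description), records$id)
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_record_df <- function(records) {
  if (inherits(records, "seq_record")) {
    records <- data.frame(id = records$id, seq = records$seq,
                          description = records$description,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (is.null(records$description)) records$description <- ""
  records
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("FASTQ parse error: truncated record starting at line %d",
                 (n %/% 4L) * 4L + 1L), call. = FALSE)
  }
  if (n == 0L) return(data.frame(id = character(0), seq = character(0),
                                 qual = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, n, 4L)]
  seq <- toupper(lines[seq(2L, n, 4L)])
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error: missing '@' header at line %d",
                 (bad[1L] - 1L) * 4L + 1L), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error: missing '+' separator at line %d",
                 (bad[1L] - 1L) * 4L + 3L), call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error: sequence/quality length mismatch at line %d",
                 (bad[1L] - 1L) * 4L + 2L), call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)), seq = seq,
             qual = qual, stringsAsFactors = FALSE)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), 4L)] <- reads$seq
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Read an annotated cassette from a GenBank flat file
#'
#' Supports the LOCUS/FEATURES/ORIGIN subset used for reporter constructs.
#' Feature locations are converted from GenBank 1-based inclusive to the
#' package's 0-based half-open convention; feature names are taken from the
#' `/label` qualifier (falling back to the feature key).
#'
#' @param path Path to a GenBank flat file.
#' @return A [reporter_cassette] (unvalidated; run [validate_cassette]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else "cassette"
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank parse error: no ORIGIN section", call. = FALSE)
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        parts <- strsplit(trimws(ln), "\\s+")[[1L]]
        loc <- parts[2L]
        strand <- if (grepl("^complement", loc)) "-" else "+"
        loc <- gsub("complement\\(|\\)|<|>", "", loc)
        se <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
        cur <- list(key = parts[1L], start = se[1L] - 1L, end = se[2L],
                    strand = strand, label = parts[1L], frame_shift = 0L)
      } else if (!is.null(cur)) {
        q <- trimws(ln)
        if (grepl("^/label=", q)) {
          cur$label <- gsub("\"", "", sub("^/label=", "", q))
        } else if (grepl("^/frame_shift=", q)) {
          cur$frame_shift <- as.integer(gsub("\"", "", sub("^/frame_shift=", "", q)))
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  features <- do.call(rbind, lapply(feats, function(f) {
    data.frame(name = f$label, start = f$start, end = f$end,
               frame_shift = f$frame_shift, strand = f$strand,
               stringsAsFactors = FALSE)
  }))
  if (is.null(features)) {
    features <- data.frame(name = character(0), start = integer(0),
                           end = integer(0), frame_shift = integer(0),
                           strand = character(0), stringsAsFactors = FALSE)
  }
  reporter_cassette(seq_record(id, seq), features, validate = FALSE)
}

#' Write an annotated cassette as a GenBank flat file
#'
#' Inverse of [read_genbank]: 0-based half-open feature coordinates are
#' written 1-based inclusive, names as `/label`, declared frame shifts as a
#' `/frame_shift` qualifier on `misc_feature` keys.
#'
#' @param cassette A [reporter_cassette].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_genbank <- function(cassette, path) {
  stopifnot(inherits(cassette, "reporter_cassette"))
  seq <- cassette$record$seq
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   SYN",
                   cassette$record$id, nchar(seq)),
           sprintf("DEFINITION  %s", cassette$record$description),
           "FEATURES             Location/Qualifiers")
  f <- cassette$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     misc_feature    %s", loc),
             sprintf("                     /label=\"%s\"", f$name[i]),
             sprintf("                     /frame_shift=\"%d\"", f$frame_shift[i]))
  }
  out <- c(out, "ORIGIN")
  n <- nchar(seq)
  for (pos in seq(1L, n, 60L)) {
    chunk <- substr(seq, pos, min(pos + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", pos, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
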