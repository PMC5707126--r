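# Sequence containers and on-disk formats. Records travel as a plain
# data.frame (columns id, desc, seq, qual) so every stage is directly
# inspectable and diffable; Biostrings handles FASTA parsing/wrapping and
# gzip, FASTQ is the fixed 4-line Phred+33 dialect.

#' Construct a sequence record set
#'
#' @param id character vector of record ids (must be unique and non-empty).
#' @param seq sequences (nucleotide or amino acid).
#' @param desc optional descriptions.
#' @param qual optional per-base Phred+33 quality strings; when present each
#'   must have the same number of characters as its sequence.
#' @return data.frame with class `seq_records`.
#' @export
seq_records <- function(id, seq, desc = "", qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  id <- as.character(id); seq <- as.character(seq)
  if (any(!nzchar(seq))) stop("empty sequence in record set")
  if (anyDuplicated(id)) stop("duplicate record ids")
  df <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                   seq = seq, qual = rep_len(as.character(qual), length(id)),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$qual) & nchar(df$qual) != nchar(df$seq)
  if (any(bad)) {
    stop("quality length differs from sequence length for record '",
         df$id[which(bad)[1]], "'")
  }
  class(df) <- c("seq_records", "data.frame")
  df
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_phred <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(pmin(pmax(s, 0L), 93L) + 33L)),
         "")
}

#' Read a FASTA file
#'
#' Accepts wrapped and unwrapped dialects and transparent gzip. An empty (or
#' all-blank) file yields an empty record set with a warning; a file whose
#' first non-blank character is not `>` is a format error.
#'
#' @param path path to a FASTA file.
#' @return a [seq_records] data.frame (no qualities).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 50L, warn = FALSE)
  close(con)
  nonblank <- which(nzchar(trimws(head_lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(seq_records(character(0), character(0)))
  }
  first <- trimws(head_lines[nonblank[1]])
  if (substr(first, 1, 1) != ">") {
    stop("malformed FASTA (line ", nonblank[1],
         " does not start with '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), desc)
}

#' Write a FASTA file
#'
#' @param records a [seq_records] data.frame.
#' @param path output path (`.gz` suffix enables gzip).
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path path; `.gz` is decompressed transparently.
#' @return a [seq_records] data.frame with qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0L) {
    warning("empty FASTQ file: ", path)
    return(seq_records(character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  }
  n <- length(lines) / 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(hdr, 1, 1) != "@")) {
    stop("malformed FASTQ (header without '@') in ", path)
  }
  if (any(substr(plus, 1, 1) != "+")) {
    stop("malformed FASTQ (separator without '+') in ", path)
  }
  hdr <- substring(hdr, 2)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  bad <- nchar(qual) != nchar(seqs)
  if (any(bad)) {
    stop("quality length differs from sequence length for record '",
         id[which(bad)[1]], "' in ", path)
  }
  seq_records(id, seqs, desc, qual)
}

#' Write a FASTQ file (4-line records, Phred+33)
#'
#' @param records a [seq_records] data.frame; all records need qualities.
#' @param path output path (`.gz` suffix enables gzip).
#' @export
write_fastq <- function(records, path) {
  if (nrow(records) > 0 && any(is.na(records$qual))) {
    stop("records without qualities cannot be written as FASTQ")
  }
  hdr <- ifelse(nzchar(records$desc),
                paste(records$id, records$desc), records$id)
  lines <- as.vector(rbind(paste0("@", hdr), records$seq, "+", records$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# ---- catalog entry naming codec ------------------------------------------

#' Encode a retroviral gene catalog entry name
#'
#' Catalog entries carry an arbitrary unique code of the form
#' `<DOMAIN>_U<index>` followed by pipe-delimited bookkeeping fields: the
#' recognition domain (the protein-domain record the genomic locus was
#' detected with), the source sequence id, the 1-based start position and the
#' length in nucleotides. Example: `GAG_U21|K-HERV|srcA|1200|450`.
#'
#' @param domain_type domain-type label (e.g. `GAG`).
#' @param unique_index positive integer, sequential within domain type.
#' @param recognition_domain recognition-domain label.
#' @param source_id source sequence id.
#' @param start 1-based start position on the source.
#' @param length entry length in nucleotides (> 0).
#' @return the encoded name string.
#' @export
encode_entry_name <- function(domain_type, unique_index, recognition_domain,
                              source_id, start, length) {
  stopifnot(nzchar(domain_type), unique_index >= 1,
            unique_index == round(unique_index), start >= 1, length > 0)
  fields <- c(domain_type, recognition_domain, source_id)
  if (any(grepl("[|]", fields))) stop("'|' not allowed inside name fields")
  if (grepl("_U[0-9]+$", domain_type)) {
    stop("domain type must not itself end in a _U<integer> suffix")
  }
  sprintf("%s_U%d|%s|%s|%d|%d", domain_type, as.integer(unique_index),
          recognition_domain, source_id, as.integer(start),
          as.integer(length))
}

#' Decode a retroviral gene catalog entry name
#'
#' Inverse of [encode_entry_name()]; all five pipe-delimited fields are
#' mandatory.
#'
#' @param name encoded name string.
#' @return list with `domain_type`, `unique_index`, `recognition_domain`,
#'   `source_id`, `start`, `length`.
#' @export
decode_entry_name <- function(name) {
  stopifnot(length(name) == 1L)
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5L) {
    stop("malformed catalog entry name (expected code|recognition|source|",
         "start|length): ", name)
  }
  m <- regmatches(parts[1], regexec("^(.*)_U([0-9]+)$", parts[1]))[[1]]
  if (length(m) != 3L) {
    stop("malformed catalog entry code (expected <DOMAIN>_U<k>): ", parts[1])
  }
  start <- suppressWarnings(as.integer(parts[4]))
  len <- suppressWarnings(as.integer(parts[5]))
  if (is.na(start) || is.na(len) || start < 1 || len < 1) {
    stop("malformed coordinates in catalog entry name: ", name)
  }
  list(domain_type = m[2], unique_index = as.integer(m[3]),
       recognition_domain = parts[2], source_id = parts[3],
       start = start, length = len)
}

# ---- tabular helpers ------------------------------------------------------

#' Read / write a tab-separated table with a header row
#' @param path file path.
#' @rdname tsv
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param df data.frame to write.
#' @rdname tsv
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a specimen design table
#'
#' Requires columns `specimen_id` and `group`; group labels are validated
#' against the study's three arms.
#'
#' @param path TSV path.
#' @param groups allowed group labels.
#' @return data.frame.
#' @export
read_design <- function(path,
                        groups = c("demyelination", "control", "OND")) {
  df <- read_tsv_table(path)
  if (!all(c("specimen_id", "group") %in% names(df))) {
    stop("design table needs 'specimen_id' and 'group' columns: ", path)
  }
  bad <- setdiff(unique(df$group), groups)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$specimen_id)) stop("duplicate specimen ids in ", path)
  df
}
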