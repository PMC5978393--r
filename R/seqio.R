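#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows count n across all_of desc rename row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rmultinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# Phred+33 <-> integer lookup kept at package scope; qualities are stored as
# compact ASCII strings in the `qual` column and decoded on demand.
.phred_offset <- 33L

#' Decode / encode Phred+33 quality strings
#'
#' Reads carry their per-base qualities as Phred+33 ASCII strings (the FASTQ
#' on-disk encoding). These helpers convert between that compact form and
#' integer vectors.
#'
#' @param qual A single quality string (Phred+33).
#' @param q An integer vector of Phred scores (all >= 0).
#' @return `qual_to_int()` returns an integer vector; `int_to_qual()` a string.
#' @examples
#' qual_to_int("II!!")
#' int_to_qual(c(40L, 40L, 0L))
#' @export
qual_to_int <- function(qual) {
  stopifnot(is.character(qual), length(qual) == 1L)
  utf8ToInt(qual) - .phred_offset
}

#' @rdname qual_to_int
#' @export
int_to_qual <- function(q) {
  if (any(q < 0L)) abort("Phred scores must be >= 0")
  intToUtf8(as.integer(q) + .phred_offset)
}

.valid_dna_regex <- "^[ACGTN]+$"

# Uppercase and map every non-ACGTN letter to N (the reader-side
# normalization contract).
normalize_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  x
}

#' Construct and validate a table of sequencing reads
#'
#' The package's central container is an ordinary tibble with columns
#' `id` (unique read identifier), `sample` (sample label or `NA` before
#' demultiplexing), `seq` (uppercase DNA over A/C/G/T/N) and `qual`
#' (Phred+33 string of the same length, or `NA` for FASTA-derived records).
#'
#' @param id,seq Character vectors (required, same length).
#' @param sample,qual Optional character vectors (recycled `NA` by default).
#' @return A validated reads tibble.
#' @export
reads_tbl <- function(id, seq, sample = NA_character_, qual = NA_character_) {
  out <- tibble(
    id = as.character(id),
    sample = as.character(sample),
    seq = normalize_dna(as.character(seq)),
    qual = as.character(qual)
  )
  validate_reads(out)
}

#' @rdname reads_tbl
#' @param reads A reads tibble to validate.
#' @export
validate_reads <- function(reads) {
  req <- c("id", "seq")
  miss <- setdiff(req, names(reads))
  if (length(miss)) abort(paste("reads table lacks column(s):", paste(miss, collapse = ", ")))
  if (!"sample" %in% names(reads)) reads$sample <- NA_character_
  if (!"qual" %in% names(reads)) reads$qual <- NA_character_
  if (any(!nzchar(reads$seq)) || anyNA(reads$seq)) abort("empty sequence in reads table")
  if (any(!grepl(.valid_dna_regex, reads$seq))) abort("sequence with letters outside {A,C,G,T,N}")
  has_q <- !is.na(reads$qual)
  if (any(nchar(reads$qual[has_q]) != nchar(reads$seq[has_q]))) {
    abort("quality string length differs from sequence length")
  }
  as_tibble(reads)
}

open_maybe_gz <- function(path, mode = "r") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a FASTQ file into a reads tibble
#'
#' Parses 4-line Phred+33 FASTQ (gzipped transparently by `.gz` extension).
#' Sequences are uppercased and non-ACGTN letters mapped to `N`; any
#' `;sample=<name>` suffix on the identifier is decoded into the `sample`
#' column (see [label_reads()]).
#'
#' @param path Path to a FASTQ(.gz) file.
#' @return A reads tibble in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(reads_tbl(character(), character())[0, ])
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (near line %d)",
                  length(lines), length(lines)))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort(sprintf("malformed FASTQ: missing '@' at line %d", (bad_hdr[1] - 1L) * 4L + 1L))
  }
  seq <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  len_bad <- which(nchar(seq) != nchar(qual))
  if (length(len_bad)) {
    abort(sprintf("malformed FASTQ: seq/qual length mismatch for record at line %d",
                  (len_bad[1] - 1L) * 4L + 1L))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  dec <- decode_sample_label(ids)
  reads_tbl(id = dec$id, seq = seq, sample = dec$sample, qual = qual)
}

#' Read a FASTA file into a reads tibble
#'
#' @param path Path to a FASTA(.gz) file.
#' @return A reads tibble (with `qual = NA`); `;sample=` labels are decoded.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(reads_tbl(character(), character())[0, ])
  ids <- sub("\\s.*$", "", names(set))
  dec <- decode_sample_label(ids)
  reads_tbl(id = dec$id, seq = as.character(set), sample = dec$sample)
}

# ---- sample-label codec -----------------------------------------------------

#' Encode / decode sample labels in sequence headers
#'
#' Sample assignment survives round trips through combined FASTA/FASTQ files
#' via a `;sample=<name>` suffix on the record identifier, so one pooled file
#' can be carried through clustering while every read remembers its sample.
#'
#' @param ids Character vector of header identifiers.
#' @param reads A reads tibble.
#' @return `decode_sample_label()` returns a list with `id` and `sample`;
#'   `encode_sample_label()` a character vector of header identifiers.
#' @export
decode_sample_label <- function(ids) {
  has <- grepl(";sample=", ids, fixed = TRUE)
  sample <- rep(NA_character_, length(ids))
  sample[has] <- sub("^.*;sample=", "", ids[has])
  ids[has] <- sub(";sample=.*$", "", ids[has])
  list(id = ids, sample = sample)
}

#' @rdname decode_sample_label
#' @export
encode_sample_label <- function(reads) {
  ifelse(is.na(reads$sample), reads$id, paste0(reads$id, ";sample=", reads$sample))
}

#' Write reads to FASTA / FASTQ
#'
#' Sample labels are encoded into the headers (see [decode_sample_label()]) so
#' that `read_*(write_*(x))` round-trips `id`, `seq`, `qual` and `sample`.
#' Paths ending in `.gz` are written gzip-compressed.
#'
#' @param reads A reads tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  reads <- validate_reads(reads)
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0(">", encode_sample_label(reads), "\n", reads$seq), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  reads <- validate_reads(reads)
  if (anyNA(reads$qual)) abort("FASTQ write requires qualities on every read")
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", encode_sample_label(reads), "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

# ---- sample sheet -----------------------------------------------------------

#' Read a demultiplexing sample sheet
#'
#' Tab-separated with header `sample  fwd_barcode  rev_barcode  i5  i7`;
#' empty cells are allowed. Sample names must be unique and barcodes unique
#' within each column. Each row must define at least one tag.
#'
#' @param path Path to the TSV sheet.
#' @param fwd_primer,rev_primer Amplicon primers (5'->3', IUPAC allowed);
#'   attached to the sheet as attributes for downstream stages.
#' @return A tibble with class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, fwd_primer = NULL, rev_primer = NULL) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = c("", "NA"), check.names = FALSE)
  need <- c("sample", "fwd_barcode", "rev_barcode", "i5", "i7")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste("sample sheet lacks column(s):", paste(miss, collapse = ", ")))
  sample_sheet(as_tibble(df[need]), fwd_primer = fwd_primer, rev_primer = rev_primer)
}

#' @rdname read_sample_sheet
#' @param entries A tibble with columns `sample`, `fwd_barcode`,
#'   `rev_barcode`, `i5`, `i7` (tag columns may be `NA`).
#' @export
sample_sheet <- function(entries, fwd_primer = NULL, rev_primer = NULL) {
  entries <- as_tibble(entries)
  for (col in c("fwd_barcode", "rev_barcode", "i5", "i7")) {
    if (!col %in% names(entries)) entries[[col]] <- NA_character_
    set <- !is.na(entries[[col]])
    entries[[col]][set] <- normalize_dna(entries[[col]][set])
    if (anyDuplicated(entries[[col]][set])) abort(paste("duplicate", col, "in sample sheet"))
  }
  if (anyDuplicated(entries$sample)) abort("duplicate sample names in sample sheet")
  no_tag <- is.na(entries$fwd_barcode) & is.na(entries$rev_barcode) &
    is.na(entries$i5) & is.na(entries$i7)
  if (any(no_tag)) abort("sample sheet row with no barcode or index")
  if (!is.null(fwd_primer) && !nzchar(fwd_primer)) abort("fwd_primer must be non-empty")
  if (!is.null(rev_primer) && !nzchar(rev_primer)) abort("rev_primer must be non-empty")
  attr(entries, "fwd_primer") <- fwd_primer
  attr(entries, "rev_primer") <- rev_primer
  class(entries) <- c("sample_sheet", class(entries))
  entries
}

# ---- OTU table I/O ----------------------------------------------------------

#' Read / write an OTU count table
#'
#' On-disk format: TSV whose first column is `#OTU_ID`, remaining columns one
#' per sample, integer cells. In memory the table is a wide tibble with an
#' `otu_id` column followed by one non-negative integer column per sample.
#'
#' @param path Path to the TSV file.
#' @param table An OTU table tibble.
#' @return `read_otu_table()` returns the tibble; `write_otu_table()` returns
#'   `path` invisibly.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE, comment.char = "")
  names(df)[1] <- "otu_id"
  df$otu_id <- as.character(df$otu_id)
  validate_otu_table(as_tibble(df))
}

#' @rdname read_otu_table
#' @export
write_otu_table <- function(table, path) {
  table <- validate_otu_table(table)
  out <- table
  names(out)[1] <- "#OTU_ID"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_otu_table
#' @export
validate_otu_table <- function(table) {
  if (names(table)[1] != "otu_id") abort("OTU table must have `otu_id` as its first column")
  if (anyDuplicated(table$otu_id)) abort("duplicate OTU ids")
  if (anyDuplicated(names(table))) abort("duplicate sample ids")
  cnt <- as.matrix(table[-1])
  if (length(cnt) && (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))) {
    abort("OTU table counts must be non-negative integers")
  }
  as_tibble(table)
}

otu_counts <- function(table) {
  m <- as.matrix(table[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- table$otu_id
  m
}

otu_table_from_matrix <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  rn <- rownames(m) %||% character(nrow(m))
  dplyr::bind_cols(tibble(otu_id = rn), out)
}
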