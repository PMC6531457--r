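#' Read and write pipeline tables
#'
#' Event tables and bulk matrices travel as TSV with a one-line
#' header; Ct matrices as TSV with cells in rows (missing values may
#' be encoded as blank, `NA` or the instrument sentinel `999`, all
#' normalized to missing at read time); clonotype tables as AIRR-style
#' TSV with columns `v_call`, `j_call`, `junction_aa`,
#' `duplicate_count`; gene lists as plain text, one symbol per line.
#'
#' @param path file path.
#' @param x object to write.
#' @name klrpath-io
NULL

#' @rdname klrpath-io
#' @export
write_event_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname klrpath-io
#' @export
read_event_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' @rdname klrpath-io
#' @param missing_sentinels Ct values treated as undetected.
#' @param control_genes,lod passed to [ct_matrix()].
#' @export
read_ct_matrix <- function(path, control_genes = c("B2M", "Spike1"),
                           lod = 24, missing_sentinels = c("", "NA", "999")) {
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                           colClasses = "character")
  m <- as.matrix(raw)
  m[trimws(m) %in% missing_sentinels] <- NA
  storage.mode(m) <- "double"
  ct_matrix(m, control_genes = control_genes, lod = lod)
}

#' @rdname klrpath-io
#' @export
write_ct_matrix <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  df <- data.frame(cell = rownames(x$ct), x$ct, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname klrpath-io
#' @param population population label attached to the table.
#' @export
read_clonotypes <- function(path, population = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("v_call", "j_call", "junction_aa", "duplicate_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input("AIRR table lacks column(s): %s",
               paste(missing, collapse = ", "))
  clonotype_table(data.frame(v_gene = df$v_call, j_gene = df$j_call,
                             cdr3_aa = df$junction_aa,
                             count = df$duplicate_count),
                  population = population)
}

#' @rdname klrpath-io
#' @export
write_clonotypes <- function(x, path) {
  stopifnot(inherits(x, "clonotype_table"))
  out <- data.frame(v_call = x$v_gene, j_call = x$j_gene,
                    junction_aa = x$cdr3_aa, duplicate_count = x$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname klrpath-io
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname klrpath-io
#' @param labels sample labels for the bulk matrix rows.
#' @export
read_bulk_matrix <- function(path, labels = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE)
  if (is.null(labels)) {
    if (!"subset" %in% names(raw))
      stop_input("bulk TSV needs a 'subset' column or explicit labels")
    labels <- raw$subset
    raw$subset <- NULL
  }
  rn <- raw[[1]]
  m <- as.matrix(raw[-1])
  rownames(m) <- rn
  as_bulk(m, labels)
}

#' @rdname klrpath-io
#' @export
write_bulk_matrix <- function(x, path) {
  stopifnot(inherits(x, "bulk_matrix"))
  df <- data.frame(sample = rownames(x$expr), subset = x$labels, x$expr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-read records as FASTQ (Phred+33)
#'
#' Each read gets a deterministic placeholder nucleotide sequence and a
#' constant per-base quality equal to its rounded mean quality; the
#' clonotype annotation is carried in the read name as
#' `id|V|J|CDR3aa`, the convention [read_fastq_reads()] parses back.
#'
#' @param reads data.frame with `read_id`, `v_gene`, `j_gene`,
#'   `cdr3_aa`, `avg_quality`.
#' @param path output FASTQ path.
#' @param read_length placeholder sequence length.
#' @export
write_reads_fastq <- function(reads, path, read_length = 48) {
  n <- nrow(reads)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    paste(bases[(seq_len(read_length) * 7 + i) %% 4 + 1], collapse = "")
  }, character(1))
  q <- pmin(pmax(round(reads$avg_quality), 0), 41)
  quals <- vapply(q, function(qi)
    strrep(rawToChar(as.raw(qi + 33L)), read_length), character(1))
  names(seqs) <- sprintf("%s|%s|%s|%s", reads$read_id, reads$v_gene,
                         reads$j_gene, reads$cdr3_aa)
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read clonotype-annotated reads from FASTQ
#'
#' Validates the 4-line record structure (reporting the index of the
#' first malformed record), parses the file with Biostrings, decodes
#' Phred+33 qualities, and splits the `id|V|J|CDR3aa` read-name
#' convention back into clonotype fields.
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `v_gene`, `j_gene`, `cdr3_aa`,
#'   `avg_quality`.
#' @export
read_fastq_reads <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || length(lines) %% 4 != 0)
    stop_input("malformed FASTQ record %d: truncated file",
               length(lines) %/% 4 + 1)
  hdr <- seq(1, length(lines), by = 4)
  bad <- which(substr(lines[hdr], 1, 1) != "@" |
               substr(lines[hdr + 2], 1, 1) != "+")
  if (length(bad))
    stop_input("malformed FASTQ record %d", bad[1])
  # Biostrings drops its internal metadata columns on conversion; benign
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as.character(Biostrings::quality(qs))
  avg <- vapply(qual, function(s) mean(utf8ToInt(s)) - 33, numeric(1),
                USE.NAMES = FALSE)
  parts <- strsplit(names(qs), "|", fixed = TRUE)
  field <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else NA_character_, character(1))
  data.frame(read_id = field(1), v_gene = field(2), j_gene = field(3),
             cdr3_aa = field(4), avg_quality = avg)
}
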