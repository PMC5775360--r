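#' Read DNA sequences from a FASTA file
#'
#' Reads one or more DNA sequences, uppercases them, maps RNA-style 'U' to 'T'
#' and validates the alphabet. Records are returned in file order.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; mark all records as circular molecules (plastomes
#'   are circular, alignments are not).
#' @return A list of sequence records, each a list with elements `id`, `seq`
#'   (uppercase character scalar over `A,C,G,T,N`) and `circular`.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    validate_dna(seqs[[i]], ids[[i]], allow_gap = FALSE)
    recs[[i]] <- seq_record(ids[[i]], seqs[[i]], circular = circular)
  }
  names(recs) <- ids
  recs
}

#' Construct a sequence record
#'
#' @param id Record label, unique within a collection.
#' @param seq Uppercase DNA string over `A,C,G,T,N`.
#' @param circular Logical; whether the molecule is circular.
#' @return A list of class `seq_record`.
#' @export
seq_record <- function(id, seq, circular = FALSE) {
  validate_dna(seq, id, allow_gap = FALSE)
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "seq_record")
}

#' Write sequence records to FASTA
#'
#' @param records List of sequence records (see [seq_record()]).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Rows must be of equal length; the gap character is `-` only. At least two
#' rows are required.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `alignment_matrix`: list with `ids`, `mat` (character matrix,
#'   one row per sequence) and `length` (column count).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate alignment ids", call. = FALSE)
  seqs <- toupper(chartr("u", "t", tolower(as.character(set))))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment rows; lengths: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(seqs)) validate_dna(seqs[[i]], ids[[i]], allow_gap = TRUE)
  alignment_matrix(ids, seqs)
}

#' Construct an alignment matrix from id/sequence vectors
#'
#' @param ids Character vector of row labels.
#' @param seqs Character vector of equal-length aligned sequences.
#' @return An `alignment_matrix` object.
#' @export
alignment_matrix <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 2L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("ragged alignment rows", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, length = ncol(mat)),
            class = "alignment_matrix")
}

#' Write an alignment to aligned FASTA
#'
#' @param alignment An `alignment_matrix`.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  seqs <- apply(alignment$mat, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read gene features from GFF3 or a flat feature table
#'
#' Accepts GFF3 (`.gff`/`.gff3`, 9 tab-separated columns, 1-based inclusive
#' coordinates) or a simple tab-separated table with header
#' `name kind start end strand` (1-based inclusive). Rows whose kind is not
#' one of `CDS`, `tRNA`, `rRNA` are skipped and the skip count reported via a
#' message. Multi-exon genes (several rows sharing one gene name) are
#' assembled into a single feature; `intron_count` is `parts - 1`.
#'
#' @param path Path to the annotation file.
#' @param genome_length Optional genome length used to validate coordinates.
#' @return A list of `gene_feature` objects: `name`, `kind`, `parts` (a
#'   data.frame with 0-based half-open `start`, `end` and `strand`), and
#'   `intron_count`.
#' @export
read_features <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(list())
  first <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) == 9L && !identical(first[[1L]], "name")) {
    tab <- parse_gff3(body)
  } else {
    tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                             stringsAsFactors = FALSE)
    need <- c("name", "kind", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("flat feature table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }
  keep <- tab$kind %in% c("CDS", "tRNA", "rRNA")
  if (any(!keep)) {
    message(sum(!keep), " feature row(s) with kinds outside CDS/tRNA/rRNA ignored")
    tab <- tab[keep, , drop = FALSE]
  }
  if (!nrow(tab)) return(list())
  if (any(tab$end < tab$start)) {
    bad <- which(tab$end < tab$start)[1L]
    stop("feature '", tab$name[bad], "': end < start", call. = FALSE)
  }
  if (!is.null(genome_length) && any(tab$end > genome_length)) {
    bad <- which(tab$end > genome_length)[1L]
    stop("feature '", tab$name[bad], "' extends beyond genome length ",
         genome_length, call. = FALSE)
  }
  feats <- lapply(split(tab, factor(tab$name, levels = unique(tab$name))),
                  function(g) {
    g <- g[order(if (g$strand[1L] == "-") -g$start else g$start), , drop = FALSE]
    gene_feature(g$name[1L], g$kind[1L],
                 starts = g$start - 1L, ends = g$end, strands = g$strand)
  })
  unname(feats)
}

parse_gff3 <- function(body) {
  parts <- strsplit(body, "\t", fixed = TRUE)
  ok <- lengths(parts) == 9L
  if (any(!ok)) stop("malformed GFF3 line: ", body[which(!ok)[1L]], call. = FALSE)
  m <- do.call(rbind, parts)
  attrs <- m[, 9L]
  name <- gff3_attr(attrs, "gene")
  alt <- gff3_attr(attrs, "Name")
  alt2 <- gff3_attr(attrs, "ID")
  name[is.na(name)] <- alt[is.na(name)]
  name[is.na(name)] <- alt2[is.na(name)]
  if (anyNA(name)) stop("GFF3 row without gene/Name/ID attribute", call. = FALSE)
  data.frame(name = name, kind = m[, 3L],
             start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
             strand = m[, 7L], stringsAsFactors = FALSE)
}

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

#' Construct a gene feature
#'
#' @param name Gene symbol (case-sensitive, e.g. `ycf1`).
#' @param kind One of `CDS`, `tRNA`, `rRNA`.
#' @param starts,ends Integer vectors of exon intervals, 0-based half-open.
#' @param strands Character vector of `+`/`-` per exon.
#' @return A list of class `gene_feature`.
#' @export
gene_feature <- function(name, kind, starts, ends, strands = "+") {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  strands <- rep_len(strands, length(starts))
  if (any(ends <= starts)) stop("feature '", name, "': empty interval", call. = FALSE)
  parts <- data.frame(start = as.integer(starts), end = as.integer(ends),
                      strand = strands, stringsAsFactors = FALSE)
  structure(list(name = name, kind = kind, parts = parts,
                 intron_count = nrow(parts) - 1L),
            class = "gene_feature")
}

#' Write features as GFF3
#'
#' @param features List of `gene_feature` objects (0-based half-open parts).
#' @param path Output path.
#' @param seqid Sequence id used in column 1.
#' @export
write_features_gff3 <- function(features, path, seqid = "genome") {
  lines <- "##gff-version 3"
  for (f in features) {
    for (i in seq_len(nrow(f$parts))) {
      lines <- c(lines, paste(seqid, "plastidkit", f$kind,
                              f$parts$start[i] + 1L, f$parts$end[i], ".",
                              f$parts$strand[i], ".",
                              paste0("ID=", f$name, ".", i, ";gene=", f$name),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Tab-separated, header first, UTF-8, `\n` line endings. Numeric columns that
#' are not integer-valued are printed with 5 decimals (the precision used for
#' nucleotide-diversity tables).
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param digits Decimal places for non-integer numeric cells.
#' @export
write_report <- function(table, path, digits = 5L) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col) && !all(is.na(col) | col == round(col))) {
      out[[j]] <- fmt_num(col, digits)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a report table written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
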