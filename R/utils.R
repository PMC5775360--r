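# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; per-base work uses character
# vectors from seq_chars(). Coordinates are 0-based half-open internally and
# converted to 1-based inclusive only at report boundaries.

DNA_BASES <- c("A", "C", "G", "T")

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

chars_seq <- function(chars) paste(chars, collapse = "")

complement_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  unname(comp[chars])
}

revcomp <- function(seq) {
  chars_seq(rev(complement_chars(seq_chars(seq))))
}

complement_seq <- function(seq) chars_seq(complement_chars(seq_chars(seq)))

reverse_seq <- function(seq) chars_seq(rev(seq_chars(seq)))

#' @noRd
validate_dna <- function(seq, id = "<sequence>", allow_gap = FALSE) {
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'", call. = FALSE)
  allowed <- if (allow_gap) "ACGTN-" else "ACGTN"
  bad <- regexpr(paste0("[^", allowed, "]"), seq)
  if (bad > 0L) {
    stop("illegal character '", substr(seq, bad, bad), "' at position ", bad,
         " in record '", id, "'", call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# runs of TRUE in a logical vector -> data.frame(start, end) 0-based half-open
true_runs <- function(x) {
  if (!length(x)) return(data.frame(start = integer(), end = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# population standard deviation (divide by n)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

fmt_num <- function(x, digits = 5L) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
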