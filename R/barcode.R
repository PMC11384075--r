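#' Spatial barcode design pattern
#'
#' The 32-base spatial barcode read from each nano-well is described by a
#' template over IUPAC symbols: exact bases are constant positions, while
#' `N` (A/C/G/T), `V` (A/C/G) and `B` (C/G/T) are degenerate positions.
#' The default template is a 12-base constant adapter-derived prefix followed
#' by the 20-base degenerate block of the capture oligo; both halves are
#' configurable because the stored orientation depends on how demultiplexing
#' was run.
#'
#' @param template 32-character string over `ACGTNVB`.
#' @return An object of class `barcode_pattern`.
#' @examples
#' barcode_pattern()
#' @export
barcode_pattern <- function(template = paste0("CTCTTCCGATCT", "NNVNNVNNVNNVNNVNNNNN")) {
  if (!is.character(template) || length(template) != 1L)
    stop("template must be a single string")
  sym <- strsplit(template, "")[[1]]
  if (length(sym) != 32L)
    stop("template must be 32 symbols long, got ", length(sym))
  ok <- sym %in% c("A", "C", "G", "T", "N", "V", "B")
  if (!all(ok))
    stop("template contains unsupported symbols: ",
         paste(unique(sym[!ok]), collapse = ", "))
  structure(list(template = template, symbols = sym), class = "barcode_pattern")
}

#' @export
print.barcode_pattern <- function(x, ...) {
  cat("barcode_pattern:", x$template, "\n")
  invisible(x)
}

# allowed base set for one IUPAC template symbol
iupac_allowed <- function(symbol) {
  switch(symbol,
         A = "A", C = "C", G = "G", T = "T",
         N = c("A", "C", "G", "T"),
         V = c("A", "C", "G"),
         B = c("C", "G", "T"),
         stop("unsupported IUPAC symbol: ", symbol))
}

#' Validate one barcode against the design pattern
#'
#' Position-local check: every base must belong to the set admitted by the
#' template symbol at that position. Returns a verdict with the first
#' offending position and symbol when invalid.
#'
#' @param seq Barcode string.
#' @param pattern A [barcode_pattern()].
#' @return A list with elements `valid` (logical), and when invalid,
#'   `reason`, `position`, `symbol`.
#' @export
validate_barcode <- function(seq, pattern = barcode_pattern()) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("seq must be a single string")
  if (nchar(seq) != 32L)
    return(list(valid = FALSE, reason = "length",
                position = NA_integer_, symbol = NA_character_))
  bases <- strsplit(seq, "")[[1]]
  for (i in seq_len(32L)) {
    if (!bases[i] %in% iupac_allowed(pattern$symbols[i]))
      return(list(valid = FALSE, reason = "mismatch",
                  position = i, symbol = bases[i]))
  }
  list(valid = TRUE, reason = NA_character_,
       position = NA_integer_, symbol = NA_character_)
}

# regex equivalent of the template, for bulk validation
pattern_regex <- function(pattern) {
  cls <- vapply(pattern$symbols, function(s) {
    a <- iupac_allowed(s)
    if (length(a) == 1L) a else paste0("[", paste(a, collapse = ""), "]")
  }, character(1))
  paste0("^", paste(cls, collapse = ""), "$")
}

#' Validate many barcodes at once
#'
#' Vectorised equivalent of [validate_barcode()] (same semantics, checked by
#' tests); returns a logical vector.
#'
#' @param seqs Character vector of barcodes.
#' @param pattern A [barcode_pattern()].
#' @return Logical vector, TRUE where the barcode conforms to the template.
#' @export
validate_barcodes <- function(seqs, pattern = barcode_pattern()) {
  ok <- nchar(seqs) == 32L
  ok[ok] <- grepl(pattern_regex(pattern), seqs[ok])
  ok
}

#' Sample random pattern-conformant barcodes
#'
#' Draws each degenerate position uniformly from its admitted base set.
#' Uniqueness is not enforced here; see the simulator for collision handling.
#'
#' @param n Number of barcodes.
#' @param pattern A [barcode_pattern()].
#' @return Character vector of `n` 32-mers.
#' @export
sample_barcodes <- function(n, pattern = barcode_pattern()) {
  if (n == 0L) return(character(0))
  cols <- lapply(pattern$symbols, function(s) {
    a <- iupac_allowed(s)
    if (length(a) == 1L) rep(a, n) else sample(a, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# --- 2-bit base packing -----------------------------------------------------

.BASE_CODE <- {
  z <- integer(256)
  z[] <- NA_integer_
  z[utf8ToInt("A") + 1L] <- 0L
  z[utf8ToInt("C") + 1L] <- 1L
  z[utf8ToInt("G") + 1L] <- 2L
  z[utf8ToInt("T") + 1L] <- 3L
  z
}
.CODE_BASE <- c("A", "C", "G", "T")

#' Pack barcodes into 2-bit representation
#'
#' Encodes each 32-mer over ACGT as 8 bytes (A=0, C=1, G=2, T=3; base i of a
#' byte occupies bits 2(i-1)..2i-1, little-endian base order within the byte).
#'
#' @param seqs Character vector of 32-mers over ACGT.
#' @return Raw vector of length `8 * length(seqs)`.
#' @export
pack_barcodes <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(raw(0))
  if (any(nchar(seqs) != 32L)) stop("all barcodes must be 32 bases long")
  codes <- .BASE_CODE[as.integer(charToRaw(paste(seqs, collapse = ""))) + 1L]
  if (anyNA(codes)) stop("barcodes contain non-ACGT bases; cannot pack")
  m <- matrix(codes, nrow = 32L)             # 32 x n
  bytes <- m[seq(1, 32, 4), , drop = FALSE] +
    4L  * m[seq(2, 32, 4), , drop = FALSE] +
    16L * m[seq(3, 32, 4), , drop = FALSE] +
    64L * m[seq(4, 32, 4), , drop = FALSE]   # 8 x n
  as.raw(bytes)
}

#' Unpack 2-bit encoded barcodes
#'
#' Inverse of [pack_barcodes()].
#'
#' @param bytes Raw vector, length a multiple of 8.
#' @return Character vector of 32-mers.
#' @export
unpack_barcodes <- function(bytes) {
  if (length(bytes) == 0L) return(character(0))
  if (length(bytes) %% 8L != 0L) stop("byte stream length not a multiple of 8")
  v <- as.integer(bytes)
  n <- length(v) %/% 8L
  m <- matrix(0L, nrow = 32L, ncol = n)
  vb <- matrix(v, nrow = 8L)
  m[seq(1, 32, 4), ] <- vb %% 4L
  m[seq(2, 32, 4), ] <- (vb %/% 4L) %% 4L
  m[seq(3, 32, 4), ] <- (vb %/% 16L) %% 4L
  m[seq(4, 32, 4), ] <- (vb %/% 64L) %% 4L
  chars <- .CODE_BASE[m + 1L]
  dim(chars) <- dim(m)
  apply_paste_columns(chars)
}

# column-wise paste of a character matrix, avoiding apply()'s per-column cost
apply_paste_columns <- function(chars) {
  do.call(paste0, lapply(seq_len(nrow(chars)), function(i) chars[i, ]))
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(charToRaw(a) != charToRaw(b))
}

# all sequences at Hamming distance exactly 1 from `seq` over ACGT
hamming1_neighbours <- function(seq) {
  bases <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (i in seq_along(bases)) {
    for (b in setdiff(.CODE_BASE, bases[i])) {
      v <- bases
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
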