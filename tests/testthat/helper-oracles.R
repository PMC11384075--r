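# Independent brute-force oracles used to cross-check the implementation.

# per-position IUPAC matcher, written independently of validate_barcode()
bf_valid_barcode <- function(seq, template) {
  if (nchar(seq) != nchar(template)) return(FALSE)
  allowed <- list(A = "A", C = "C", G = "G", T = "T",
                  N = c("A", "C", "G", "T"),
                  V = c("A", "C", "G"), B = c("C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  t <- strsplit(template, "")[[1]]
  all(vapply(seq_along(s), function(i) s[i] %in% allowed[[t[i]]], logical(1)))
}

# naive Hamming distance on split characters (independent of hamming())
bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive whitelist scan implementing the <=1 mismatch contract
bf_match <- function(query, wl) {
  d <- unname(vapply(wl, bf_hamming, numeric(1), a = query))
  if (any(d == 0)) return(which(d == 0)[1])
  ones <- which(d == 1)
  if (length(ones) == 1L) ones else NA_integer_
}

# fast exhaustive scan for large whitelists: integer base matrix comparison
bf_match_bulk <- function(queries, wl) {
  enc <- function(x) {
    m <- matrix(as.integer(charToRaw(paste(x, collapse = ""))),
                nrow = nchar(x[1]))
    m
  }
  wm <- enc(wl)
  qm <- enc(queries)
  out <- integer(length(queries))
  for (i in seq_along(queries)) {
    d <- colSums(wm != qm[, i])
    ex <- which(d == 0)
    if (length(ex)) { out[i] <- ex[1]; next }
    ones <- which(d == 1)
    out[i] <- if (length(ones) == 1L) ones else NA_integer_
  }
  out
}

# explicit Hamming-1 connected components by repeated set expansion
bf_umi_components <- function(umis) {
  u <- unique(substr(umis, 1, 8))
  if (!length(u)) return(0L)
  n <- length(u)
  adj <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) bf_hamming(u[i], u[j]) <= 1L))
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    frontier <- s
    while (length(frontier)) {
      seen[frontier] <- TRUE
      nxt <- unique(unlist(lapply(frontier, function(i) which(adj[i, ]))))
      frontier <- nxt[!seen[nxt]]
    }
  }
  comps
}

# hexagonal lattice enumeration written independently of hex_lattice()
bf_lattice_count <- function(width, height, pitch, margin) {
  count <- 0L
  k <- 0L
  repeat {
    y <- margin + k * pitch * sqrt(3) / 2
    if (y > height - margin) break
    x <- margin + (k %% 2) * pitch / 2
    while (x <= width - margin) {
      count <- count + 1L
      x <- x + pitch
    }
    k <- k + 1L
  }
  count
}
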