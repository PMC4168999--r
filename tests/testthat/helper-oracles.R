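# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package internals: the motif
# oracle is a naive position-by-position loop with its own IUPAC map, the
# alignment oracle is a plain Gotoh dynamic programme, and the Fisher
# oracle enumerates tables with binomial coefficients.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# exhaustive single-strand scan: every start, every spacer length
oracle_scan_plus <- function(seq, half5, spacer_min, spacer_max, half3,
                             max_mm5 = 0L, max_mm3 = 0L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  h5 <- strsplit(half5, "", fixed = TRUE)[[1L]]
  h3 <- if (nchar(half3) > 0L) strsplit(half3, "", fixed = TRUE)[[1L]] else character(0L)
  rows <- list()
  for (sp in spacer_min:spacer_max) {
    w <- length(h5) + sp + length(h3)
    if (w > length(chars)) next
    for (i in seq_len(length(chars) - w + 1L)) {
      mm5 <- 0L; mm3 <- 0L; sp_ok <- TRUE
      for (j in seq_along(h5)) {
        if (!chars[i + j - 1L] %in% ORACLE_IUPAC[[h5[j]]]) mm5 <- mm5 + 1L
      }
      for (k in seq_len(sp)) {
        if (!chars[i + length(h5) + k - 1L] %in% c("A", "C", "G", "T")) sp_ok <- FALSE
      }
      if (length(h3) > 0L) {
        for (j in seq_along(h3)) {
          if (!chars[i + length(h5) + sp + j - 1L] %in% ORACLE_IUPAC[[h3[j]]]) {
            mm3 <- mm3 + 1L
          }
        }
      }
      if (sp_ok && mm5 <= max_mm5 && mm3 <= max_mm3) {
        rows[[length(rows) + 1L]] <- data.frame(start = i, end = i + w - 1L,
                                                spacer_len = sp,
                                                mm5 = mm5, mm3 = mm3)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0L), end = integer(0L),
                      spacer_len = integer(0L), mm5 = integer(0L),
                      mm3 = integer(0L)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$spacer_len), ]
}

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# plain Gotoh local alignment; a gap of length L costs open + L * extend
oracle_sw_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - (open + extend), E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - (open + extend), F[i - 1L, j] - extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + submat[av[i - 1L], bv[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# two-sided Fisher by direct enumeration with binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  denom <- choose(n, c1)
  probs <- vapply(lo:hi, function(k) choose(r1, k) * choose(r2, c1 - k) / denom,
                  numeric(1L))
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

random_dna_string <- function(n, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_protein_string <- function(n) {
  paste(sample(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1L]], n, replace = TRUE),
        collapse = "")
}

# flatten a fingerprint call's hits to (motif, offset3) rows
fingerprint_hit_table <- function(call) {
  parts <- list()
  if (!is.null(call$xbox_hits)) parts$x <- call$xbox_hits[, c("motif", "offset3")]
  if (!is.null(call$fox_hits)) parts$f <- call$fox_hits[, c("motif", "offset3")]
  if (length(parts) == 0L) {
    return(data.frame(motif = character(0L), offset3 = integer(0L)))
  }
  do.call(rbind, unname(parts))
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
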