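# Degenerate IUPAC consensus motifs with an optional variable-length spacer
# between two half-sites, and the scanner that applies them.  Matching is
# set-membership per position; a subject "N" matches no motif letter (not
# even motif "N"), the conservative choice for masked sequence.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  W = c("A", "T"), S = c("C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Degenerate consensus motif
#'
#' An IUPAC consensus with an optional variable-length spacer between a 5'
#' and a 3' half-site.  An empty \code{half3} with a zero spacer encodes a
#' plain single-block motif.  The packaged defaults are the RFX X-box
#' (\code{RYYRYY N1-3 RRNRAC}, with the \code{RYYNYY} 5' half as a named
#' alternative) and the forkhead motifs (\code{RYMAAYA} core;
#' \code{WDTGTTTGTTTA} / \code{KTTTGTTGTTKTW} stringent).
#'
#' @param name Motif label.
#' @param half5 IUPAC string (5' half-site, or the whole motif).
#' @param spacer_min,spacer_max Spacer length range (>= 0).
#' @param half3 IUPAC string (3' half-site; "" for single-block motifs).
#' @param class Motif class label, e.g. \code{"xbox"} or \code{"fox"}.
#' @param source Free-text citation for the consensus.
#' @return An object of class \code{consensus_motif}.
#' @export
consensus_motif <- function(name, half5, spacer_min = 0L, spacer_max = 0L,
                            half3 = "", class = "other", source = "") {
  half5 <- toupper(half5); half3 <- toupper(half3)
  for (h in c(half5, half3)) {
    chars <- strsplit(h, "", fixed = TRUE)[[1L]]
    bad <- setdiff(chars, names(IUPAC_SETS))
    if (length(bad) > 0L) {
      stop("illegal IUPAC letter(s) in motif '", name, "': ",
           paste(unique(bad), collapse = ", "))
    }
  }
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (spacer_min < 0L || spacer_max < spacer_min) {
    stop("require 0 <= spacer_min <= spacer_max")
  }
  if (nchar(half3) == 0L && spacer_max > 0L) {
    stop("a single-block motif (empty half3) must have a zero spacer")
  }
  if (nchar(half5) == 0L) stop("half5 must be non-empty")
  structure(list(name = name, half5 = half5, spacer_min = spacer_min,
                 spacer_max = spacer_max, half3 = half3, class = class,
                 source = source),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  pat <- if (nchar(x$half3) > 0L) {
    sprintf("%s N(%d-%d) %s", x$half5, x$spacer_min, x$spacer_max, x$half3)
  } else {
    x$half5
  }
  cat(sprintf("<consensus_motif> %s [%s]: %s (widths %d-%d)\n",
              x$name, x$class, pat, motif_min_width(x), motif_max_width(x)))
  invisible(x)
}

motif_min_width <- function(m) nchar(m$half5) + m$spacer_min + nchar(m$half3)
motif_max_width <- function(m) nchar(m$half5) + m$spacer_max + nchar(m$half3)

#' Compile a consensus motif into a matcher
#'
#' @param motif A \code{consensus_motif}.
#' @return A \code{motif_matcher}: per-spacer-length lists of allowed-base
#'   sets, with half-site index masks used for mismatch counting.  Spacer
#'   positions admit any of \code{A,C,G,T} (never \code{N}).
#' @export
compile_consensus <- function(motif) {
  stopifnot(inherits(motif, "consensus_motif"))
  h5 <- strsplit(motif$half5, "", fixed = TRUE)[[1L]]
  h3 <- if (nchar(motif$half3) > 0L) strsplit(motif$half3, "", fixed = TRUE)[[1L]]
        else character(0L)
  layouts <- lapply(seq.int(motif$spacer_min, motif$spacer_max), function(sp) {
    letters <- c(h5, rep("N", sp), h3)
    list(spacer_len = sp,
         sets = lapply(letters, function(ch) IUPAC_SETS[[ch]]),
         in_half5 = c(rep(TRUE, length(h5)), rep(FALSE, sp + length(h3))),
         in_half3 = c(rep(FALSE, length(h5) + sp), rep(TRUE, length(h3))),
         width = length(letters))
  })
  structure(list(motif = motif, layouts = layouts,
                 min_width = motif_min_width(motif),
                 max_width = motif_max_width(motif)),
            class = "motif_matcher")
}

# Vectorised one-strand scan: for each layout (spacer length), slide the
# allowed-set profile over the sequence and count half-site mismatches at
# every start.  Returns 1-based inclusive coordinates on the scanned strand.
scan_one_strand <- function(chars, matcher, max_mm5, max_mm3) {
  n <- length(chars)
  out <- list()
  for (lay in matcher$layouts) {
    w <- lay$width
    if (w > n) next
    nstart <- n - w + 1L
    mm5 <- integer(nstart); mm3 <- integer(nstart); mm_sp <- integer(nstart)
    for (j in seq_len(w)) {
      ok <- chars[j:(j + nstart - 1L)] %in% lay$sets[[j]]
      if (lay$in_half5[j]) mm5 <- mm5 + !ok
      else if (lay$in_half3[j]) mm3 <- mm3 + !ok
      else mm_sp <- mm_sp + !ok
    }
    hit <- which(mm5 <= max_mm5 & mm3 <= max_mm3 & mm_sp == 0L)
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        start = hit, end = hit + w - 1L, spacer_len = lay$spacer_len,
        mm5 = mm5[hit], mm3 = mm3[hit])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0L), end = integer(0L),
                      spacer_len = integer(0L), mm5 = integer(0L),
                      mm3 = integer(0L)))
  }
  do.call(rbind, out)
}

#' Scan a sequence for a motif
#'
#' Tests every start position and every admissible spacer length; all
#' matches are reported (overlaps allowed).  Minus-strand matches are
#' reported at plus-strand coordinates with \code{strand == "-"} and the
#' matched sequence given in motif orientation.
#'
#' @param seq A \code{dna_seq} or nucleotide string.
#' @param matcher A \code{motif_matcher} (or a \code{consensus_motif},
#'   compiled on the fly).
#' @param strands \code{"both"}, \code{"+"} or \code{"-"}.
#' @param max_mm5,max_mm3 Mismatches tolerated in the 5'/3' half-site
#'   (default 0: exact degenerate-consensus matching).
#' @return Data frame of hits: \code{motif}, \code{class}, \code{start},
#'   \code{end} (1-based inclusive, plus strand), \code{strand},
#'   \code{spacer_len}, \code{match}, \code{mm5}, \code{mm3}.
#' @examples
#' m <- consensus_motif("xbox", "RYYRYY", 1, 3, "RRNRAC", class = "xbox")
#' scan_motif("GTTGCCATGGCAAC", m)
#' @export
scan_motif <- function(seq, matcher, strands = c("both", "+", "-"),
                       max_mm5 = 0L, max_mm3 = 0L) {
  strands <- match.arg(strands)
  if (inherits(matcher, "consensus_motif")) matcher <- compile_consensus(matcher)
  stopifnot(inherits(matcher, "motif_matcher"))
  s <- as_dna_string(seq)
  n <- nchar(s)
  empty <- data.frame(motif = character(0L), class = character(0L),
                      start = integer(0L), end = integer(0L),
                      strand = character(0L), spacer_len = integer(0L),
                      match = character(0L), mm5 = integer(0L), mm3 = integer(0L),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  res <- list()
  if (strands %in% c("both", "+")) {
    h <- scan_one_strand(chars, matcher, max_mm5, max_mm3)
    if (nrow(h) > 0L) {
      h$strand <- "+"
      h$match <- substring(s, h$start, h$end)
      res[[length(res) + 1L]] <- h
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- reverse_complement(s)
    h <- scan_one_strand(strsplit(rc, "", fixed = TRUE)[[1L]], matcher,
                         max_mm5, max_mm3)
    if (nrow(h) > 0L) {
      h$match <- substring(rc, h$start, h$end)
      start_plus <- n - h$end + 1L
      h$end <- n - h$start + 1L
      h$start <- start_plus
      h$strand <- "-"
      res[[length(res) + 1L]] <- h
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out$motif <- matcher$motif$name
  out$class <- matcher$motif$class
  out <- out[order(out$start, out$strand, out$spacer_len),
             c("motif", "class", "start", "end", "strand", "spacer_len",
               "match", "mm5", "mm3")]
  rownames(out) <- NULL
  out
}

#' Classify an X-box hit
#'
#' \code{canonical}: both half-sites match the consensus exactly.
#' \code{relaxed}: the 3' half-site is exact and the (often more degenerate)
#' 5' half-site carries between 1 and \code{max_mm5} mismatches.
#' \code{none}: anything else, including any 3' half-site mismatch.
#'
#' @param hit One row of a \code{\link{scan_motif}} result for an X-box
#'   family motif.
#' @param max_mm5 Mismatch tolerance for the 5' half-site (default 2; this
#'   is a configurable operating point, not a published threshold).
#' @return \code{"canonical"}, \code{"relaxed"} or \code{"none"}.
#' @export
classify_xbox_hit <- function(hit, max_mm5 = 2L) {
  if (!is.data.frame(hit) || nrow(hit) != 1L) stop("hit must be a single row")
  if (!identical(hit$class, "xbox")) {
    stop("classification is defined for X-box family hits only")
  }
  if (hit$mm5 == 0L && hit$mm3 == 0L) return("canonical")
  if (hit$mm3 == 0L && hit$mm5 > 0L && hit$mm5 <= max_mm5) return("relaxed")
  "none"
}

#' Default motility-fingerprint motif set
#'
#' The X-box consensus is used in its \code{RYYRYY N1-3 RRNRAC} form by
#' default; the more degenerate \code{RYYNYY} 5' half is available as
#' \code{xbox_form = "RYYNYY"}.  The FOX component defaults to the
#' consensus core motif shared by most forkhead proteins (\code{RYMAAYA});
#' the stringent FOXJ1 sites can be added with \code{include_strict}.
#'
#' @param xbox_form \code{"RYYRYY"} (default) or \code{"RYYNYY"}.
#' @param include_strict Also include the two stringent FOXJ1 motifs.
#' @return Named list of \code{consensus_motif} objects.
#' @export
default_motif_set <- function(xbox_form = c("RYYRYY", "RYYNYY"),
                              include_strict = FALSE) {
  xbox_form <- match.arg(xbox_form)
  motifs <- list(
    xbox = consensus_motif("xbox", xbox_form, 1L, 3L, "RRNRAC",
                           class = "xbox", source = "RFX palindromic X-box"),
    fox_core = consensus_motif("fox_core", "RYMAAYA", class = "fox",
                               source = "forkhead consensus core")
  )
  if (include_strict) {
    motifs$foxj1_strict_a <- consensus_motif("foxj1_strict_a", "WDTGTTTGTTTA",
                                             class = "fox",
                                             source = "stringent FOXJ1 site")
    motifs$foxj1_strict_b <- consensus_motif("foxj1_strict_b", "KTTTGTTGTTKTW",
                                             class = "fox",
                                             source = "stringent FOXJ1 site")
  }
  motifs
}

#' Motility fingerprint of a promoter window
#'
#' Scans both strands of the terminal \code{window} bases of an upstream
#' region (supplied 5'-to-3', ending at its anchor: the TSS, or the ATG when
#' a sizeable 5'UTR makes the TSS unreliable) for the configured X-box and
#' FOX motifs.  Positions are reported as negative offsets from the anchor
#' for both motif ends (\code{offset5}, \code{offset3}; the base immediately
#' 5' of the anchor is \code{-1}), because published positions such as
#' \code{-16} do not state which end is measured.  X-box hits are kept when
#' they classify as \code{canonical} or \code{relaxed}.
#'
#' The verdict is \code{positive} iff the window holds at least one X-box
#' hit and at least one FOX hit.
#'
#' @param promoter A \code{dna_seq} or string ending at the anchor.
#' @param anchor \code{"TSS"} or \code{"ATG"} (bookkeeping label).
#' @param window Bases upstream of the anchor to scan (default 500;
#'   1000 for the expanded analysis).
#' @param motifs Motif set (default \code{\link{default_motif_set}()}).
#' @param max_mm5 5' half-site mismatch tolerance for relaxed X-boxes.
#' @return An object of class \code{fingerprint_call}: \code{window},
#'   \code{anchor}, \code{xbox_hits}, \code{fox_hits} (data frames with
#'   anchor-relative \code{offset5}/\code{offset3} and, for X-boxes, an
#'   \code{xbox_class} column), \code{xbox_separations} (start-to-start
#'   distances between distinct X-box hits), \code{nearest_fox_distance}
#'   (end-to-start gap, 0 when overlapping), and \code{verdict}.
#' @export
fingerprint_window <- function(promoter, anchor = c("TSS", "ATG"),
                               window = 500L, motifs = default_motif_set(),
                               max_mm5 = 2L) {
  anchor <- match.arg(anchor)
  s <- as_dna_string(promoter)
  n <- nchar(s)
  window <- as.integer(window)
  if (window > n) {
    warning("window (", window, ") exceeds promoter length (", n,
            "); scanning the available ", n, " nt")
    window <- n
  }
  sub <- substr(s, n - window + 1L, n)
  shift <- -window - 1L  # window-local 1-based start -> anchor-relative offset
  xbox <- list(); fox <- list()
  for (m in motifs) {
    mm5 <- if (identical(m$class, "xbox")) max_mm5 else 0L
    h <- scan_motif(sub, m, strands = "both", max_mm5 = mm5, max_mm3 = 0L)
    if (nrow(h) == 0L) next
    h$offset5 <- h$start + shift
    h$offset3 <- h$end + shift
    if (identical(m$class, "xbox")) {
      h$xbox_class <- vapply(seq_len(nrow(h)), function(i)
        classify_xbox_hit(h[i, ], max_mm5 = max_mm5), character(1L))
      h <- h[h$xbox_class != "none", , drop = FALSE]
      if (nrow(h) > 0L) xbox[[length(xbox) + 1L]] <- h
    } else if (identical(m$class, "fox")) {
      fox[[length(fox) + 1L]] <- h
    }
  }
  bind <- function(lst) if (length(lst) > 0L) do.call(rbind, lst) else NULL
  xbox <- bind(xbox); fox <- bind(fox)
  seps <- numeric(0L)
  if (!is.null(xbox) && nrow(xbox) > 1L) {
    st <- xbox$start
    seps <- as.vector(stats::dist(matrix(st, ncol = 1L)))
  }
  call <- structure(list(window = window, anchor = anchor,
                         xbox_hits = xbox, fox_hits = fox,
                         xbox_separations = seps,
                         nearest_fox_distance = NA_real_,
                         verdict = if (!is.null(xbox) && !is.null(fox))
                                     "positive" else "negative"),
                    class = "fingerprint_call")
  call$nearest_fox_distance <- nearest_fox_to_xbox(call)
  call
}

#' @export
print.fingerprint_call <- function(x, ...) {
  nx <- if (is.null(x$xbox_hits)) 0L else nrow(x$xbox_hits)
  nf <- if (is.null(x$fox_hits)) 0L else nrow(x$fox_hits)
  cat(sprintf("<fingerprint_call> %s: %d X-box hit(s), %d FOX hit(s) in %d bp upstream of %s\n",
              x$verdict, nx, nf, x$window, x$anchor))
  if (nx > 0L) {
    cat("  X-boxes (offset3 = 3' end relative to anchor):\n")
    for (i in seq_len(nx)) {
      h <- x$xbox_hits[i, ]
      cat(sprintf("    %s %s [%s] at %d..%d (%s)\n", h$motif, h$match,
                  h$xbox_class, h$offset5, h$offset3, h$strand))
    }
  }
  if (nf > 0L) {
    for (i in seq_len(nf)) {
      h <- x$fox_hits[i, ]
      cat(sprintf("    FOX %s %s at %d..%d (%s)\n", h$motif, h$match,
                  h$offset5, h$offset3, h$strand))
    }
  }
  if (!is.na(x$nearest_fox_distance)) {
    cat(sprintf("  nearest FOX-to-X-box gap: %g bp\n", x$nearest_fox_distance))
  }
  invisible(x)
}
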