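# Cross-species promoter conservation: apply the fingerprint to orthologous
# upstream windows and tabulate motif presence per species.  No cross-species
# alignment is attempted -- conservation is positional/compositional per
# species (motif presence and distances, not aligned columns).

#' Species promoter set
#'
#' @param entries Named list (one element per species), each a list with
#'   \code{seq} (upstream sequence ending at its anchor), \code{anchor}
#'   (\code{"TSS"} or \code{"ATG"}), and optional \code{utr5} (5'UTR length
#'   in nt, recorded when distances are measured from the ATG).
#' @return An object of class \code{species_promoter_set}.
#' @export
species_promoter_set <- function(entries) {
  if (length(entries) == 0L) stop("at least one species is required")
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be named by species")
  }
  entries <- lapply(entries, function(e) {
    if (is.character(e) || inherits(e, "dna_seq")) e <- list(seq = e)
    e$seq <- as_dna_string(e$seq)
    e$anchor <- if (is.null(e$anchor)) "TSS" else match.arg(e$anchor, c("TSS", "ATG"))
    e$utr5 <- if (is.null(e$utr5)) NA_integer_ else as.integer(e$utr5)
    e
  })
  structure(entries, class = "species_promoter_set")
}

#' Read a species promoter set from multi-FASTA
#'
#' Headers are \code{species} or \code{species anchor=ATG utr5=120}.
#'
#' @param path Multi-FASTA of upstream regions keyed by species.
#' @return A \code{\link{species_promoter_set}}.
#' @export
read_promoter_set <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  entries <- lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    toks <- strsplit(hdr, "\\s+")[[1L]]
    e <- list(seq = toupper(as.character(set[[i]])), anchor = "TSS",
              utr5 = NA_integer_)
    for (tk in toks[-1L]) {
      kv <- strsplit(tk, "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L && kv[1L] == "anchor") e$anchor <- kv[2L]
      if (length(kv) == 2L && kv[1L] == "utr5") e$utr5 <- as.integer(kv[2L])
    }
    e
  })
  names(entries) <- vapply(names(set), function(h)
    strsplit(h, "\\s+")[[1L]][1L], character(1L))
  species_promoter_set(entries)
}

#' Nearest FOX-to-X-box distance
#'
#' Minimum absolute gap between any FOX hit and any X-box hit of a positive
#' fingerprint, under the end-to-start, non-overlapping convention: the gap
#' between two motifs is \code{start(downstream) - end(upstream)}, clamped
#' at 0 for overlapping motifs.
#'
#' @param call A \code{\link{fingerprint_window}} result.
#' @return Distance in bp, or \code{NA} for a negative fingerprint.
#' @export
nearest_fox_to_xbox <- function(call) {
  stopifnot(inherits(call, "fingerprint_call"))
  if (is.null(call$xbox_hits) || is.null(call$fox_hits)) return(NA_real_)
  best <- Inf
  for (i in seq_len(nrow(call$fox_hits))) {
    for (j in seq_len(nrow(call$xbox_hits))) {
      f <- call$fox_hits[i, ]; x <- call$xbox_hits[j, ]
      gap <- max(x$start - f$end, f$start - x$end, 0L)
      best <- min(best, gap)
    }
  }
  as.numeric(best)
}

#' Build a cross-species conservation table
#'
#' Runs \code{\link{fingerprint_window}} on every species and summarises
#' per-class conservation fractions: the fraction of species carrying at
#' least one hit of the class (\code{xbox}, \code{xbox_canonical},
#' \code{xbox_relaxed}, \code{fox}).
#'
#' @param set A \code{\link{species_promoter_set}}.
#' @param motifs Motif set.
#' @param window Window length in bp.
#' @param max_mm5 Relaxed X-box 5' half-site tolerance.
#' @return An object of class \code{conservation_table}: \code{calls}
#'   (named list of fingerprint calls), \code{fractions} (named numeric in
#'   [0, 1]), \code{table} (one row per species: verdict, hit counts,
#'   nearest FOX position and X-box positions/sequences).
#' @export
build_conservation_table <- function(set, motifs = default_motif_set(),
                                     window = 500L, max_mm5 = 2L) {
  if (!inherits(set, "species_promoter_set")) set <- species_promoter_set(set)
  calls <- lapply(set, function(e) {
    fingerprint_window(e$seq, anchor = e$anchor, window = window,
                       motifs = motifs, max_mm5 = max_mm5)
  })
  has_class <- function(call, cls) {
    switch(cls,
      xbox = !is.null(call$xbox_hits),
      xbox_canonical = !is.null(call$xbox_hits) &&
        any(call$xbox_hits$xbox_class == "canonical"),
      xbox_relaxed = !is.null(call$xbox_hits) &&
        any(call$xbox_hits$xbox_class == "relaxed"),
      fox = !is.null(call$fox_hits))
  }
  classes <- c("xbox", "xbox_canonical", "xbox_relaxed", "fox")
  fractions <- vapply(classes, function(cl)
    mean(vapply(calls, has_class, logical(1L), cls = cl)), numeric(1L))
  rows <- lapply(names(calls), function(sp) {
    call <- calls[[sp]]
    xb <- call$xbox_hits
    fx <- call$fox_hits
    fmt_hit <- function(h) if (is.null(h) || nrow(h) == 0L) NA_character_ else
      paste(sprintf("%s@%d", h$match, h$offset3), collapse = ",")
    data.frame(species = sp, anchor = call$anchor, verdict = call$verdict,
               n_xbox = if (is.null(xb)) 0L else nrow(xb),
               n_fox = if (is.null(fx)) 0L else nrow(fx),
               fox_hits = fmt_hit(fx), xbox_hits = fmt_hit(xb),
               nearest_fox_distance = call$nearest_fox_distance,
               stringsAsFactors = FALSE)
  })
  structure(list(calls = calls, fractions = fractions,
                 table = do.call(rbind, rows), window = window),
            class = "conservation_table")
}

#' @export
print.conservation_table <- function(x, ...) {
  cat(sprintf("<conservation_table> %d species, %d bp window\n",
              length(x$calls), x$window))
  print(x$table, row.names = FALSE)
  cat("conservation fractions:\n")
  print(round(x$fractions, 3L))
  invisible(x)
}

#' Write a conservation table as TSV
#'
#' @param ct A \code{\link{build_conservation_table}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_conservation_tsv <- function(ct, path) {
  frac <- paste(sprintf("%s=%.3f", names(ct$fractions), ct$fractions),
                collapse = " ")
  write_tsv_commented(ct$table, path,
                      comment = c(sprintf("window=%d", ct$window),
                                  paste("conservation fractions:", frac)))
}
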