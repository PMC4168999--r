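# Consequence prediction for splice-acceptor substitutions.  When the
# invariant AG of a U2-type acceptor is destroyed, the spliceosome can adopt
# the nearest exonic AG 3' of the original junction (the cryptic acceptor),
# deleting the intervening transcript bases; a deletion not divisible by 3
# frameshifts translation, replacing the protein tail with novel residues
# until a new stop is met, typically in the 3'UTR.

#' Parse a minimal intronic HGVS-c substitution
#'
#' Accepts the subset \code{c.<pos>-<off><ref}>\code{<alt>} (negative
#' intronic offset relative to the first base of the downstream exon),
#' e.g. \code{"c.2432-1G>C"}.
#'
#' @param x HGVS-c string.
#' @return An \code{acceptor_variant}: \code{position} (1-based coding
#'   coordinate of the first exonic base), \code{offset} (negative),
#'   \code{ref}, \code{alt}.
#' @export
parse_hgvs_c <- function(x) {
  m <- regmatches(x, regexec("^c\\.([0-9]+)-([0-9]+)([ACGT])>([ACGT])$", x))[[1L]]
  if (length(m) != 5L) {
    stop("cannot parse '", x,
         "' as an intronic acceptor substitution (expected e.g. c.2432-1G>C)")
  }
  acceptor_variant(position = as.integer(m[2L]), offset = -as.integer(m[3L]),
                   ref = m[4L], alt = m[5L])
}

#' Acceptor variant
#'
#' @param position 1-based coding coordinate of the first base of the exon
#'   downstream of the affected intron.
#' @param offset Negative intronic offset (\code{-1} = last intron base).
#' @param ref,alt Reference and alternate base.
#' @return An object of class \code{acceptor_variant}.
#' @export
acceptor_variant <- function(position, offset, ref, alt) {
  position <- as.integer(position); offset <- as.integer(offset)
  if (position < 1L) stop("position must be >= 1")
  if (offset >= 0L) stop("offset must be negative (intronic)")
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
    stop("ref and alt must be single bases")
  }
  if (ref == alt) stop("ref == alt: not a variant")
  structure(list(position = position, offset = offset, ref = ref, alt = alt),
            class = "acceptor_variant")
}

#' @export
print.acceptor_variant <- function(x, ...) {
  cat(sprintf("<acceptor_variant> c.%d%d%s>%s\n", x$position, x$offset,
              x$ref, x$alt))
  invisible(x)
}

# transcript offsets (0-based) at which each exon begins
exon_tx_starts <- function(model) {
  lens <- model$exons[, "end"] - model$exons[, "start"]
  c(0L, cumsum(lens)[-length(lens)])
}

#' Apply an acceptor variant to a genomic sequence
#'
#' Applies the single-base substitution and flags the affected intron's
#' acceptor as disrupted iff its invariant terminal \code{AG} no longer
#' reads \code{AG}.  Plus-strand models only; reverse-complement the locus
#' to analyse a minus-strand gene.
#'
#' @param model A \code{\link{gene_model}} (\code{+} strand).
#' @param genome Locus sequence.
#' @param variant An \code{\link{acceptor_variant}} or HGVS-c string.
#' @return List: \code{genome} (mutated \code{dna_seq}), \code{exon_index}
#'   (1-based index of the downstream exon), \code{genomic_pos} (0-based
#'   position substituted), \code{disrupted} (logical).
#' @export
apply_acceptor_variant <- function(model, genome, variant) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  stopifnot(inherits(variant, "acceptor_variant"))
  if (model$strand != "+") {
    stop("variant application supports plus-strand models; reverse-complement the locus")
  }
  g <- as_dna_string(genome)
  t0 <- model$cds_start + variant$position - 1L
  starts <- exon_tx_starts(model)
  k <- match(t0, starts)
  if (is.na(k)) {
    stop("coding position ", variant$position,
         " is not the first base of any exon; the offset does not address an intron")
  }
  if (k == 1L) stop("the first exon has no upstream intron")
  gpos <- model$exons[k, "start"] + variant$offset  # 0-based genomic
  if (gpos < model$exons[k - 1L, "end"]) {
    stop("offset ", variant$offset, " reaches past the upstream intron")
  }
  have <- substr(g, gpos + 1L, gpos + 1L)
  if (have != variant$ref) {
    stop("reference mismatch at genomic position ", gpos, ": genome has '",
         have, "', variant states '", variant$ref, "'")
  }
  substr(g, gpos + 1L, gpos + 1L) <- variant$alt
  acc <- substr(g, model$exons[k, "start"] - 1L, model$exons[k, "start"])
  list(genome = dna_seq(g, id = "mutated"), exon_index = k,
       genomic_pos = gpos, disrupted = !identical(acc, "AG"))
}

#' Find the cryptic acceptor 3' of a disrupted junction
#'
#' Scans the exon sequence 3'-ward from the original exon start for the
#' nearest \code{AG} dinucleotide within \code{search_window} nt.  Splicing
#' to it removes every exonic base 5' of the base following the cryptic
#' \code{AG}, so the deleted count is the AG's offset plus 2.  Intronic
#' cryptic sites and exon skipping are deliberately not modelled.
#'
#' @param model A \code{\link{gene_model}}.
#' @param genome Locus sequence (mutated or wild type; the exon itself is
#'   unchanged by an intronic substitution).
#' @param exon_index 1-based index of the exon whose acceptor is disrupted.
#' @param search_window Scan limit in nt (default 50).
#' @return List: \code{found}, \code{offset} (0-based offset of the cryptic
#'   AG into the exon), \code{deleted_count}, \code{deleted_seq}.
#' @export
find_cryptic_acceptor <- function(model, genome, exon_index,
                                  search_window = 50L) {
  g <- as_dna_string(genome)
  ex <- model$exons[exon_index, ]
  exon_seq <- substr(g, ex["start"] + 1L, ex["end"])
  region <- substr(exon_seq, 1L, min(search_window, nchar(exon_seq)))
  p <- regexpr("AG", region, fixed = TRUE)
  if (p < 0L || (p + 1L) > search_window) {
    return(list(found = FALSE, offset = NA_integer_,
                deleted_count = NA_integer_, deleted_seq = NA_character_))
  }
  offset <- as.integer(p) - 1L
  list(found = TRUE, offset = offset, deleted_count = offset + 2L,
       deleted_seq = substr(exon_seq, 1L, offset + 2L))
}

#' Three-letter HGVS frameshift string
#'
#' Formats \code{p.<Wt><codon><Mut>fsTer<N>}, where \code{N} counts codons
#' from the first altered residue (= 1) to the novel stop.
#'
#' @param codon 1-based index of the first altered codon (>= 2; initiator
#'   changes are outside frameshift nomenclature).
#' @param wt_aa,mut_aa One- or three-letter residue codes.
#' @param ter_ordinal Stop ordinal (>= 2).
#' @return The HGVS-p string, e.g. \code{"p.Glu811GlyfsTer78"}.
#' @export
format_hgvs_fs <- function(codon, wt_aa, mut_aa, ter_ordinal) {
  codon <- as.integer(codon); ter_ordinal <- as.integer(ter_ordinal)
  if (codon < 2L) stop("initiator-codon changes are outside fs nomenclature")
  if (ter_ordinal < 2L) stop("ter_ordinal must be >= 2")
  sprintf("p.%s%d%sfsTer%d", aa_three_letter(wt_aa), codon,
          aa_three_letter(mut_aa), ter_ordinal)
}

aa_three_letter <- function(aa) {
  code <- Biostrings::AMINO_ACID_CODE  # one-letter -> three-letter
  aa <- as.character(aa)
  if (nchar(aa) == 1L) {
    out <- code[toupper(aa)]
    if (is.na(out)) stop("unknown residue: ", aa)
    return(unname(out))
  }
  norm <- paste0(toupper(substr(aa, 1L, 1L)), tolower(substr(aa, 2L, nchar(aa))))
  if (!norm %in% code) stop("unknown residue name: ", aa)
  norm
}

#' Full consequence of a splice-acceptor substitution
#'
#' Applies the variant, tests acceptor disruption, locates the cryptic
#' acceptor, builds the mutant transcript, translates wild type and mutant
#' (the mutant with 3'UTR readthrough), and derives the complete outcome:
#' deleted bases, frameshift status, first altered codon, replaced and
#' novel residue counts, stop position, HGVS strings, and the predicted
#' average-mass shift.
#'
#' \code{replaced_count} counts the wild-type residues lost from the first
#' altered codon to the wild-type C-terminus (inclusive);
#' \code{novel_count} counts the mutant residues from the first altered
#' codon to the residue preceding the novel stop, so that
#' \code{ter_codon = first_altered_codon + novel_count} always holds.
#'
#' @param model A \code{\link{gene_model}} (\code{+} strand).
#' @param genome Locus sequence (wild type).
#' @param variant An \code{\link{acceptor_variant}} or HGVS-c string.
#' @param search_window Cryptic-acceptor scan limit in nt.
#' @param mass_table Average-mass table.
#' @return An object of class \code{splice_consequence}.  Its \code{type}
#'   is one of \code{"frameshift"}, \code{"inframe_deletion"},
#'   \code{"acceptor_intact"} (the substitution leaves the AG readable; the
#'   transcript is wild type) or \code{"no_cryptic_acceptor"}.
#' @export
splice_consequence <- function(model, genome, variant, search_window = 50L,
                               mass_table = average_mass_table()) {
  if (is.character(variant)) variant <- parse_hgvs_c(variant)
  app <- apply_acceptor_variant(model, genome, variant)
  wt_tx <- splice_transcript(model, genome)
  hgvs_c_variant <- sprintf("c.%d%d%s>%s", variant$position, variant$offset,
                            variant$ref, variant$alt)
  base <- list(gene_id = model$gene_id, variant = hgvs_c_variant,
               acceptor_disrupted = app$disrupted,
               wt_transcript = wt_tx$residues)
  if (!app$disrupted) {
    mut_tx <- splice_transcript(model, app$genome)
    out <- c(base, list(type = "acceptor_intact",
                        mut_transcript = mut_tx$residues))
    return(structure(out, class = "splice_consequence"))
  }
  cry <- find_cryptic_acceptor(model, app$genome, app$exon_index,
                               search_window = search_window)
  if (!cry$found) {
    out <- c(base, list(type = "no_cryptic_acceptor",
                        search_window = search_window))
    return(structure(out, class = "splice_consequence"))
  }
  del <- cry$deleted_count
  t0 <- model$cds_start + variant$position - 1L
  wt <- wt_tx$residues
  mut_tx <- paste0(substr(wt, 1L, t0), substr(wt, t0 + del + 1L, nchar(wt)))
  hgvs_c_effect <- sprintf("c.%d-%ddel%s", variant$position,
                           variant$position + del - 1L, cry$deleted_seq)
  wt_trans <- translate_cds(wt, model$cds_start)
  mut_trans <- translate_cds(mut_tx, model$cds_start, readthrough = TRUE)
  wt_p <- wt_trans$protein$residues
  mut_p <- mut_trans$protein$residues
  base <- c(base, list(cryptic_offset = cry$offset, deleted_count = del,
                       deleted_seq = cry$deleted_seq,
                       hgvs_c_effect = hgvs_c_effect,
                       mut_transcript = mut_tx,
                       wt_protein = wt_p, mut_protein = mut_p,
                       mass_shift_da = protein_average_mass(mut_p, mass_table) -
                                       protein_average_mass(wt_p, mass_table)))
  if (del %% 3L == 0L) {
    out <- c(base, list(type = "inframe_deletion",
                        deleted_codons = del %/% 3L,
                        frameshift = FALSE))
    return(structure(out, class = "splice_consequence"))
  }
  wt_chars <- strsplit(wt_p, "", fixed = TRUE)[[1L]]
  mut_chars <- strsplit(mut_p, "", fixed = TRUE)[[1L]]
  nmin <- min(length(wt_chars), length(mut_chars))
  diffs <- which(wt_chars[seq_len(nmin)] != mut_chars[seq_len(nmin)])
  first <- if (length(diffs) > 0L) diffs[1L] else nmin + 1L
  if (first > length(mut_chars) || first > length(wt_chars)) {
    # the shifted frame happens to re-encode the wild-type residues up to
    # the shorter protein's end: no residue substitution to report, only a
    # stop relocation (or none at all)
    type <- if (length(wt_chars) == length(mut_chars)) "synonymous"
            else "stop_shift"
    out <- c(base, list(type = type, frameshift = TRUE,
                        ter_codon = mut_trans$ter_codon_index))
    return(structure(out, class = "splice_consequence"))
  }
  replaced <- length(wt_chars) - first + 1L
  novel <- length(mut_chars) - first + 1L
  ter <- mut_trans$ter_codon_index
  out <- c(base, list(type = "frameshift", frameshift = TRUE,
                      first_altered_codon = first,
                      wt_aa = wt_chars[first], mut_aa = mut_chars[first],
                      replaced_count = replaced, novel_count = novel,
                      ter_codon = ter, fs_ter_ordinal = novel + 1L,
                      hgvs_p = format_hgvs_fs(first, wt_chars[first],
                                              mut_chars[first], novel + 1L)))
  stopifnot(out$ter_codon == out$first_altered_codon + out$novel_count)
  structure(out, class = "splice_consequence")
}

#' @export
print.splice_consequence <- function(x, ...) {
  cat(sprintf("<splice_consequence> %s %s: %s\n", x$gene_id, x$variant, x$type))
  if (identical(x$type, "frameshift")) {
    cat(sprintf("  %s (%s): %d nt deleted, %d wild-type residue(s) replaced by %d novel, Ter at codon %d\n",
                x$hgvs_c_effect, x$hgvs_p, x$deleted_count,
                x$replaced_count, x$novel_count, x$ter_codon))
    cat(sprintf("  predicted average-mass shift: %+.2f kDa\n",
                x$mass_shift_da / 1000))
  } else if (identical(x$type, "inframe_deletion")) {
    cat(sprintf("  %s: in-frame deletion of %d codon(s)\n",
                x$hgvs_c_effect, x$deleted_codons))
  }
  invisible(x)
}

#' Splice consequence as a flat list for JSON/TSV reports
#'
#' @param x A \code{\link{splice_consequence}}.
#' @param sequences Include the transcript/protein strings.
#' @return Named list of scalar fields (NA for inapplicable ones).
#' @export
splice_consequence_record <- function(x, sequences = FALSE) {
  stopifnot(inherits(x, "splice_consequence"))
  g <- function(f, default = NA) if (!is.null(x[[f]])) x[[f]] else default
  rec <- list(gene_id = x$gene_id, variant = x$variant, type = x$type,
              acceptor_disrupted = x$acceptor_disrupted,
              cryptic_offset = g("cryptic_offset"),
              deleted_count = g("deleted_count"),
              deleted_seq = g("deleted_seq"),
              hgvs_c_effect = g("hgvs_c_effect"),
              first_altered_codon = g("first_altered_codon"),
              wt_aa = g("wt_aa"), mut_aa = g("mut_aa"),
              replaced_count = g("replaced_count"),
              novel_count = g("novel_count"),
              ter_codon = g("ter_codon"),
              hgvs_p = g("hgvs_p"),
              mass_shift_da = g("mass_shift_da"),
              # cryptic usage shortens RT-PCR amplicons by the deleted count
              rt_pcr_size_delta = if (!is.null(x$deleted_count))
                -x$deleted_count else NA)
  if (sequences) {
    rec$wt_transcript <- x$wt_transcript
    rec$mut_transcript <- g("mut_transcript")
    rec$wt_protein <- g("wt_protein")
    rec$mut_protein <- g("mut_protein")
  }
  rec
}
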