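# Core sequence and gene-model types.  Internal coordinates are 0-based
# half-open; user-facing HGVS and report coordinates are 1-based.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Nucleotide sequence
#'
#' A labelled nucleotide string over \code{A,C,G,T,N}.  Input is uppercased
#' on ingest; any other character is rejected.  \code{N} is preserved: it
#' translates to \code{X} inside a codon and never matches a motif letter.
#'
#' @param residues Character scalar of bases (case-insensitive).
#' @param id Free-text label.
#' @return An object of class \code{dna_seq} with fields \code{id} and
#'   \code{residues}.
#' @examples
#' dna_seq("gttgccATGGCAAC", id = "xbox")
#' @export
dna_seq <- function(residues, id = "") {
  res <- toupper(as.character(residues))
  if (length(res) != 1L || is.na(res)) stop("residues must be a single string")
  bad <- setdiff(strsplit(res, "", fixed = TRUE)[[1L]], DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("illegal nucleotide character(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(id = as.character(id), residues = res), class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  cat(sprintf("<dna_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  preview <- if (nchar(x$residues) > 60L) paste0(substr(x$residues, 1L, 60L), "...")
             else x$residues
  cat(" ", preview, "\n")
  invisible(x)
}

# Accept a dna_seq or a bare string; return the validated residue string.
as_dna_string <- function(x) {
  if (inherits(x, "dna_seq")) return(x$residues)
  dna_seq(x)$residues
}

#' Protein sequence
#'
#' A labelled amino-acid string over the 20 one-letter residues plus an
#' optional single terminal \code{*}.  \code{X} (unknown, e.g. from
#' \code{N}-containing codons) is also admitted.
#'
#' @param residues Character scalar of one-letter residues.
#' @param id Free-text label.
#' @return An object of class \code{protein_seq}.
#' @export
protein_seq <- function(residues, id = "") {
  res <- toupper(as.character(residues))
  if (length(res) != 1L || is.na(res)) stop("residues must be a single string")
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  stars <- which(chars == "*")
  if (length(stars) > 1L || (length(stars) == 1L && stars != length(chars))) {
    stop("'*' may appear at most once, and only at the final position")
  }
  bad <- setdiff(chars, c(AA_ALPHABET, "X", "*"))
  if (length(bad) > 0L) {
    stop("illegal amino-acid character(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(list(id = as.character(id), residues = res), class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, nchar(gsub("*", "", x$residues, fixed = TRUE))))
  invisible(x)
}

as_protein_string <- function(x) {
  if (inherits(x, "protein_seq")) return(x$residues)
  protein_seq(x)$residues
}

#' Reverse complement
#'
#' @param seq A \code{dna_seq} or nucleotide string.
#' @return The reverse complement, in the same form as the input
#'   (\code{dna_seq} in, \code{dna_seq} out).  \code{N} maps to \code{N}.
#' @examples
#' reverse_complement("GTTGCCATGGCAAC")  # palindromic: returns itself
#' @export
reverse_complement <- function(seq) {
  s <- as_dna_string(seq)
  rc <- chartr("ACGTN", "TGCAN", s)
  rc <- paste(rev(strsplit(rc, "", fixed = TRUE)[[1L]]), collapse = "")
  if (inherits(seq, "dna_seq")) dna_seq(rc, id = seq$id) else rc
}

#' Gene model
#'
#' Exon structure of a single transcript on a genomic sequence.  Exons are
#' genomic intervals, 0-based half-open, stored in ascending genomic order;
#' transcript order is ascending for \code{+} strand and descending for
#' \code{-}.  \code{cds_start}/\code{cds_end} are 0-based offsets into the
#' spliced transcript delimiting the coding region.  \code{anchor} records
#' which landmark (TSS or ATG) upstream distances are measured from when
#' this model's promoter is analysed.
#'
#' @param gene_id Label.
#' @param exons Two-column matrix or data.frame of \code{start}, \code{end}
#'   (0-based half-open genomic intervals).
#' @param strand \code{"+"} or \code{"-"}.
#' @param cds_start,cds_end 0-based transcript offsets of the CDS.
#' @param anchor \code{"TSS"} or \code{"ATG"}.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, exons, strand = "+", cds_start, cds_end,
                       anchor = c("TSS", "ATG")) {
  anchor <- match.arg(anchor)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE)) {
      stop("exons must be in ascending genomic order")
    }
    if (any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
      stop("exons overlap")
    }
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  spliced_len <- sum(exons[, "end"] - exons[, "start"])
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < 0L || cds_start >= cds_end || cds_end > spliced_len) {
    stop("require 0 <= cds_start < cds_end <= spliced length (", spliced_len, ")")
  }
  structure(list(gene_id = as.character(gene_id), exons = exons, strand = strand,
                 cds_start = cds_start, cds_end = cds_end, anchor = anchor),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  strand %s  %d exon(s), spliced %d nt, CDS [%d,%d) anchored at %s\n",
              x$gene_id, x$strand, nrow(x$exons),
              sum(x$exons[, "end"] - x$exons[, "start"]),
              x$cds_start, x$cds_end, x$anchor))
  invisible(x)
}

#' Splice a transcript from a gene model
#'
#' Concatenates the exon sequences in transcript order (reverse-complemented
#' for \code{-} strand models).  Intronic bases never appear in the output.
#'
#' @param model A \code{gene_model}.
#' @param genome A \code{dna_seq} or nucleotide string holding the locus.
#' @return A \code{dna_seq} of length equal to the summed exon lengths.
#' @export
splice_transcript <- function(model, genome) {
  g <- as_dna_string(genome)
  n <- nchar(g)
  ex <- model$exons
  if (any(ex[, "end"] > n) || any(ex[, "start"] < 0L)) {
    stop("exon interval out of genome bounds")
  }
  pieces <- substring(g, ex[, "start"] + 1L, ex[, "end"])
  if (model$strand == "-") {
    pieces <- rev(vapply(pieces, function(p) reverse_complement(p), character(1L)))
  }
  dna_seq(paste(pieces, collapse = ""), id = paste0(model$gene_id, "_transcript"))
}

#' Acceptor dinucleotides of every intron
#'
#' For a \code{+}-strand model, the last two genomic bases of each intron
#' (the bases immediately 5' of each internal exon) read \code{AG} at a
#' canonical U2-type acceptor.
#'
#' @param model A \code{gene_model} (plus strand).
#' @param genome Locus sequence.
#' @return Character vector, one dinucleotide per intron (length
#'   \code{nrow(exons) - 1}).
#' @export
intron_acceptors <- function(model, genome) {
  if (model$strand != "-") {
    g <- as_dna_string(genome)
    starts <- model$exons[-1L, "start"]
    substring(g, starts - 1L, starts)
  } else {
    g <- as_dna_string(genome)
    ends <- model$exons[-nrow(model$exons), "end"]
    vapply(substring(g, ends + 1L, ends + 2L),
           function(d) reverse_complement(d), character(1L), USE.NAMES = FALSE)
  }
}

#' Standard codon table
#'
#' The standard genetic code as a named character vector (64 codons to
#' one-letter residues, stops as \code{*}), taken from
#' \code{Biostrings::GENETIC_CODE}.
#'
#' @return Named character vector of length 64.
#' @export
standard_codon_table <- function() {
  tab <- Biostrings::GENETIC_CODE
  aa <- as.vector(tab)
  names(aa) <- names(tab)
  aa
}

#' Translate a coding sequence
#'
#' Translates codon by codon from \code{cds_start}, stopping at the first
#' stop codon.  With \code{readthrough = TRUE} translation is allowed to
#' run past an annotated CDS end (\code{cds_end}) into the 3'UTR until a
#' stop is found -- the behaviour needed for frameshifts that abolish the
#' annotated stop.  Codons containing \code{N} translate to \code{X}.
#'
#' @param transcript A \code{dna_seq} or string (the spliced transcript).
#' @param cds_start 0-based offset of the first coding base.
#' @param table Codon table (default the standard code).
#' @param readthrough Permit translation past \code{cds_end}.
#' @param cds_end Optional 0-based end of the annotated CDS; only consulted
#'   when \code{readthrough = FALSE}, in which case failure to find a stop
#'   by \code{cds_end} raises the no-stop condition.
#' @return List with \code{protein} (a \code{protein_seq}, stop excluded)
#'   and \code{ter_codon_index} (1-based codon position of the stop).
#' @export
translate_cds <- function(transcript, cds_start, table = standard_codon_table(),
                          readthrough = FALSE, cds_end = NULL) {
  s <- as_dna_string(transcript)
  n <- nchar(s)
  cds_start <- as.integer(cds_start)
  if (cds_start < 0L || cds_start >= n) stop("cds_start outside transcript")
  stops <- names(table)[table == "*"]
  limit <- if (!readthrough && !is.null(cds_end)) as.integer(cds_end) else n
  aa <- character(0L)
  i <- cds_start
  ter <- NA_integer_
  codon_index <- 0L
  while (i + 3L <= limit) {
    codon_index <- codon_index + 1L
    codon <- substr(s, i + 1L, i + 3L)
    if (grepl("N", codon, fixed = TRUE)) {
      aa <- c(aa, "X")
    } else if (codon %in% stops) {
      ter <- codon_index
      break
    } else {
      res <- unname(table[codon])
      if (is.na(res)) stop("unknown codon: ", codon)
      aa <- c(aa, res)
    }
    i <- i + 3L
  }
  if (is.na(ter)) {
    stop(structure(class = c("ciliaprint_no_stop", "error", "condition"),
                   list(message = paste0("no stop codon found before position ",
                                         limit, " in frame from ", cds_start),
                        call = sys.call())))
  }
  list(protein = protein_seq(paste(aa, collapse = "")),
       ter_codon_index = ter)
}

#' Average residue mass table
#'
#' ExPASy-style average (not monoisotopic) residue masses in daltons, with
#' the mass of one water molecule.  Average masses are the appropriate
#' scale for gel-mobility size shifts.
#'
#' @return List with \code{residues} (named numeric, Da) and \code{water}.
#' @export
average_mass_table <- function() {
  list(residues = c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  ), water = 18.01524)
}

#' Average protein mass
#'
#' Sum of average residue masses plus one water.
#'
#' @param p A \code{protein_seq} or residue string (no \code{*}).
#' @param table Mass table from \code{\link{average_mass_table}}.
#' @return Mass in daltons.
#' @examples
#' protein_average_mass("G")  # 75.07 Da
#' @export
protein_average_mass <- function(p, table = average_mass_table()) {
  s <- as_protein_string(p)
  if (grepl("*", s, fixed = TRUE)) stop("terminator '*' has no mass; strip it first")
  if (nchar(s) == 0L) return(table$water)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  m <- table$residues[chars]
  if (anyNA(m)) stop("unknown residue(s): ", paste(unique(chars[is.na(m)]), collapse = ", "))
  sum(m) + table$water
}
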