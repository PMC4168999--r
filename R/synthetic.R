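# Seeded generators for every input class the pipeline consumes, each with
# machine-readable ground truth.  One top-level seed; per-generator streams
# are derived deterministically from it (seed x generator label), so adding
# a generator never perturbs existing fixtures.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Derive a per-generator seed from a top-level seed
#'
#' Deterministic 31-bit hash of (seed, label).
#'
#' @param seed Top-level integer seed.
#' @param label Generator label.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147480009
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer(h)
}

# run code under a derived seed, restoring the caller's RNG state
with_derived_seed <- function(seed, label, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
           get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(derive_seed(seed, label))
  force(code)
}

#' Random nucleotide sequence
#'
#' I.i.d. bases at a configurable GC content.  Uses the current RNG stream.
#'
#' @param n Length.
#' @param gc GC fraction (default 0.5).
#' @return Nucleotide string.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Sample a concrete instance of a consensus motif
#'
#' Each consensus position is drawn uniformly from its allowed base set;
#' the spacer length is drawn uniformly from the admissible range (or
#' fixed via \code{spacer_len}).
#'
#' @param motif A \code{\link{consensus_motif}}.
#' @param spacer_len Optional fixed spacer length.
#' @return List: \code{seq}, \code{spacer_len}.
#' @export
sample_motif_instance <- function(motif, spacer_len = NULL) {
  if (is.null(spacer_len)) {
    spacer_len <- if (motif$spacer_max > motif$spacer_min) {
      sample(motif$spacer_min:motif$spacer_max, 1L)
    } else motif$spacer_min
  }
  letters <- c(strsplit(motif$half5, "", fixed = TRUE)[[1L]],
               rep("N", spacer_len),
               if (nchar(motif$half3) > 0L)
                 strsplit(motif$half3, "", fixed = TRUE)[[1L]])
  seq <- vapply(letters, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1L), USE.NAMES = FALSE)
  list(seq = paste(seq, collapse = ""), spacer_len = spacer_len)
}

#' Per-site substitution divergence
#'
#' Each position independently substitutes to a different letter of the
#' alphabet with probability \code{rate}.
#'
#' @param seq Sequence string.
#' @param rate Per-site substitution probability.
#' @param alphabet Letters to substitute among.
#' @return Diverged string.
#' @export
diverge_sequence <- function(seq, rate, alphabet = c("A", "C", "G", "T")) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  flip <- runif(length(chars)) < rate
  for (i in which(flip)) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a cross-species promoter set with planted motifs
#'
#' Backgrounds are i.i.d. bases at the given GC content; each planted motif
#' is a concrete instance sampled from its consensus, placed so its 3' end
#' sits at the requested anchor-relative offset, then diverged by per-site
#' substitution.  Overlapping planted motifs are a recipe error.
#'
#' @param n_species Number of simulated species.
#' @param length Promoter length (each sequence ends at its anchor).
#' @param planted Named numeric vector: motif name (must exist in
#'   \code{motifs}) to 3'-end offset (negative, e.g. \code{-16}).
#' @param motifs Motif set the names refer to.
#' @param divergence Per-site substitution rate applied to each planted
#'   instance (0 = exact).
#' @param gc Background GC fraction.
#' @param seed Top-level seed.
#' @return List: \code{set} (a \code{\link{species_promoter_set}}),
#'   \code{truth} (data frame of planted positions, classes and sequences).
#' @export
simulate_promoter_set <- function(n_species = 6L, length = 500L,
                                  planted = c(xbox = -16, fox_core = -60),
                                  motifs = default_motif_set(),
                                  divergence = 0, gc = 0.5, seed = 1L) {
  stopifnot(all(names(planted) %in% names(motifs)))
  with_derived_seed(seed, "promoters", {
    entries <- list()
    truth <- list()
    for (s in seq_len(n_species)) {
      sp <- sprintf("species_%02d", s)
      bg <- strsplit(random_dna(length, gc), "", fixed = TRUE)[[1L]]
      occupied <- logical(length)
      for (mn in names(planted)) {
        m <- motifs[[mn]]
        inst <- sample_motif_instance(m)
        w <- nchar(inst$seq)
        end <- length + planted[[mn]] + 1L     # offset3 -> 1-based end
        start <- end - w + 1L
        if (start < 1L || end > length) {
          stop("planted motif '", mn, "' does not fit the window")
        }
        if (any(occupied[start:end])) {
          stop("planted motifs overlap at ", start, "..", end)
        }
        occupied[start:end] <- TRUE
        placed <- diverge_sequence(inst$seq, divergence)
        bg[start:end] <- strsplit(placed, "", fixed = TRUE)[[1L]]
        truth[[length(truth) + 1L]] <- data.frame(
          species = sp, motif = mn, class = m$class,
          start = start, end = end,
          offset5 = start - length - 1L, offset3 = planted[[mn]],
          spacer_len = inst$spacer_len,
          planted_seq = inst$seq, diverged_seq = placed,
          stringsAsFactors = FALSE)
      }
      entries[[sp]] <- list(seq = paste(bg, collapse = ""), anchor = "TSS")
    }
    list(set = species_promoter_set(entries), truth = do.call(rbind, truth))
  })
}

# ---- mini-genes ------------------------------------------------------------

#' Deterministic two-exon mini-gene fixture
#'
#' Exon 1 \code{ATGGCT}, exon 2 \code{AGGATTTAAGCTGA} (AG-initial, the same
#' configuration as a final-exon acceptor whose first two coding bases are
#' AG), joined by a canonical \code{GT..AG} intron.  Wild-type mRNA
#' \code{ATGGCTAGGATTTAAGCTGA}; the acceptor variant is \code{c.7-1G>C}.
#'
#' @return List: \code{model}, \code{genome}, \code{variant}, \code{truth}
#'   (from the generator's naive oracle).
#' @export
minigene_fixture <- function() {
  exon1 <- "ATGGCT"; intron <- "GTAAGTATCTTTCCAG"; exon2 <- "AGGATTTAAGCTGA"
  build_minigene(exon1, intron, exon2, gene_id = "minigene_fixture")
}

# assemble model + genome + variant + oracle truth from the three pieces
build_minigene <- function(exon1, intron, exon2, gene_id = "minigene",
                           search_window = 50L) {
  stopifnot(substr(intron, nchar(intron) - 1L, nchar(intron)) == "AG")
  genome <- paste0(exon1, intron, exon2)
  n1 <- nchar(exon1); ni <- nchar(intron); n2 <- nchar(exon2)
  model <- gene_model(gene_id,
                      rbind(c(0L, n1), c(n1 + ni, n1 + ni + n2)),
                      strand = "+", cds_start = 0L, cds_end = n1 + n2,
                      anchor = "TSS")
  variant <- sprintf("c.%d-1G>C", n1 + 1L)
  truth <- naive_splice_truth(exon1, exon2, search_window = search_window)
  list(model = model, genome = dna_seq(genome, id = gene_id),
       variant = variant, truth = truth)
}

# one-letter -> three-letter residue codes for the oracle's HGVS strings
ORACLE_AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# plain loop translator used only by the oracle
naive_translate <- function(tx) {
  code <- Biostrings::GENETIC_CODE
  aa <- character(0L)
  i <- 1L
  ter <- NA_integer_
  while (i + 2L <= nchar(tx)) {
    codon <- substr(tx, i, i + 2L)
    if (codon %in% STOP_CODONS) { ter <- (i - 1L) %/% 3L + 1L; break }
    aa <- c(aa, unname(code[codon]))
    i <- i + 3L
  }
  list(protein = paste(aa, collapse = ""), ter = ter)
}

#' Naive splice-and-translate oracle for two-exon mini-genes
#'
#' The generator's independent truth engine: enumerates the mutant
#' transcript by plain string operations (first \code{AG} of exon 2 within
#' the search window, delete everything up to and including it from the
#' transcript) and translates both transcripts with a loop translator.
#' Deliberately shares no code with \code{\link{splice_consequence}}.
#'
#' @param exon1,exon2 Exon sequences (CDS starts at base 1 of exon 1).
#' @param search_window Cryptic-acceptor scan limit.
#' @return List of truth fields: \code{type}, \code{deleted_count},
#'   \code{first_altered_codon}, \code{replaced_count}, \code{novel_count},
#'   \code{ter_codon}, \code{hgvs_p}, \code{mut_transcript}, plus both
#'   proteins; \code{type} is \code{"no_stop"} when either transcript
#'   lacks an in-frame stop (flagged fixture).
#' @export
naive_splice_truth <- function(exon1, exon2, search_window = 50L) {
  wt_tx <- paste0(exon1, exon2)
  region <- substr(exon2, 1L, search_window)
  p <- regexpr("AG", region, fixed = TRUE)
  if (p < 0L) {
    return(list(type = "no_cryptic_acceptor", wt_transcript = wt_tx))
  }
  del <- as.integer(p) + 1L
  mut_tx <- paste0(exon1, substr(exon2, del + 1L, nchar(exon2)))
  wt <- naive_translate(wt_tx)
  mut <- naive_translate(mut_tx)
  if (is.na(wt$ter) || is.na(mut$ter)) {
    return(list(type = "no_stop", deleted_count = del,
                wt_transcript = wt_tx, mut_transcript = mut_tx))
  }
  out <- list(deleted_count = del, wt_transcript = wt_tx,
              mut_transcript = mut_tx, wt_protein = wt$protein,
              mut_protein = mut$protein, ter_codon = mut$ter)
  if (del %% 3L == 0L) {
    out$type <- "inframe_deletion"
    return(out)
  }
  wt_c <- strsplit(wt$protein, "", fixed = TRUE)[[1L]]
  mut_c <- strsplit(mut$protein, "", fixed = TRUE)[[1L]]
  nmin <- min(length(wt_c), length(mut_c))
  first <- NA_integer_
  for (i in seq_len(nmin)) {
    if (wt_c[i] != mut_c[i]) { first <- i; break }
  }
  if (is.na(first)) {
    out$type <- "no_difference"
    return(out)
  }
  out$type <- "frameshift"
  out$first_altered_codon <- first
  out$replaced_count <- length(wt_c) - first + 1L
  out$novel_count <- length(mut_c) - first + 1L
  out$hgvs_p <- paste0("p.", ORACLE_AA3[[wt_c[first]]], first,
                       ORACLE_AA3[[mut_c[first]]], "fsTer",
                       out$novel_count + 1L)
  out
}

#' Simulate a randomized two-exon mini-gene with truth
#'
#' Exon 1 is \code{ATG} plus random sense codons (optionally plus a partial
#' codon so the junction need not fall on a codon boundary); exon 2's start
#' is controlled by \code{mode}: \code{"ag_initial"} reproduces the
#' final-exon configuration whose first two coding bases are \code{AG}
#' (cryptic offset 0, 2 nt deleted), \code{"inframe"} places the first
#' \code{AG} at offset 1 (3 nt deleted, no frameshift), \code{"random"}
#' leaves it unconstrained.  A stop-in-every-frame cassette near the exon-2
#' end guarantees both transcripts terminate.  Truth comes from
#' \code{\link{naive_splice_truth}}.
#'
#' @param seed Top-level seed.
#' @param mode Exon-2 composition control.
#' @param exon1_codons Number of sense codons after the initiator.
#' @param exon2_len Random exon-2 core length in nt.
#' @param partial Extra 5' bases of exon 1 beyond a codon boundary (0-2).
#' @return As \code{\link{minigene_fixture}}.
#' @export
simulate_minigene <- function(seed = 1L,
                              mode = c("ag_initial", "inframe", "random"),
                              exon1_codons = 4L, exon2_len = 45L,
                              partial = NULL) {
  mode <- match.arg(mode)
  with_derived_seed(seed, paste0("minigene_", mode), {
    sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    if (is.null(partial)) partial <- sample(0:2, 1L)
    exon1 <- paste0("ATG", paste(sample(sense, exon1_codons, replace = TRUE),
                                 collapse = ""),
                    substr(random_dna(2L), 1L, partial))
    core <- random_dna(exon2_len)
    head <- switch(mode,
      ag_initial = "AG",
      inframe = paste0(sample(c("C", "G", "T"), 1L), "AG"),
      random = "")
    exon2 <- paste0(head, core, "TAAATAAATAAA", random_dna(6L))
    intron <- paste0("GT", random_dna(18L), "AG")
    build_minigene(exon1, intron, exon2,
                   gene_id = sprintf("minigene_seed%d", seed))
  })
}

# ---- full-scale surrogate locus -------------------------------------------

#' Synthetic full-scale splice-acceptor locus (surrogate, 854-aa wild type)
#'
#' Constructs, fully synthetically, a 13-exon gene model reproducing the
#' structural configuration of a final-exon acceptor mutation in a gene
#' with an 854-residue product: the last intron ends in the canonical
#' \code{AG}; the final exon begins \code{AG} (its first two coding bases);
#' the first base of the final exon is coding position 2432; codon 811
#' (\code{GAG}, Glu) spans the junction.  The sequence is engineered so
#' that the wild-type frame terminates after codon 854 and, after the 2-nt
#' cryptic-acceptor deletion, the shifted frame reads 77 novel residues
#' before a stop at codon 888 in the 3'UTR -- i.e. the expected consequence
#' of \code{c.2432-1G>C} is \code{p.Glu811GlyfsTer78}.  The construction is
#' verified internally against the naive oracle.
#'
#' @param seed Top-level seed.
#' @return List: \code{model}, \code{genome}, \code{variant}
#'   (\code{"c.2432-1G>C"}), \code{truth}.
#' @export
simulate_heatr2_like_locus <- function(seed = 1L) {
  with_derived_seed(seed, "heatr2_like", {
    utr5 <- 30L; wt_aa <- 854L
    coding_len <- (wt_aa + 1L) * 3L            # 2565, stop included
    first_alt <- 811L; novel <- 77L
    junction <- (first_alt - 1L) * 3L + 1L     # coding pos of codon 811 = 2431
    mut_stop_start <- junction + 2L + novel * 3L  # 2664 in coding coords
    total <- mut_stop_start + 2L + 49L         # coding region + 3'UTR tail
    sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    cv <- character(total)
    head_codons <- c("ATG", sample(sense, first_alt - 2L, replace = TRUE), "GAG")
    cv[seq_len(junction + 2L)] <- strsplit(paste(head_codons, collapse = ""),
                                           "", fixed = TRUE)[[1L]]
    forced <- c("2434" = "G",
                stats::setNames(c("T", "A", "A"),
                                (coding_len - 2L):coding_len),
                stats::setNames(c("T", "A", "A"),
                                mut_stop_start:(mut_stop_start + 2L)))
    wt_ends <- seq(junction + 5L, coding_len - 3L, by = 3L)       # codons 812..854
    mut_ends <- seq(junction + 7L, mut_stop_start - 1L, by = 3L)  # shifted 812..887
    for (p in (junction + 3L):total) {
      cv[p] <- if (!is.na(forced[as.character(p)])) forced[[as.character(p)]]
               else sample(c("A", "C", "G", "T"), 1L)
      for (frame_end in list(wt_ends, mut_ends)) {
        if (p %in% frame_end) {
          while (paste(cv[(p - 2L):p], collapse = "") %in% STOP_CODONS) {
            stopifnot(is.na(forced[as.character(p)]))
            cv[p] <- sample(c("A", "C", "G", "T"), 1L)
          }
        }
      }
    }
    transcript <- paste0(random_dna(utr5), paste(cv, collapse = ""))
    # exon 13 starts at coding position junction + 1 (= 2432), i.e. 0-based
    # transcript offset utr5 + junction; exon 12 ends with codon 811's G
    exon13_tx <- utr5 + junction
    cuts <- round(seq(0L, exon13_tx, length.out = 13L))
    tx_bounds <- cbind(start = c(cuts[-13L], exon13_tx),
                       end = c(cuts[-1L], nchar(transcript)))
    introns <- replicate(12L, paste0("GT", random_dna(81L), "AG"))
    pieces <- substring(transcript, tx_bounds[, "start"] + 1L, tx_bounds[, "end"])
    genome <- pieces[1L]
    exons <- matrix(0L, nrow = 13L, ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    exons[1L, ] <- c(0L, nchar(pieces[1L]))
    for (i in 2:13) {
      gstart <- exons[i - 1L, "end"] + nchar(introns[i - 1L])
      exons[i, ] <- c(gstart, gstart + nchar(pieces[i]))
      genome <- paste0(genome, introns[i - 1L], pieces[i])
    }
    model <- gene_model("surrogate_locus", exons, strand = "+",
                        cds_start = utr5, cds_end = utr5 + coding_len,
                        anchor = "TSS")
    # independent verification of the engineered truth; the oracle
    # translates from base 1, so feed it the coding part only
    check <- naive_splice_truth(
      substr(transcript, utr5 + 1L, exon13_tx),
      substring(transcript, exon13_tx + 1L))
    stopifnot(identical(check$type, "frameshift"),
              check$deleted_count == 2L,
              check$first_altered_codon == first_alt,
              check$replaced_count == wt_aa - first_alt + 1L,
              check$novel_count == novel,
              check$ter_codon == first_alt + novel,
              identical(check$hgvs_p,
                        sprintf("p.Glu%dGlyfsTer%d", first_alt, novel + 1L)))
    list(model = model, genome = dna_seq(genome, id = "surrogate_locus"),
         variant = "c.2432-1G>C",
         truth = list(type = "frameshift", deleted_count = 2L,
                      first_altered_codon = first_alt,
                      replaced_count = wt_aa - first_alt + 1L,
                      novel_count = novel, ter_codon = first_alt + novel,
                      fs_ter_ordinal = novel + 1L,
                      hgvs_p = sprintf("p.Glu%dGlyfsTer%d", first_alt, novel + 1L),
                      hgvs_c_effect = "c.2432-2433delAG",
                      wt_length = wt_aa))
  })
}

# ---- proteomes -------------------------------------------------------------

#' Random protein sequence
#'
#' @param n Length.
#' @return Residue string (uniform over the 20 amino acids).
#' @export
random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Simulate proteomes with a planted orthologue presence pattern
#'
#' Reference proteins are random sequences; a species that carries a gene
#' receives a per-site-diverged copy, a species that lacks it receives an
#' unrelated random sequence of the same length in its place, and every
#' proteome gains unrelated decoys.
#'
#' @param pattern Logical species x gene matrix (dimnames required):
#'   \code{TRUE} where the orthologue is present.
#' @param divergence Per-site substitution rate for present orthologues.
#' @param n_decoys Unrelated decoy proteins per proteome.
#' @param protein_len Protein length.
#' @param seed Top-level seed.
#' @return List: \code{reference} (named vector of query sequences),
#'   \code{proteomes} (list of \code{\link{proteome}}), \code{truth}
#'   (the pattern).
#' @export
simulate_proteomes <- function(pattern, divergence = 0.05, n_decoys = 3L,
                               protein_len = 120L, seed = 1L) {
  stopifnot(is.matrix(pattern), is.logical(pattern),
            !is.null(rownames(pattern)), !is.null(colnames(pattern)))
  with_derived_seed(seed, "proteomes", {
    genes <- colnames(pattern)
    reference <- stats::setNames(
      vapply(genes, function(g) random_protein(protein_len), character(1L)),
      genes)
    proteomes <- lapply(rownames(pattern), function(sp) {
      seqs <- character(0L)
      for (g in genes) {
        if (pattern[sp, g]) {
          seqs[paste0(g, "_", sp)] <-
            diverge_sequence(reference[[g]], divergence, alphabet = AA_ALPHABET)
        } else {
          seqs[paste0("unrelated_", g, "_", sp)] <- random_protein(protein_len)
        }
      }
      for (i in seq_len(n_decoys)) {
        seqs[paste0("decoy", i, "_", sp)] <- random_protein(protein_len)
      }
      proteome(sp, seqs)
    })
    list(reference = reference, proteomes = proteomes, truth = pattern)
  })
}

#' Simulate doublet-scoring counts
#'
#' Binomial draws of visible-dynein-arm counts for a control and a
#' knock-down group at the stated numbers of scored axonemal microtubule
#' doublets.
#'
#' @param p_control,p_kd Per-doublet visibility probabilities.
#' @param n_control,n_kd Doublets scored (defaults 63 and 126).
#' @param seed Top-level seed.
#' @return 2x2 integer matrix (rows control/knockdown, columns
#'   visible/not_visible).
#' @export
simulate_doublet_counts <- function(p_control, p_kd, n_control = 63L,
                                    n_kd = 126L, seed = 1L) {
  stopifnot(p_control >= 0, p_control <= 1, p_kd >= 0, p_kd <= 1)
  with_derived_seed(seed, "doublets", {
    k1 <- rbinom(1L, n_control, p_control)
    k2 <- rbinom(1L, n_kd, p_kd)
    matrix(c(k1, n_control - k1, k2, n_kd - k2), nrow = 2L, byrow = TRUE,
           dimnames = list(group = c("control", "knockdown"),
                           arm = c("visible", "not_visible")))
  })
}
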