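# Reciprocal-best-hit orthology over proteome sets, and presence/absence
# matrices for gene/marker co-conservation.  The desk-scale aligner is
# exact local alignment with BLOSUM62 and affine gaps (open 11 / extend 1,
# the BLASTP operating point); heuristic search tools rank by the same
# score on this scale.

#' Proteome
#'
#' @param species Species label.
#' @param sequences Named character vector of protein sequences (unique,
#'   non-empty ids).
#' @return An object of class \code{proteome}.
#' @export
proteome <- function(species, sequences) {
  if (length(sequences) == 0L) stop("empty proteome")
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids)) {
    stop("sequences must have unique non-empty ids")
  }
  structure(list(species = as.character(species),
                 sequences = toupper(sequences)),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s: %d protein(s)\n", x$species, length(x$sequences)))
  invisible(x)
}

#' Read a proteome from protein FASTA
#'
#' @param path FASTA path.
#' @param species Species label (default: file stem).
#' @return A \code{\link{proteome}}.
#' @export
read_proteome <- function(path, species = NULL) {
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  proteome(species, read_fasta(path, type = "protein"))
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise protein alignment
#'
#' Local (Smith-Waterman) alignment under a substitution matrix with affine
#' gaps; a gap of length L costs \code{gap_open + L * gap_extend}.
#' Identity is identical aligned pairs over aligned columns (internal gaps
#' included).
#'
#' @param a,b Protein sequences (strings or \code{protein_seq}).
#' @param gap_open,gap_extend Affine gap parameters (default 11 / 1).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param type \code{"local"} or \code{"global"}.
#' @return List: \code{score}, \code{pid} (percent identity in [0, 100]).
#' @export
pairwise_align_protein <- function(a, b, gap_open = 11, gap_extend = 1,
                                   matrix = NULL, type = c("local", "global")) {
  type <- match.arg(type)
  a <- as_protein_string(a); b <- as_protein_string(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  list(score = Biostrings::score(al), pid = Biostrings::pid(al, type = "PID1"))
}

#' Percent identity to a reference sequence
#'
#' Global pairwise alignment identity -- a pairwise substitute for
#' identities read off multiple alignments, and flagged as such in report
#' headers.
#'
#' @param a,b Protein sequences.
#' @inheritParams pairwise_align_protein
#' @return Percent identity in [0, 100].
#' @export
percent_identity_global <- function(a, b, gap_open = 11, gap_extend = 1) {
  pairwise_align_protein(a, b, gap_open, gap_extend, type = "global")$pid
}

# best-scoring record of a proteome against one query; ties broken by
# lexicographic id and flagged ambiguous
best_hit <- function(query_seq, prot, gap_open, gap_extend) {
  scores <- vapply(prot$sequences, function(s)
    pairwise_align_protein(query_seq, s, gap_open, gap_extend)$score,
    numeric(1L))
  top <- max(scores)
  ids <- sort(names(scores)[scores == top])
  list(id = ids[1L], score = top, ambiguous = length(ids) > 1L)
}

#' Reciprocal best hit
#'
#' The query's best local-alignment hit in the target proteome is accepted
#' as a reciprocal orthologue call iff the reverse search of that hit
#' against the source proteome returns the query as its own best hit, and
#' the forward score reaches \code{min_score}.
#'
#' @param query_id Id of the query within \code{source}.
#' @param source,target \code{\link{proteome}} objects.
#' @param min_score Minimum forward score (no published default; configure
#'   per dataset).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return One-row data frame: \code{query}, \code{species}, \code{hit},
#'   \code{forward_score}, \code{reverse_score}, \code{reciprocal},
#'   \code{ambiguous}, \code{pid} (global percent identity query vs hit).
#' @export
reciprocal_best_hit <- function(query_id, source, target, min_score = 0,
                                gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(source, "proteome"), inherits(target, "proteome"))
  if (!query_id %in% names(source$sequences)) {
    stop("query '", query_id, "' is not in the source proteome")
  }
  query_seq <- source$sequences[[query_id]]
  absent <- data.frame(query = query_id, species = target$species,
                       hit = NA_character_, forward_score = NA_real_,
                       reverse_score = NA_real_, reciprocal = FALSE,
                       ambiguous = FALSE, pid = NA_real_,
                       stringsAsFactors = FALSE)
  if (length(target$sequences) == 0L) return(absent)
  fwd <- best_hit(query_seq, target, gap_open, gap_extend)
  if (fwd$score < min_score) {
    absent$forward_score <- fwd$score
    return(absent)
  }
  rev <- best_hit(target$sequences[[fwd$id]], source, gap_open, gap_extend)
  data.frame(query = query_id, species = target$species, hit = fwd$id,
             forward_score = fwd$score, reverse_score = rev$score,
             reciprocal = identical(rev$id, query_id),
             ambiguous = fwd$ambiguous || rev$ambiguous,
             pid = percent_identity_global(query_seq,
                                           target$sequences[[fwd$id]],
                                           gap_open, gap_extend),
             stringsAsFactors = FALSE)
}

#' Default dynein-arm marker categories
#'
#' Outer-arm (ODA) markers DNAH9, DNAH5, DNAL1 and inner-arm (IDA) markers
#' DNAH3, DNAH1, DNAH2.
#'
#' @return Named list of character vectors.
#' @export
default_marker_categories <- function() {
  list(ODA = c("DNAH9", "DNAH5", "DNAL1"),
       IDA = c("DNAH3", "DNAH1", "DNAH2"))
}

#' Build a presence/absence matrix across proteomes
#'
#' Calls every query against every proteome by reciprocal best hit.  Gene
#' columns are \code{full} (reciprocal call) or \code{absent}; each
#' category column is \code{full} when all member genes are present,
#' \code{half} when at least one but not all are, and \code{absent} when
#' none is.
#'
#' @param reference Named character vector of query protein sequences
#'   (genes and category members).
#' @param categories Named list mapping category to member gene ids
#'   (default \code{\link{default_marker_categories}()}).
#' @param proteomes List of \code{\link{proteome}} objects.
#' @param min_score Minimum forward score for a call.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return An object of class \code{presence_matrix}: \code{matrix}
#'   (species x columns, tokens \code{full}/\code{half}/\code{absent}),
#'   \code{gene_calls} (logical species x gene), \code{details} (all RBH
#'   rows), \code{categories}.
#' @export
build_presence_matrix <- function(reference, categories = default_marker_categories(),
                                  proteomes, min_score = 0,
                                  gap_open = 11, gap_extend = 1) {
  genes <- names(reference)
  if (is.null(genes) || any(genes == "")) stop("reference queries must be named")
  unknown <- setdiff(unlist(categories), genes)
  if (length(unknown) > 0L) {
    stop("category member(s) missing from the reference set: ",
         paste(unknown, collapse = ", "))
  }
  src <- proteome("reference", reference)
  species <- vapply(proteomes, function(p) p$species, character(1L))
  details <- list()
  calls <- matrix(FALSE, nrow = length(proteomes), ncol = length(genes),
                  dimnames = list(species, genes))
  for (i in seq_along(proteomes)) {
    for (gid in genes) {
      rbh <- reciprocal_best_hit(gid, src, proteomes[[i]], min_score,
                                 gap_open, gap_extend)
      calls[i, gid] <- rbh$reciprocal
      details[[length(details) + 1L]] <- rbh
    }
  }
  cols <- c(genes, names(categories))
  mat <- matrix("absent", nrow = length(proteomes), ncol = length(cols),
                dimnames = list(species, cols))
  mat[, genes] <- ifelse(calls, "full", "absent")
  for (cat_name in names(categories)) {
    members <- categories[[cat_name]]
    n_present <- rowSums(calls[, members, drop = FALSE])
    mat[, cat_name] <- ifelse(n_present == length(members), "full",
                              ifelse(n_present > 0L, "half", "absent"))
  }
  structure(list(matrix = mat, gene_calls = calls,
                 details = do.call(rbind, details), categories = categories),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d species x %d column(s)\n",
              nrow(x$matrix), ncol(x$matrix)))
  print(x$matrix, quote = FALSE)
  invisible(x)
}

#' Gene/category co-conservation concordance
#'
#' Fraction of species where gene presence (\code{full}) agrees with
#' category presence (\code{full} or \code{half}: evidence for at least one
#' member orthologue), with a two-sided Fisher exact p on the 2x2 presence
#' table.  A single-valued column yields a degenerate table whose only
#' arrangement has probability 1, so p = 1.
#'
#' @param pm A \code{\link{presence_matrix}}.
#' @param gene_column Gene column name.
#' @param category_column Category column name.
#' @return List: \code{fraction}, \code{p_value}, \code{table} (2x2 counts).
#' @export
coconservation_concordance <- function(pm, gene_column, category_column) {
  stopifnot(inherits(pm, "presence_matrix"))
  m <- pm$matrix
  if (nrow(m) < 2L) stop("at least two species are required")
  if (!gene_column %in% colnames(m)) stop("unknown gene column: ", gene_column)
  if (!category_column %in% colnames(m)) stop("unknown category column: ", category_column)
  g <- m[, gene_column] == "full"
  k <- m[, category_column] %in% c("full", "half")
  tab <- matrix(c(sum(g & k), sum(g & !k), sum(!g & k), sum(!g & !k)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(gene = c("present", "absent"),
                                category = c("present", "absent")))
  list(fraction = mean(g == k), p_value = fisher_exact_2x2(tab), table = tab)
}
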