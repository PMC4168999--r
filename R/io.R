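# File I/O: FASTA via Biostrings, GFF3 via rtracklayer, JSON gene models
# via jsonlite, tabular output as TSV with a commented header line.

#' Read a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @param type \code{"dna"} or \code{"protein"}.
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  out
}

#' Write a FASTA file (60-column wrap)
#'
#' @param seqs Named character vector, or a list of \code{dna_seq} /
#'   \code{protein_seq} objects.
#' @param path Output path.
#' @param type \code{"dna"} or \code{"protein"}.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(s) s$id, character(1L))
    seqs <- vapply(seqs, function(s) s$residues, character(1L))
    names(seqs) <- nm
  }
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Reads exon and CDS features of a single mRNA from a GFF3 file (1-based
#' inclusive coordinates, converted to the package's 0-based half-open
#' convention on ingest).  Only \code{gene}, \code{mRNA}/\code{transcript},
#' \code{exon} and \code{CDS} features are consulted.
#'
#' @param path GFF3 file describing one transcript.
#' @param gene_id Optional label; defaults to the mRNA ID (or file stem).
#' @param anchor \code{"TSS"} or \code{"ATG"}.
#' @return A \code{\link{gene_model}}.
#' @export
read_gene_model_gff3 <- function(path, gene_id = NULL, anchor = "TSS") {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  keep <- type %in% c("gene", "mRNA", "transcript", "exon", "CDS")
  gff <- gff[keep]
  type <- type[keep]
  exons <- gff[type == "exon"]
  cds <- gff[type == "CDS"]
  if (length(exons) == 0L) stop("no exon features in ", path)
  if (length(cds) == 0L) stop("no CDS features in ", path)
  strand <- unique(as.character(BiocGenerics::strand(exons)))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    stop("exons must share a single +/- strand")
  }
  ex <- cbind(start = BiocGenerics::start(exons) - 1L, end = BiocGenerics::end(exons))
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  cds_g <- c(min(BiocGenerics::start(cds)) - 1L, max(BiocGenerics::end(cds)))
  if (is.null(gene_id)) {
    mrna <- gff[type %in% c("mRNA", "transcript")]
    gene_id <- if (length(mrna) > 0L && !is.null(mrna$ID) && !is.na(mrna$ID[1L])) {
      as.character(mrna$ID[1L])
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  # map the genomic CDS bounds onto transcript offsets
  tx <- genomic_to_transcript(ex, strand, c(cds_g[1L], cds_g[2L] - 1L))
  cds_start <- min(tx); cds_end <- max(tx) + 1L
  gene_model(gene_id, ex, strand = strand, cds_start = cds_start,
             cds_end = cds_end, anchor = anchor)
}

# Map genomic 0-based positions (base coordinates, not interval ends) to
# 0-based transcript offsets for an exon matrix in ascending genomic order.
genomic_to_transcript <- function(exons, strand, gpos) {
  lens <- exons[, "end"] - exons[, "start"]
  vapply(gpos, function(g) {
    k <- which(g >= exons[, "start"] & g < exons[, "end"])
    if (length(k) != 1L) stop("genomic position ", g, " is not exonic")
    if (strand == "+") {
      sum(lens[seq_len(k - 1L)]) + (g - exons[k, "start"])
    } else {
      nk <- nrow(exons)
      after <- if (k < nk) sum(lens[(k + 1L):nk]) else 0L
      after + (exons[k, "end"] - 1L - g)
    }
  }, integer(1L))
}

#' Read a gene model from JSON
#'
#' The JSON schema is: \code{\{"gene_id": str, "strand": "+"|"-",
#' "anchor": "TSS"|"ATG", "exons": [[start, end], ...],
#' "cds_start": int, "cds_end": int\}} with 0-based half-open genomic exon
#' intervals and 0-based transcript-offset CDS bounds.
#'
#' @param path JSON file.
#' @return A \code{\link{gene_model}}.
#' @export
read_gene_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- x$exons
  if (!is.matrix(ex)) ex <- do.call(rbind, lapply(ex, as.integer))
  gene_model(x$gene_id, ex,
             strand = x$strand, cds_start = x$cds_start, cds_end = x$cds_end,
             anchor = if (is.null(x$anchor)) "TSS" else x$anchor)
}

#' Write a gene model as JSON
#'
#' @param model A \code{\link{gene_model}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_model_json <- function(model, path) {
  x <- list(gene_id = model$gene_id, strand = model$strand, anchor = model$anchor,
            exons = lapply(seq_len(nrow(model$exons)),
                           function(i) as.integer(model$exons[i, ])),
            cds_start = model$cds_start, cds_end = model$cds_end)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a data frame as TSV with a commented header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comment Optional comment lines placed above the header.
#' @return \code{path}, invisibly.
#' @export
write_tsv_commented <- function(df, path, comment = character(0L)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a commented-header TSV written by this package
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tsv_commented <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  if (length(hdr) == 0L) stop("no commented header in ", path)
  cols <- strsplit(sub("^# ", "", hdr[length(hdr)]), "\t", fixed = TRUE)[[1L]]
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
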