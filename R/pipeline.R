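# Command-line style entry point wiring the analyses together.  Subcommands:
# fingerprint, conserve, splice, profile, stats, simulate.  Results go to
# files (TSV/JSON/FASTA); logging goes to stderr; every output directory
# receives a JSON provenance block (hashed inputs, parameters, seed,
# package version).  On error, partial outputs are removed.

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

# minimal --key value / --flag parser; unknown keys are rejected upstream
parse_cli_args <- function(argv) {
  out <- list(positional = character(0L))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(argv) && !startsWith(argv[[i + 1L]], "--")) {
        vals <- character(0L)
        j <- i + 1L
        while (j <= length(argv) && !startsWith(argv[[j]], "--")) {
          vals <- c(vals, argv[[j]])
          j <- j + 1L
        }
        out[[key]] <- vals
        i <- j
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

require_opt <- function(opts, keys, subcommand) {
  missing <- keys[!keys %in% names(opts)]
  if (length(missing) > 0L) {
    stop("missing required option(s) for '", subcommand, "': ",
         paste0("--", missing, collapse = ", "), call. = FALSE)
  }
}

check_known <- function(opts, known, subcommand) {
  unknown <- setdiff(setdiff(names(opts), "positional"), known)
  if (length(unknown) > 0L) {
    stop("unknown option(s) for '", subcommand, "': ",
         paste0("--", unknown, collapse = ", "), call. = FALSE)
  }
}

write_provenance <- function(outdir, subcommand, inputs, params, seed = NA) {
  prov <- list(tool = "ciliaprint",
               version = as.character(packageVersion("ciliaprint")),
               subcommand = subcommand,
               inputs = lapply(inputs, function(p)
                 list(path = p, md5 = unname(tools::md5sum(p)))),
               parameters = params, seed = seed)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline subcommand
#'
#' Subcommands: \code{fingerprint} (motif scan of promoter FASTA),
#' \code{conserve} (cross-species conservation table), \code{splice}
#' (acceptor-variant consequence report), \code{profile} (RBH
#' presence/absence matrix), \code{stats} (Fisher / power), and
#' \code{simulate} (seeded synthetic fixtures with truth).  Options follow
#' \code{--key value} syntax; unknown options are rejected; results are
#' written under \code{--out} together with a JSON provenance block.
#' Partial outputs are removed on error.
#'
#' @param argv Character vector: subcommand followed by its options, e.g.
#'   \code{c("stats", "--fisher", "61", "2", "8", "118", "--out", "res")}.
#' @return Invisibly, a list of the paths written.
#' @export
run_pipeline <- function(argv) {
  if (length(argv) == 0L) {
    stop("usage: ciliaprint <fingerprint|conserve|splice|profile|stats|simulate> [options]",
         call. = FALSE)
  }
  subcommand <- argv[[1L]]
  opts <- parse_cli_args(argv[-1L])
  outdir <- if (!is.null(opts$out)) opts$out else "."
  created <- !dir.exists(outdir)
  if (created) dir.create(outdir, recursive = TRUE)
  written <- character(0L)
  note <- function(p) { written <<- c(written, p); p }
  ok <- FALSE
  on.exit({
    if (!ok) {
      for (p in written) unlink(p)
      if (created) unlink(outdir, recursive = TRUE)
      log_msg("ERROR", "run failed; partial outputs removed")
    }
  })
  out <- switch(subcommand,
    fingerprint = cli_fingerprint(opts, outdir, note),
    conserve = cli_conserve(opts, outdir, note),
    splice = cli_splice(opts, outdir, note),
    profile = cli_profile(opts, outdir, note),
    stats = cli_stats(opts, outdir, note),
    simulate = cli_simulate(opts, outdir, note),
    stop("unknown subcommand: ", subcommand, call. = FALSE))
  ok <- TRUE
  log_msg("INFO", "wrote ", length(written), " file(s) to ", outdir)
  invisible(written)
}

opt1 <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) default else opts[[key]][[1L]]
}

cli_fingerprint <- function(opts, outdir, note) {
  check_known(opts, c("fasta", "window", "anchor", "xbox-form", "max-mm5", "out"),
              "fingerprint")
  require_opt(opts, "fasta", "fingerprint")
  window <- as.integer(opt1(opts, "window", "500"))
  motifs <- default_motif_set(xbox_form = opt1(opts, "xbox-form", "RYYRYY"))
  max_mm5 <- as.integer(opt1(opts, "max-mm5", "2"))
  set <- read_promoter_set(opt1(opts, "fasta"))
  ct <- build_conservation_table(set, motifs = motifs, window = window,
                                 max_mm5 = max_mm5)
  hits <- list()
  for (sp in names(ct$calls)) {
    call <- ct$calls[[sp]]
    for (h in list(call$xbox_hits, call$fox_hits)) {
      if (!is.null(h)) {
        h$species <- sp
        if (is.null(h$xbox_class)) h$xbox_class <- NA_character_
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  hit_df <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(species = character(0L), motif = character(0L))
  note(write_tsv_commented(hit_df, file.path(outdir, "fingerprint_hits.tsv"),
                           comment = sprintf("window=%d anchor-relative offsets", window)))
  verdicts <- lapply(ct$calls, function(call)
    list(verdict = call$verdict,
         nearest_fox_distance = call$nearest_fox_distance,
         xbox_separations = call$xbox_separations))
  jsonlite::write_json(verdicts, note(file.path(outdir, "fingerprint_calls.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(outdir, "fingerprint", opt1(opts, "fasta"),
                   list(window = window, max_mm5 = max_mm5))
  note(file.path(outdir, "provenance.json"))
}

cli_conserve <- function(opts, outdir, note) {
  check_known(opts, c("fasta", "window", "xbox-form", "max-mm5", "out"), "conserve")
  require_opt(opts, "fasta", "conserve")
  window <- as.integer(opt1(opts, "window", "500"))
  motifs <- default_motif_set(xbox_form = opt1(opts, "xbox-form", "RYYRYY"))
  set <- read_promoter_set(opt1(opts, "fasta"))
  ct <- build_conservation_table(set, motifs = motifs, window = window,
                                 max_mm5 = as.integer(opt1(opts, "max-mm5", "2")))
  note(write_conservation_tsv(ct, file.path(outdir, "conservation.tsv")))
  jsonlite::write_json(as.list(ct$fractions),
                       note(file.path(outdir, "conservation_fractions.json")),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(outdir, "conserve", opt1(opts, "fasta"),
                   list(window = window))
  note(file.path(outdir, "provenance.json"))
}

cli_splice <- function(opts, outdir, note) {
  check_known(opts, c("model", "genome", "variant", "search-window",
                      "emit-fasta", "out"), "splice")
  require_opt(opts, c("model", "genome", "variant"), "splice")
  model_path <- opt1(opts, "model")
  model <- if (grepl("\\.json$", model_path)) read_gene_model_json(model_path)
           else read_gene_model_gff3(model_path)
  genome <- read_fasta(opt1(opts, "genome"))[[1L]]
  cons <- splice_consequence(model, genome, opt1(opts, "variant"),
                             search_window = as.integer(opt1(opts, "search-window", "50")))
  rec <- splice_consequence_record(cons, sequences = FALSE)
  jsonlite::write_json(rec, note(file.path(outdir, "splice_consequence.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note(write_tsv_commented(as.data.frame(rec),
                           file.path(outdir, "splice_consequence.tsv")))
  if (isTRUE(opts[["emit-fasta"]]) && !is.null(cons$mut_transcript)) {
    seqs <- c(stats::setNames(cons$mut_transcript,
                              paste0(cons$gene_id, "_mut_transcript")))
    note(write_fasta(seqs, file.path(outdir, "mutant_transcript.fasta")))
    if (!is.null(cons$mut_protein)) {
      note(write_fasta(stats::setNames(cons$mut_protein,
                                       paste0(cons$gene_id, "_mut_protein")),
                       file.path(outdir, "mutant_protein.fasta"),
                       type = "protein"))
    }
  }
  write_provenance(outdir, "splice",
                   c(model_path, opt1(opts, "genome")),
                   list(variant = opt1(opts, "variant")))
  note(file.path(outdir, "provenance.json"))
}

cli_profile <- function(opts, outdir, note) {
  check_known(opts, c("reference", "proteome", "categories", "min-score", "out"),
              "profile")
  require_opt(opts, c("reference", "proteome"), "profile")
  reference <- read_fasta(opt1(opts, "reference"), type = "protein")
  proteomes <- lapply(opts$proteome, read_proteome)
  categories <- if (!is.null(opts$categories)) {
    yaml::read_yaml(opt1(opts, "categories"))
  } else default_marker_categories()
  pm <- build_presence_matrix(reference, categories, proteomes,
                              min_score = as.numeric(opt1(opts, "min-score", "0")))
  df <- data.frame(species = rownames(pm$matrix), pm$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  note(write_tsv_commented(df, file.path(outdir, "presence_matrix.tsv"),
    comment = "percent identities computed by pairwise global alignment (not multiple alignment)"))
  jsonlite::write_json(list(matrix = as.data.frame(pm$matrix),
                            details = pm$details),
                       note(file.path(outdir, "presence_matrix.json")),
                       pretty = TRUE, digits = NA)
  write_provenance(outdir, "profile",
                   c(opt1(opts, "reference"), unlist(opts$proteome)),
                   list(min_score = as.numeric(opt1(opts, "min-score", "0"))))
  note(file.path(outdir, "provenance.json"))
}

cli_stats <- function(opts, outdir, note) {
  check_known(opts, c("fisher", "fisher-pct", "power", "out"), "stats")
  res <- list()
  if (!is.null(opts$fisher)) {
    cts <- as.integer(opts$fisher)
    if (length(cts) != 4L) stop("--fisher needs four counts", call. = FALSE)
    res$fisher <- list(counts = cts,
                       p_value = fisher_exact_2x2(cts[1L], cts[2L], cts[3L], cts[4L]))
  }
  if (!is.null(opts[["fisher-pct"]])) {
    v <- opts[["fisher-pct"]]
    if (length(v) != 4L) stop("--fisher-pct needs pct1 pct2 n1 n2", call. = FALSE)
    n1 <- as.integer(v[3L]); n2 <- as.integer(v[4L])
    c1 <- counts_from_percent(v[1L], n1)
    c2 <- counts_from_percent(v[2L], n2)
    res$fisher_pct <- list(
      counts = c(c1$count, n1 - c1$count, c2$count, n2 - c2$count),
      consistent = c(c1$consistent, c2$consistent),
      p_value = fisher_exact_2x2(c1$count, n1 - c1$count,
                                 c2$count, n2 - c2$count))
  }
  if (!is.null(opts$power)) {
    v <- as.numeric(opts$power)
    if (length(v) != 2L) stop("--power needs q n_chr", call. = FALSE)
    res$power <- list(q = v[1L], n_chr = as.integer(v[2L]),
                      power = exclusion_power(v[1L], v[2L]))
  }
  if (length(res) == 0L) {
    stop("stats requires at least one of --fisher, --fisher-pct, --power",
         call. = FALSE)
  }
  jsonlite::write_json(res, note(file.path(outdir, "stats.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rows <- do.call(rbind, lapply(names(res), function(nm) {
    data.frame(analysis = nm,
               value = if (nm == "power") res[[nm]]$power else res[[nm]]$p_value)
  }))
  note(write_tsv_commented(rows, file.path(outdir, "stats.tsv")))
  write_provenance(outdir, "stats", character(0L), res)
  note(file.path(outdir, "provenance.json"))
}

cli_simulate <- function(opts, outdir, note) {
  check_known(opts, c("what", "seed", "n-species", "length", "divergence",
                      "mode", "p-control", "p-kd", "out"), "simulate")
  require_opt(opts, "what", "simulate")
  seed <- as.integer(opt1(opts, "seed", "1"))
  what <- opt1(opts, "what")
  manifest <- list(what = what, seed = seed)
  if (what == "promoters") {
    sim <- simulate_promoter_set(
      n_species = as.integer(opt1(opts, "n-species", "6")),
      length = as.integer(opt1(opts, "length", "500")),
      divergence = as.numeric(opt1(opts, "divergence", "0")),
      seed = seed)
    seqs <- vapply(sim$set, function(e) e$seq, character(1L))
    note(write_fasta(seqs, file.path(outdir, "promoters.fasta")))
    note(write_tsv_commented(sim$truth, file.path(outdir, "promoters_truth.tsv")))
    manifest$files <- c("promoters.fasta", "promoters_truth.tsv")
  } else if (what == "minigene") {
    sim <- simulate_minigene(seed = seed, mode = opt1(opts, "mode", "ag_initial"))
    note(write_fasta(stats::setNames(sim$genome$residues, sim$model$gene_id),
                     file.path(outdir, "minigene.fasta")))
    note(write_gene_model_json(sim$model, file.path(outdir, "minigene_model.json")))
    jsonlite::write_json(c(list(variant = sim$variant), sim$truth),
                         note(file.path(outdir, "minigene_truth.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$files <- c("minigene.fasta", "minigene_model.json",
                        "minigene_truth.json")
  } else if (what == "counts") {
    tab <- simulate_doublet_counts(
      p_control = as.numeric(opt1(opts, "p-control", "0.97")),
      p_kd = as.numeric(opt1(opts, "p-kd", "0.063")),
      seed = seed)
    df <- data.frame(group = rownames(tab), visible = tab[, 1L],
                     not_visible = tab[, 2L])
    note(write_tsv_commented(df, file.path(outdir, "doublet_counts.tsv")))
    manifest$files <- "doublet_counts.tsv"
  } else {
    stop("unknown --what: ", what,
         " (expected promoters, minigene or counts)", call. = FALSE)
  }
  jsonlite::write_json(manifest, note(file.path(outdir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(outdir, "simulate", character(0L), manifest, seed = seed)
  note(file.path(outdir, "provenance.json"))
}
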