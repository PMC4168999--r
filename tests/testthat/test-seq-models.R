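test_that("reverse complement is correct, involutive, and agrees with Biostrings", {
  expect_equal(reverse_complement("GTTGCCATGGCAAC"), "GTTGCCATGGCAAC")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGU"), "illegal")
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna_string(sample(0:80, 1L), with_n = TRUE)
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("gene models enforce exon ordering and CDS bounds", {
  expect_error(gene_model("g", rbind(c(0, 10), c(5, 20)), cds_start = 0,
                          cds_end = 10), "overlap")
  expect_error(gene_model("g", rbind(c(10, 20), c(0, 5)), cds_start = 0,
                          cds_end = 10), "ascending")
  expect_error(gene_model("g", rbind(c(0, 10)), cds_start = 0, cds_end = 20),
               "spliced length")
  m <- gene_model("g", rbind(c(0, 6), c(10, 14)), cds_start = 0, cds_end = 10)
  expect_s3_class(m, "gene_model")
})

test_that("splicing concatenates exons and drops marked intronic bases", {
  # single exon: identity
  m1 <- gene_model("one", rbind(c(0, 8)), cds_start = 0, cds_end = 8)
  expect_equal(splice_transcript(m1, "ATGGCTAA")$residues, "ATGGCTAA")
  # the two-exon mini-gene fixture
  fx <- minigene_fixture()
  expect_equal(splice_transcript(fx$model, fx$genome)$residues,
               "ATGGCTAGGATTTAAGCTGA")
  # sentinel N-filled intron never reaches the transcript
  g <- paste0("ATGGCT", "NNNNNNNN", "AGGATT")
  m2 <- gene_model("sent", rbind(c(0, 6), c(14, 20)), cds_start = 0, cds_end = 12)
  tx <- splice_transcript(m2, g)$residues
  expect_false(grepl("N", tx, fixed = TRUE))
  expect_equal(nchar(tx), sum(m2$exons[, "end"] - m2$exons[, "start"]))
  # out-of-bounds exon
  expect_error(splice_transcript(m2, "ATGGCT"), "bounds")
})

test_that("minus-strand splicing reverse-complements exons in transcript order", {
  # transcript should read exon2' then exon1' (genomically later exon first)
  g <- paste0("AAATTT", "GGGG", "CCGGA")   # exon1 0..6, intron, exon2 10..15
  m <- gene_model("neg", rbind(c(0, 6), c(10, 15)), strand = "-",
                  cds_start = 0, cds_end = 11)
  expect_equal(splice_transcript(m, g)$residues,
               paste0(oracle_revcomp("CCGGA"), oracle_revcomp("AAATTT")))
})

test_that("translation stops at the first stop and reports the Ter codon", {
  expect_equal(translate_cds("ATGTAA", 0),
               list(protein = protein_seq("M"), ter_codon_index = 2L))
  r <- translate_cds("ATGGCTAGGATTTAAGCTGA", 0)
  expect_equal(r$protein$residues, "MARI")
  expect_equal(r$ter_codon_index, 5L)
  r2 <- translate_cds("ATGGCTGATTTAAGCTGA", 0, readthrough = TRUE)
  expect_equal(r2$protein$residues, "MADLS")
  expect_equal(r2$ter_codon_index, 6L)
  # codons containing N become X, never a stop
  expect_equal(translate_cds("ATGANATAA", 0)$protein$residues, "MX")
  # explicit no-stop condition, not silent truncation
  expect_error(translate_cds("ATGGCTGCA", 0), class = "ciliaprint_no_stop")
  # protein length bound: 3 * len + 3 <= available bases when a stop is found
  set.seed(5)
  for (i in 1:10) {
    tx <- paste0("ATG", random_dna_string(60), "TAAATAAATAAA")
    r <- translate_cds(tx, 0)
    expect_lte(nchar(r$protein$residues) * 3 + 3, nchar(tx))
  }
})

test_that("average mass sums residues plus one water and is additive", {
  expect_equal(protein_average_mass(""), 18.01524, tolerance = 1e-6)
  expect_equal(round(protein_average_mass("G"), 2), 75.07)
  expect_error(protein_average_mass("MA*"), "terminator")
  expect_error(protein_average_mass("MAZ"), "illegal|unknown")
  set.seed(7)
  w <- average_mass_table()$water
  for (i in 1:10) {
    a <- random_protein_string(sample(1:30, 1L))
    b <- random_protein_string(sample(1:30, 1L))
    expect_equal(protein_average_mass(paste0(a, b)),
                 protein_average_mass(a) + protein_average_mass(b) - w,
                 tolerance = 1e-9)
  }
  # independent residue-sum check on an arbitrary peptide
  tab <- average_mass_table()$residues
  pep <- "MKVAGE"
  expect_equal(protein_average_mass(pep),
               sum(tab[strsplit(pep, "")[[1]]]) + w)
})

test_that("protein sequences reject misplaced terminators", {
  expect_error(protein_seq("M*A"), "final position")
  expect_error(protein_seq("M**"), "final position")
  expect_silent(protein_seq("MA*"))
})

test_that("gene models round-trip through JSON and GFF3", {
  fx <- minigene_fixture()
  jf <- tempfile(fileext = ".json")
  write_gene_model_json(fx$model, jf)
  m2 <- read_gene_model_json(jf)
  expect_equal(m2$exons, fx$model$exons)
  expect_equal(m2$cds_start, fx$model$cds_start)
  # hand-written GFF3 (1-based inclusive) for the same structure
  gff <- tempfile(fileext = ".gff3")
  n1 <- 6L; i1 <- 16L; n2 <- 14L
  writeLines(c(
    "##gff-version 3",
    sprintf("chr\tsrc\tmRNA\t1\t%d\t.\t+\t.\tID=minigene_fixture", n1 + i1 + n2),
    sprintf("chr\tsrc\texon\t1\t%d\t.\t+\t.\tParent=minigene_fixture", n1),
    sprintf("chr\tsrc\texon\t%d\t%d\t.\t+\t.\tParent=minigene_fixture",
            n1 + i1 + 1L, n1 + i1 + n2),
    sprintf("chr\tsrc\tCDS\t1\t%d\t.\t+\t0\tParent=minigene_fixture", n1),
    sprintf("chr\tsrc\tCDS\t%d\t%d\t.\t+\t0\tParent=minigene_fixture",
            n1 + i1 + 1L, n1 + i1 + n2)), gff)
  m3 <- read_gene_model_gff3(gff)
  expect_equal(m3$exons, fx$model$exons)
  expect_equal(splice_transcript(m3, fx$genome)$residues,
               splice_transcript(fx$model, fx$genome)$residues)
})

test_that("FASTA round-trips preserve sequences with 60-column wrapping", {
  f <- tempfile(fileext = ".fasta")
  seqs <- c(long = paste(rep("ACGT", 40), collapse = ""), short = "TTGA")
  write_fasta(seqs, f)
  expect_true(all(nchar(readLines(f)) <= 60))
  back <- read_fasta(f)
  expect_identical(back, seqs)
})
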