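test_that("minimal HGVS-c acceptor substitutions parse and validate", {
  v <- parse_hgvs_c("c.2432-1G>C")
  expect_equal(v$position, 2432L)
  expect_equal(v$offset, -1L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "C")
  expect_error(parse_hgvs_c("c.2432+1G>C"), "cannot parse")
  expect_error(acceptor_variant(10, -1, "A", "A"), "ref == alt")
  expect_error(acceptor_variant(10, 1, "A", "C"), "negative")
})

test_that("acceptor disruption is flagged iff the intronic AG is destroyed", {
  fx <- minigene_fixture()
  app <- apply_acceptor_variant(fx$model, fx$genome, fx$variant)
  expect_true(app$disrupted)
  expect_equal(app$exon_index, 2L)
  # ref mismatch is a reference error
  expect_error(apply_acceptor_variant(fx$model, fx$genome, "c.7-1A>C"),
               "reference mismatch")
  # a substitution at -5 leaves the AG intact (intron ...TTTCCAG: -5 is T)
  app2 <- apply_acceptor_variant(fx$model, fx$genome, "c.7-5T>G")
  expect_false(app2$disrupted)
  # offsets must address the intron immediately upstream of an exon start
  expect_error(apply_acceptor_variant(fx$model, fx$genome, "c.8-1G>C"),
               "first base")
})

test_that("the cryptic acceptor search follows the 3'-ward nearest-AG rule", {
  fx <- minigene_fixture()
  cry <- find_cryptic_acceptor(fx$model, fx$genome, 2L)
  expect_true(cry$found)
  expect_equal(cry$offset, 0L)
  expect_equal(cry$deleted_count, 2L)
  expect_equal(cry$deleted_seq, "AG")
  # exon beginning CCAG...: 4 bases deleted
  g2 <- build_minigene("ATGGCT", "GTAAGTATCTTTCCAG", "CCAGGATTTAAGCTGA")
  cry2 <- find_cryptic_acceptor(g2$model, g2$genome, 2L)
  expect_equal(cry2$deleted_count, 4L)
  # no AG within the window: explicit no-cryptic-acceptor condition
  g3 <- build_minigene("ATGGCT", "GTAAGTATCTTTCCAG",
                       paste0(strrep("C", 50), "TAAATAAATAAA"))
  cry3 <- find_cryptic_acceptor(g3$model, g3$genome, 2L)
  expect_false(cry3$found)
  sc3 <- splice_consequence(g3$model, g3$genome, g3$variant)
  expect_equal(sc3$type, "no_cryptic_acceptor")
})

test_that("the mini-gene fixture yields the full expected frameshift consequence", {
  fx <- minigene_fixture()
  sc <- splice_consequence(fx$model, fx$genome, fx$variant)
  expect_equal(sc$type, "frameshift")
  expect_equal(sc$wt_transcript, "ATGGCTAGGATTTAAGCTGA")
  expect_equal(sc$mut_transcript, "ATGGCTGATTTAAGCTGA")
  expect_equal(sc$deleted_count, 2L)
  expect_equal(sc$hgvs_c_effect, "c.7-8delAG")
  expect_equal(sc$first_altered_codon, 3L)
  expect_equal(sc$wt_aa, "R")
  expect_equal(sc$mut_aa, "D")
  expect_equal(sc$replaced_count, 2L)
  expect_equal(sc$novel_count, 3L)
  expect_equal(sc$ter_codon, 6L)
  expect_equal(sc$hgvs_p, "p.Arg3AspfsTer4")
})

test_that("a non-disrupting substitution round-trips to the wild-type transcript", {
  fx <- minigene_fixture()
  sc <- splice_consequence(fx$model, fx$genome, "c.7-5T>G")
  expect_equal(sc$type, "acceptor_intact")
  expect_equal(sc$mut_transcript, sc$wt_transcript)
})

test_that("an in-frame 3-nt deletion is reported without frameshift fields", {
  sim <- simulate_minigene(seed = 21L, mode = "inframe")
  sc <- splice_consequence(sim$model, sim$genome, sim$variant)
  expect_equal(sc$type, "inframe_deletion")
  expect_equal(sc$deleted_count, 3L)
  expect_false(sc$frameshift)
  expect_null(sc$hgvs_p)
  expect_equal(sim$truth$type, "inframe_deletion")
})

test_that("HGVS frameshift strings format correctly and reject invalid input", {
  expect_equal(format_hgvs_fs(811, "Glu", "Gly", 78), "p.Glu811GlyfsTer78")
  expect_equal(format_hgvs_fs(3, "R", "D", 4), "p.Arg3AspfsTer4")
  expect_error(format_hgvs_fs(1, "Met", "Val", 5), "initiator")
  expect_error(format_hgvs_fs(3, "Xyz", "Asp", 4), "unknown")
  expect_error(format_hgvs_fs(3, "Arg", "Asp", 1), "ter_ordinal")
})

test_that("splice consequences agree with the naive oracle on seeded mini-genes", {
  modes <- c("ag_initial", "inframe", "random")
  for (seed in 1:60) {
    sim <- simulate_minigene(seed = seed, mode = modes[(seed %% 3) + 1])
    if (sim$truth$type %in% c("no_stop", "no_difference")) next
    sc <- splice_consequence(sim$model, sim$genome, sim$variant)
    expect_equal(sc$type, sim$truth$type, info = paste("seed", seed))
    if (sim$truth$type == "no_cryptic_acceptor") next
    expect_equal(sc$mut_transcript, sim$truth$mut_transcript)
    expect_equal(sc$deleted_count, sim$truth$deleted_count)
    # frameshift iff the deletion length is not a multiple of 3
    expect_equal(sc$type == "frameshift", sim$truth$deleted_count %% 3 != 0)
    if (sim$truth$type == "frameshift") {
      expect_equal(sc$hgvs_p, sim$truth$hgvs_p, info = paste("seed", seed))
      expect_equal(sc$ter_codon, sim$truth$ter_codon)
      expect_equal(sc$ter_codon, sc$first_altered_codon + sc$novel_count)
    }
  }
})

test_that("the engineered full-scale locus reproduces its designed consequence", {
  loc <- simulate_heatr2_like_locus(seed = 1L)
  sc <- splice_consequence(loc$model, loc$genome, loc$variant)
  expect_equal(sc$type, "frameshift")
  expect_equal(sc$deleted_count, 2L)
  expect_equal(sc$hgvs_c_effect, "c.2432-2433delAG")
  expect_equal(sc$first_altered_codon, 811L)
  expect_equal(sc$replaced_count, 44L)
  expect_equal(sc$novel_count, 77L)
  expect_equal(sc$ter_codon, 888L)
  expect_equal(sc$hgvs_p, "p.Glu811GlyfsTer78")
  # replacing 44 residues with 77 adds ~33 residues: a few-kDa mass increase
  expect_gt(sc$mass_shift_da, 2000)
  expect_lt(sc$mass_shift_da, 6000)
})
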