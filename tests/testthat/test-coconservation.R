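test_that("pairwise alignment matches the dynamic-programming oracle", {
  sub <- get_blosum62()
  # self-alignment: 100% identity, diagonal score
  r <- pairwise_align_protein("MKV", "MKV")
  expect_equal(r$pid, 100)
  expect_equal(r$score, sub["M", "M"] + sub["K", "K"] + sub["V", "V"])
  set.seed(31)
  for (i in 1:12) {
    a <- random_protein_string(50)
    b <- random_protein_string(50)
    expect_equal(pairwise_align_protein(a, b)$score,
                 oracle_sw_score(a, b, sub))
  }
  expect_error(pairwise_align_protein("", "MKV"), "empty")
})

test_that("reciprocal best hit recovers a planted orthologue among decoys", {
  set.seed(32)
  ref_seq <- random_protein_string(120)
  mutated <- ciliaprint::diverge_sequence(ref_seq, 0.10,
                                          alphabet = strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]])
  src <- proteome("human", c(QUERY = ref_seq, other = random_protein_string(120)))
  tgt <- proteome("fly", c(d1 = random_protein_string(120),
                           ortho = mutated,
                           d2 = random_protein_string(120)))
  call <- reciprocal_best_hit("QUERY", src, tgt, min_score = 100)
  expect_true(call$reciprocal)
  expect_equal(call$hit, "ortho")
  expect_gt(call$pid, 80)
  # a query with no hit above min_score is absent
  lonely <- proteome("human", c(QUERY = random_protein_string(120)))
  weak <- reciprocal_best_hit("QUERY", lonely, tgt, min_score = 1e6)
  expect_false(weak$reciprocal)
  expect_true(is.na(weak$hit))
})

test_that("RBH is symmetric on a two-proteome fixture", {
  set.seed(33)
  base <- random_protein_string(100)
  aa <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
  pa <- proteome("A", c(a = base, da = random_protein_string(100)))
  pb <- proteome("B", c(b = ciliaprint::diverge_sequence(base, 0.05, alphabet = aa),
                        db = random_protein_string(100)))
  ab <- reciprocal_best_hit("a", pa, pb, min_score = 50)
  ba <- reciprocal_best_hit("b", pb, pa, min_score = 50)
  expect_true(ab$reciprocal && ba$reciprocal)
  expect_equal(ab$hit, "b")
  expect_equal(ba$hit, "a")
  expect_equal(ab$forward_score, ba$reverse_score)
})

test_that("presence matrices honour planted patterns including half categories", {
  pat <- matrix(TRUE, nrow = 3, ncol = 4,
                dimnames = list(c("sp1", "sp2", "sp3"),
                                c("GENE", "M1", "M2", "M3")))
  pat["sp2", "M1"] <- FALSE          # one of three markers ablated: half
  pat["sp3", ] <- FALSE              # nothing planted: absent row
  sim <- simulate_proteomes(pat, divergence = 0.05, seed = 34L)
  pm <- build_presence_matrix(sim$reference, list(CAT = c("M1", "M2", "M3")),
                              sim$proteomes, min_score = 100)
  expect_equal(unname(pm$matrix["sp1", "CAT"]), "full")
  expect_equal(unname(pm$matrix["sp2", "CAT"]), "half")
  expect_equal(unname(pm$matrix["sp3", "CAT"]), "absent")
  expect_equal(unname(pm$matrix["sp1", "GENE"]), "full")
  expect_equal(unname(pm$matrix["sp3", "GENE"]), "absent")
  expect_true(all(pm$gene_calls == sim$truth))
  expect_error(build_presence_matrix(sim$reference, list(BAD = "NOPE"),
                                     sim$proteomes), "missing from the reference")
})

test_that("matrix calls are invariant to within-proteome record order", {
  pat <- matrix(c(TRUE, TRUE, FALSE, TRUE), nrow = 2,
                dimnames = list(c("s1", "s2"), c("g1", "g2")))
  sim <- simulate_proteomes(pat, divergence = 0.05, seed = 35L)
  shuffled <- lapply(sim$proteomes, function(p) {
    proteome(p$species, p$sequences[rev(seq_along(p$sequences))])
  })
  pm1 <- build_presence_matrix(sim$reference, list(C = c("g1", "g2")),
                               sim$proteomes, min_score = 100)
  pm2 <- build_presence_matrix(sim$reference, list(C = c("g1", "g2")),
                               shuffled, min_score = 100)
  expect_identical(pm1$matrix, pm2$matrix)
})

test_that("raising min_score never converts absent to present", {
  pat <- matrix(c(TRUE, FALSE, TRUE, TRUE), nrow = 2,
                dimnames = list(c("s1", "s2"), c("g1", "g2")))
  sim <- simulate_proteomes(pat, divergence = 0.05, seed = 36L)
  lo <- build_presence_matrix(sim$reference, list(C = c("g1", "g2")),
                              sim$proteomes, min_score = 0)
  hi <- build_presence_matrix(sim$reference, list(C = c("g1", "g2")),
                              sim$proteomes, min_score = 200)
  expect_true(all(!(lo$gene_calls == FALSE & hi$gene_calls == TRUE)))
})

test_that("concordance fractions and degenerate Fisher behave as specified", {
  mk <- function(gene, cat) {
    m <- cbind(GENE = gene, CAT = cat)
    rownames(m) <- paste0("sp", seq_len(nrow(m)))
    structure(list(matrix = m), class = "presence_matrix")
  }
  conc <- mk(rep("full", 10), rep("full", 10))
  r <- coconservation_concordance(conc, "GENE", "CAT")
  expect_equal(r$fraction, 1.0)
  disc <- mk(rep(c("full", "absent"), each = 5),
             rep(c("absent", "full"), each = 5))
  expect_equal(coconservation_concordance(disc, "GENE", "CAT")$fraction, 0.0)
  # single-valued category column: concordance defined, p = 1
  degen <- mk(c("full", "absent", "full"), rep("full", 3))
  rd <- coconservation_concordance(degen, "GENE", "CAT")
  expect_equal(rd$p_value, 1.0)
})

test_that("simulated concordance is recovered within binomial error", {
  set.seed(37)
  n <- 40L
  agree <- runif(n) < 0.8
  gene <- ifelse(runif(n) < 0.5, "full", "absent")
  cat_ <- ifelse(agree, gene, ifelse(gene == "full", "absent", "full"))
  m <- cbind(GENE = gene, CAT = cat_)
  rownames(m) <- paste0("sp", seq_len(n))
  pm <- structure(list(matrix = m), class = "presence_matrix")
  r <- coconservation_concordance(pm, "GENE", "CAT")
  expect_equal(r$fraction, mean(agree))
  expect_lt(abs(r$fraction - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})
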