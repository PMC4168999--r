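xbox <- default_motif_set()$xbox
fox <- default_motif_set()$fox_core

test_that("compiled matchers expose the correct width range and reject bad letters", {
  m <- compile_consensus(xbox)
  expect_equal(m$min_width, 13L)
  expect_equal(m$max_width, 15L)
  expect_equal(compile_consensus(fox)$min_width, 7L)
  expect_error(consensus_motif("bad", "RYJ"), "illegal IUPAC")
  expect_error(consensus_motif("bad", "RY", 2, 1), "spacer")
})

test_that("the canonical palindromic X-box is hit once per strand at the same position", {
  h <- scan_motif("GTTGCCATGGCAAC", xbox)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$strand, c("+", "-"))
  expect_true(all(h$start == 1L & h$end == 14L & h$spacer_len == 2L))
  expect_true(all(h$mm5 == 0L & h$mm3 == 0L))
  expect_true(all(h$match == "GTTGCCATGGCAAC"))
})

test_that("N in the subject matches no motif letter", {
  expect_equal(nrow(scan_motif(strrep("N", 14), xbox)), 0L)
  # an N anywhere inside the only match kills it, including under motif N
  s <- "GTTGCCNTGGCAAC"   # N in the spacer region
  expect_equal(nrow(scan_motif(s, xbox)), 0L)
  expect_equal(nrow(scan_motif("", xbox)), 0L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  motifs <- list(xbox = xbox, fox = fox,
                 alt = consensus_motif("alt", "RYYNYY", 1, 3, "RRNRAC",
                                       class = "xbox"))
  for (rep in 1:60) {
    s <- random_dna_string(sample(20:200, 1L), with_n = (rep %% 3 == 0))
    m <- motifs[[sample(length(motifs), 1L)]]
    mm5 <- sample(0:2, 1L)
    got <- scan_motif(s, m, strands = "+", max_mm5 = mm5)
    want <- oracle_scan_plus(s, m$half5, m$spacer_min, m$spacer_max, m$half3,
                             max_mm5 = mm5)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0L) {
      for (col in c("start", "end", "spacer_len", "mm5", "mm3")) {
        expect_equal(got[[col]], want[[col]], ignore_attr = TRUE)
      }
    }
    # minus strand: oracle applied to the reverse complement, coordinates mapped
    gotm <- scan_motif(s, m, strands = "-", max_mm5 = mm5)
    wantm <- oracle_scan_plus(oracle_revcomp(s), m$half5, m$spacer_min,
                              m$spacer_max, m$half3, max_mm5 = mm5)
    expect_equal(nrow(gotm), nrow(wantm))
    if (nrow(gotm) > 0L) {
      n <- nchar(s)
      expect_identical(
        sort(paste(gotm$start, gotm$end, gotm$spacer_len)),
        sort(paste(n - wantm$end + 1L, n - wantm$start + 1L, wantm$spacer_len)))
    }
  }
})

test_that("X-box hit classification separates canonical, relaxed and none", {
  h <- scan_motif("GTTGCCATGGCAAC", xbox, strands = "+")
  expect_equal(classify_xbox_hit(h[1, ]), "canonical")
  # force two mismatches into the 5' half-site: relaxed
  s2 <- paste0("AAAGCC", "AT", "GGCAAC")  # RYYRYY violated at pos 2,3
  h2 <- scan_motif(s2, xbox, strands = "+", max_mm5 = 2)
  expect_true(nrow(h2) >= 1L)
  expect_equal(h2$mm5[1], 2L)
  expect_equal(classify_xbox_hit(h2[1, ]), "relaxed")
  # any 3' half-site mismatch is out
  h3 <- h2[1, ]; h3$mm3 <- 1L
  expect_equal(classify_xbox_hit(h3), "none")
  # beyond the tolerance
  expect_equal(classify_xbox_hit(transform(h2[1, ], mm5 = 3L)), "none")
  fh <- scan_motif("ACCAATA", fox, strands = "+")
  expect_error(classify_xbox_hit(fh[1, ]), "X-box")
})

test_that("enlarging the mismatch tolerance or spacer range never removes a hit", {
  set.seed(77)
  for (rep in 1:10) {
    s <- random_dna_string(150)
    h0 <- scan_motif(s, xbox, max_mm5 = 0)
    h1 <- scan_motif(s, xbox, max_mm5 = 1)
    h2 <- scan_motif(s, xbox, max_mm5 = 2)
    key <- function(h) paste(h$start, h$end, h$strand, h$spacer_len)
    expect_true(all(key(h0) %in% key(h1)))
    expect_true(all(key(h1) %in% key(h2)))
    wide <- consensus_motif("xw", xbox$half5, 0, 4, xbox$half3, class = "xbox")
    hw <- scan_motif(s, wide, max_mm5 = 0)
    expect_true(all(key(h0) %in% key(hw)))
  }
})

test_that("fingerprint recovers planted motifs at their anchor-relative offsets", {
  sim <- simulate_promoter_set(n_species = 1L, length = 500L,
                               planted = c(xbox = -16, fox_core = -40),
                               divergence = 0, seed = 42L)
  call <- fingerprint_window(sim$set[[1]]$seq, window = 500)
  expect_equal(call$verdict, "positive")
  expect_true(-16 %in% call$xbox_hits$offset3)
  expect_true(-40 %in% call$fox_hits$offset3)
})

test_that("a poly-A window is fingerprint-negative", {
  call <- fingerprint_window(strrep("A", 500), window = 500)
  expect_equal(call$verdict, "negative")
  expect_null(call$xbox_hits)
  expect_null(call$fox_hits)
})

test_that("two planted X-boxes report their pairwise separation", {
  # plant two exact canonical instances 100 nt apart (start-to-start)
  inst <- "GTTGCCATGGCAAC"
  s <- strsplit(strrep("A", 500), "")[[1]]
  s[201:214] <- strsplit(inst, "")[[1]]
  s[301:314] <- strsplit(inst, "")[[1]]
  call <- fingerprint_window(paste(s, collapse = ""), window = 500,
                             motifs = default_motif_set()["xbox"])
  expect_true(100 %in% call$xbox_separations)
})

test_that("a window longer than the promoter warns and truncates", {
  expect_warning(call <- fingerprint_window(strrep("A", 120), window = 500),
                 "window")
  expect_equal(call$window, 120L)
})
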