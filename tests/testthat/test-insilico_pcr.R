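test_that("find_primer_sites recovers planted sites on both strands", {
  set.seed(30)
  primer <- "GACCGTGAATATAGTTCTGATGAAT"
  g <- ora_random_dna(2000)
  substr(g, 101, 100 + nchar(primer)) <- primer
  sites <- find_primer_sites(g, primer)
  plus <- sites[sites$strand == "+", ]
  expect_true(any(plus$position == 100 & plus$mismatches == 0))

  g2 <- ora_random_dna(2000)
  substr(g2, 501, 500 + nchar(primer)) <- ora_revcomp(primer)
  sites2 <- find_primer_sites(g2, primer)
  expect_true(any(sites2$position == 500 & sites2$strand == "-"))
})

test_that("find_primer_sites equals the sliding-window oracle with mismatches", {
  set.seed(31)
  params <- match_params(max_mismatches = 2, three_prime_exact_nt = 5)
  for (k in 1:6) {
    primer <- ora_random_dna(18)
    g <- ora_random_dna(800)
    # plant exact and near-exact copies to guarantee non-trivial hits
    mutant <- primer
    substr(mutant, 3, 3) <- setdiff(c("A","C","G","T"),
                                    substr(primer, 3, 3))[1]
    substr(g, 51, 50 + 18) <- primer
    substr(g, 301, 300 + 18) <- mutant
    mine <- find_primer_sites(g, primer, params)
    ora <- oracle_sites(g, primer, max_mm = 2, anchor = 5)
    keym <- sort(paste(mine$position, mine$strand, mine$mismatches))
    keyo <- sort(paste(ora$position, ora$strand, ora$mismatches))
    expect_identical(keym, keyo)
  }
})

test_that("the 3-prime anchor vetoes mismatches at the primer end", {
  primer <- "ACGTACGTACGTACGTAA"
  g <- paste0(strrep("C", 50), primer, strrep("C", 50))
  broken <- g
  substr(broken, 50 + nchar(primer), 50 + nchar(primer)) <- "G"  # 3' end
  params <- match_params(max_mismatches = 2)
  expect_equal(nrow(find_primer_sites(g, primer, params)), 1)
  hit <- find_primer_sites(broken, primer, params)
  expect_false(any(hit$strand == "+" & hit$position == 50))
})

test_that("predict_amplicons reports planted spacings exactly", {
  pair <- p335_panel()$LC3
  set.seed(32)
  g <- genome_record("t", ora_random_dna(2000))
  g <- plant_primer_sites(g, pair, spacing_bp = 128, position = 700)
  amp <- predict_amplicons(g, pair)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length_bp, 128)
  expect_equal(amp$start, 700)
  expect_equal(amp$orientation, "+")

  expect_equal(nrow(predict_amplicons(genome_record("e", strrep("A", 500)),
                                      pair)), 0)
})

test_that("multiple forward sites pair with every downstream reverse site", {
  pair <- primer_pair("demo", "ACGTACGTACGTACG", "TTTTCCCCAAAAGGG")
  rc <- ora_revcomp(pair$reverse)
  g <- paste0(strrep("C", 20), pair$forward, strrep("C", 30), pair$forward,
              strrep("C", 40), rc, strrep("C", 20))
  amp <- predict_amplicons(g, pair)
  expect_equal(nrow(amp), 2)
  # brute-force pairing oracle
  f_starts <- c(20, 20 + 15 + 30)
  r_end <- 20 + 15 + 30 + 15 + 40 + 15
  expect_setequal(amp$length_bp, r_end - f_starts)
})

test_that("amplicon lengths are invariant under strand reversal", {
  pair <- p335_panel()$`98204`
  set.seed(33)
  g <- genome_record("t", ora_random_dna(3000))
  g <- plant_primer_sites(g, pair, spacing_bp = 412, position = 1000)
  amp <- predict_amplicons(g, pair)
  grc <- genome_record("t_rc", ora_revcomp(g$sequence))
  amp_rc <- predict_amplicons(grc, pair)
  expect_equal(sort(amp$length_bp), sort(amp_rc$length_bp))
  expect_setequal(amp_rc$orientation, "-")
})

test_that("site finding and amplicons honour monotonicity", {
  set.seed(34)
  primer <- ora_random_dna(18)
  g <- ora_random_dna(3000)
  substr(g, 1001, 1018) <- primer
  s0 <- find_primer_sites(g, primer, match_params(max_mismatches = 0))
  s2 <- find_primer_sites(g, primer, match_params(max_mismatches = 2))
  expect_true(all(paste(s0$position, s0$strand) %in%
                    paste(s2$position, s2$strand)))

  pair <- p335_panel()$`62503`
  gg <- genome_record("t", ora_random_dna(3000))
  gg <- plant_primer_sites(gg, pair, spacing_bp = 784, position = 100)
  a_wide <- predict_amplicons(gg, pair, match_params(max_product_bp = 5000))
  a_narrow <- predict_amplicons(gg, pair, match_params(max_product_bp = 500))
  expect_true(all(a_narrow$length_bp %in% a_wide$length_bp))
  expect_equal(nrow(a_narrow), 0)
})

test_that("circular genomes wrap across the origin", {
  pair <- primer_pair("wrap", "ACGTACGTACGTACG", "TTTTCCCCAAAAGGG")
  rc <- ora_revcomp(pair$reverse)
  lin <- paste0(rc, strrep("C", 100), pair$forward)  # forward near the end
  g_lin <- genome_record("lin", lin, topology = "linear")
  g_circ <- genome_record("circ", lin, topology = "circular")
  expect_equal(nrow(predict_amplicons(g_lin, pair)), 0)
  amp <- predict_amplicons(g_circ, pair)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length_bp, 15 + 15)  # wraps directly into the reverse site
})

test_that("simulate_multiplex calls labels, flags and conflicts", {
  panel <- p335_panel()
  set.seed(35)
  g <- genome_record("t", ora_random_dna(4000))
  g <- plant_primer_sites(g, panel$LC3, spacing_bp = 128, position = 200)
  res <- simulate_multiplex(g, panel)
  expect_equal(res$called_labels, "sub-group III")
  expect_false(res$flags$conflict)

  # wrong spacing: amplicon reported, label withheld, size-mismatch flag
  g2 <- genome_record("t2", ora_random_dna(4000))
  g2 <- plant_primer_sites(g2, panel$LC3, spacing_bp = 200, position = 200)
  res2 <- simulate_multiplex(g2, panel)
  expect_equal(nrow(res2$amplicons), 1)
  expect_length(res2$called_labels, 0)
  expect_true("LC3" %in% res2$flags$size_mismatch)

  # two planted pairs: both labels called, conflict flagged
  g3 <- genome_record("t3", ora_random_dna(4000))
  g3 <- plant_primer_sites(g3, panel$LC3, spacing_bp = 128, position = 200)
  g3 <- plant_primer_sites(g3, panel$`62503`, spacing_bp = 784, position = 1500)
  res3 <- simulate_multiplex(g3, panel)
  expect_setequal(res3$called_labels, c("sub-group III", "sub-group IV"))
  expect_true(res3$flags$conflict)

  # the size-unvalidated BppU pair calls its label via the any-amplicon path
  g4 <- genome_record("t4", ora_random_dna(4000))
  g4 <- plant_primer_sites(g4, panel$Tuc2009U, spacing_bp = 300, position = 500)
  res4 <- simulate_multiplex(g4, panel)
  expect_equal(res4$called_labels, "sub-group II (BppU-positive)")
  expect_true("Tuc2009U" %in% res4$flags$unvalidated)

  expect_error(simulate_multiplex(g, c(panel, panel["LC3"])), "duplicate")
})

test_that("cwps_type follows the product-size decision rules", {
  panel <- synthetic_cwps_panel()
  set.seed(36)
  g <- genome_record("strain", ora_random_dna(5000))
  g <- plant_primer_sites(g, panel$cwpsA, spacing_bp = 442, position = 300)
  g <- plant_primer_sites(g, panel$rmlB, spacing_bp = 891, position = 2000)
  res <- cwps_type(g, panel)
  expect_equal(res$type, "A")
  expect_true(res$control_ok)
  expect_true(res$valid)

  # only the control amplifies -> unknown
  g2 <- genome_record("s2", ora_random_dna(5000))
  g2 <- plant_primer_sites(g2, panel$rmlB, spacing_bp = 891, position = 2000)
  res2 <- cwps_type(g2, panel)
  expect_equal(res2$type, "unknown")

  # no control product -> assay invalid
  g3 <- genome_record("s3", ora_random_dna(5000))
  g3 <- plant_primer_sites(g3, panel$cwpsB, spacing_bp = 183, position = 300)
  res3 <- cwps_type(g3, panel)
  expect_false(res3$valid)
  expect_true(is.na(res3$type))

  expect_error(cwps_type(g, panel[c("cwpsA", "cwpsB")]), "control")
})

test_that("primer panels round-trip through TSV", {
  panel <- p335_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(panel, path)
  back <- read_panel_tsv(path)
  expect_equal(names(back), names(panel))
  expect_equal(back$LC3$forward, panel$LC3$forward)
  expect_equal(back$`62503`$expected_size_bp, 784L)
  expect_true(is.na(back$Tuc2009U$expected_size_bp))
})
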