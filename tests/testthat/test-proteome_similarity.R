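test_that("align_pair matches the forced small examples", {
  p <- "MKVLLTAGGGWLK"
  self <- align_pair(p, p)
  expect_equal(self$identity, 1.0)
  expect_equal(self$query_coverage, 1.0)
  expect_equal(self$subject_coverage, 1.0)

  expect_equal(align_pair("MKV", "MRV")$identity, 2 / 3)
  expect_error(align_pair("MKB1", "MKV"), "amino-acid alphabet")
})

test_that("align_pair agrees with the brute-force DP oracle", {
  set.seed(101)
  for (k in 1:40) {
    a <- ora_random_protein(sample(5:50, 1))
    b <- ora_random_protein(sample(5:50, 1))
    mine <- align_pair(a, b)
    ora <- oracle_sw(a, b)
    expect_equal(mine$score, ora$score)
    if (ora$score > 0) {
      expect_equal(mine$identity, ora$identity)
      expect_equal(mine$aln_length, ora$columns)
    }
  }
})

test_that("E-values follow Karlin-Altschul with the configured search space", {
  cfg <- scoring_config()
  h <- align_pair("MKVLLTAGGGWLK", "MKVLLTAGGGWLK", cfg)
  m <- 13; n <- 13
  expect_equal(h$evalue, cfg$K * m * n * exp(-cfg$lambda * h$score))
  cfg2 <- scoring_config(search_space = 1e6)
  h2 <- align_pair("MKVLLTAGGGWLK", "MKVLLTAGGGWLK", cfg2)
  expect_equal(h2$evalue, cfg2$K * 1e6 * exp(-cfg2$lambda * h2$score))
})

test_that("threshold semantics: identity strictly greater, coverage at least", {
  thr <- similarity_thresholds()  # E <= 1e-4, identity > 0.5, coverage >= 0.5
  at_identity <- make_hit(identity = 0.5)
  expect_equal(nrow(filter_hits(at_identity, thr)), 0)
  above_identity <- make_hit(identity = 0.5 + 1e-9)
  expect_equal(nrow(filter_hits(above_identity, thr)), 1)
  at_coverage <- make_hit(qcov = 0.5, scov = 0.9)
  expect_equal(nrow(filter_hits(at_coverage, thr)), 1)
  below_coverage <- make_hit(qcov = 0.5 - 1e-9)
  expect_equal(nrow(filter_hits(below_coverage, thr)), 0)
  at_evalue <- make_hit(evalue = 1e-4)
  expect_equal(nrow(filter_hits(at_evalue, thr)), 1)
  above_evalue <- make_hit(evalue = 2e-4)
  expect_equal(nrow(filter_hits(above_evalue, thr)), 0)
})

test_that("all_vs_all retains twins, rejects duplicates and low identity", {
  set.seed(7)
  base <- vapply(1:4, function(i) ora_random_protein(120), "")
  pro <- list(p1 = setNames(base, paste0("p1_", 1:4)),
              p2 = setNames(vapply(base, mutate_protein, "",
                                   target_identity = 0.9), paste0("p2_", 1:4)))
  hits <- all_vs_all(pro)
  # every protein pairs with its twin in both orientations
  for (i in 1:4) {
    expect_true(any(hits$query_id == paste0("p1_", i) &
                      hits$subject_id == paste0("p2_", i)))
    expect_true(any(hits$query_id == paste0("p2_", i) &
                      hits$subject_id == paste0("p1_", i)))
  }
  expect_false(any(hits$query_id == hits$subject_id))  # no self-hits

  # proteins diverged to ~30% identity yield no retained hits
  pro30 <- list(a = setNames(base[1], "a_1"),
                b = setNames(mutate_protein(base[1], 0.30, seed = 4), "b_1"))
  expect_equal(nrow(all_vs_all(pro30)), 0)

  dup <- list(p1 = setNames("MKVLLTAGGG", "x"), p2 = setNames("MKVLLTAGGG", "x"))
  expect_error(all_vs_all(dup), "duplicate protein ids")
})

test_that("retained hits are symmetric under proteome reordering", {
  set.seed(8)
  base <- vapply(1:3, function(i) ora_random_protein(100), "")
  pro <- list(a = setNames(base, paste0("a", 1:3)),
              b = setNames(vapply(base, mutate_protein, "",
                                  target_identity = 0.85), paste0("b", 1:3)))
  h1 <- all_vs_all(pro)
  h2 <- all_vs_all(rev(pro))
  key <- function(h) sort(paste(h$query_id, h$subject_id, round(h$score, 6)))
  expect_identical(key(h1), key(h2))
})

test_that("filtering is monotone in every threshold", {
  set.seed(9)
  base <- vapply(1:5, function(i) ora_random_protein(150), "")
  idents <- sample(c(.55, .7, .9), 5, TRUE)
  pro <- list(a = setNames(base, paste0("a", 1:5)),
              b = setNames(mapply(mutate_protein, base, idents),
                           paste0("b", 1:5)))
  strict <- all_vs_all(pro, similarity_thresholds())
  relaxed <- all_vs_all(pro, similarity_thresholds(max_evalue = 1,
                                                   min_identity = 0.2,
                                                   min_coverage = 0.2))
  key <- function(h) paste(h$query_id, h$subject_id)
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("bidirectional_best_hits equals brute-force reciprocal maxima", {
  # direct examples
  single <- rbind(make_hit("a1", "b1", qphage = "A", sphage = "B"),
                  make_hit("b1", "a1", qphage = "B", sphage = "A"))
  bb <- bidirectional_best_hits(single)
  expect_equal(nrow(bb), 1)
  expect_equal(bb$protein_a, "a1")

  # a query's non-best subject can never form a BBH
  h <- rbind(make_hit("a1", "b1", score = 100, qphage = "A", sphage = "B"),
             make_hit("a1", "b2", score = 90, qphage = "A", sphage = "B"),
             make_hit("b1", "a1", score = 100, qphage = "B", sphage = "A"),
             make_hit("b2", "a1", score = 90, qphage = "B", sphage = "A"))
  bb <- bidirectional_best_hits(h)
  expect_equal(nrow(bb), 1)
  expect_equal(bb$protein_b, "b1")

  # random tables vs exhaustive oracle
  set.seed(10)
  for (rep in 1:20) {
    qs <- paste0("a", 1:4); ss <- paste0("b", 1:4)
    rows <- list()
    for (q in qs) for (s in ss) {
      if (runif(1) < 0.5) next
      sc <- sample(50:60, 1)
      rows[[length(rows) + 1]] <- make_hit(q, s, score = sc,
                                           identity = runif(1, .6, .9),
                                           qphage = "A", sphage = "B")
      rows[[length(rows) + 1]] <- make_hit(s, q, score = sc,
                                           identity = runif(1, .6, .9),
                                           qphage = "B", sphage = "A")
    }
    if (length(rows) == 0) next
    h <- do.call(rbind, rows)
    mine <- bidirectional_best_hits(h)
    # oracle: enumerate reciprocal maxima with the documented tie-breaks
    best_of <- function(q, qp) {
      sub <- h[h$query_id == q & h$query_phage == qp, , drop = FALSE]
      if (nrow(sub) == 0) return(NA)
      sub <- sub[order(-sub$score, -sub$identity, sub$subject_id), ]
      sub$subject_id[1]
    }
    expected <- character(0)
    for (q in qs) {
      b <- best_of(q, "A")
      if (!is.na(b) && identical(best_of(b, "B"), q))
        expected <- c(expected, paste(q, b))
    }
    expect_setequal(paste(mine$protein_a, mine$protein_b), expected)
  }
})

test_that("hit tables round-trip through outfmt6 TSV", {
  h <- rbind(make_hit("a1", "b1"), make_hit("b1", "a1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_outfmt6(h, path)
  back <- read_hits_outfmt6(path)
  expect_equal(back$qseqid, h$query_id)
  expect_equal(back$pident, 100 * h$identity)
  expect_equal(back$bitscore, round(h$bitscore, 1))
})
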