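test_that("mutate_protein hits its identity target and is deterministic", {
  p <- random_protein(1000, seed = 3)
  expect_identical(mutate_protein(p, 1.0, seed = 5), p)
  expect_error(mutate_protein(p, 0, seed = 1), "target_identity")
  expect_error(mutate_protein("", 0.9, seed = 1), "non-empty")

  # realised identity within the 99% binomial interval around 0.94
  m <- mutate_protein(p, 0.94, seed = 17)
  ident <- mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  half <- 2.576 * sqrt(0.94 * 0.06 / 1000)
  expect_gt(ident, 0.94 - half)
  expect_lt(ident, 0.94 + half)

  expect_identical(mutate_protein(p, 0.9, seed = 7),
                   mutate_protein(p, 0.9, seed = 7))
})

test_that("back_translate is deterministic and translates back exactly", {
  p <- random_protein(80, seed = 9)
  cds <- back_translate(p)
  expect_equal(nchar(cds), 3 * (nchar(p) + 1))
  expect_equal(translate_cds(cds), p)
  expect_identical(back_translate(p), cds)
})

test_that("make_phage plants the adhesion module as specified", {
  # sub-group IV template: Dit 290, short Tal 371, RBP 342
  r <- make_phage(phage_template("IV"), divergence = 0, seed = 2)
  comp <- r$truth$components
  expect_equal(comp$size_aa[comp$role == "dit"], 290)
  expect_equal(comp$size_aa[comp$role == "tal"], 371)
  expect_equal(comp$size_aa[comp$role == "rbp"], 342)
  expect_equal(comp$size_aa[comp$role == "tmp"], 900)
  # holin/lysin immediately after the adhesion genes
  roles_in_order <- r$phage$orfs$label[match(comp$orf_id, r$phage$orfs$orf_id)]
  expect_equal(tail(roles_in_order, 2), c("holin", "lysin"))

  # divergence 0: adhesion proteins identical to the reference seeds
  panel <- reference_panel()
  dit_seed <- panel$proteins$protein[panel$proteins$role == "dit" &
                                       panel$proteins$subgroup == "IV"]
  dit_planted <- r$phage$orfs$protein[r$phage$orfs$orf_id ==
                                        comp$orf_id[comp$role == "dit"]]
  expect_identical(dit_planted, dit_seed)

  # genome scale matches the sequenced isolates (~30-40 kb, 45-60 ORFs)
  expect_gt(nchar(r$phage$genome$sequence), 25000)
  expect_lt(nchar(r$phage$genome$sequence), 42000)
  expect_gte(nrow(r$phage$orfs), 45)
  expect_lte(nrow(r$phage$orfs), 60)
})

test_that("generators are pure functions of their seed", {
  a <- make_phage(phage_template("II"), 0.05, seed = 31)
  b <- make_phage(phage_template("II"), 0.05, seed = 31)
  expect_identical(a$phage$genome$sequence, b$phage$genome$sequence)
  expect_identical(a$phage$orfs, b$phage$orfs)
  c <- make_phage(phage_template("II"), 0.05, seed = 32)
  expect_false(identical(a$phage$genome$sequence, c$phage$genome$sequence))
})

test_that("every planted component is recoverable at divergence 0", {
  for (sg in c("I", "II", "III", "IV")) {
    r <- make_phage(phage_template(sg), divergence = 0, seed = 5)
    mod <- assign_roles(locate_module(r$phage))
    comp <- r$truth$components
    module_truth <- comp$orf_id[!comp$role %in% c("holin", "lysin")]
    expect_identical(mod$orfs$orf_id, module_truth)
    got <- setNames(mod$orfs$role, mod$orfs$orf_id)
    want <- setNames(comp$role[!comp$role %in% c("holin", "lysin")],
                     module_truth)
    expect_identical(got, want)
  }
})

test_that("plant_primer_sites writes sites at the requested spacing", {
  pair <- p335_panel()$`62503`
  g <- genome_record("t", ora_random_dna(3000))
  g2 <- plant_primer_sites(g, pair, spacing_bp = 784, position = 500)
  expect_equal(substr(g2$sequence, 501, 500 + nchar(pair$forward)),
               pair$forward)
  truth <- attr(g2, "truth_amplicons")
  expect_equal(truth$length_bp, 784)

  expect_error(plant_primer_sites(g, pair, spacing_bp = 30, position = 0),
               "smaller than combined primer length")
  expect_error(plant_primer_sites(g, pair, spacing_bp = 784, position = 2500),
               "do not fit")
  expect_error(plant_primer_sites(g2, pair, spacing_bp = 200, position = 510),
               "overlaps")
})

test_that("make_plaque_data draws Poisson counts with censoring", {
  set.seed(1)
  d0 <- make_plaque_data(1e8, 0, 1e-4, n_replicates = 5, seed = 4)
  expect_true(all(d0$plaque_count == 0))
  expect_true(all(d0$censored))

  # Poisson oracle: titre 1e8, EOP 1e-4, volume 1e-4 ml -> mean 1
  d1 <- make_plaque_data(1e8, 1e-4, 1e-4, n_replicates = 400, seed = 8)
  expect_gt(mean(d1$plaque_count), 1 - 3 * sqrt(1 / 400))
  expect_lt(mean(d1$plaque_count), 1 + 3 * sqrt(1 / 400))
  # reference plate at EOP 1: mean 1e4
  d2 <- make_plaque_data(1e8, 1, 1e-4, n_replicates = 10, seed = 9)
  expect_gt(mean(d2$plaque_count), 9800)
  expect_lt(mean(d2$plaque_count), 10200)
})

test_that("make_host_range follows its probabilities", {
  strains <- setNames(rep(c("A", "B", "C", "U"), each = 3),
                      sprintf("s%02d", 1:12))
  hr0 <- make_host_range(5, strains, c(A = 0, B = 0, C = 0, U = 0), seed = 2)
  expect_false(any(hr0$matrix))

  hrA <- make_host_range(5, strains, c(A = 1, B = 0, C = 0, U = 0), seed = 2)
  expect_true(all(hrA$matrix[, strains == "A"]))
  expect_false(any(hrA$matrix[, strains != "A"]))

  # empirical frequency within the 99% binomial interval at large n
  hr <- make_host_range(200, strains, c(A = 0.7, B = 0.1, C = 0.3, U = 0.5),
                        seed = 3)
  fA <- mean(hr$matrix[, strains == "A"])
  n <- 200 * 3
  expect_lt(abs(fA - 0.7), 2.576 * sqrt(0.7 * 0.3 / n))

  expect_error(make_host_range(2, c(s1 = "Z"), c(A = 1), seed = 1),
               "unknown CWPS label")
})

test_that("write_cohort emits FASTA, ORF TSV and truth JSON", {
  coh <- make_phage_set(list(phage_template("III", n_background_orfs = 5)),
                        divergence = 0, seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "genomes.fasta")))
  genomes <- read_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(genomes[[1]]$sequence, coh$phages[[1]]$genome$sequence)
  ph <- read_annotations(file.path(dir, "orfs.tsv"), genomes[[1]])
  expect_equal(ph$orfs$protein, coh$phages[[1]]$orfs$protein)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth[[1]]$subgroup, "III")
})
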