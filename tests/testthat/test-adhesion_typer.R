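# Table-2 architecture signatures expected for each sub-group template at
# divergence 0 (dit/tal classes follow the package's size bands).
SIGNATURES <- list(
  I   = list(dit = "evolved", tal = "fused_with_RBP", bppu = "absent",
             bppa = FALSE, arity = "fused_tal_rbp"),
  II  = list(dit = "classical", tal = "long_PGNase", bppu = "classical",
             bppa = TRUE, arity = "multi_component_baseplate"),
  III = list(dit = "classical_p2", tal = "short_p2like", bppu = "absent",
             bppa = FALSE, arity = "single_component_RBP"),
  IV  = list(dit = "classical_p2", tal = "short_p2like", bppu = "absent",
             bppa = FALSE, arity = "single_component_RBP")
)

test_that("architecture calls match the template signature for all sub-groups", {
  for (sg in names(SIGNATURES)) {
    r <- make_phage(phage_template(sg), divergence = 0, seed = 3)
    mod <- assign_roles(locate_module(r$phage))
    arch <- classify_architecture(mod)
    sig <- SIGNATURES[[sg]]
    expect_equal(arch$dit_class, sig$dit, label = sg)
    expect_equal(arch$tal_class, sig$tal, label = sg)
    expect_equal(arch$bppu_class, sig$bppu, label = sg)
    expect_equal(arch$bppa_present, sig$bppa, label = sg)
    expect_equal(arch$arity, sig$arity, label = sg)
    # role order invariant: TMP < Dit < Tal <= peripherals
    pos <- setNames(seq_len(nrow(mod$orfs)), mod$orfs$role)
    tal_pos <- pos[[if (sg == "I") "tal_rbp_fused" else "tal"]]
    expect_lt(pos[["tmp"]], pos[["dit"]])
    expect_lt(pos[["dit"]], tal_pos)
  }
})

test_that("classification is invariant to extra background ORFs", {
  a <- make_phage(phage_template("III", n_background_orfs = 30),
                  divergence = 0.05, seed = 12, phage_id = "x")
  b <- make_phage(phage_template("III", n_background_orfs = 50),
                  divergence = 0.05, seed = 12, phage_id = "x")
  arch_a <- classify_architecture(assign_roles(locate_module(a$phage)))
  arch_b <- classify_architecture(assign_roles(locate_module(b$phage)))
  expect_equal(unclass(arch_a), unclass(arch_b))
})

test_that("missing lysis cassette truncates the module with a warning", {
  r <- make_phage(phage_template("IV", n_background_orfs = 20),
                  divergence = 0, seed = 6)
  keep <- !r$phage$orfs$label %in% c("holin", "lysin")
  ph <- annotated_phage(r$phage$genome, r$phage$orfs[keep, ])
  expect_warning(mod <- locate_module(ph), "no lysis cassette")
  expect_true(mod$truncated)
  # module runs to the genome end
  expect_equal(tail(mod$orfs$orf_id, 1), tail(ph$orfs$orf_id, 1))
})

test_that("degenerate modules raise absence/ambiguity errors", {
  r <- make_phage(phage_template("IV", n_background_orfs = 6),
                  divergence = 0, seed = 6)
  orfs <- r$phage$orfs
  keep <- orfs$label %in% c("tmp", "holin", "lysin")
  ph <- annotated_phage(r$phage$genome, orfs[keep, ])
  mod <- locate_module(ph)
  expect_error(assign_roles(mod), "no Dit")

  # no TMP homolog and no ORF >= 700 aa -> module not found
  small <- orfs[orfs$label %in% c("dit", "rbp"), ]
  ph2 <- annotated_phage(r$phage$genome, small)
  expect_error(locate_module(ph2), "module not found")
})

test_that("size-band gaps resolve to the nearest band with a warning", {
  r <- make_phage(phage_template("II", component_sizes = c(dit = 400)),
                  divergence = 0, seed = 7)
  mod <- assign_roles(locate_module(r$phage))
  expect_warning(arch <- classify_architecture(mod), "band gap")
  expect_true(arch$dit_class %in% c("classical_p2", "evolved"))
  # 400 is equidistant from both band edges; ties resolve to the lower band
  expect_equal(arch$dit_class, "classical_p2")
})

test_that("assign_rbp_subgroup recognises references, mutants and novelty", {
  panel <- reference_panel()
  lc3_like <- rbp_reference_protein(panel, "III")
  expect_equal(assign_rbp_subgroup(lc3_like), "III")

  # 94% identity mutant (the LC3/Dub35A relationship) still calls III
  mut <- mutate_protein(lc3_like, 0.94, seed = 44)
  expect_equal(assign_rbp_subgroup(mut), "III")

  # all four references call their own sub-group
  for (sg in c("I", "II", "III", "IV")) {
    ref <- rbp_reference_protein(panel, sg)
    expect_equal(assign_rbp_subgroup(ref), sg, label = sg)
  }

  # fused candidates are compared on the C-terminal half
  fused <- panel$proteins$protein[panel$proteins$role == "tal_rbp_fused"]
  expect_equal(assign_rbp_subgroup(fused, is_fused = TRUE), "I")

  # a random 340-aa protein is novel
  set.seed(45)
  expect_equal(assign_rbp_subgroup(ora_random_protein(340)), "novel")
})

test_that("chimeric phages are flagged discordant", {
  arch <- structure(list(dit_class = "classical", tal_class = "long_PGNase",
                         bppu_class = "classical", bppa_present = TRUE,
                         rbp_size_aa = 173L,
                         arity = "multi_component_baseplate"),
                    class = "architecture_call")
  a <- assemble_assignment("p", "grp01", "II", arch, "II")
  expect_true(a$concordant)
  b <- assemble_assignment("p", "grp01", "II", arch, "I")
  expect_false(b$concordant)
  c <- assemble_assignment("p", NA_character_, NA_character_, arch, "II")
  expect_true(is.na(c$concordant))

  # end to end: sub-group II backbone carrying a sub-group I RBP
  r <- make_phage(phage_template("II", rbp_subgroup = "I"),
                  divergence = 0.05, seed = 9)
  mod <- assign_roles(locate_module(r$phage))
  rbp <- module_rbp(mod)
  expect_equal(assign_rbp_subgroup(rbp$protein, is_fused = rbp$is_fused), "I")
})

test_that("module boundaries are recovered at divergence 0.1 (>= 95%)", {
  templates <- rep(list(phage_template("I"), phage_template("II"),
                        phage_template("III"), phage_template("IV")), 5)
  ok <- 0L
  for (k in seq_along(templates)) {
    r <- make_phage(templates[[k]], divergence = 0.1, seed = 500 + k)
    truth_ids <- with(r$truth,
                      components$orf_id[!components$role %in% c("holin", "lysin")])
    mod <- try(locate_module(r$phage), silent = TRUE)
    if (!inherits(mod, "try-error") &&
        identical(mod$orfs$orf_id, truth_ids)) ok <- ok + 1L
  }
  expect_gte(ok / length(templates), 0.95)
})

test_that("the shipped panel FASTA equals the in-code reference panel", {
  path <- system.file("extdata", "synthetic_reference_panel.fasta",
                      package = "p335typer")
  shipped <- read_panel_fasta(path)
  expect_equal(shipped$proteins, reference_panel()$proteins)
  expect_equal(shipped$dit_bands, reference_panel()$dit_bands)
})

test_that("reference panels round-trip through labelled FASTA", {
  panel <- reference_panel()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_panel_fasta(panel, path)
  back <- read_panel_fasta(path)
  expect_equal(back$proteins, panel$proteins)
  expect_equal(back$min_identity, panel$min_identity)
  expect_equal(back$dit_bands, panel$dit_bands)
})
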