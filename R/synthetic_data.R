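# Synthetic phages, diverged protein families, planted primer sites,
# plaque counts and host-range matrices with known ground truth.
#
# Generators are pure functions of their seed. Planted proteins are
# back-translated with the lexicographically first codon per residue;
# GC steering is applied only to the intergenic filler.

#' Substitution-only protein mutagenesis to a target identity
#'
#' Each position is substituted independently with probability
#' `1 - target_identity`, to a uniformly chosen different residue.
#'
#' @param protein amino-acid string.
#' @param target_identity expected identity fraction in `(0, 1]`.
#' @param seed RNG seed (`NULL` = use current stream).
#' @return mutated protein of identical length.
#' @export
mutate_protein <- function(protein, target_identity, seed = NULL) {
  validate_protein(protein)
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]")
  with_seed(seed, {
    aa <- strsplit(protein, "", fixed = TRUE)[[1]]
    hit <- runif(length(aa)) < (1 - target_identity)
    for (i in which(hit)) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
    paste(aa, collapse = "")
  })
}

codon_map <- function() {
  if (is.null(.pkg_cache$codon_map)) {
    code <- genetic_code_11()
    aas <- unique(code)
    m <- vapply(aas, function(a) sort(names(code)[code == a])[1], "")
    .pkg_cache$codon_map <- m
  }
  .pkg_cache$codon_map
}

#' Back-translate a protein deterministically
#'
#' Uses the lexicographically first codon per residue (translation table 11)
#' and appends a TAA stop, so the coding sequence is a pure function of the
#' protein.
#'
#' @param protein amino-acid string (X not allowed).
#' @return coding DNA string, stop codon included.
#' @export
back_translate <- function(protein) {
  validate_protein(protein)
  if (grepl("X", protein, fixed = TRUE))
    stop("cannot back-translate 'X' residues")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste0(paste(codon_map()[aa], collapse = ""), "TAA")
}

#' Phage genome template
#'
#' Defaults reproduce the component-size signature of the sub-group
#' exemplars (I: evolved Dit 548 aa + fused Tal-RBP 1904 aa; II: classical
#' Dit 253 + long Tal 906 + BppU 322 + BppA 286 + BppL 173; III: Dit 298 +
#' short Tal 385 + RBP 343; IV: Dit 290 + Tal 371 + RBP 342) at the genome
#' scale of the sequenced isolates (~30-38 kb, ~45-60 ORFs).
#'
#' @param subgroup one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param component_sizes optional named vector role -> aa length overriding
#'   the sub-group defaults.
#' @param n_background_orfs number of background (non-module) ORFs.
#' @param target_gc genome GC fraction steered via intergenic filler.
#' @param rbp_subgroup sub-group supplying the RBP gene; set different from
#'   `subgroup` to plant a chimeric (discordant) phage.
#' @return a `phage_template` list.
#' @export
phage_template <- function(subgroup, component_sizes = NULL,
                           n_background_orfs = 45L, target_gc = 0.36,
                           rbp_subgroup = subgroup) {
  subgroup <- match.arg(subgroup, SUBGROUPS)
  rbp_subgroup <- match.arg(rbp_subgroup, SUBGROUPS)
  sizes <- TEMPLATE_SIZES[[subgroup]]
  if (!is.null(component_sizes)) {
    unknown <- setdiff(names(component_sizes), names(sizes))
    if (length(unknown))
      stop(sprintf("unknown component role: %s", unknown[1]))
    sizes[names(component_sizes)] <- component_sizes
  }
  if (any(sizes <= 0)) stop("component sizes must be positive")
  stopifnot(n_background_orfs >= 0, target_gc > 0, target_gc < 1)
  structure(list(subgroup = subgroup, component_sizes = sizes,
                 n_background_orfs = as.integer(n_background_orfs),
                 target_gc = target_gc, rbp_subgroup = rbp_subgroup),
            class = "phage_template")
}

# deterministic pool of background protein seeds, shared by all phages
# built from the same sub-group template (so they form protein families)
background_pool <- function(subgroup, n) {
  with_seed(panel_seed("tmp", subgroup) + 5000L, {
    lens <- sample(80:300, n, replace = TRUE)
    vapply(lens, function(l) random_protein(l), "")
  })
}

resize_protein <- function(protein, len) {
  n <- nchar(protein)
  if (len <= n) return(substr(protein, 1, len))
  paste0(protein, random_protein(len - n, start_met = FALSE))
}

#' Generate a synthetic phage with planted ground truth
#'
#' The genome contains, in order: background ORFs, the adhesion module at
#' the template's component sizes (reference seeds mutated at `divergence`),
#' the holin/lysin pair immediately after the adhesion genes, and the
#' remaining background ORFs, separated by GC-steered intergenic filler.
#'
#' @param template a [phage_template()].
#' @param divergence per-residue substitution probability applied to every
#'   planted protein (identity target `1 - divergence`).
#' @param seed RNG seed; the phage is a pure function of (template, seed).
#' @param phage_id genome identifier.
#' @return list with `phage` (an [annotated_phage()]) and `truth` (sub-group,
#'   RBP sub-group, per-role component ORFs, protein -> seed-family map).
#' @export
make_phage <- function(template, divergence = 0.05, seed = 1L,
                       phage_id = sprintf("syn%s_%d", template$subgroup, seed)) {
  stopifnot(inherits(template, "phage_template"),
            divergence >= 0, divergence < 1)
  panel <- reference_panel()
  with_seed(seed, {
    ident <- 1 - divergence
    mut <- function(p) if (divergence == 0) p else mutate_protein(p, ident)

    pr <- panel$proteins
    seed_of <- function(role, sg) pr$protein[pr$role == role & pr$subgroup == sg]
    roles <- names(template$component_sizes)
    comp <- list()
    for (role in roles) {
      sg <- template$subgroup
      chimeric <- role %in% c("rbp", "tal_rbp_fused") &&
        template$rbp_subgroup != template$subgroup
      if (chimeric) {
        # chimeric RBP: the receptor-binding gene comes from another
        # sub-group and is planted at its donor's natural size
        base <- rbp_reference_protein(panel, template$rbp_subgroup)
        comp[[role]] <- mut(base)
      } else {
        base <- seed_of(role, sg)
        comp[[role]] <- mut(resize_protein(base, template$component_sizes[[role]]))
      }
    }
    lysis <- lapply(c(holin = "holin", lysin = "lysin"),
                    function(r) mut(seed_of(r, "all")))

    nbg <- template$n_background_orfs
    bg <- if (nbg > 0) vapply(background_pool(template$subgroup, nbg), mut, "")
          else character(0)
    n_front <- ceiling(0.6 * nbg)

    genes <- c(
      if (n_front > 0) setNames(bg[seq_len(n_front)],
                                sprintf("bg%03d", seq_len(n_front))),
      setNames(unlist(comp), roles),
      setNames(unlist(lysis), c("holin", "lysin")),
      if (nbg > n_front) setNames(bg[(n_front + 1):nbg],
                                  sprintf("bg%03d", (n_front + 1):nbg)))
    cds <- vapply(genes, back_translate, "")
    n_genes <- length(genes)
    fill_len <- c(200L, sample(20:60, n_genes - 1L, replace = TRUE), 200L)
    coding_len <- sum(nchar(cds))
    total_len <- coding_len + sum(fill_len)
    coding_gc <- sum(vapply(cds, function(s)
      lengths(regmatches(s, gregexpr("[GC]", s))), 0L))
    fill_gc <- (template$target_gc * total_len - coding_gc) / sum(fill_len)
    fill_gc <- min(max(fill_gc, 0.05), 0.95)
    fillers <- vapply(fill_len, function(l) random_dna(l, fill_gc), "")

    pieces <- character(2L * n_genes + 1L)
    pieces[seq(1L, 2L * n_genes + 1L, 2L)] <- fillers
    pieces[seq(2L, 2L * n_genes, 2L)] <- cds
    seqstr <- paste(pieces, collapse = "")
    if (nchar(seqstr) != total_len) stop("impossible packing")

    starts <- cumsum(c(0L, nchar(pieces)))[seq(2L, 2L * n_genes, 2L)]
    ends <- starts + nchar(cds)
    orf_ids <- sprintf("%s_orf%03d", phage_id, seq_len(n_genes))
    role_label <- names(genes)
    orfs <- data.frame(orf_id = orf_ids, start = starts, end = ends,
                       strand = "+",
                       protein = unname(genes),
                       label = role_label, stringsAsFactors = FALSE)
    genome <- genome_record(phage_id, seqstr,
                            description = sprintf("synthetic sub-group %s phage",
                                                  template$subgroup))
    phage <- annotated_phage(genome, orfs,
                             metadata = list(subgroup = template$subgroup,
                                             seed = seed))
    module_roles <- c(roles, "holin", "lysin")
    comp_idx <- match(module_roles, role_label)
    truth <- list(
      phage_id = phage_id,
      subgroup = template$subgroup,
      rbp_subgroup = template$rbp_subgroup,
      components = data.frame(role = module_roles,
                              orf_id = orf_ids[comp_idx],
                              start = starts[comp_idx], end = ends[comp_idx],
                              size_aa = nchar(unname(genes[comp_idx])),
                              stringsAsFactors = FALSE),
      protein_families = setNames(
        ifelse(role_label %in% c(roles, "holin", "lysin"),
               paste0(ifelse(role_label %in% c("holin", "lysin"), "all",
                             ifelse(role_label %in% c("rbp", "tal_rbp_fused"),
                                    template$rbp_subgroup, template$subgroup)),
                      "_", role_label),
               paste0(template$subgroup, "_", role_label)),
        orf_ids))
    list(phage = phage, truth = truth)
  })
}

#' Generate a cohort of synthetic phages
#'
#' @param templates list of [phage_template()] objects (one phage each).
#' @param divergence per-phage divergence from the shared seed proteins.
#' @param seed base seed; phage k uses `seed + k`.
#' @return list with `phages` (named list of annotated phages) and `truth`
#'   (named list of truth entries).
#' @export
make_phage_set <- function(templates, divergence = 0.05, seed = 1L) {
  out_p <- list(); out_t <- list()
  for (k in seq_along(templates)) {
    id <- sprintf("syn%02d_%s", k, templates[[k]]$subgroup)
    r <- make_phage(templates[[k]], divergence, seed = seed + k, phage_id = id)
    out_p[[id]] <- r$phage
    out_t[[id]] <- r$truth
  }
  list(phages = out_p, truth = out_t)
}

#' Plant a primer pair's binding sites in a genome
#'
#' Writes the forward primer at `position` on the plus strand and the
#' reverse complement of the reverse primer so that the inclusive span from
#' the forward start to the reverse-site end equals `spacing_bp` (the
#' amplicon size an in silico PCR should report).
#'
#' @param genome a [genome_record()].
#' @param pair a [primer_pair()].
#' @param spacing_bp amplicon length to plant (>= total primer length).
#' @param position 0-based plus-strand start of the forward site.
#' @return the modified genome; planted spans and the expected amplicon are
#'   recorded in attributes `planted` and `truth_amplicons`.
#' @export
plant_primer_sites <- function(genome, pair, spacing_bp, position) {
  stopifnot(inherits(genome, "genome_record"), inherits(pair, "primer_pair"))
  lf <- nchar(pair$forward); lr <- nchar(pair$reverse)
  if (spacing_bp < lf + lr)
    stop(sprintf("spacing %d bp smaller than combined primer length %d",
                 spacing_bp, lf + lr))
  L <- nchar(genome$sequence)
  if (position < 0 || position + spacing_bp > L)
    stop("primer sites do not fit in the genome at this position")
  new_spans <- rbind(c(position, position + lf),
                     c(position + spacing_bp - lr, position + spacing_bp))
  old_spans <- attr(genome, "planted")
  if (!is.null(old_spans)) {
    for (i in seq_len(nrow(new_spans))) for (j in seq_len(nrow(old_spans))) {
      if (new_spans[i, 1] < old_spans[j, 2] && old_spans[j, 1] < new_spans[i, 2])
        stop("planted primer site overlaps an existing planted feature")
    }
  }
  s <- genome$sequence
  substr(s, position + 1L, position + lf) <- pair$forward
  rc <- revcomp(pair$reverse)
  substr(s, position + spacing_bp - lr + 1L, position + spacing_bp) <- rc
  genome$sequence <- s
  attr(genome, "planted") <- rbind(old_spans, new_spans)
  amp <- data.frame(pair_name = pair$name, start = position,
                    length_bp = spacing_bp, stringsAsFactors = FALSE)
  attr(genome, "truth_amplicons") <- rbind(attr(genome, "truth_amplicons"), amp)
  genome
}

#' Simulate plaque counts around a true titre
#'
#' Counts are Poisson with mean `true_titre * true_eop * volume_plated_ml`;
#' zero counts are flagged censored at the detection limit `1 / volume`.
#'
#' @param true_titre plaque-forming units per ml under the reference
#'   condition.
#' @param true_eop efficiency of plaquing under the assayed condition.
#' @param volume_plated_ml plated volume (ml).
#' @param n_replicates number of replicate plates.
#' @param seed RNG seed.
#' @param phage_id,condition identifiers written into the records.
#' @return data frame of plaque-assay records (`phage_id`, `condition`,
#'   `plaque_count`, `volume_plated_ml`, `replicate`, `censored`).
#' @export
make_plaque_data <- function(true_titre, true_eop, volume_plated_ml,
                             n_replicates = 3L, seed = 1L,
                             phage_id = "phage", condition = "Ca_10mM") {
  stopifnot(true_titre > 0, true_eop >= 0, true_eop <= 1,
            volume_plated_ml > 0, n_replicates >= 1)
  with_seed(seed, {
    counts <- rpois(n_replicates, true_titre * true_eop * volume_plated_ml)
    data.frame(phage_id = phage_id, condition = condition,
               plaque_count = counts, volume_plated_ml = volume_plated_ml,
               replicate = seq_len(n_replicates), censored = counts == 0,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a binary host-range matrix with CWPS-typed strains
#'
#' @param n_phages number of phages (rows).
#' @param strains_with_cwps named character vector strain -> CWPS type in
#'   `{A, B, C, U}`.
#' @param infect_prob_by_type named numeric vector type -> infection
#'   probability.
#' @param seed RNG seed.
#' @return object of class `host_range`: `matrix` (logical phages x strains)
#'   and `strain_types`.
#' @export
make_host_range <- function(n_phages, strains_with_cwps, infect_prob_by_type,
                            seed = 1L) {
  types <- as.character(strains_with_cwps)
  if (!all(types %in% c("A", "B", "C", "U")))
    stop(sprintf("unknown CWPS label: %s",
                 setdiff(types, c("A", "B", "C", "U"))[1]))
  if (is.null(names(strains_with_cwps)))
    stop("strains_with_cwps must be named by strain")
  miss <- setdiff(unique(types), names(infect_prob_by_type))
  if (length(miss))
    stop(sprintf("no infection probability for CWPS type %s", miss[1]))
  p <- infect_prob_by_type[types]
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  with_seed(seed, {
    m <- matrix(rbinom(n_phages * length(types), 1,
                       rep(p, each = n_phages)) == 1,
                nrow = n_phages,
                dimnames = list(sprintf("phage%02d", seq_len(n_phages)),
                                names(strains_with_cwps)))
    host_range(m, strains_with_cwps)
  })
}

#' Write a synthetic phage cohort to disk (FASTA + ORF TSV + truth JSON)
#'
#' @param cohort from [make_phage_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(lapply(cohort$phages, function(p) p$genome),
              file.path(dir, "genomes.fasta"))
  orf_path <- file.path(dir, "orfs.tsv")
  first <- TRUE
  for (p in cohort$phages) {
    df <- data.frame(phage_id = p$genome$id, orf_id = p$orfs$orf_id,
                     start_1based = p$orfs$start + 1L, end_1based = p$orfs$end,
                     strand = p$orfs$strand, label = p$orfs$label)
    write.table(df, orf_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = first, append = !first)
    first <- FALSE
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
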