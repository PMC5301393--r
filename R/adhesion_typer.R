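# Adhesion-module location, role assignment, architecture classification
# and sub-group I-IV calling.
#
# The adhesion module is the gene span from the tail tape measure protein
# (TMP) through to, but not including, the lysis cassette (holin + lysin).
# Roles are assigned by homology to a labelled reference panel; architecture
# classes come from size bands fitted between the populated size clusters of
# the four sub-group exemplars.

# Best panel hits for a set of proteins. Returns a data frame with one row
# per (protein, panel entry) pair that was evaluated and passed the score
# floor; identity/coverage thresholds are applied by callers.
panel_hits <- function(proteins, panel, config = scoring_config()) {
  stopifnot(length(proteins) >= 1, !is.null(names(proteins)))
  refs <- panel$proteins
  seqs <- c(unname(proteins), refs$protein)
  nq <- length(proteins)
  qlen <- nchar(proteins); rlen <- nchar(refs$protein)
  qi <- rep(seq_len(nq), each = nrow(refs))
  ri <- rep(seq_len(nrow(refs)), times = nq)
  thr <- similarity_thresholds(max_evalue = Inf,
                               min_identity = panel$min_identity,
                               min_coverage = panel$min_coverage)
  keep <- ratio_possible(qlen[qi], rlen[ri], thr)
  qi <- qi[keep]; ri <- ri[keep]
  if (length(qi) == 0) return(NULL)
  st <- sw_batch(seqs, cbind(qi, nq + ri), config, min_score = panel$min_score)
  ok <- !is.na(st$columns)
  if (!any(ok)) return(NULL)
  data.frame(
    query = names(proteins)[qi[ok]],
    ref_id = refs$id[ri[ok]], role = refs$role[ri[ok]],
    subgroup = refs$subgroup[ri[ok]],
    identity = st$matches[ok] / st$columns[ok],
    query_coverage = st$alen_a[ok] / qlen[qi[ok]],
    ref_coverage = st$alen_b[ok] / rlen[ri[ok]],
    score = st$score[ok], stringsAsFactors = FALSE)
}

qualifying_panel_hits <- function(proteins, panel, config = scoring_config()) {
  h <- panel_hits(proteins, panel, config)
  if (is.null(h)) return(NULL)
  h <- h[h$identity > panel$min_identity &
           pmin(h$query_coverage, h$ref_coverage) >= panel$min_coverage, ,
         drop = FALSE]
  if (nrow(h) == 0) NULL else h
}

#' Locate the adhesion module of a phage
#'
#' The TMP is the best panel-TMP homolog (fallback: the longest ORF of at
#' least 700 aa); the module runs from the TMP up to, but not including, the
#' first holin/lysin homolog downstream. With no detectable lysis cassette
#' the module extends to the genome end, with a warning.
#'
#' @param phage an [annotated_phage()].
#' @param panel a [reference_panel()].
#' @param config a [scoring_config()].
#' @return object of class `adhesion_module`: `phage_id`, `orfs` (the module
#'   span, ordered), `tmp_orf`, `panel_hits`, `truncated`.
#' @export
locate_module <- function(phage, panel = reference_panel(),
                          config = scoring_config()) {
  stopifnot(inherits(phage, "annotated_phage"))
  orfs <- phage$orfs
  if (nrow(orfs) == 0) stop("module not found: phage has no ORFs")
  prots <- setNames(orfs$protein, orfs$orf_id)
  hits <- qualifying_panel_hits(prots, panel, config)

  tmp_orf <- NULL
  if (!is.null(hits)) {
    th <- hits[hits$role == "tmp", , drop = FALSE]
    if (nrow(th)) tmp_orf <- th$query[which.max(th$score)]
  }
  if (is.null(tmp_orf)) {
    plen <- nchar(orfs$protein)
    big <- which(plen >= 700)
    if (length(big) == 0)
      stop(sprintf("module not found for phage '%s': no TMP homolog and no ORF >= 700 aa",
                   phage$genome$id))
    tmp_orf <- orfs$orf_id[big[which.max(plen[big])]]
  }
  tmp_idx <- match(tmp_orf, orfs$orf_id)

  lysis_idx <- integer(0)
  if (!is.null(hits)) {
    lh <- hits[hits$role %in% c("holin", "lysin"), , drop = FALSE]
    if (nrow(lh)) {
      idx <- match(unique(lh$query), orfs$orf_id)
      lysis_idx <- idx[idx > tmp_idx]
    }
  }
  truncated <- length(lysis_idx) == 0
  end_idx <- if (truncated) nrow(orfs) else min(lysis_idx) - 1L
  if (truncated)
    warning(sprintf("phage '%s': no lysis cassette found; module extends to genome end",
                    phage$genome$id))
  span <- orfs[tmp_idx:end_idx, , drop = FALSE]
  rownames(span) <- NULL
  structure(list(phage_id = phage$genome$id, orfs = span, tmp_orf = tmp_orf,
                 panel_hits = hits, truncated = truncated),
            class = "adhesion_module")
}

#' @export
print.adhesion_module <- function(x, ...) {
  cat(sprintf("<adhesion_module> %s: %d ORFs from %s%s\n", x$phage_id,
              nrow(x$orfs), x$tmp_orf,
              if (x$truncated) " (truncated: no lysis cassette)" else ""))
  if (!is.null(x$orfs$role))
    cat(" roles:", paste(x$orfs$role, collapse = " "), "\n")
  invisible(x)
}

SINGLETON_ROLES <- c("tmp", "dit", "tal", "tal_rbp_fused")

#' Assign component roles within an adhesion module
#'
#' Each ORF receives the role of its best-scoring qualifying panel hit;
#' unassigned ORFs are labelled `"unknown"`. A single ORF whose best hit is
#' the fused Tal-RBP reference sets the `fused_tal_rbp` arity. Canonical
#' gene order (TMP < Dit < Tal <= peripheral components) is enforced.
#'
#' @param module an [locate_module()] result.
#' @param panel a [reference_panel()].
#' @param config a [scoring_config()].
#' @return the module with a `role` column, `arity`, and `role_evidence`
#'   (best reference id per ORF).
#' @export
assign_roles <- function(module, panel = reference_panel(),
                         config = scoring_config()) {
  stopifnot(inherits(module, "adhesion_module"))
  orfs <- module$orfs
  prots <- setNames(orfs$protein, orfs$orf_id)
  hits <- qualifying_panel_hits(prots, panel, config)

  role <- setNames(rep("unknown", nrow(orfs)), orfs$orf_id)
  evidence <- setNames(rep(NA_character_, nrow(orfs)), orfs$orf_id)
  if (!is.null(hits)) {
    # homology restricted to the C-terminal RBP domain of a fused reference
    # marks a standalone RBP, not a fused Tal-RBP
    part <- hits$role == "tal_rbp_fused" & hits$ref_coverage < 0.7
    hits$role[part] <- "rbp"
    hits <- hits[order(hits$query, -hits$score, -hits$identity, hits$ref_id), ,
                 drop = FALSE]
    best <- hits[!duplicated(hits$query), , drop = FALSE]
    role[best$query] <- best$role
    evidence[best$query] <- sprintf("%s (identity %.2f)", best$ref_id,
                                    best$identity)
  }
  for (r in SINGLETON_ROLES) {
    claimants <- names(role)[role == r]
    if (length(claimants) > 1)
      stop(sprintf("ambiguous role '%s' in phage '%s': claimed by %s",
                   r, module$phage_id, paste(claimants, collapse = ", ")))
  }
  fused <- any(role == "tal_rbp_fused")
  if (!any(role == "dit"))
    stop(sprintf("phage '%s': no Dit identified in adhesion module",
                 module$phage_id))
  if (!any(role == "tal") && !fused)
    stop(sprintf("phage '%s': no Tal identified in adhesion module",
                 module$phage_id))

  pos <- setNames(seq_len(nrow(orfs)), orfs$orf_id)
  p_of <- function(r) pos[[names(role)[role == r][1]]]
  tal_pos <- if (fused) p_of("tal_rbp_fused") else p_of("tal")
  periph <- pos[names(role)[role %in% c("bppu", "bppa", "rbp")]]
  if (!(p_of("tmp") < p_of("dit") && p_of("dit") < tal_pos &&
        (length(periph) == 0 || all(tal_pos <= periph))))
    stop(sprintf("phage '%s': adhesion-module gene order violates TMP < Dit < Tal <= peripherals",
                 module$phage_id))

  module$orfs$role <- unname(role)
  module$role_evidence <- evidence
  module$arity <- if (fused) "fused_tal_rbp"
                  else if (any(role == "bppu")) "multi_component_baseplate"
                  else "single_component_RBP"
  module
}

nearest_band <- function(len, bands) {
  # bands: named vector of representative boundary midpoints
  names(bands)[which.min(abs(bands - len))]
}

#' Classify baseplate architecture from component sizes
#'
#' Dit classes: classical (<= 270 aa), classical_p2 (271-350), evolved
#' (>= 450); lengths in the unpopulated 351-449 gap go to the nearest band
#' with a warning. Tal: long peptidoglycan-hydrolase form (>= 850), short
#' p2-like form (<= 450), or fused with the RBP; the 451-849 gap resolves to
#' the nearest band with a warning. BppU is extended above 400 aa.
#'
#' @param module a role-assigned [assign_roles()] module.
#' @param panel a [reference_panel()] (size-band source).
#' @return object of class `architecture_call`: `dit_class`, `tal_class`,
#'   `bppu_class`, `bppa_present`, `rbp_size_aa`, `arity`.
#' @export
classify_architecture <- function(module, panel = reference_panel()) {
  stopifnot(inherits(module, "adhesion_module"))
  if (is.null(module$orfs$role))
    stop("assign_roles() must be applied before classify_architecture()")
  orfs <- module$orfs
  len_of <- function(r) {
    i <- which(orfs$role == r)
    if (length(i) == 0) NA_integer_ else nchar(orfs$protein[i[1]])
  }
  fused <- identical(module$arity, "fused_tal_rbp")
  dit_len <- len_of("dit")
  tal_len <- if (fused) len_of("tal_rbp_fused") else len_of("tal")
  if (is.na(dit_len)) stop("missing Dit: architecture undefined")
  if (is.na(tal_len)) stop("missing Tal: architecture undefined")

  b <- panel$dit_bands
  dit_class <- if (dit_len <= b[["classical_max"]]) "classical"
    else if (dit_len <= b[["classical_p2_max"]]) "classical_p2"
    else if (dit_len >= b[["evolved_min"]]) "evolved"
    else {
      cl <- nearest_band(dit_len, c(classical_p2 = b[["classical_p2_max"]],
                                    evolved = b[["evolved_min"]]))
      warning(sprintf("Dit length %d aa falls in a band gap; using nearest band '%s'",
                      dit_len, cl))
      cl
    }
  tal_class <- if (fused) "fused_with_RBP"
    else if (tal_len >= panel$tal_long_min) "long_PGNase"
    else if (tal_len <= panel$tal_short_max) "short_p2like"
    else {
      cl <- nearest_band(tal_len, c(short_p2like = panel$tal_short_max,
                                    long_PGNase = panel$tal_long_min))
      warning(sprintf("Tal length %d aa falls in a band gap; using nearest band '%s'",
                      tal_len, cl))
      cl
    }
  bppu_len <- len_of("bppu")
  bppu_class <- if (is.na(bppu_len)) "absent"
    else if (bppu_len > panel$bppu_extended_min) "extended" else "classical"
  rbp_len <- if (fused) nchar(c_terminal_half(orfs$protein[orfs$role == "tal_rbp_fused"][1]))
             else len_of("rbp")
  structure(list(dit_class = dit_class, tal_class = tal_class,
                 bppu_class = bppu_class,
                 bppa_present = any(orfs$role == "bppa"),
                 rbp_size_aa = if (is.na(rbp_len)) 0L else as.integer(rbp_len),
                 arity = module$arity),
            class = "architecture_call")
}

#' Extract the RBP-bearing protein of a module
#'
#' @param module a role-assigned module.
#' @return list(protein, is_fused) or NULL when no RBP component exists.
#' @export
module_rbp <- function(module) {
  orfs <- module$orfs
  if (identical(module$arity, "fused_tal_rbp")) {
    list(protein = orfs$protein[orfs$role == "tal_rbp_fused"][1],
         is_fused = TRUE)
  } else if (any(orfs$role == "rbp")) {
    list(protein = orfs$protein[orfs$role == "rbp"][1], is_fused = FALSE)
  } else NULL
}

#' Assign the RBP sub-group of a receptor binding protein
#'
#' The best panel RBP hit with identity above the panel threshold over at
#' least the panel coverage wins; below threshold the call is `"novel"`.
#' Fused Tal-RBPs (candidate or reference) are compared on their C-terminal
#' half only, where the receptor-interacting domain lives. Ties resolve by
#' higher identity, then panel order I < II < III < IV.
#'
#' @param rbp_protein amino-acid string.
#' @param panel a [reference_panel()].
#' @param is_fused is the candidate a fused Tal-RBP?
#' @param config a [scoring_config()].
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`, `"novel"`.
#' @export
assign_rbp_subgroup <- function(rbp_protein, panel = reference_panel(),
                                is_fused = FALSE, config = scoring_config()) {
  validate_protein(rbp_protein, "rbp_protein")
  cand <- if (is_fused) c_terminal_half(rbp_protein) else rbp_protein
  refs <- do.call(rbind, lapply(SUBGROUPS, function(sg) {
    data.frame(subgroup = sg, protein = rbp_reference_protein(panel, sg),
               stringsAsFactors = FALSE)
  }))
  prots <- setNames(refs$protein, paste0("sg", refs$subgroup))
  minipanel <- panel
  minipanel$proteins <- data.frame(id = names(prots), role = "rbp",
                                   subgroup = refs$subgroup, protein = prots,
                                   stringsAsFactors = FALSE)
  h <- qualifying_panel_hits(setNames(cand, "candidate"), minipanel, config)
  if (is.null(h)) return("novel")
  h <- h[order(-h$score, -h$identity, match(h$subgroup, SUBGROUPS)), ,
         drop = FALSE]
  h$subgroup[1]
}

#' Assemble the final sub-group assignment of a phage
#'
#' @param phage_id phage identifier.
#' @param proteome_group group id from [group_phages()] (NA when grouping
#'   was skipped).
#' @param proteome_subgroup sub-group label carried by the phage's proteome
#'   group (NA when undefined).
#' @param architecture an [classify_architecture()] call.
#' @param rbp_subgroup from [assign_rbp_subgroup()].
#' @return one-row data frame of class `subgroup_assignment` with a
#'   `concordant` flag (NA when either label is undefined).
#' @export
assemble_assignment <- function(phage_id, proteome_group, proteome_subgroup,
                                architecture, rbp_subgroup) {
  concordant <- if (is.na(proteome_subgroup) || is.na(rbp_subgroup)) NA
                else identical(proteome_subgroup, rbp_subgroup)
  out <- data.frame(phage_id = phage_id,
                    proteome_group = proteome_group,
                    proteome_subgroup = proteome_subgroup,
                    rbp_subgroup = rbp_subgroup,
                    dit_class = architecture$dit_class,
                    tal_class = architecture$tal_class,
                    bppu_class = architecture$bppu_class,
                    bppa_present = architecture$bppa_present,
                    rbp_size_aa = architecture$rbp_size_aa,
                    arity = architecture$arity,
                    concordant = concordant,
                    stringsAsFactors = FALSE)
  class(out) <- c("subgroup_assignment", class(out))
  out
}
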