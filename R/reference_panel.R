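# Labelled reference panel for adhesion-module typing.
#
# The panel stands in for structural-domain assignment: each adhesion-module
# role (TMP, Dit, Tal, BppU, BppA, BppL/RBP, fused Tal-RBP) has one labelled
# representative per sub-group, at the component sizes characteristic of the
# sub-group exemplars, plus shared holin/lysin references marking the lysis
# cassette. The shipped panel is SYNTHETIC: reference proteins are
# deterministic pseudo-random sequences of the documented lengths, generated
# from fixed seeds, so the whole pipeline runs offline; real reference
# proteins can be supplied via read_panel_fasta().

# component sizes (aa) per sub-group exemplar used by the synthetic panel
# and as phage-template defaults: I = BK5-T (evolved Dit, fused Tal-RBP),
# II = Tuc2009 (multi-component baseplate), III = LC3, IV = BM13.
TEMPLATE_SIZES <- list(
  I   = c(tmp = 900, dit = 548, tal_rbp_fused = 1904),
  II  = c(tmp = 900, dit = 253, tal = 906, bppu = 322, bppa = 286, rbp = 173),
  III = c(tmp = 900, dit = 298, tal = 385, rbp = 343),
  IV  = c(tmp = 900, dit = 290, tal = 371, rbp = 342)
)
LYSIS_SIZES <- c(holin = 85, lysin = 250)
SUBGROUPS <- c("I", "II", "III", "IV")

panel_seed <- function(role, subgroup) {
  # fixed, collision-free seeds so the panel is identical in every session
  r <- match(role, c("tmp", "dit", "tal", "bppu", "bppa", "rbp",
                     "tal_rbp_fused", "holin", "lysin"))
  s <- match(subgroup, c(SUBGROUPS, "all"))
  100000L + 97L * r + 11L * s
}

#' The default (synthetic) adhesion-module reference panel
#'
#' @param min_identity identity fraction a panel hit must strictly exceed
#'   (default 0.3, the weakest homology tier used for RBP relatedness).
#' @param min_coverage coverage both sequences must reach (default 0.5).
#' @param min_score raw Smith-Waterman score below which panel hits are not
#'   evaluated (cheap noise floor; default 40).
#' @return object of class `reference_panel`: `proteins` data frame
#'   (`id`, `role`, `subgroup`, `protein`), thresholds, and the Dit/Tal/BppU
#'   size-band boundaries used by [classify_architecture()].
#' @export
reference_panel <- function(min_identity = 0.3, min_coverage = 0.5,
                            min_score = 40) {
  key <- sprintf("panel_%s_%s_%s", min_identity, min_coverage, min_score)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  rows <- list()
  add <- function(role, subgroup, len) {
    id <- sprintf("ref_%s_%s", subgroup, role)
    rows[[length(rows) + 1L]] <<-
      data.frame(id = id, role = role, subgroup = subgroup,
                 protein = random_protein(len, seed = panel_seed(role, subgroup)),
                 stringsAsFactors = FALSE)
  }
  for (sg in SUBGROUPS)
    for (role in names(TEMPLATE_SIZES[[sg]]))
      add(role, sg, TEMPLATE_SIZES[[sg]][[role]])
  for (role in names(LYSIS_SIZES)) add(role, "all", LYSIS_SIZES[[role]])
  # the sub-group I RBP moiety (C-terminal half of the fused Tal-RBP) also
  # stands alone in the panel so that standalone BK5-T-like RBP genes are
  # recognised at full coverage
  pr <- do.call(rbind, rows)
  fused <- pr$protein[pr$role == "tal_rbp_fused" & pr$subgroup == "I"]
  rows[[length(rows) + 1L]] <-
    data.frame(id = "ref_I_rbp", role = "rbp", subgroup = "I",
               protein = c_terminal_half(fused), stringsAsFactors = FALSE)
  panel <- structure(
    list(proteins = do.call(rbind, rows),
         min_identity = min_identity, min_coverage = min_coverage,
         min_score = min_score,
         dit_bands = c(classical_max = 270, classical_p2_max = 350,
                       evolved_min = 450),
         tal_long_min = 850, tal_short_max = 450, bppu_extended_min = 400),
    class = "reference_panel")
  .pkg_cache[[key]] <- panel
  panel
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d labelled references (identity > %.2f, coverage >= %.2f)\n",
              nrow(x$proteins), x$min_identity, x$min_coverage))
  invisible(x)
}

# the RBP-like seed protein for a sub-group: the standalone RBP for II-IV,
# the C-terminal half of the fused Tal-RBP for sub-group I
rbp_reference_protein <- function(panel, subgroup) {
  pr <- panel$proteins
  if (subgroup == "I") {
    fused <- pr$protein[pr$role == "tal_rbp_fused" & pr$subgroup == "I"]
    c_terminal_half(fused)
  } else {
    pr$protein[pr$role == "rbp" & pr$subgroup == subgroup]
  }
}

c_terminal_half <- function(protein) {
  n <- nchar(protein)
  substr(protein, n %/% 2 + 1L, n)
}

#' Write or read a reference panel as labelled FASTA
#'
#' Headers carry the role and sub-group: `>id role=<role> subgroup=<sg>`.
#' Thresholds and size bands travel in a JSON sidecar written next to the
#' FASTA (same path with extension `.json`).
#'
#' @param panel a [reference_panel()].
#' @param path FASTA path.
#' @return `path` (write); a `reference_panel` (read).
#' @export
write_panel_fasta <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(panel$proteins))) {
    p <- panel$proteins[k, ]
    writeLines(sprintf(">%s role=%s subgroup=%s", p$id, p$role, p$subgroup), con)
    n <- nchar(p$protein)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(p$protein, starts, pmin(starts + 69L, n)), con)
  }
  meta <- panel[setdiff(names(panel), "proteins")]
  meta <- lapply(meta, function(v) if (length(v) > 1) as.list(v) else v)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  get_field <- function(h, f) {
    m <- regmatches(h, regexec(sprintf("%s=(\\S+)", f), h))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  pr <- data.frame(
    id = vapply(strsplit(hdr, "\\s+"), `[`, "", 1),
    role = vapply(hdr, get_field, "", f = "role"),
    subgroup = vapply(hdr, get_field, "", f = "subgroup"),
    protein = as.character(set), stringsAsFactors = FALSE)
  rownames(pr) <- NULL
  if (anyNA(pr$role) || anyNA(pr$subgroup))
    stop("panel FASTA headers must carry role= and subgroup= fields")
  if (anyDuplicated(pr$id)) stop("duplicate panel ids")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  panel <- reference_panel()
  panel$proteins <- pr
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.list(v) && all(vapply(v, is.numeric, logical(1)))) v <- unlist(v)
    panel[[nm]] <- v
  }
  panel
}
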