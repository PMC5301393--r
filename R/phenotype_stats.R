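# Efficiency of plaquing, calcium-dependence and antibody-neutralisation
# classification, and host-range x CWPS cross-tabulation.

#' Titre from plaque-assay records
#'
#' Point estimate `sum(counts) / sum(volumes)` (equal to mean(count)/volume
#' for equal volumes) with an exact Poisson 95% interval on the summed
#' counts. A zero total count is censored at the detection limit
#' `1 / total volume` rather than given a point value.
#'
#' @param assays data frame of records for one phage and condition:
#'   `phage_id`, `condition`, `plaque_count`, `volume_plated_ml`,
#'   `replicate`.
#' @param normalize allow mixed plated volumes (summing counts over the
#'   total volume); without it mixed volumes are an error.
#' @return object of class `phage_titre`: `estimate` (pfu/ml, NA when
#'   censored), `lower`, `upper`, `censored`, `bound` (upper bound when
#'   censored), `total_count`, `total_volume_ml`.
#' @export
titre <- function(assays, normalize = FALSE) {
  need <- c("phage_id", "condition", "plaque_count", "volume_plated_ml")
  miss <- setdiff(need, names(assays))
  if (length(miss))
    stop(sprintf("assay records missing columns: %s", paste(miss, collapse = ", ")))
  if (nrow(assays) < 1) stop("at least one replicate required")
  if (length(unique(assays$phage_id)) > 1 ||
      length(unique(assays$condition)) > 1)
    stop("titre() expects records for a single phage and condition")
  if (any(assays$plaque_count < 0) || any(assays$volume_plated_ml <= 0))
    stop("counts must be >= 0 and volumes > 0")
  vols <- unique(assays$volume_plated_ml)
  if (length(vols) > 1 && !normalize)
    stop("mixed plated volumes; pass normalize = TRUE to pool over total volume")
  total <- sum(assays$plaque_count)
  V <- sum(assays$volume_plated_ml)
  censored <- total == 0
  # exact Poisson 95% CI (Garwood): gamma quantiles on the summed count
  lower <- if (total == 0) 0 else qgamma(0.025, total) / V
  upper <- qgamma(0.975, total + 1) / V
  structure(list(phage_id = assays$phage_id[1],
                 condition = assays$condition[1],
                 estimate = if (censored) NA_real_ else total / V,
                 lower = lower, upper = upper,
                 censored = censored,
                 bound = if (censored) 1 / V else NA_real_,
                 total_count = total, total_volume_ml = V),
            class = "phage_titre")
}

#' @export
print.phage_titre <- function(x, ...) {
  if (x$censored)
    cat(sprintf("<phage_titre> %s [%s]: censored, < %.3g pfu/ml\n",
                x$phage_id, x$condition, x$bound))
  else
    cat(sprintf("<phage_titre> %s [%s]: %.3g pfu/ml (95%% CI %.3g-%.3g)\n",
                x$phage_id, x$condition, x$estimate, x$lower, x$upper))
  invisible(x)
}

#' Efficiency of plaquing relative to a reference condition
#'
#' `eop = titre(test) / titre(reference)`; `log10_reduction = -log10(eop)`.
#' A censored test titre yields a bound (`eop <=`, `reduction >=`) and the
#' category `no_plaques` (flagged indeterminate when the bound does not
#' reach the dependence threshold). An uncensored reduction of at least
#' `dependent_log` (default 4) classifies the phage as dependent on the
#' reference condition, otherwise independent. EOP above 1 is allowed but
#' flagged.
#'
#' @param titre_test,titre_reference [titre()] objects; the reference must
#'   be uncensored.
#' @param dependent_log log10 reduction at or above which the phage is
#'   classified dependent.
#' @param phage_id identifier carried into the result.
#' @return object of class `eop_result`: `eop`, `eop_is_bound`,
#'   `log10_reduction`, `reduction_is_bound`, `category`
#'   (independent / dependent / no_plaques), `flags`.
#' @export
compute_eop <- function(titre_test, titre_reference, dependent_log = 4,
                        phage_id = titre_test$phage_id) {
  stopifnot(inherits(titre_test, "phage_titre"),
            inherits(titre_reference, "phage_titre"))
  if (titre_reference$censored)
    stop("reference titre is censored; EOP undefined")
  ref <- titre_reference$estimate
  if (ref <= 0) stop("reference titre must be positive")
  flags <- character(0)
  if (titre_test$censored) {
    eop <- titre_test$bound / ref
    red <- -log10(eop)
    indeterminate <- red < dependent_log
    if (indeterminate) flags <- c(flags, "indeterminate_bound")
    out <- list(phage_id = phage_id, eop = eop, eop_is_bound = TRUE,
                log10_reduction = red, reduction_is_bound = TRUE,
                category = "no_plaques", flags = flags)
  } else {
    eop <- titre_test$estimate / ref
    if (eop > 1) flags <- c(flags, "eop_above_1")
    red <- -log10(eop)
    out <- list(phage_id = phage_id, eop = eop, eop_is_bound = FALSE,
                log10_reduction = red, reduction_is_bound = FALSE,
                category = if (red >= dependent_log) "dependent" else "independent",
                flags = flags)
  }
  structure(out, class = "eop_result")
}

#' @export
print.eop_result <- function(x, ...) {
  cat(sprintf("<eop_result> %s: EOP %s%.3g (%s%.2f log), %s%s\n", x$phage_id,
              if (x$eop_is_bound) "<= " else "", x$eop,
              if (x$reduction_is_bound) ">= " else "", x$log10_reduction,
              x$category,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Antibody-neutralisation classification
#'
#' EOP of the antibody-treated lysate relative to the water control, tiered
#' as strong (>= `strong_log`, default 4), partial (>= `partial_log`,
#' default 2) or not_neutralized. A pre-bleed serum control whose own EOP
#' departs from 1 by more than `nonspecific_log` (default 0.5 log) flags the
#' result non-specific.
#'
#' @param titre_antibody,titre_water [titre()] objects (water control
#'   mandatory).
#' @param titre_prebleed optional pre-bleed control titre.
#' @param partial_log,strong_log,nonspecific_log tier thresholds (log10).
#' @return an `eop_result` with fields `tier` and `non_specific`.
#' @export
neutralization <- function(titre_antibody, titre_water, titre_prebleed = NULL,
                           partial_log = 2, strong_log = 4,
                           nonspecific_log = 0.5) {
  if (missing(titre_water) || is.null(titre_water))
    stop("water control titre is required")
  res <- compute_eop(titre_antibody, titre_water, dependent_log = strong_log)
  red <- res$log10_reduction
  res$tier <- if (red >= strong_log) "strong"
              else if (red >= partial_log) "partial"
              else "not_neutralized"
  res$non_specific <- FALSE
  if (!is.null(titre_prebleed)) {
    pre <- compute_eop(titre_prebleed, titre_water, dependent_log = strong_log)
    if (pre$eop_is_bound || abs(log10(pre$eop)) > nonspecific_log) {
      res$non_specific <- TRUE
      res$flags <- c(res$flags, "non_specific")
    }
  }
  res
}

#' Construct a host-range matrix
#'
#' @param matrix logical phages x strains infection matrix (complete).
#' @param strain_types named character vector strain -> CWPS type in
#'   `{A, B, C, U}`.
#' @return object of class `host_range`.
#' @export
host_range <- function(matrix, strain_types) {
  if (anyNA(matrix)) stop("host-range matrix must be complete (no NA)")
  if (is.null(colnames(matrix)) || is.null(rownames(matrix)))
    stop("host-range matrix needs phage row names and strain column names")
  types <- as.character(strain_types)[match(colnames(matrix),
                                            names(strain_types))]
  if (anyNA(types))
    stop("every strain column needs a CWPS type")
  if (!all(types %in% c("A", "B", "C", "U")))
    stop(sprintf("unknown CWPS type label: %s",
                 setdiff(types, c("A", "B", "C", "U"))[1]))
  structure(list(matrix = matrix == TRUE,
                 strain_types = setNames(types, colnames(matrix))),
            class = "host_range")
}

#' Host-range x CWPS cross-tabulation
#'
#' `strains_infected_by_type[t]` counts strains of CWPS type t infected by
#' at least one phage; `phages_infecting_type[t]` counts phages infecting at
#' least one strain of type t.
#'
#' @param hr a [host_range()].
#' @return object of class `cwps_crosstab` with the two named count vectors.
#' @export
crosstab <- function(hr) {
  stopifnot(inherits(hr, "host_range"))
  m <- hr$matrix
  types <- hr$strain_types[colnames(m)]   # robust to column permutation
  lev <- c("A", "B", "C", "U")
  strains_infected <- setNames(integer(4), lev)
  phages_infecting <- setNames(integer(4), lev)
  for (t in lev) {
    cols <- which(types == t)
    if (length(cols)) {
      sub <- m[, cols, drop = FALSE]
      strains_infected[[t]] <- sum(colSums(sub) > 0)
      phages_infecting[[t]] <- sum(rowSums(sub) > 0)
    }
  }
  structure(list(strains_infected_by_type = strains_infected,
                 phages_infecting_type = phages_infecting,
                 n_phages = nrow(m), n_strains = ncol(m)),
            class = "cwps_crosstab")
}

#' @export
print.cwps_crosstab <- function(x, ...) {
  cat(sprintf("<cwps_crosstab> %d phages x %d strains\n", x$n_phages,
              x$n_strains))
  cat(" strains infected by type:",
      paste(sprintf("%s=%d", names(x$strains_infected_by_type),
                    x$strains_infected_by_type), collapse = " "), "\n")
  cat(" phages infecting type:   ",
      paste(sprintf("%s=%d", names(x$phages_infecting_type),
                    x$phages_infecting_type), collapse = " "), "\n")
  invisible(x)
}

#' Read or write host-range data as TSV (matrix + strain-type sidecar)
#'
#' @param hr a [host_range()] (write).
#' @param path matrix TSV path; the sidecar is `<path>.types.tsv`.
#' @return `path` (write); a `host_range` (read).
#' @export
write_host_range <- function(hr, path) {
  write.table(hr$matrix * 1L, path, sep = "\t", quote = FALSE)
  write.table(data.frame(strain = names(hr$strain_types),
                         cwps_type = hr$strain_types),
              paste0(path, ".types.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_host_range
#' @export
read_host_range <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  ty <- read.delim(paste0(path, ".types.tsv"), stringsAsFactors = FALSE)
  host_range(m == 1, setNames(ty$cwps_type, ty$strain))
}

#' Read plaque-assay records from TSV
#'
#' Columns: phage_id, condition, plaque_count, volume_plated_ml, replicate.
#'
#' @param path TSV path.
#' @return data frame of assay records.
#' @export
read_plaque_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
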