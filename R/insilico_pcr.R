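# In silico single-pair and multiplex PCR: primer-site search, amplicon
# prediction, P335 sub-group typing and CWPS strain typing.
#
# Matching is exact by default (the conservative in silico analogue of a
# wet-validated assay); when mismatches are allowed, the 3'-terminal bases
# of each primer must still match exactly. Multiplex reactions are simulated
# as independent single-pair reactions; primer competition is out of scope.

#' Construct a primer pair
#'
#' @param name pair name.
#' @param forward,reverse primer sequences written 5'->3' (>= 15 nt,
#'   `{A,C,G,T}` only).
#' @param expected_size_bp expected product size (NA when unvalidated).
#' @param label target label called when the expected size amplifies
#'   (sub-group or CWPS type).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_size_bp = NA,
                        label = NA_character_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stop(sprintf("primer in pair '%s' shorter than 15 nt", name))
    if (grepl("[^ACGT]", p))
      stop(sprintf("primer in pair '%s' contains non-ACGT characters", name))
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_size_bp = if (is.na(expected_size_bp)) NA_integer_
                                    else as.integer(expected_size_bp),
                 label = label),
            class = "primer_pair")
}

#' The published seven-pair P335 typing panel
#'
#' Primer pairs designed on the RBP/baseplate-encoding genes of
#' representatives of the four P335 sub-groups, with their expected product
#' sizes. The Tuc2009U pair detects BppU-encoding elements and carries no
#' validated product size: its amplicons are reported as unvalidated.
#'
#' @return named list of [primer_pair()] objects.
#' @export
p335_panel <- function() {
  list(
    `62503` = primer_pair("62503", "gaccgtgaatatagttctgatgaat",
                          "gtagtaattccgatttcccattctc", 784,
                          "sub-group IV"),
    `98101` = primer_pair("98101", "gacagaacattttataacactatccac",
                          "caaactgtaacgcattatcactggc", 268,
                          "sub-group II (single-component)"),
    `53801` = primer_pair("53801", "caaagatgggaagatagagagta",
                          "cctcgtggtgcgccggt", 554,
                          "sub-group II (multi-component)"),
    `98204` = primer_pair("98204", "gcctttggagctttttcggttgat",
                          "gcgccgttaggtatattatcc", 412,
                          "sub-group II (single-component)"),
    LC3 = primer_pair("LC3", "cgttgaagtaaatggaagcttaac",
                      "gaggatatttccccaccaattg", 128,
                      "sub-group III"),
    `38502` = primer_pair("38502", "gatagtgaatctccgggagcg",
                          "atcactgattgttactgtgtcccc", 1002,
                          "sub-group I"),
    Tuc2009U = primer_pair("Tuc2009U", "catgcggatgtcaatagtcaagcc",
                           "gtatcaaatccattcgcttcggttc", NA,
                           "sub-group II (BppU-positive)")
  )
}

#' A synthetic CWPS strain-typing panel
#'
#' The CWPS multiplex scheme types *L. lactis* strains as A, B or C from
#' product sizes 442, 183 and 686 bp, with an 891 bp rmlB positive control.
#' The published primer sequences are not part of this package; this panel
#' carries SYNTHETIC primer sequences with the published product sizes, for
#' use with genomes whose sites were planted by [plant_primer_sites()].
#' Supply your own panel for real genomes.
#'
#' @return named list of [primer_pair()] objects with labels A, B, C,
#'   control.
#' @export
synthetic_cwps_panel <- function() {
  mkp <- function(name, size, label, seed) {
    primer_pair(name, random_dna(24, 0.5, seed), random_dna(24, 0.5, seed + 1),
                size, label)
  }
  list(cwpsA = mkp("cwpsA", 442, "A", 210001L),
       cwpsB = mkp("cwpsB", 183, "B", 210003L),
       cwpsC = mkp("cwpsC", 686, "C", 210005L),
       rmlB = mkp("rmlB", 891, "control", 210007L))
}

#' In silico matching parameters
#'
#' @param max_mismatches mismatches tolerated per primer site (3' anchor
#'   excluded).
#' @param three_prime_exact_nt 3'-terminal bases that must match exactly.
#' @param max_product_bp maximum amplicon size considered.
#' @param size_tolerance_bp gel-resolution analogue for label calling.
#' @return a `match_params` list.
#' @export
match_params <- function(max_mismatches = 0L, three_prime_exact_nt = 5L,
                         max_product_bp = 5000L, size_tolerance_bp = 20L) {
  stopifnot(max_mismatches >= 0, three_prime_exact_nt >= 0,
            max_product_bp >= 1, size_tolerance_bp >= 0)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_exact_nt = as.integer(three_prime_exact_nt),
                 max_product_bp = as.integer(max_product_bp),
                 size_tolerance_bp = as.integer(size_tolerance_bp)),
            class = "match_params")
}

# mismatch counts of `pattern` against every window of `gchars`
# (vectorised over window positions; N in the genome never matches)
window_mismatches <- function(gchars, pattern) {
  pl <- nchar(pattern)
  n <- length(gchars)
  if (n < pl) return(integer(0))
  pch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  npos <- n - pl + 1L
  mm <- integer(npos)
  for (k in seq_len(pl))
    mm <- mm + (gchars[k:(k + npos - 1L)] != pch[k])
  mm
}

#' Find primer binding sites
#'
#' Reports all positions where the primer (plus strand) or its reverse
#' complement (minus strand) matches with at most `max_mismatches`
#' mismatches, requiring the 3'-terminal `three_prime_exact_nt` bases to
#' match exactly. Circular genomes wrap across the origin.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param primer primer sequence (5'->3').
#' @param params a [match_params()].
#' @return data frame: `position` (0-based start of the matched window on
#'   the plus strand), `strand`, `mismatches`.
#' @export
find_primer_sites <- function(genome, primer, params = match_params()) {
  seq <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  circular <- inherits(genome, "genome_record") &&
    genome$topology == "circular"
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer)) stop("primer contains non-ACGT characters")
  pl <- nchar(primer)
  L <- nchar(seq)
  scan_seq <- if (circular && L >= pl) paste0(seq, substr(seq, 1, pl - 1L)) else seq
  gchars <- strsplit(scan_seq, "", fixed = TRUE)[[1]]
  a <- min(params$three_prime_exact_nt, pl)

  scan_one <- function(pattern, anchor_at_start) {
    mm <- window_mismatches(gchars, pattern)
    hit <- which(mm <= params$max_mismatches)
    if (a > 0 && length(hit)) {
      anchor <- if (anchor_at_start) substr(pattern, 1, a)
                else substr(pattern, pl - a + 1L, pl)
      offs <- if (anchor_at_start) 0L else pl - a
      ach <- strsplit(anchor, "", fixed = TRUE)[[1]]
      ok <- vapply(hit, function(p) {
        all(gchars[(p + offs):(p + offs + a - 1L)] == ach)
      }, logical(1))
      hit <- hit[ok]
    }
    data.frame(position = hit - 1L, mismatches = mm[hit])
  }
  # plus strand: primer 3' end is the rightmost base of the window
  plus <- scan_one(primer, anchor_at_start = FALSE)
  # minus strand: the window holds revcomp(primer); the primer 3' end maps
  # to the leftmost base of the window
  minus <- scan_one(revcomp(primer), anchor_at_start = TRUE)
  out <- rbind(
    if (nrow(plus)) data.frame(position = plus$position, strand = "+",
                               mismatches = plus$mismatches),
    if (nrow(minus)) data.frame(position = minus$position, strand = "-",
                                mismatches = minus$mismatches))
  if (is.null(out))
    out <- data.frame(position = integer(), strand = character(),
                      mismatches = integer())
  out <- out[out$position < L, , drop = FALSE]   # circular: dedupe wrap copies
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict amplicons of a primer pair
#'
#' One amplicon is reported for every plus-strand site of one primer
#' upstream of a minus-strand site of the other within `max_product_bp`.
#' The amplicon spans the first base of the upstream site to the last base
#' of the downstream site (both primers counted, the standard product-size
#' convention). Linear genomes do not wrap; circular genomes do.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param pair a [primer_pair()].
#' @param params a [match_params()].
#' @return data frame: `pair_name`, `start`, `end` (0-based half-open),
#'   `length_bp`, `orientation` (strand carrying the forward primer).
#' @export
predict_amplicons <- function(genome, pair, params = match_params()) {
  stopifnot(inherits(pair, "primer_pair"))
  L <- if (inherits(genome, "genome_record")) nchar(genome$sequence) else nchar(genome)
  circular <- inherits(genome, "genome_record") &&
    genome$topology == "circular"
  fs <- find_primer_sites(genome, pair$forward, params)
  rs <- find_primer_sites(genome, pair$reverse, params)
  lf <- nchar(pair$forward); lr <- nchar(pair$reverse)

  combine <- function(up, up_len, down, down_len, orientation) {
    if (nrow(up) == 0 || nrow(down) == 0) return(NULL)
    out <- NULL
    for (i in seq_len(nrow(up))) {
      s <- up$position[i]
      ends <- down$position + down_len
      if (circular) ends <- ifelse(ends <= s, ends + L, ends)
      len <- ends - s
      ok <- len >= up_len + down_len & len <= params$max_product_bp
      if (any(ok))
        out <- rbind(out, data.frame(pair_name = pair$name, start = s,
                                     end = ends[ok], length_bp = len[ok],
                                     orientation = orientation))
    }
    out
  }
  amp <- rbind(
    combine(fs[fs$strand == "+", ], lf, rs[rs$strand == "-", ], lr, "+"),
    combine(rs[rs$strand == "+", ], lr, fs[fs$strand == "-", ], lf, "-"))
  if (is.null(amp))
    amp <- data.frame(pair_name = character(), start = integer(),
                      end = integer(), length_bp = integer(),
                      orientation = character())
  amp <- amp[order(amp$start, amp$length_bp), , drop = FALSE]
  rownames(amp) <- NULL
  amp
}

#' Simulate a multiplex PCR as independent single-pair reactions
#'
#' Labels are called when an amplicon's size falls within
#' `size_tolerance_bp` of the pair's expected size; amplicons of pairs
#' without a validated expected size call their label flagged
#' `"unvalidated"`. Multiple distinct called labels raise a conflict flag;
#' conflicts are reported, not resolved.
#'
#' @param genome a [genome_record()].
#' @param panel named list of [primer_pair()] objects.
#' @param params a [match_params()].
#' @return object of class `typing_result`: `genome_id`, `amplicons`,
#'   `called_labels`, `flags` (`size_mismatch`, `unvalidated`, `conflict`).
#' @export
simulate_multiplex <- function(genome, panel, params = match_params()) {
  stopifnot(length(panel) >= 1)
  nm <- vapply(panel, function(p) p$name, "")
  if (anyDuplicated(nm)) stop("duplicate pair names in panel")
  amps <- list(); labels <- character(0)
  size_mismatch <- character(0); unvalidated <- character(0)
  for (pair in panel) {
    a <- predict_amplicons(genome, pair, params)
    if (nrow(a) == 0) next
    amps[[pair$name]] <- a
    if (is.na(pair$expected_size_bp)) {
      labels <- c(labels, pair$label)
      unvalidated <- c(unvalidated, pair$name)
    } else {
      within <- abs(a$length_bp - pair$expected_size_bp) <=
        params$size_tolerance_bp
      if (any(within)) labels <- c(labels, pair$label)
      if (any(!within)) size_mismatch <- c(size_mismatch, pair$name)
    }
  }
  amplicons <- if (length(amps)) do.call(rbind, c(amps, make.row.names = FALSE))
    else data.frame(pair_name = character(), start = integer(),
                    end = integer(), length_bp = integer(),
                    orientation = character())
  labels <- unique(labels)
  structure(list(
    genome_id = if (inherits(genome, "genome_record")) genome$id else "genome",
    amplicons = amplicons, called_labels = labels,
    flags = list(size_mismatch = size_mismatch, unvalidated = unvalidated,
                 conflict = length(labels) > 1)),
    class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("<typing_result> %s: %d amplicons; labels: %s%s\n", x$genome_id,
              nrow(x$amplicons),
              if (length(x$called_labels)) paste(x$called_labels, collapse = ", ")
              else "(untyped)",
              if (x$flags$conflict) " [conflict]" else ""))
  invisible(x)
}

#' CWPS-type a strain genome by multiplex PCR
#'
#' The strain type is called from which type-specific product amplifies
#' within tolerance of its expected size (442 bp A, 183 bp B, 686 bp C);
#' the 891 bp rmlB control validates the assay. No type product with a
#' valid control gives `"unknown"`; a missing control invalidates the assay.
#'
#' @param strain_genome a [genome_record()].
#' @param cwps_panel named list of [primer_pair()] objects, labels in
#'   `{A, B, C, control}` (see [synthetic_cwps_panel()]).
#' @param params a [match_params()].
#' @return list: `type` (`"A"`, `"B"`, `"C"`, `"unknown"` or NA when
#'   invalid), `control_ok`, `valid`, `conflict`.
#' @export
cwps_type <- function(strain_genome, cwps_panel, params = match_params()) {
  labels <- vapply(cwps_panel, function(p) p$label, "")
  if (!"control" %in% labels)
    stop("CWPS panel must contain a positive-control pair (label 'control')")
  res <- simulate_multiplex(strain_genome, cwps_panel, params)
  control_ok <- "control" %in% res$called_labels
  types <- setdiff(res$called_labels, "control")
  if (!control_ok)
    return(list(type = NA_character_, control_ok = FALSE, valid = FALSE,
                conflict = FALSE))
  if (length(types) == 0)
    return(list(type = "unknown", control_ok = TRUE, valid = TRUE,
                conflict = FALSE))
  list(type = if (length(types) == 1) types else NA_character_,
       control_ok = TRUE, valid = TRUE, conflict = length(types) > 1)
}

#' Read or write a primer panel as TSV
#'
#' Columns: name, forward, reverse, expected_size (empty = unvalidated),
#' label.
#'
#' @param panel named list of [primer_pair()]s (write).
#' @param path TSV path.
#' @return `path` (write); a named list of [primer_pair()]s (read).
#' @export
write_panel_tsv <- function(panel, path) {
  df <- do.call(rbind, lapply(panel, function(p) {
    data.frame(name = p$name, forward = p$forward, reverse = p$reverse,
               expected_size = p$expected_size_bp, label = p$label)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(k) {
    primer_pair(df$name[k], df$forward[k], df$reverse[k],
                if (is.na(df$expected_size[k])) NA else df$expected_size[k],
                df$label[k])
  })
  setNames(out, df$name)
}
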