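# All-against-all pairwise protein comparison and bidirectional best hits.
#
# BLAST is not re-implemented; the comparison engine is Smith-Waterman local
# alignment (BLOSUM62, gap open 11 / extend 1, BLAST gap-cost convention)
# with Karlin-Altschul E-values. Identity uses the BLAST convention of
# counting gap columns in the denominator; coverage of a sequence is the
# number of its residues inside the aligned span divided by its length.

#' Alignment scoring configuration
#'
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend` (BLAST convention, defaults 11/1).
#' @param K,lambda Karlin-Altschul parameters for gapped BLOSUM62 11/1.
#' @param search_space E-value search space. `NULL` (default) uses query
#'   length x subject-database residues; [align_pair()] on its own uses
#'   query length x subject length.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(gap_open = 11, gap_extend = 1,
                           K = 0.041, lambda = 0.267, search_space = NULL) {
  stopifnot(gap_open >= 0, gap_extend >= 0, K > 0, lambda > 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 K = K, lambda = lambda, search_space = search_space),
            class = "scoring_config")
}

#' Similarity acceptance thresholds
#'
#' Retained hits must satisfy `evalue <= max_evalue`, `identity >
#' min_identity` (strict, "greater than 50 percent identity") and
#' `min(query_coverage, subject_coverage) >= min_coverage` ("across at
#' least 50 percent of the amino acid sequence", applied to both sequences).
#'
#' @param max_evalue maximum E-value (default 1e-4).
#' @param min_identity identity fraction that must be strictly exceeded.
#' @param min_coverage coverage fraction that must be reached by both
#'   sequences.
#' @return a `similarity_thresholds` list.
#' @export
similarity_thresholds <- function(max_evalue = 1e-4, min_identity = 0.5,
                                  min_coverage = 0.5) {
  stopifnot(max_evalue >= 0, min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_coverage = min_coverage),
            class = "similarity_thresholds")
}

karlin_evalue <- function(score, m, n, config) {
  config$K * m * n * exp(-config$lambda * score)
}

bit_score <- function(score, config) {
  (config$lambda * score - log(config$K)) / log(2)
}

# batch Smith-Waterman over index pairs; returns raw stats data frame
sw_batch <- function(seqs, pairs, config, min_score = 0) {
  sub <- blosum62()
  alphabet <- paste(rownames(sub), collapse = "")
  sw_align_batch(seqs, pairs, sub, alphabet,
                 config$gap_open, config$gap_extend, as.numeric(min_score))
}

hit_row <- function(query_id, subject_id, st, qlen, slen, config, n_db,
                    swapped = FALSE) {
  # st carries a = first sequence of the aligned pair; swap for b->a rows
  if (!swapped) {
    q_res <- st$alen_a; s_res <- st$alen_b
    qs <- st$a_start; qe <- st$a_end; ss <- st$b_start; se <- st$b_end
  } else {
    q_res <- st$alen_b; s_res <- st$alen_a
    qs <- st$b_start; qe <- st$b_end; ss <- st$a_start; se <- st$a_end
  }
  data.frame(query_id = query_id, subject_id = subject_id,
             identity = st$matches / st$columns,
             aln_length = st$columns,
             query_coverage = q_res / qlen,
             subject_coverage = s_res / slen,
             mismatches = st$mismatches, gap_opens = st$gap_opens,
             q_start = qs, q_end = qe, s_start = ss, s_end = se,
             score = st$score,
             evalue = karlin_evalue(st$score, qlen, n_db, config),
             bitscore = bit_score(st$score, config),
             stringsAsFactors = FALSE)
}

#' Align two proteins (Smith-Waterman local alignment)
#'
#' @param protein_a,protein_b amino-acid strings (20 residues + X).
#' @param config a [scoring_config()].
#' @return one-row data frame: `query_id`, `subject_id`, `identity`
#'   (identical columns / alignment columns, gaps included), `aln_length`,
#'   `query_coverage`, `subject_coverage`, alignment bounds, `score`,
#'   `evalue`, `bitscore`.
#' @export
align_pair <- function(protein_a, protein_b, config = scoring_config()) {
  validate_protein(protein_a, "protein_a")
  validate_protein(protein_b, "protein_b")
  st <- sw_batch(c(protein_a, protein_b), matrix(c(1L, 2L), nrow = 1), config)
  st <- as.list(st[1, ])
  # standalone search space defaults to m x n; a configured search_space
  # overrides the subject term so that E = K * search_space * exp(-lambda S)
  n_db <- if (is.null(config$search_space)) nchar(protein_b)
          else config$search_space / nchar(protein_a)
  hit_row("query", "subject", st, nchar(protein_a), nchar(protein_b),
          config, n_db)
}

#' Filter hits by similarity thresholds
#'
#' @param hits hit table as produced by [all_vs_all()].
#' @param thresholds a [similarity_thresholds()].
#' @return the retained rows.
#' @export
filter_hits <- function(hits, thresholds = similarity_thresholds()) {
  keep <- hits$evalue <= thresholds$max_evalue &
    hits$identity > thresholds$min_identity &
    pmin(hits$query_coverage, hits$subject_coverage) >= thresholds$min_coverage
  hits[keep, , drop = FALSE]
}

# Pairs whose length ratio provably cannot satisfy the identity/coverage
# thresholds are skipped: matches <= len_short and columns >= min_coverage *
# len_long give identity <= len_short / (min_coverage * len_long).
ratio_possible <- function(len_a, len_b, thresholds) {
  if (thresholds$min_coverage <= 0 || thresholds$min_identity <= 0)
    return(rep(TRUE, length(len_a)))
  short <- pmin(len_a, len_b); long <- pmax(len_a, len_b)
  short / (thresholds$min_coverage * long) > thresholds$min_identity
}

#' All-against-all protein comparison under acceptance thresholds
#'
#' Every cross-protein pair (self-hits excluded) is aligned once and both
#' orientations are reported when they pass the thresholds. The E-value
#' search space is fixed per run as query length x total residues in the
#' database (all input proteins).
#'
#' @param proteomes named list (phage id -> named character vector of
#'   proteins). Protein ids must be unique across the whole input.
#' @param thresholds a [similarity_thresholds()].
#' @param config a [scoring_config()].
#' @return data frame of retained hits with columns `query_id`,
#'   `subject_id`, `query_phage`, `subject_phage`, `identity`, `aln_length`,
#'   coverages, alignment bounds, `score`, `evalue`, `bitscore`.
#' @export
all_vs_all <- function(proteomes, thresholds = similarity_thresholds(),
                       config = scoring_config()) {
  stopifnot(is.list(proteomes), length(proteomes) >= 1)
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all proteins must be named")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protein ids across input: %s",
                 ids[anyDuplicated(ids)]))
  seqs <- unlist(proteomes, use.names = FALSE)
  for (k in seq_along(seqs)) validate_protein(seqs[k], ids[k])
  phage <- rep(names(proteomes), lengths(proteomes))
  lens <- nchar(seqs)
  n_db <- sum(lens)
  np <- length(seqs)
  if (np < 2) return(empty_hits())

  cmb <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
  ia <- cmb[, 1]; ib <- cmb[, 2]
  keep <- ratio_possible(lens[ia], lens[ib], thresholds)
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0) return(empty_hits())

  # score below which no orientation can reach max_evalue: skip traceback
  min_score <- if (thresholds$max_evalue > 0) {
    pmax(0, (log(config$K * pmax(lens[ia], lens[ib]) * n_db) -
               log(thresholds$max_evalue)) / config$lambda)
  } else rep(Inf, length(ia))

  st <- sw_batch(seqs, cbind(ia, ib), config, min_score)
  done <- !is.na(st$columns)
  if (!any(done)) return(empty_hits())
  rows <- vector("list", 2L * sum(done))
  r <- 0L
  for (k in which(done)) {
    stk <- as.list(st[k, ])
    i <- ia[k]; j <- ib[k]
    h1 <- hit_row(ids[i], ids[j], stk, lens[i], lens[j], config, n_db)
    h2 <- hit_row(ids[j], ids[i], stk, lens[j], lens[i], config, n_db,
                  swapped = TRUE)
    h1$query_phage <- phage[i]; h1$subject_phage <- phage[j]
    h2$query_phage <- phage[j]; h2$subject_phage <- phage[i]
    rows[[r + 1L]] <- h1; rows[[r + 2L]] <- h2
    r <- r + 2L
  }
  hits <- do.call(rbind, rows[seq_len(r)])
  hits <- filter_hits(hits, thresholds)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), aln_length = integer(),
             query_coverage = numeric(), subject_coverage = numeric(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             score = numeric(), evalue = numeric(), bitscore = numeric(),
             query_phage = character(), subject_phage = character(),
             stringsAsFactors = FALSE)
}

#' Bidirectional best hits
#'
#' For each ordered phage pair, each query's best-scoring subject is found
#' (ties broken by higher identity, then lexicographic subject id); a
#' protein pair is a BBH when each is the other's best hit.
#'
#' @param hits retained hit table from [all_vs_all()].
#' @return data frame of unordered pairs: `protein_a`, `protein_b` (sorted),
#'   `phage_a`, `phage_b`, `identity` (maximum over the two orientations),
#'   `score`.
#' @export
bidirectional_best_hits <- function(hits) {
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      phage_a = character(), phage_b = character(),
                      identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  h <- hits[hits$query_phage != hits$subject_phage, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  ord <- order(h$query_phage, h$subject_phage, h$query_id,
               -h$score, -h$identity, h$subject_id)
  h <- h[ord, , drop = FALSE]
  key <- paste(h$query_phage, h$subject_phage, h$query_id, sep = "\r")
  best <- h[!duplicated(key), , drop = FALSE]

  fwd <- paste(best$query_id, best$subject_id, sep = "\r")
  rev_ <- paste(best$subject_id, best$query_id, sep = "\r")
  is_bbh <- fwd %in% rev_
  b <- best[is_bbh, , drop = FALSE]
  if (nrow(b) == 0) return(empty)
  a_first <- b$query_id < b$subject_id
  pa <- ifelse(a_first, b$query_id, b$subject_id)
  pb <- ifelse(a_first, b$subject_id, b$query_id)
  fa <- ifelse(a_first, b$query_phage, b$subject_phage)
  fb <- ifelse(a_first, b$subject_phage, b$query_phage)
  out <- data.frame(protein_a = pa, protein_b = pb, phage_a = fa,
                    phage_b = fb, identity = b$identity, score = b$score,
                    stringsAsFactors = FALSE)
  key2 <- paste(out$protein_a, out$protein_b, sep = "\r")
  agg_id <- tapply(out$identity, key2, max)
  agg_sc <- tapply(out$score, key2, max)
  out <- out[!duplicated(key2), , drop = FALSE]
  k <- paste(out$protein_a, out$protein_b, sep = "\r")
  out$identity <- as.numeric(agg_id[k])
  out$score <- as.numeric(agg_sc[k])
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write or read a BLAST outfmt-6 style hit table
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore (tab-separated, no header).
#'
#' @param hits hit table from [all_vs_all()].
#' @param path TSV path.
#' @return `path` (write) or a hit table with the 12 standard columns (read).
#' @export
write_hits_outfmt6 <- function(hits, path) {
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                   pident = sprintf("%.3f", 100 * hits$identity),
                   length = hits$aln_length, mismatch = hits$mismatches,
                   gapopen = hits$gap_opens, qstart = hits$q_start,
                   qend = hits$q_end, sstart = hits$s_start,
                   send = hits$s_end,
                   evalue = format(hits$evalue, digits = 3, scientific = TRUE),
                   bitscore = sprintf("%.1f", hits$bitscore))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_outfmt6
#' @export
read_hits_outfmt6 <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  df
}
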