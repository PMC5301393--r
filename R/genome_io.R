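# Genome and annotation I/O, ORF finding, translation, genome statistics.
#
# Internal coordinates are 0-based half-open on the forward strand; GenBank
# and tabular input (1-based inclusive) are converted on read.

#' Construct a genome record
#'
#' @param id record identifier.
#' @param sequence DNA string over `{A,C,G,T,N}`; uppercased on input.
#' @param topology `"linear"` (default) or `"circular"`. Circular genomes
#'   wrap in ORF and primer-site scanning.
#' @param description free-text description.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular"),
                          description = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  validate_dna(sequence, sprintf("sequence of record '%s'", id))
  structure(list(id = id, sequence = sequence, topology = topology,
                 description = description),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s%s\n", x$id, nchar(x$sequence),
              x$topology,
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Read nucleotide FASTA
#'
#' Sequences are uppercased; characters outside `{A,C,G,T,N}` or empty
#' records raise a parse error naming the offending record. An empty file
#' yields an empty list.
#'
#' @param path FASTA file.
#' @param topology topology applied to all records.
#' @return list of [genome_record()] objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", lines))) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop(sprintf("not FASTA-formatted (no '>' header): %s", path))
  }
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    nm <- names(set)[k]
    if (is.na(nm) || !nzchar(trimws(nm)))
      stop(sprintf("record %d: malformed empty header", k))
    toks <- strsplit(trimws(nm), "\\s+")[[1]]
    id <- toks[1]
    desc <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
    seq <- as.character(set[[k]])
    if (!nzchar(seq)) stop(sprintf("record '%s': empty sequence", id))
    out[[k]] <- genome_record(id, seq, topology, desc)
  }
  out
}

#' Write genome records as FASTA (70-column wrap)
#'
#' @param records a `genome_record` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(r$sequence, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}

#' Translate a coding sequence (translation table 11)
#'
#' The initiator codon is always rendered as M when it is one of the allowed
#' start codons; a terminal stop codon is dropped; internal stop codons or
#' untranslatable (N-containing) codons are errors.
#'
#' @param dna in-frame coding DNA string (length divisible by 3).
#' @param starts codons rendered as M in first position.
#' @return amino-acid string.
#' @export
translate_cds <- function(dna, starts = c("ATG", "GTG", "TTG")) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0 || n %% 3 != 0)
    stop("coding sequence length must be a positive multiple of 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- genetic_code_11()
  aa <- unname(code[codons])
  if (anyNA(aa))
    stop(sprintf("untranslatable codon '%s'", codons[which(is.na(aa))[1]]))
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("internal stop codon in coding sequence")
  if (length(aa) == 0) stop("coding sequence encodes no residues")
  if (codons[1] %in% starts) aa[1] <- "M"
  paste(aa, collapse = "")
}

# build the ordered ORF table sorted by start, with validation
orf_table <- function(orf_id, start, end, strand, protein, label,
                      genome_len, circular = FALSE) {
  df <- data.frame(orf_id = as.character(orf_id), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   protein = as.character(protein), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (anyDuplicated(df$orf_id))
      stop("duplicate orf_id within phage")
    lim <- if (circular) 2L * genome_len else genome_len
    bad <- df$start < 0 | df$start >= df$end | df$end > lim
    if (any(bad))
      stop(sprintf("ORF '%s' has coordinates outside the genome",
                   df$orf_id[which(bad)[1]]))
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Construct an annotated phage
#'
#' @param genome a [genome_record()].
#' @param orfs data frame with columns `orf_id`, `start`, `end` (0-based
#'   half-open), `strand`, `protein`, `label`; re-ordered by start.
#' @param host optional host strain name.
#' @param metadata named list of free-form metadata.
#' @return object of class `annotated_phage`.
#' @export
annotated_phage <- function(genome, orfs, host = NULL, metadata = list()) {
  stopifnot(inherits(genome, "genome_record"))
  orfs <- orf_table(orfs$orf_id, orfs$start, orfs$end, orfs$strand,
                    orfs$protein, orfs$label %||% NA_character_,
                    nchar(genome$sequence),
                    circular = genome$topology == "circular")
  structure(list(genome = genome, orfs = orfs, host = host,
                 metadata = metadata),
            class = "annotated_phage")
}

#' @export
print.annotated_phage <- function(x, ...) {
  cat(sprintf("<annotated_phage> %s: %d bp, %d ORFs\n",
              x$genome$id, nchar(x$genome$sequence), nrow(x$orfs)))
  invisible(x)
}

#' Extract the proteome of an annotated phage
#'
#' @param phage an [annotated_phage()].
#' @return named character vector of protein sequences (names are ORF ids).
#' @export
proteome <- function(phage) {
  stopifnot(inherits(phage, "annotated_phage"))
  setNames(phage$orfs$protein, phage$orfs$orf_id)
}

#' Read ORF annotations (GenBank CDS features or tabular TSV)
#'
#' GenBank flat files are parsed for CDS features only; `/translation`
#' qualifiers are used when present, otherwise the span is translated with
#' table 11. The tabular format has columns `phage_id`, `orf_id`,
#' `start_1based`, `end_1based`, `strand`, `label`. Both use 1-based
#' inclusive coordinates, converted to 0-based half-open on read.
#'
#' @param path annotation file.
#' @param genome the corresponding [genome_record()].
#' @param format `"auto"`, `"genbank"` or `"tsv"`.
#' @return an [annotated_phage()].
#' @export
read_annotations <- function(path, genome, format = c("auto", "genbank", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(genome, "genome_record"))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^(LOCUS|FEATURES)", lines))) "genbank" else "tsv"
  }
  if (format == "genbank") parse_genbank_cds(lines, genome)
  else parse_orf_tsv(path, genome)
}

parse_orf_tsv <- function(path, genome) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("phage_id", "orf_id", "start_1based", "end_1based", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("ORF table missing columns: %s", paste(miss, collapse = ", ")))
  df <- df[df$phage_id == genome$id, , drop = FALSE]
  L <- nchar(genome$sequence)
  prot <- character(nrow(df))
  for (k in seq_len(nrow(df))) {
    s0 <- df$start_1based[k] - 1L; e0 <- df$end_1based[k]
    if (s0 < 0 || e0 > L || s0 >= e0)
      stop(sprintf("ORF '%s' outside genome bounds", df$orf_id[k]))
    span <- substr(genome$sequence, s0 + 1L, e0)
    if (df$strand[k] == "-") span <- revcomp(span)
    prot[k] <- translate_cds(span)
  }
  annotated_phage(genome,
                  data.frame(orf_id = df$orf_id, start = df$start_1based - 1L,
                             end = df$end_1based, strand = df$strand,
                             protein = prot,
                             label = df$label %||% NA_character_,
                             stringsAsFactors = FALSE))
}

parse_genbank_cds <- function(lines, genome) {
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) stop("no FEATURES section in GenBank file")
  body <- lines[(fstart[1] + 1):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1)]

  feat_idx <- grep("^ {5}\\S", body)
  if (length(feat_idx) == 0) stop("no features found in GenBank file")
  bounds <- c(feat_idx, length(body) + 1L)
  L <- nchar(genome$sequence)
  recs <- list()
  for (k in seq_along(feat_idx)) {
    block <- body[feat_idx[k]:(bounds[k + 1] - 1L)]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (key != "CDS") next
    # location may continue over lines until the first qualifier
    qual_start <- grep("^ {10,}/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- paste(gsub("\\s+", "", c(sub("^ {5}\\S+\\s*", "", block[1]),
                                    if (loc_end >= 2) block[2:loc_end] else character())),
                 collapse = "")
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order|complement", loc))
      stop(sprintf("unsupported compound CDS location: %s", loc))
    m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
    if (length(m) != 3) stop(sprintf("cannot parse CDS location: %s", loc))
    s1 <- as.integer(m[2]); e1 <- as.integer(m[3])
    if (s1 < 1 || e1 > L || s1 > e1)
      stop(sprintf("CDS %s outside genome bounds (genome length %d)", loc, L))

    quals <- paste(block[-seq_len(loc_end)], collapse = "\n")
    get_qual <- function(name) {
      pat <- sprintf('/%s="([^"]*)"', name)
      mm <- regmatches(quals, regexec(pat, quals))[[1]]
      if (length(mm) == 2) gsub("[\\s\n ]+", "", mm[2]) else NA_character_
    }
    get_qual_text <- function(name) {
      pat <- sprintf('/%s="([^"]*)"', name)
      mm <- regmatches(quals, regexec(pat, quals))[[1]]
      if (length(mm) == 2) gsub("\\s*\n\\s*", " ", mm[2]) else NA_character_
    }
    translation <- get_qual("translation")
    label <- get_qual_text("product")
    if (is.na(label)) label <- get_qual_text("gene")
    orf_id <- get_qual_text("locus_tag")
    if (is.na(orf_id)) orf_id <- get_qual_text("protein_id")
    if (is.na(orf_id)) orf_id <- sprintf("%s_cds%03d", genome$id, length(recs) + 1L)

    if (is.na(translation)) {
      span <- substr(genome$sequence, s1, e1)
      if (strand == "-") span <- revcomp(span)
      translation <- translate_cds(span)  # errors if untranslatable
    }
    recs[[length(recs) + 1L]] <-
      data.frame(orf_id = orf_id, start = s1 - 1L, end = e1, strand = strand,
                 protein = translation, label = label, stringsAsFactors = FALSE)
  }
  orfs <- if (length(recs)) do.call(rbind, recs)
  else data.frame(orf_id = character(), start = integer(), end = integer(),
                  strand = character(), protein = character(),
                  label = character(), stringsAsFactors = FALSE)
  annotated_phage(genome, orfs)
}

# single-strand ORF scan of a plain sequence; returns 0-based [start,end)
# on that strand's own coordinates
scan_orfs_one_strand <- function(seq, min_codons, starts) {
  n <- nchar(seq)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < min_codons) next
    pos <- frame + seq(0L, (ncod - 1L)) * 3L        # 0-based codon starts
    codons <- substring(seq, pos + 1L, pos + 3L)
    is_stop <- codons %in% stops
    is_start <- codons %in% starts
    prev_stop <- 0L                                  # codon index (1-based), 0 = none yet
    for (s in which(is_stop)) {
      seg <- (prev_stop + 1L):s
      cand <- seg[is_start[seg]]
      if (length(cand)) {
        first <- cand[1]
        len_codons <- s - first + 1L                 # includes the stop codon
        if (len_codons >= min_codons) {
          out[[length(out) + 1L]] <- c(start = pos[first], end = pos[s] + 3L)
        }
      }
      prev_stop <- s
    }
  }
  out
}

#' Find open reading frames (simple longest-ORF finder)
#'
#' A deliberately simple stand-in for gene prediction on synthetic and test
#' genomes: every returned ORF begins at an allowed start codon, ends at the
#' first in-frame stop, spans at least `min_codons` codons (stop included),
#' and for nested same-stop ORFs only the longest is kept. Both strands are
#' scanned; circular genomes wrap across the origin (wrapped ORFs have
#' `end > genome length`, i.e. coordinates in the doubled sequence).
#'
#' @param genome a [genome_record()].
#' @param min_codons minimum ORF length in codons, stop included (>= 2).
#' @param starts allowed start codons.
#' @return data frame of ORFs (`orf_id`, `start`, `end`, `strand`,
#'   `protein`, `label`), ordered by start.
#' @export
find_orfs <- function(genome, min_codons = 30L,
                      starts = c("ATG", "GTG", "TTG")) {
  stopifnot(inherits(genome, "genome_record"), min_codons >= 2)
  L <- nchar(genome$sequence)
  circular <- genome$topology == "circular"
  fw <- if (circular) paste0(genome$sequence, genome$sequence) else genome$sequence
  rv <- revcomp(fw)
  n <- nchar(fw)

  hits <- list()
  for (h in scan_orfs_one_strand(fw, min_codons, starts)) {
    hits[[length(hits) + 1L]] <- list(start = h[["start"]], end = h[["end"]],
                                      strand = "+")
  }
  for (h in scan_orfs_one_strand(rv, min_codons, starts)) {
    # map [s,e) on the reverse strand back to forward coordinates
    hits[[length(hits) + 1L]] <- list(start = n - h[["end"]],
                                      end = n - h[["start"]], strand = "-")
  }
  keep <- list()
  for (h in hits) {
    len <- h$end - h$start
    if (circular) {
      if (len > L) next                      # longer than the genome itself
      s <- h$start %% L
      h$start <- s; h$end <- s + len
      if (h$start >= L) next
    }
    keep[[length(keep) + 1L]] <- h
  }
  # deduplicate (circular doubling can find the same ORF twice)
  if (length(keep)) {
    sig <- vapply(keep, function(h) paste(h$start, h$end, h$strand), "")
    keep <- keep[!duplicated(sig)]
  }
  if (length(keep) == 0)
    return(data.frame(orf_id = character(), start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      label = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(keep, function(h) {
    span <- substr(fw, h$start + 1L, h$end)
    if (h$strand == "-") span <- revcomp(span)
    data.frame(start = h$start, end = h$end, strand = h$strand,
               protein = translate_cds(span), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$orf_id <- sprintf("%s_orf%04d", genome$id, seq_len(nrow(df)))
  df$label <- NA_character_
  rownames(df) <- NULL
  df[, c("orf_id", "start", "end", "strand", "protein", "label")]
}

#' GC content of a genome
#'
#' `(G + C) / (A + C + G + T)`; N is excluded from the denominator.
#'
#' @param genome a [genome_record()] or DNA string.
#' @return fraction in `[0, 1]`. See [gc_percent()] for the conventional
#'   2-decimal percentage.
#' @export
gc_content <- function(genome) {
  seq <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  validate_dna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = c("A", "C", "G", "T", "N")))
  denom <- sum(tab[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence contains no unambiguous bases")
  unname((tab[["G"]] + tab[["C"]]) / denom)
}

#' @rdname gc_content
#' @export
gc_percent <- function(genome) round(100 * gc_content(genome), 2)

#' Write an ORF table in the tabular interchange format
#'
#' Columns `phage_id`, `orf_id`, `start_1based`, `end_1based`, `strand`,
#' `label` (1-based inclusive coordinates).
#'
#' @param phage an [annotated_phage()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_orf_tsv <- function(phage, path) {
  stopifnot(inherits(phage, "annotated_phage"))
  df <- data.frame(phage_id = phage$genome$id, orf_id = phage$orfs$orf_id,
                   start_1based = phage$orfs$start + 1L,
                   end_1based = phage$orfs$end, strand = phage$orfs$strand,
                   label = phage$orfs$label, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
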