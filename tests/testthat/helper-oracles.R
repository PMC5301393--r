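# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (full DP matrices, sliding windows, double loops)
# and never call the code paths they check.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

ora_random_protein <- function(len) paste(sample(AA_LETTERS, len, TRUE), collapse = "")
ora_random_dna <- function(len) paste(sample(c("A","C","G","T"), len, TRUE), collapse = "")

ora_blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

# Full-matrix affine Smith-Waterman with the same documented tie-breaks as
# the package implementation (best cell = first maximum in row-major order;
# M predecessor prefers M, X, Y; fresh start only when max < 0; gap states
# prefer opening from M).
oracle_sw <- function(a, b, gap_open = 11, gap_extend = 1) {
  sub <- ora_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1); pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  goe <- gap_open + gap_extend
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    ox <- M[i, j + 1] - goe; ex <- X[i, j + 1] - gap_extend
    if (ox >= ex) { X[i + 1, j + 1] <- ox; pX[i + 1, j + 1] <- 1L }
    else { X[i + 1, j + 1] <- ex; pX[i + 1, j + 1] <- 2L }
    oy <- M[i + 1, j] - goe; ey <- Y[i + 1, j] - gap_extend
    if (oy >= ey) { Y[i + 1, j + 1] <- oy; pY[i + 1, j + 1] <- 1L }
    else { Y[i + 1, j + 1] <- ey; pY[i + 1, j + 1] <- 2L }
    cand <- c(M[i, j], X[i, j], Y[i, j])
    pred <- max(cand)
    ptr <- which(cand == pred)[1]
    if (pred < 0) { pred <- 0; ptr <- 0L }
    mv <- sub[av[i], bv[j]] + pred
    M[i + 1, j + 1] <- mv; pM[i + 1, j + 1] <- ptr
    if (mv > best) { best <- mv; bi <- i; bj <- j }
  }
  matches <- 0L; columns <- 0L
  if (best > 0) {
    i <- bi + 1L; j <- bj + 1L; state <- 1L
    while (i > 1 && j > 1) {
      if (state == 1L) {
        columns <- columns + 1L
        if (av[i - 1] == bv[j - 1]) matches <- matches + 1L
        p <- pM[i, j]; i <- i - 1L; j <- j - 1L
        if (p == 0L) break
        state <- p
      } else if (state == 2L) {
        columns <- columns + 1L
        p <- pX[i, j]; i <- i - 1L
        if (p == 1L) state <- 1L
      } else {
        columns <- columns + 1L
        p <- pY[i, j]; j <- j - 1L
        if (p == 1L) state <- 1L
      }
    }
  }
  list(score = best, matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else NaN)
}

ora_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# exhaustive sliding-window primer-site scan
oracle_sites <- function(seq, primer, max_mm = 0, anchor = 5) {
  scan <- function(pattern, anchor_at_start) {
    pl <- nchar(pattern); L <- nchar(seq)
    out <- NULL
    if (L < pl) return(out)
    for (p in 0:(L - pl)) {
      win <- substr(seq, p + 1, p + pl)
      mm <- sum(strsplit(win, "")[[1]] != strsplit(pattern, "")[[1]])
      if (mm > max_mm) next
      a <- min(anchor, pl)
      if (a > 0) {
        if (anchor_at_start) {
          if (substr(win, 1, a) != substr(pattern, 1, a)) next
        } else {
          if (substr(win, pl - a + 1, pl) != substr(pattern, pl - a + 1, pl)) next
        }
      }
      out <- rbind(out, data.frame(position = p, mismatches = mm))
    }
    out
  }
  plus <- scan(primer, FALSE)
  minus <- scan(ora_revcomp(primer), TRUE)
  rbind(
    if (!is.null(plus)) cbind(plus, strand = "+"),
    if (!is.null(minus)) cbind(minus, strand = "-"))
}

# double-loop host-range cross-tabulation
oracle_crosstab <- function(m, types) {
  lev <- c("A", "B", "C", "U")
  si <- setNames(integer(4), lev); pi_ <- setNames(integer(4), lev)
  for (t in lev) {
    for (s in seq_len(ncol(m))) {
      if (types[[colnames(m)[s]]] == t && any(m[, s])) si[[t]] <- si[[t]] + 1L
    }
    for (p in seq_len(nrow(m))) {
      hit <- FALSE
      for (s in seq_len(ncol(m)))
        if (types[[colnames(m)[s]]] == t && m[p, s]) hit <- TRUE
      if (hit) pi_[[t]] <- pi_[[t]] + 1L
    }
  }
  list(strains = si, phages = pi_)
}

# independent six-frame ORF enumeration: walk from every start codon to the
# first in-frame stop, keep the longest ORF per (stop, strand)
oracle_orfs <- function(seq, min_codons = 30, starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  find_on <- function(s, strand) {
    L <- nchar(s)
    best <- list()   # keyed by stop position
    for (p in 0:(L - 3)) {
      if (!substr(s, p + 1, p + 3) %in% starts) next
      q <- p
      repeat {
        if (q + 3 > L) { q <- NA; break }
        cod <- substr(s, q + 1, q + 3)
        if (cod %in% stops && q > p) break
        if (cod %in% stops && q == p) { q <- NA; break }
        q <- q + 3
      }
      if (is.na(q)) next
      key <- as.character(q)
      if (is.null(best[[key]]) || best[[key]] > p) best[[key]] <- p
    }
    out <- NULL
    for (key in names(best)) {
      p <- best[[key]]; q <- as.integer(key)
      if ((q + 3 - p) / 3 >= min_codons)
        out <- rbind(out, data.frame(start = p, end = q + 3, strand = strand))
    }
    out
  }
  fw <- find_on(seq, "+")
  rvseq <- ora_revcomp(seq)
  rv <- find_on(rvseq, "-")
  L <- nchar(seq)
  if (!is.null(rv)) {
    tmp <- rv
    rv$start <- L - tmp$end; rv$end <- L - tmp$start
  }
  out <- rbind(fw, rv)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive MCL re-implementation (no pruning, direct matrix iteration) used
# to cross-check cluster extraction on tiny graphs
naive_mcl <- function(adj, inflation = 2, iters = 60) {
  diag(adj) <- apply(adj, 2, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (k in seq_len(iters)) {
    M <- M %*% M
    M <- M ^ inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  lab <- apply(M, 2, which.max)
  split(colnames(adj), lab)
}

# convenience: a synthetic retained-hit row for threshold tests
make_hit <- function(query = "q", subject = "s", identity = 0.9,
                     qcov = 0.9, scov = 0.9, evalue = 1e-10, score = 100,
                     qphage = "p1", sphage = "p2") {
  data.frame(query_id = query, subject_id = subject, identity = identity,
             aln_length = 100L, query_coverage = qcov,
             subject_coverage = scov, mismatches = 1L, gap_opens = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             score = score, evalue = evalue, bitscore = score,
             query_phage = qphage, subject_phage = sphage,
             stringsAsFactors = FALSE)
}

# standard synthetic cohort used by pipeline and acceptance tests
acceptance_templates <- function(chimera = TRUE) {
  t <- c(rep(list(phage_template("I")), 2),
         rep(list(phage_template("II")), 2),
         rep(list(phage_template("III")), 2),
         rep(list(phage_template("IV")), 2))
  if (chimera) t <- c(t, list(phage_template("II", rbp_subgroup = "I")))
  t
}
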