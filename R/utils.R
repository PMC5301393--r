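# Internal helpers shared across modules.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generator functions are pure
#' functions of their `seed` argument without disturbing the caller's RNG
#' stream. `seed = NULL` uses the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# reverse complement of a plain character DNA string (A,C,G,T,N)
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

validate_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(sprintf("%s must be a non-empty character string", what), call. = FALSE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                 what, substr(bad, 1, 10)), call. = FALSE)
  invisible(seq)
}

validate_protein <- function(prot, what = "protein") {
  if (!is.character(prot) || length(prot) != 1L || is.na(prot) || !nzchar(prot))
    stop(sprintf("%s must be a non-empty character string", what), call. = FALSE)
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X]"), "", prot)
  if (nzchar(bad))
    stop(sprintf("%s contains characters outside the amino-acid alphabet: '%s'",
                 what, substr(bad, 1, 10)), call. = FALSE)
  invisible(prot)
}

# cached package-level objects (genetic code, BLOSUM62, reference panel)
.pkg_cache <- new.env(parent = emptyenv())

genetic_code_11 <- function() {
  if (is.null(.pkg_cache$gc11))
    .pkg_cache$gc11 <- Biostrings::getGeneticCode("11")
  .pkg_cache$gc11
}

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

random_protein <- function(len, seed = NULL, start_met = TRUE) {
  with_seed(seed, {
    aa <- sample(AA20, len, replace = TRUE)
    if (start_met) aa[1] <- "M"
    paste(aa, collapse = "")
  })
}

random_dna <- function(len, gc = 0.5, seed = NULL) {
  gc <- min(max(gc, 0), 1)
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                        collapse = ""))
}
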