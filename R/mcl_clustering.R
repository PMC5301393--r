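# Markov clustering of the protein similarity graph and phage-level
# proteome grouping. MCL is implemented from scratch on a dense
# column-stochastic matrix; the scale here is tens of phages x ~60 proteins.

#' MCL parameters
#'
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param expansion matrix power used in the expansion step (>= 2).
#' @param prune_threshold entries below this are zeroed after inflation.
#' @param max_iterations iteration cap; non-convergence is an error.
#' @param convergence_eps maximum elementwise change defining convergence.
#' @return an `mcl_params` list.
#' @export
mcl_params <- function(inflation = 2.0, expansion = 2L,
                       prune_threshold = 1e-5, max_iterations = 200L,
                       convergence_eps = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, prune_threshold >= 0,
            max_iterations >= 1, convergence_eps > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_eps = convergence_eps),
            class = "mcl_params")
}

#' Construct a protein similarity graph
#'
#' Nodes are protein ids; undirected weighted edges carry the percent
#' identity of the retained hit. Self-loops are rejected; duplicate edges
#' keep the maximum weight.
#'
#' @param edges data frame with columns `from`, `to`, `weight` (percent
#'   identity in `(0, 100]`).
#' @param nodes character vector of all node ids (isolated nodes allowed);
#'   defaults to the nodes present in `edges`.
#' @return a `similarity_graph` list.
#' @export
similarity_graph <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (any(edges$weight <= 0 | edges$weight > 100))
    stop("edge weights must be percent identities in (0, 100]")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing))
    stop(sprintf("edge endpoint not in node set: %s", missing[1]))
  # canonical unordered representation, max weight per pair
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  uk <- !duplicated(key)
  edges <- data.frame(from = a[uk], to = b[uk],
                      weight = as.numeric(w[key[uk]]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Build the similarity graph fed to MCL from BBH pairs
#'
#' Edge weight is the percent identity of the retained hit (maximum over
#' orientations); all proteins of the input proteomes are nodes, so proteins
#' without partners become singleton families.
#'
#' @param bbh data frame from [bidirectional_best_hits()].
#' @param proteomes the proteome list given to [all_vs_all()].
#' @return a [similarity_graph()].
#' @export
build_similarity_graph <- function(bbh, proteomes) {
  nodes <- unlist(lapply(proteomes, names), use.names = FALSE)
  edges <- if (nrow(bbh)) data.frame(from = bbh$protein_a, to = bbh$protein_b,
                                     weight = 100 * bbh$identity,
                                     stringsAsFactors = FALSE)
           else NULL
  similarity_graph(edges, nodes)
}

#' Markov clustering (MCL)
#'
#' Builds a column-stochastic transition matrix over the graph with
#' self-loops equal to each node's maximum incident edge weight (1 for
#' isolated nodes), then alternates expansion (matrix power) and inflation
#' (elementwise power followed by column renormalisation) with pruning until
#' the elementwise change falls below `convergence_eps`. Clusters are read
#' from the attractor structure of the limit; overlapping attractor systems
#' are merged and nodes attracted to several clusters are assigned to the
#' lexicographically smallest family id.
#'
#' @param graph a [similarity_graph()].
#' @param params an [mcl_params()].
#' @return object of class `protein_families`: list with `families` (named
#'   list family id -> member ids), `membership` (named vector protein ->
#'   family id), `iterations`, `n_ties`.
#' @export
mcl <- function(graph, params = mcl_params()) {
  stopifnot(inherits(graph, "similarity_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("graph is empty")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes); j <- match(graph$edges$to, nodes)
    M[cbind(i, j)] <- graph$edges$weight
    M[cbind(j, i)] <- graph$edges$weight
  }
  mx <- apply(M, 2, max)
  diag(M) <- ifelse(mx > 0, mx, 1)        # standard self-loop regularisation
  M <- sweep(M, 2, colSums(M), "/")

  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    Mexp <- M
    for (k in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ params$inflation
    Minf[Minf < params$prune_threshold] <- 0
    cs <- colSums(Minf)
    if (any(cs == 0)) stop("MCL pruning removed an entire column")
    Minf <- sweep(Minf, 2, cs, "/")
    if (max(abs(colSums(Minf) - 1)) > 1e-9)
      stop("internal error: columns not stochastic after inflation")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < params$convergence_eps) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MCL did not converge after %d iterations", iter))

  # attractors: nodes with positive diagonal mass in the limit
  attr_idx <- which(diag(M) > 0)
  clusters <- lapply(attr_idx, function(i) which(M[i, ] > 0))
  # merge attractor systems that overlap
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged[[hit[1]]] <- sort(unique(c(unlist(merged[hit]), cl)))
      if (length(hit) > 1) merged <- merged[-hit[-1]]
    } else merged[[length(merged) + 1L]] <- sort(cl)
  }
  # orphan nodes (all mass pruned off attractors) become singletons
  covered <- unlist(merged)
  for (i in setdiff(seq_len(n), covered))
    merged[[length(merged) + 1L]] <- i

  members <- lapply(merged, function(ix) nodes[ix])
  ord <- order(vapply(members, function(m) sort(m)[1], ""))
  members <- members[ord]
  fam_ids <- sprintf("fam%04d", seq_along(members))

  membership <- setNames(rep(NA_character_, n), nodes)
  n_ties <- 0L
  for (k in seq_along(members)) {
    for (nd in members[[k]]) {
      if (is.na(membership[[nd]])) membership[[nd]] <- fam_ids[k]
      else n_ties <- n_ties + 1L     # overlap: keep smallest family id
    }
  }
  families <- split(names(membership), membership)
  families <- families[order(names(families))]
  # partition sanity: coverage and disjointness
  stopifnot(!anyNA(membership),
            length(unlist(families)) == n,
            !anyDuplicated(unlist(families)))
  structure(list(families = families, membership = membership,
                 iterations = iter, n_ties = n_ties),
            class = "protein_families")
}

#' @export
print.protein_families <- function(x, ...) {
  cat(sprintf("<protein_families> %d families over %d proteins (%d MCL iterations)\n",
              length(x$families), length(x$membership), x$iterations))
  invisible(x)
}

#' Family profiles per phage
#'
#' A phage's profile is the set of families containing at least one of its
#' proteins.
#'
#' @param families a `protein_families` object from [mcl()].
#' @param proteomes named list (phage -> named protein vector).
#' @return named list phage id -> character vector of family ids.
#' @export
phage_profiles <- function(families, proteomes) {
  membership <- families$membership
  lapply(proteomes, function(p) {
    ids <- names(p)
    fam <- membership[ids]
    if (anyNA(fam))
      stop(sprintf("protein missing from all families: %s",
                   ids[which(is.na(fam))[1]]))
    sort(unique(unname(fam)))
  })
}

#' Group phages by shared-family profiles
#'
#' Pairwise similarity is the Dice coefficient `2|A n B| / (|A| + |B|)`;
#' groups are connected components of the graph with edges where similarity
#' `>= link_threshold`.
#'
#' @param profiles from [phage_profiles()].
#' @param link_threshold Dice similarity at or above which two phages are
#'   linked (default 0.5).
#' @return object of class `phage_grouping`: list with `groups` (named
#'   vector phage -> group id), `similarity` (symmetric matrix with unit
#'   diagonal).
#' @export
group_phages <- function(profiles, link_threshold = 0.5) {
  stopifnot(length(profiles) >= 1)
  phages <- names(profiles)
  n <- length(phages)
  sim <- matrix(0, n, n, dimnames = list(phages, phages))
  diag(sim) <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- profiles[[i]]; b <- profiles[[j]]
      denom <- length(a) + length(b)
      d <- if (denom == 0) 0 else 2 * length(intersect(a, b)) / denom
      sim[i, j] <- d; sim[j, i] <- d
    }
  }
  adj <- (sim >= link_threshold) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # stable group ids ordered by each component's first phage
  first <- tapply(seq_len(n), comp, min)
  relabel <- rank(first)
  groups <- setNames(sprintf("grp%02d", relabel[as.character(comp)]), phages)
  structure(list(groups = groups, similarity = sim), class = "phage_grouping")
}

#' Write protein families or phage groups as TSV
#'
#' @param x a `protein_families` or `phage_grouping` object.
#' @param path output TSV (id, cluster_id).
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(x, path) {
  df <- if (inherits(x, "protein_families")) {
    data.frame(protein_id = names(x$membership), cluster_id = x$membership)
  } else if (inherits(x, "phage_grouping")) {
    data.frame(phage_id = names(x$groups), cluster_id = x$groups)
  } else stop("unsupported object")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abc-style edge list (node1 node2 weight)
#'
#' Interoperability reader for ".mcl"/abc edge lists as consumed by the
#' reference MCL implementation.
#'
#' @param path whitespace-separated file with columns node1, node2, weight.
#' @param nodes optional full node set.
#' @return a [similarity_graph()].
#' @export
read_abc_graph <- function(path, nodes = NULL) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("abc edge list needs three columns")
  names(df)[1:3] <- c("from", "to", "weight")
  similarity_graph(df[, 1:3], nodes)
}
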