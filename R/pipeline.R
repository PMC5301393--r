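# End-to-end orchestration: genomes -> proteomes -> BBH -> MCL -> grouping
# -> adhesion typing -> PCR typing -> per-phage report.

#' Pipeline run configuration
#'
#' All thresholds of the pipeline in one serialisable object; nothing is
#' hard-coded elsewhere. Round-trips through JSON unchanged
#' ([write_config()] / [read_config()]).
#'
#' @param thresholds a [similarity_thresholds()].
#' @param scoring a [scoring_config()].
#' @param mcl an [mcl_params()].
#' @param link_threshold Dice similarity linking phages into groups.
#' @param match a [match_params()].
#' @param eop_dependent_log calcium-dependence threshold (log10).
#' @param seed seed for synthetic runs.
#' @param output_dir directory for persisted artifacts (NULL = none).
#' @return a `run_config` list.
#' @export
run_config <- function(thresholds = similarity_thresholds(),
                       scoring = scoring_config(),
                       mcl = mcl_params(), link_threshold = 0.5,
                       match = match_params(), eop_dependent_log = 4,
                       seed = 1L, output_dir = NULL) {
  structure(list(thresholds = thresholds, scoring = scoring, mcl = mcl,
                 link_threshold = link_threshold, match = match,
                 eop_dependent_log = eop_dependent_log, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(lapply(unclass(config), unclass), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(
    thresholds = do.call(similarity_thresholds, as.list(x$thresholds)),
    scoring = do.call(scoring_config, as.list(x$scoring)),
    mcl = do.call(mcl_params, as.list(x$mcl)),
    link_threshold = x$link_threshold,
    match = do.call(match_params, as.list(x$match)),
    eop_dependent_log = x$eop_dependent_log,
    seed = x$seed,
    output_dir = x$output_dir)
  cfg
}

stage <- function(name, phage_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed%s: %s", name,
                 if (is.null(phage_id)) "" else paste0(" for phage ", phage_id),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Classify a collection of phages end to end
#'
#' Runs all-against-all comparison, bidirectional best hits, MCL protein
#' families, proteome grouping, adhesion-module typing and PCR typing, and
#' assembles one report row per phage. Each proteome group carries the
#' modal RBP sub-group of its members as its sub-group label; a phage whose
#' own RBP sub-group departs from its group's label is flagged discordant.
#' With a single phage the grouping stages are skipped with a warning.
#'
#' @param phages named list of [annotated_phage()] objects.
#' @param config a [run_config()].
#' @param panel a [reference_panel()].
#' @param primer_panel named list of [primer_pair()]s used for PCR typing.
#' @param output_dir overrides `config$output_dir`.
#' @return list of class `classify_run`: `report` (one row per phage),
#'   `grouping`, `families`, `hits`, `bbh`, `modules`, `log`.
#' @export
run_classify <- function(phages, config = run_config(),
                         panel = reference_panel(),
                         primer_panel = p335_panel(),
                         output_dir = config$output_dir) {
  stopifnot(is.list(phages), length(phages) >= 1)
  if (is.null(names(phages)))
    names(phages) <- vapply(phages, function(p) p$genome$id, "")
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message("[run_classify] ", msg)
  }

  proteomes <- lapply(phages, proteome)
  note("input: %d phages, %d proteins", length(phages),
       sum(lengths(proteomes)))

  single <- length(phages) < 2
  if (single) {
    warning("single phage input: proteome grouping skipped")
    hits <- empty_hits(); bbh <- bidirectional_best_hits(hits)
    families <- NULL; grouping <- NULL
  } else {
    hits <- stage("all_vs_all", NULL,
                  all_vs_all(proteomes, config$thresholds, config$scoring))
    note("retained hits: %d", nrow(hits))
    bbh <- stage("bidirectional_best_hits", NULL, bidirectional_best_hits(hits))
    note("BBH pairs: %d", nrow(bbh))
    graph <- build_similarity_graph(bbh, proteomes)
    families <- stage("mcl", NULL, mcl(graph, config$mcl))
    note("protein families: %d (MCL iterations: %d)",
         length(families$families), families$iterations)
    profiles <- stage("phage_profiles", NULL,
                      phage_profiles(families, proteomes))
    grouping <- stage("group_phages", NULL,
                      group_phages(profiles, config$link_threshold))
    note("proteome groups: %d", length(unique(grouping$groups)))
  }

  modules <- list(); arch <- list(); rbp_sg <- character(length(phages))
  names(rbp_sg) <- names(phages)
  typing <- list()
  for (id in names(phages)) {
    mod <- stage("locate_module", id, locate_module(phages[[id]], panel,
                                                    config$scoring))
    mod <- stage("assign_roles", id, assign_roles(mod, panel, config$scoring))
    modules[[id]] <- mod
    arch[[id]] <- stage("classify_architecture", id,
                        classify_architecture(mod, panel))
    r <- module_rbp(mod)
    rbp_sg[[id]] <- if (is.null(r)) NA_character_
      else stage("assign_rbp_subgroup", id,
                 assign_rbp_subgroup(r$protein, panel, r$is_fused,
                                     config$scoring))
    typing[[id]] <- stage("pcr_typing", id,
                          simulate_multiplex(phages[[id]]$genome,
                                             primer_panel, config$match))
  }
  note("adhesion modules typed: %d", length(modules))

  # sub-group label of each proteome group: modal RBP sub-group of members
  group_label <- NULL
  if (!single) {
    groups <- grouping$groups
    group_label <- vapply(unique(groups), function(g) {
      members <- names(groups)[groups == g]
      sg <- rbp_sg[members]
      sg <- sg[!is.na(sg) & sg != "novel"]
      if (length(sg) == 0) return(NA_character_)
      tb <- sort(table(sg), decreasing = TRUE)
      top <- names(tb)[tb == tb[1]]
      sort(top)[1]
    }, "")
  }

  rows <- lapply(names(phages), function(id) {
    pg <- if (single) NA_character_ else unname(grouping$groups[[id]])
    psg <- if (single) NA_character_ else unname(group_label[[pg]])
    a <- assemble_assignment(id, pg, psg, arch[[id]], rbp_sg[[id]])
    a$pcr_labels <- paste(typing[[id]]$called_labels, collapse = ";")
    a
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(report, file.path(output_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_hits_outfmt6(hits, file.path(output_dir, "hits.tsv"))
    if (!is.null(families))
      write_clusters_tsv(families, file.path(output_dir, "families.tsv"))
    if (!is.null(grouping))
      write_clusters_tsv(grouping, file.path(output_dir, "groups.tsv"))
    mods <- do.call(rbind, lapply(modules, function(m) {
      data.frame(phage_id = m$phage_id, orf_id = m$orfs$orf_id,
                 role = m$orfs$role, start = m$orfs$start, end = m$orfs$end)
    }))
    write.table(mods, file.path(output_dir, "modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(output_dir, "run.log"))
  }
  structure(list(report = report, grouping = grouping, families = families,
                 hits = hits, bbh = bbh, modules = modules, log = log),
            class = "classify_run")
}

#' @export
print.classify_run <- function(x, ...) {
  cat(sprintf("<classify_run> %d phages\n", nrow(x$report)))
  print(x$report[, c("phage_id", "proteome_group", "proteome_subgroup",
                     "rbp_subgroup", "concordant")])
  invisible(x)
}

#' Batch PCR typing of a genome collection (survey mode)
#'
#' @param genomes a list of [genome_record()]s, a FASTA path, or a directory
#'   of FASTA files. Unreadable genomes are skipped with a warning and the
#'   run status reflects the partial failure.
#' @param panel named list of [primer_pair()]s.
#' @param params a [match_params()].
#' @return list of class `survey_run`: `results` (one row per genome),
#'   `typing` (full [simulate_multiplex()] objects), `label_summary`,
#'   `n_warnings`, `status` (0 success, 1 partial).
#' @export
run_survey <- function(genomes, panel = p335_panel(),
                       params = match_params()) {
  n_warn <- 0L
  if (is.character(genomes)) {
    paths <- if (length(genomes) == 1 && dir.exists(genomes)) {
      list.files(genomes, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    } else genomes
    recs <- list()
    for (p in paths) {
      g <- tryCatch(read_fasta(p), error = function(e) {
        warning(sprintf("skipping unreadable genome file '%s': %s", p,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(g)) n_warn <- n_warn + 1L else recs <- c(recs, g)
    }
    genomes <- recs
  }
  results <- list(); typing <- list()
  for (g in genomes) {
    tr <- simulate_multiplex(g, panel, params)
    typing[[g$id]] <- tr
    results[[g$id]] <- data.frame(
      genome_id = g$id,
      labels = if (length(tr$called_labels))
        paste(tr$called_labels, collapse = ";") else "untyped",
      n_amplicons = nrow(tr$amplicons),
      conflict = tr$flags$conflict, stringsAsFactors = FALSE)
  }
  results <- if (length(results)) do.call(rbind, c(results, make.row.names = FALSE))
    else data.frame(genome_id = character(), labels = character(),
                    n_amplicons = integer(), conflict = logical())
  lab <- unlist(lapply(typing, function(t) t$called_labels))
  structure(list(results = results, typing = typing,
                 label_summary = if (length(lab)) table(lab) else table(character(0)),
                 n_warnings = n_warn,
                 status = if (n_warn > 0) 1L else 0L),
            class = "survey_run")
}
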