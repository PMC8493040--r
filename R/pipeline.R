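# End-to-end pipeline: parse -> build graph -> embed (or IC) -> similarity
# -> screen -> (optional) coincidence vs a reference PPI -> link prediction.

#' Assemble a pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Two embedding modes
#' mirror the two pipeline variants — `go_dtw` (term vectors from the GO
#' graph, DTW protein similarity) and `goa_cosine` (protein vectors from the
#' GOA graph, cosine similarity) — plus the IC baselines `ic_jc` and
#' `ic_rel`, which skip the embedding stage.
#'
#' @param obo,gaf input file paths; `ppi` an optional reference edge list.
#' @param mode `"go_dtw"`, `"goa_cosine"`, `"ic_jc"` or `"ic_rel"`.
#' @param method embedding method for the embedding modes.
#' @param dim,p,q,walk_length,walks_per_node,window,epochs embedding
#'   hyperparameters (see [embed_graph()]).
#' @param metric local DTW metric.
#' @param tau,band,band_frac screening rule (exactly one of `tau`/`band`).
#' @param index,remove_frac,probe_frac,repeats link-prediction settings.
#' @param seed run-level seed.
#' @param outdir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(obo, gaf, ppi = NULL,
                       mode = c("go_dtw", "goa_cosine", "ic_jc", "ic_rel"),
                       method = c("node2vec", "deepwalk", "line", "sdne"),
                       dim = 128L, p = 1, q = 1, walk_length = 80L,
                       walks_per_node = 10L, window = 10L, epochs = 5L,
                       metric = "euclidean", tau = NULL, band = "top",
                       band_frac = 0.05, index = "ra", remove_frac = 0.2,
                       probe_frac = 0.2, repeats = 5L, seed = 1L,
                       outdir = tempfile("gosimnet_run_")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  structure(as.list(environment()), class = "run_config")
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full protein-similarity pipeline
#'
#' Executes every stage of the configured variant and writes `scores.tsv`
#' (all scored pairs), `network.tsv` (the screened similarity network),
#' `result.json` (config echo, stage counts, coincidence degree when a PPI
#' reference is given, link-prediction summary) and `run.log` into the
#' output directory. A failing stage aborts with the stage named and leaves
#' a `FAILED` marker file.
#'
#' @param config a [run_config()].
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logf))
  result <- list(
    package_version = as.character(utils::packageVersion("gosimnet")),
    r_version = R.version.string,
    config = config[!vapply(config, is.null, logical(1))]
  )
  stage <- "setup"
  ok <- FALSE
  on.exit({
    if (!ok) writeLines(stage, file.path(config$outdir, "FAILED"))
  }, add = TRUE)

  t_stage <- function(name, expr) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_line(logf, sprintf("stage '%s' FAILED: %s", name, conditionMessage(e)))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line(logf, sprintf("stage '%s' done in %.2fs", name,
                           proc.time()[["elapsed"]] - t0))
    out
  }

  log_line(logf, "config: ", jsonlite::toJSON(result$config, auto_unbox = TRUE))

  ont <- t_stage("parse_obo", parse_obo(config$obo))
  ann <- t_stage("parse_gaf", parse_gaf(config$gaf, ont))
  result$counts <- list(terms = sum(!ont$terms$obsolete),
                        relations = nrow(ont$relations),
                        proteins = length(ann$annotations),
                        dropped_annotations = ann$n_dropped)
  proteins <- names(ann$annotations)

  if (config$mode %in% c("go_dtw", "goa_cosine")) {
    graph <- t_stage("build_graph", {
      if (config$mode == "go_dtw") build_go_graph(ont)
      else build_goa_graph(ont, ann)
    })
    emb <- t_stage("embed", embed_graph(
      graph, method = config$method, dim = config$dim, seed = config$seed,
      p = config$p, q = config$q, walk_length = config$walk_length,
      walks_per_node = config$walks_per_node, window = config$window,
      epochs = config$epochs))
    sim <- t_stage("similarity", similarity_matrix(
      proteins, mode = config$mode, embeddings = emb, annotations = ann,
      metric = config$metric))
  } else {
    ict <- t_stage("ic_table", compute_ic_table(ont, ann))
    termsim <- if (config$mode == "ic_jc") {
      function(g1, g2) sim_jc(g1, g2, ict)
    } else {
      function(g1, g2) sim_rel(g1, g2, ict)
    }
    sim <- t_stage("similarity", {
      n <- length(proteins)
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      a <- proteins[pmin(idx[, 1], idx[, 2])]
      b <- proteins[pmax(idx[, 1], idx[, 2])]
      cache <- new.env(parent = emptyenv())
      memo_sim <- function(g1, g2) {
        key <- paste(min(g1, g2), max(g1, g2))
        v <- get0(key, envir = cache, ifnotfound = NULL)
        if (!is.null(v)) return(v)
        v <- termsim(g1, g2)
        assign(key, v, envir = cache)
        v
      }
      score <- mapply(function(x, y) bma(x, y, ann, memo_sim), a, b)
      def <- !is.na(score)
      structure(list(
        pairs = data.frame(protein_a = pmin(a, b)[def],
                           protein_b = pmax(a, b)[def],
                           score = score[def], stringsAsFactors = FALSE),
        undefined = data.frame(protein_a = pmin(a, b)[!def],
                               protein_b = pmax(a, b)[!def],
                               reason = rep("undefined term similarity",
                                            sum(!def)),
                               stringsAsFactors = FALSE),
        mode = config$mode, metric = NA_character_, proteins = proteins),
        class = "protein_similarity")
    })
  }
  result$counts$scored_pairs <- nrow(sim$pairs)
  result$counts$undefined_pairs <- nrow(sim$undefined)

  utils::write.table(sim$pairs, file.path(config$outdir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net <- t_stage("screen", {
    if (!is.null(config$tau)) screen_network(sim, tau = config$tau)
    else screen_network(sim, band = config$band,
                        band_frac = config$band_frac)
  })
  result$network <- list(rule = net$rule, nodes = length(net$nodes),
                         edges = nrow(net$edges))
  utils::write.table(net$edges, file.path(config$outdir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(config$ppi)) {
    ppi <- t_stage("coincidence", {
      ref <- utils::read.table(config$ppi, sep = "\t", header = FALSE,
                               colClasses = "character")
      coincidence_degree(net, ref)
    })
    result$coincidence_degree <- ppi
  }

  lp <- t_stage("link_prediction", run_link_prediction(
    net, index = config$index, remove_frac = config$remove_frac,
    probe_frac = config$probe_frac, repeats = config$repeats,
    seed = config$seed))
  result$link_prediction <- list(
    index = lp$index, auc_mean = lp$auc_mean, auc_sd = lp$auc_sd,
    aucpr_mean = lp$aucpr_mean, aucpr_sd = lp$aucpr_sd,
    per_repeat = lp$per_repeat)

  jsonlite::write_json(result, file.path(config$outdir, "result.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  ok <- TRUE
  log_line(logf, "pipeline complete: ", config$outdir)
  invisible(config$outdir)
}
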