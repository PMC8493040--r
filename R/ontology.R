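# OBO parsing and the ontology_graph container.

#' Construct an ontology graph object
#'
#' Low-level constructor for the container returned by [parse_obo()] and
#' [gen_ontology()]. Terms are a data frame with columns `id`, `name`,
#' `namespace`, `obsolete`; relations a data frame with columns `child`,
#' `parent`, `type` (directed child -> parent, e.g. `is_a`, `part_of`).
#'
#' @param terms data frame of term records.
#' @param relations data frame of directed typed relations.
#' @param alt_ids named character vector mapping alternate accession ->
#'   canonical accession (may be empty).
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, relations,
                           alt_ids = stats::setNames(character(0), character(0))) {
  terms <- data.frame(
    id = as.character(terms$id),
    name = as.character(terms$name),
    namespace = as.character(terms$namespace),
    obsolete = as.logical(terms$obsolete),
    stringsAsFactors = FALSE
  )
  relations <- data.frame(
    child = as.character(relations$child),
    parent = as.character(relations$parent),
    type = as.character(relations$type),
    stringsAsFactors = FALSE
  )
  relations <- unique(relations)
  # relations must not touch obsolete or unknown terms
  live <- terms$id[!terms$obsolete]
  ok <- relations$child %in% live & relations$parent %in% live
  relations <- relations[ok, , drop = FALSE]
  rownames(terms) <- NULL
  rownames(relations) <- NULL
  structure(
    list(terms = terms, relations = relations, alt_ids = alt_ids),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  live <- sum(!x$terms$obsolete)
  cat(sprintf(
    "<ontology_graph> %d terms (%d obsolete excluded), %d relations, namespaces: %s\n",
    live, sum(x$terms$obsolete), nrow(x$relations),
    paste(sort(unique(x$terms$namespace[!x$terms$obsolete])), collapse = ", ")
  ))
  invisible(x)
}

# Terms that are live (non-obsolete).
live_terms <- function(ontology) {
  ontology$terms[!ontology$terms$obsolete, , drop = FALSE]
}

#' Parse a GO ontology in OBO format
#'
#' Reads a go.obo-dialect flat file (`[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a`, `relationship`, `alt_id`, `is_obsolete` tags) into an
#' [ontology_graph()]. Obsolete terms are dropped together with any relation
#' touching them; `alt_id` accessions are recorded so annotations citing them
#' can be mapped to the canonical id.
#'
#' @param path path to the OBO file.
#' @return An `ontology_graph`.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L || !any(lines[starts] == "[Term]")) {
    stop("no [Term] stanza found in ", path)
  }
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0); names_ <- character(0); ns <- character(0)
  obs <- logical(0)
  rel_child <- character(0); rel_parent <- character(0); rel_type <- character(0)
  alt_from <- character(0); alt_to <- character(0)

  strip_comment <- function(x) sub("\\s*!.*$", "", x)

  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    chunk <- lines[(starts[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk)]
    tag <- sub(":.*$", "", chunk)
    val <- trimws(sub("^[^:]+:\\s*", "", chunk))
    id <- val[tag == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      warning("skipping [Term] stanza without an id")
      next
    }
    ids <- c(ids, id)
    nm <- val[tag == "name"][1]
    names_ <- c(names_, if (is.na(nm)) "" else nm)
    n1 <- val[tag == "namespace"][1]
    ns <- c(ns, if (is.na(n1)) NA_character_ else n1)
    obs <- c(obs, isTRUE(any(tag == "is_obsolete" & grepl("^true", val))))

    isa <- strip_comment(val[tag == "is_a"])
    if (length(isa)) {
      rel_child <- c(rel_child, rep(id, length(isa)))
      rel_parent <- c(rel_parent, isa)
      rel_type <- c(rel_type, rep("is_a", length(isa)))
    }
    rel <- strip_comment(val[tag == "relationship"])
    if (length(rel)) {
      parts <- strsplit(rel, "\\s+")
      for (p in parts) {
        if (length(p) >= 2) {
          rel_child <- c(rel_child, id)
          rel_type <- c(rel_type, p[1])
          rel_parent <- c(rel_parent, p[2])
        }
      }
    }
    alts <- val[tag == "alt_id"]
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
  }

  terms <- data.frame(id = ids, name = names_, namespace = ns,
                      obsolete = obs, stringsAsFactors = FALSE)
  terms <- terms[!duplicated(terms$id), , drop = FALSE]
  # map relation endpoints cited by alt_id to canonical ids
  alt <- stats::setNames(alt_to, alt_from)
  hit <- rel_parent %in% names(alt)
  rel_parent[hit] <- unname(alt[rel_parent[hit]])
  relations <- data.frame(child = rel_child, parent = rel_parent,
                          type = rel_type, stringsAsFactors = FALSE)
  og <- ontology_graph(terms, relations, alt_ids = alt)
  message(sprintf("parse_obo: %d terms (%d obsolete), %d relations",
                  sum(!og$terms$obsolete), sum(og$terms$obsolete),
                  nrow(og$relations)))
  og
}

#' Write an ontology graph back to OBO-dialect text
#'
#' Emits one `[Term]` stanza per live term with its `is_a` and
#' `relationship` lines; re-parsing the written file reproduces the graph.
#'
#' @param ontology an `ontology_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  terms <- live_terms(ontology)
  rel <- ontology$relations
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", terms$name[i]))
    if (!is.na(terms$namespace[i])) {
      out <- c(out, paste0("namespace: ", terms$namespace[i]))
    }
    r <- rel[rel$child == id, , drop = FALSE]
    if (nrow(r)) {
      isa <- r$parent[r$type == "is_a"]
      out <- c(out, if (length(isa)) paste0("is_a: ", isa))
      oth <- r[r$type != "is_a", , drop = FALSE]
      if (nrow(oth)) {
        out <- c(out, paste0("relationship: ", oth$type, " ", oth$parent))
      }
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
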