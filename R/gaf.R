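# GAF 2.x parsing and the annotation_set container.

#' Construct an annotation set
#'
#' @param annotations named list: protein id -> character vector of GO term
#'   ids (deduplicated, sorted).
#' @param evidence optional data frame with columns `protein`, `term`,
#'   `evidence`.
#' @param n_dropped count of annotation rows dropped because their term was
#'   absent from the companion ontology.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, evidence = NULL, n_dropped = 0L) {
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  annotations <- annotations[lengths(annotations) > 0L]
  if (length(annotations) == 0L) stop("annotation set is empty")
  structure(
    list(annotations = annotations, evidence = evidence,
         n_dropped = as.integer(n_dropped)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d proteins, %d (protein, term) pairs, %d rows dropped\n",
    length(x$annotations), sum(lengths(x$annotations)), x$n_dropped
  ))
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Reads a tab-separated Gene Association File: comment lines start with
#' `!`; column 2 is the protein (DB object) accession, column 5 the GO id,
#' column 7 the evidence code. Annotations citing terms absent from
#' `ontology` (after `alt_id` mapping) are dropped and counted; duplicate
#' (protein, term) pairs collapse to set semantics. Evidence codes are not
#' filtered unless an include/exclude list is given.
#'
#' @param path path to the GAF file.
#' @param ontology companion [ontology_graph()].
#' @param evidence_include optional character vector: keep only these codes.
#' @param evidence_exclude optional character vector: drop these codes.
#' @return An [annotation_set()].
#' @export
parse_gaf <- function(path, ontology, evidence_include = NULL,
                      evidence_exclude = NULL) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 15L
  if (any(short)) {
    warning(sprintf("parse_gaf: skipping %d row(s) with fewer than 15 columns",
                    sum(short)))
    fields <- fields[!short]
  }
  if (length(fields) == 0L) stop("no annotation rows in ", path)
  protein <- vapply(fields, `[[`, "", 2L)
  term <- vapply(fields, `[[`, "", 5L)
  evid <- vapply(fields, `[[`, "", 7L)

  # map alternate accessions to canonical ids
  alt <- ontology$alt_ids
  hit <- term %in% names(alt)
  term[hit] <- unname(alt[term[hit]])

  known <- term %in% live_terms(ontology)$id
  n_dropped <- sum(!known)
  protein <- protein[known]; term <- term[known]; evid <- evid[known]

  if (!is.null(evidence_include)) {
    keep <- evid %in% evidence_include
    protein <- protein[keep]; term <- term[keep]; evid <- evid[keep]
  }
  if (!is.null(evidence_exclude)) {
    keep <- !(evid %in% evidence_exclude)
    protein <- protein[keep]; term <- term[keep]; evid <- evid[keep]
  }
  if (length(protein) == 0L) stop("no annotations survive filtering in ", path)

  ev <- unique(data.frame(protein = protein, term = term, evidence = evid,
                          stringsAsFactors = FALSE))
  ann <- split(term, protein)
  annotation_set(ann, evidence = ev, n_dropped = n_dropped)
}

#' Write an annotation set as a minimal GAF 2.2 file
#'
#' Emits one 17-column row per (protein, term) pair; evidence defaults to
#' `IEA` when none is recorded.
#'
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @param aspect single-letter GO aspect written in column 9.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, aspect = "P") {
  prot <- rep(names(annotations$annotations),
              lengths(annotations$annotations))
  term <- unlist(annotations$annotations, use.names = FALSE)
  ev <- rep("IEA", length(prot))
  if (!is.null(annotations$evidence)) {
    key <- paste(annotations$evidence$protein, annotations$evidence$term)
    m <- match(paste(prot, term), key)
    ev[!is.na(m)] <- annotations$evidence$evidence[m[!is.na(m)]]
  }
  rows <- paste("UniProtKB", prot, prot, "", term, "GO_REF:0000000", ev, "",
                aspect, "", "", "protein", "taxon:0000", "20210101",
                "UniProt", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}
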