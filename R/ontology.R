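#' Chemical-ontology term trees
#'
#' The classifier labels families with terms from a hierarchical chemical
#' ontology (superclass > class > subclass > deeper levels). The tree is
#' held as a data frame with columns `term_id`, `name`, `parent_id`
#' (`NA` for roots) and `level`.
#'
#' @param terms Data frame with columns `term_id`, `name`, `parent_id`,
#'   `level`.
#' @return An object of class `ontology` (a validated data frame).
#' @export
ontology <- function(terms) {
  req <- c("term_id", "name", "parent_id", "level")
  if (!all(req %in% names(terms)))
    stop("ontology needs columns: ", paste(req, collapse = ", "))
  terms <- as.data.frame(terms)[req]
  terms$term_id <- as.character(terms$term_id)
  terms$parent_id <- as.character(terms$parent_id)
  if (anyDuplicated(terms$term_id))
    stop("duplicate term ids in ontology")
  known <- terms$parent_id %in% terms$term_id | is.na(terms$parent_id)
  if (!all(known))
    stop("unknown parent ids: ",
         paste(unique(terms$parent_id[!known]), collapse = ", "))
  # cycle check via depth computation
  d <- term_depths(terms)
  if (any(is.na(d))) stop("ontology parent links contain a cycle")
  structure(terms, class = c("ontology", "data.frame"))
}

term_depths <- function(terms) {
  depth <- setNames(rep(NA_real_, nrow(terms)), terms$term_id)
  parent <- setNames(terms$parent_id, terms$term_id)
  for (id in terms$term_id) {
    seen <- character(0)
    cur <- id
    n <- 0L
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) return(setNames(rep(NA_real_, nrow(terms)), terms$term_id))
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      n <- n + 1L
      if (n > nrow(terms)) return(setNames(rep(NA_real_, nrow(terms)), terms$term_id))
    }
    depth[[id]] <- n
  }
  depth
}

#' Read an ontology from JSON or TSV
#'
#' JSON input is an array of objects `{term_id, name, parent_id, level}`
#' (missing/`null` parent marks a root); TSV input has the same columns.
#'
#' @param file Path to a `.json` or `.tsv` file.
#' @return An [ontology] object.
#' @export
read_ontology <- function(file) {
  if (!file.exists(file)) stop("ontology file not found: ", file)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(file)
    if (is.null(df$parent_id)) df$parent_id <- NA_character_
    df$parent_id[vapply(df$parent_id, function(x) is.null(x) || length(x) == 0, TRUE)] <- NA
  } else {
    df <- utils::read.delim(file, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  }
  ontology(df)
}

#' Write an ontology to JSON
#' @param onto An [ontology] object.
#' @param file Output path.
#' @export
write_ontology <- function(onto, file) {
  jsonlite::write_json(as.data.frame(onto), file, na = "null",
                       auto_unbox = FALSE, digits = NA)
  invisible(file)
}

# All ancestors of a term, closest first (excluding the term itself).
term_ancestors <- function(onto, term_id) {
  parent <- setNames(onto$parent_id, onto$term_id)
  out <- character(0)
  cur <- term_id
  repeat {
    p <- unname(parent[cur])
    if (length(p) != 1L || is.na(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}
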