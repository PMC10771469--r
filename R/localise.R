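#' @title Partner-annotation aggregation per binding surface
#'
#' @description
#' Similar interfaces tend to bind similar partners, so the partners of a
#' binding surface can be profiled by their annotations (subcellular
#' location, molecular function, or biological process — one namespace per
#' run). `aggregate_annotations` counts, for every cluster, how many of its
#' *distinct* partners carry each term: a partner contributing several
#' interfaces to one cluster counts once, matching partner-level (not
#' interface-level) statistics. Annotation lookup is fully offline: the
#' table is supplied by the user as a two-column TSV.
#'
#' @name localise
NULL

#' Read a partner-annotation table
#'
#' TSV with columns `partner_id` and `term`; a partner with several terms
#' appears on several rows. A partner may be listed with an empty term to
#' mark it present-but-uncurated.
#'
#' @param path TSV path.
#' @return a named list partner id -> character vector of terms (possibly
#'   empty), of class `partner_annotation_table`.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("partner_id", "term") %in% names(tab)))
    stop("read_annotation_table: need columns partner_id, term",
         call. = FALSE)
  rows <- split(tab$term, tab$partner_id)
  rows <- lapply(rows, function(v) unique(v[nzchar(v)]))
  structure(rows, class = "partner_annotation_table")
}

#' Aggregate partner annotations over binding surfaces
#'
#' @param result a `clustering_result` (see [cluster_interfaces()]).
#' @param table a `partner_annotation_table` (or a plain named list partner
#'   id -> terms).
#' @param partner_of named character vector mapping every interface name to
#'   a partner identifier. By default the partner is taken as the part of
#'   the interface name before the last `-` (the `<partner>-<structure>`
#'   naming convention).
#' @return a data frame with columns `cluster_id`, `term`, `count`,
#'   `n_partners`, `fraction`; partners absent from the table are counted
#'   under the pseudo-term `"unannotated"` (with a warning), as are
#'   partners listed with no terms.
#' @export
aggregate_annotations <- function(result, table, partner_of = NULL) {
  stopifnot(inherits(result, "clustering_result"))
  if (is.null(partner_of)) {
    nm <- names(result$assignment)
    partner_of <- stats::setNames(sub("-[^-]*$", "", nm), nm)
  }
  missing <- setdiff(names(result$assignment), names(partner_of))
  if (length(missing))
    stop(sprintf("aggregate_annotations: no partner mapping for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  unknown_seen <- character(0)
  rows <- list()
  for (pr in result$profiles) {
    partners <- unique(unname(partner_of[pr$members]))
    term_counts <- list()
    unannot <- 0L
    for (p in partners) {
      terms <- if (p %in% names(table)) table[[p]] else NULL
      if (is.null(terms)) unknown_seen <- c(unknown_seen, p)
      if (length(terms) == 0L) {
        unannot <- unannot + 1L
      } else {
        for (tm in terms)
          term_counts[[tm]] <- (term_counts[[tm]] %||% 0L) + 1L
      }
    }
    terms <- names(term_counts)
    counts <- as.integer(unlist(term_counts, use.names = FALSE))
    if (unannot > 0L) {
      terms <- c(terms, "unannotated")
      counts <- c(counts, unannot)
    }
    if (length(terms))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = pr$cluster_id, term = terms, count = counts,
        n_partners = length(partners),
        fraction = counts / length(partners))
  }
  if (length(unknown_seen))
    warning(sprintf(
      "aggregate_annotations: partner(s) absent from table, counted as unannotated: %s",
      paste(unique(unknown_seen), collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster_id = integer(0), term = character(0),
                      count = integer(0), n_partners = integer(0),
                      fraction = numeric(0))
  out[order(out$cluster_id, -out$count, out$term), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
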