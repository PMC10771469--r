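#' @title Spatial clustering of a residue list
#'
#' @description
#' A flat list of (possibly interacting) residues on a structure may in
#' fact cover more than one surface patch. `cluster_residues` groups the
#' residues by agglomerative hierarchical clustering of their C-alpha to
#' C-alpha Euclidean distances — defaults: average linkage, 15 Angstrom
#' cutoff, "distance" criterion (cut the dendrogram at the cutoff,
#' inclusive). The "maxclust" criterion (ask for a fixed number of
#' clusters) is exposed as well.
#'
#' @name resclust
NULL

#' Cluster residues into spatial patches
#'
#' @param residues integer vector of residue numbers, all present in `s`.
#' @param s a [ca_structure()].
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward.D2"`.
#' @param cutoff dendrogram cut: Angstrom for `criterion = "distance"`
#'   (default 15), target cluster count for `criterion = "maxclust"`.
#' @param criterion `"distance"` (default) or `"maxclust"`.
#' @return a `residue_cluster_result`: `clusters` (list cluster id ->
#'   residue numbers, ids 1..k by decreasing size), `assignment` (named
#'   integer vector), plus the parameters used.
#' @export
cluster_residues <- function(residues, s, linkage = "average", cutoff = 15,
                             criterion = c("distance", "maxclust")) {
  criterion <- match.arg(criterion)
  linkage <- match.arg(linkage, .linkages)
  residues <- as.integer(residues)
  if (length(residues) == 0L)
    stop("cluster_residues: empty residue list", call. = FALSE)
  if (anyDuplicated(residues))
    residues <- unique(residues)
  missing <- setdiff(residues, s$residues)
  if (length(missing))
    stop(sprintf("cluster_residues: residue(s) not in structure: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (length(residues) == 1L) {
    raw <- stats::setNames(1L, as.character(residues))
  } else {
    xyz <- s$coords[match(residues, s$residues), , drop = FALSE]
    hc <- stats::hclust(stats::dist(xyz), method = linkage)
    raw <- if (criterion == "distance") stats::cutree(hc, h = cutoff)
           else stats::cutree(hc, k = min(cutoff, length(residues)))
    raw <- stats::setNames(as.integer(raw), as.character(residues))
  }
  assignment <- .relabel_by_size(raw)
  clusters <- lapply(sort(unique(assignment)), function(k)
    as.integer(names(assignment)[assignment == k]))
  structure(list(clusters = clusters, assignment = assignment,
                 cutoff = cutoff, linkage = linkage, criterion = criterion),
            class = "residue_cluster_result")
}

#' @export
print.residue_cluster_result <- function(x, ...) {
  cat(sprintf(
    "<residue_cluster_result> %d residue(s) -> %d patch(es) [%s, %s %g]\n",
    length(x$assignment), length(x$clusters), x$linkage, x$criterion,
    x$cutoff))
  invisible(x)
}

#' Write residue clusters as TSV
#'
#' Columns `residue`, `cluster_id`, one row per residue.
#'
#' @param result a `residue_cluster_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_clusters <- function(result, path) {
  utils::write.table(
    data.frame(residue = as.integer(names(result$assignment)),
               cluster_id = as.integer(result$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
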