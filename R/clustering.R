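#' @title Clustering interfaces into binding surfaces
#'
#' @description
#' Interfaces are grouped by agglomerative hierarchical clustering of the
#' sin-theta similarity matrix, average linkage by default, cutting the
#' dendrogram at a similarity threshold (default 0.866 = sin 60 degrees;
#' the cut is inclusive, so a merge at exactly the threshold is accepted).
#' Each resulting cluster is a binding surface. For every surface K the
#' probability of residue i to belong to it, `P_iK`, is the fraction of
#' member interfaces that contain i; the probabilities can be baked into the
#' B-factor column of a PDB file as `50 * (1 + P)` (so 0 outside the
#' surface, 50-100 inside) to make the surface stand out in molecular
#' viewers.
#'
#' @name clustering
NULL

.linkages <- c("average", "single", "complete", "ward.D2")

#' Cluster interfaces into binding surfaces
#'
#' A single input interface yields one singleton cluster without invoking
#' the clustering engine. Cluster ids are 1..k ordered by decreasing member
#' count, ties broken by the smallest first-member index in input order.
#'
#' @param sim a `similarity_matrix` (see [similarity_matrix()]).
#' @param ifs the [interface_set()] behind `sim`; needed to compute
#'   per-residue probabilities. May be `NULL`, in which case profiles carry
#'   no probabilities.
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward.D2"`.
#' @param threshold dendrogram cut in `(0, 1]`; default 0.866.
#' @return a `clustering_result` with fields `profiles` (list of
#'   `cluster_profile`), `assignment` (named integer vector interface ->
#'   cluster id), `linkage`, `threshold`, and `merge_trace` (plain-text
#'   dendrogram merge log).
#' @export
cluster_interfaces <- function(sim, ifs = NULL, linkage = "average",
                               threshold = 0.866) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("cluster_interfaces: threshold must be in (0, 1]", call. = FALSE)
  linkage <- match.arg(linkage, .linkages)
  nm <- sim$interface_names
  m <- length(nm)
  if (m == 1L) {
    assignment <- stats::setNames(1L, nm)
    trace <- character(0)
  } else {
    hc <- stats::hclust(stats::as.dist(sim$values), method = linkage)
    raw <- stats::cutree(hc, h = threshold)   # merges at <= threshold kept
    assignment <- stats::setNames(as.integer(raw), nm)
    trace <- sprintf("merge %d: (%d, %d) at height %.6f",
                     seq_len(nrow(hc$merge)), hc$merge[, 1], hc$merge[, 2],
                     hc$height)
  }
  assignment <- .relabel_by_size(assignment)
  profiles <- lapply(sort(unique(assignment)), function(k) {
    members <- names(assignment)[assignment == k]
    if (is.null(ifs)) {
      structure(list(cluster_id = k, members = members,
                     probabilities = numeric(0)),
                class = "cluster_profile")
    } else {
      residue_probabilities(members, ifs, cluster_id = k)
    }
  })
  structure(list(profiles = profiles, linkage = linkage,
                 threshold = threshold, assignment = assignment,
                 merge_trace = trace),
            class = "clustering_result")
}

# Relabel cluster ids 1..k by decreasing member count; ties broken by the
# smallest first-member position in the input order.
.relabel_by_size <- function(assignment) {
  ids <- unique(assignment)
  size <- vapply(ids, function(k) sum(assignment == k), integer(1))
  first <- vapply(ids, function(k) which(assignment == k)[1], integer(1))
  ord <- ids[order(-size, first)]
  stats::setNames(match(assignment, ord), names(assignment))
}

#' Number of binding surfaces in a clustering result
#' @param result a `clustering_result`.
#' @export
n_clusters <- function(result) length(result$profiles)

#' @export
print.clustering_result <- function(x, ...) {
  sizes <- vapply(x$profiles, function(p) length(p$members), integer(1))
  cat(sprintf(
    "<clustering_result> %d interface(s) -> %d binding surface(s) [%s linkage, threshold %.3f]\n",
    length(x$assignment), length(x$profiles), x$linkage, x$threshold))
  cat(sprintf("  sizes: %s\n", paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Per-residue binding-surface probabilities of one cluster
#'
#' `P_iK` is the fraction of the cluster's member interfaces that contain
#' residue i; residues never observed in the cluster are absent from the
#' map (rather than carried with probability zero).
#'
#' @param members character vector of member interface names.
#' @param ifs the [interface_set()] the names refer to.
#' @param cluster_id integer label stored in the profile.
#' @return a `cluster_profile` with fields `cluster_id`, `members`,
#'   `probabilities` (named numeric, names = residue numbers, values in
#'   `(0, 1]`).
#' @export
residue_probabilities <- function(members, ifs, cluster_id = 1L) {
  if (length(members) == 0L)
    stop("residue_probabilities: empty member list", call. = FALSE)
  unknown <- setdiff(members, interface_names(ifs))
  if (length(unknown))
    stop(sprintf("residue_probabilities: unknown interface(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  counts <- table(unlist(lapply(ifs$interfaces[members],
                                function(i) i$residues)))
  probs <- as.numeric(counts) / length(members)
  names(probs) <- names(counts)
  probs <- probs[order(as.integer(names(probs)))]
  structure(list(cluster_id = as.integer(cluster_id), members = members,
                 probabilities = probs),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> id %d, %d member(s), %d residue(s)\n",
              x$cluster_id, length(x$members), length(x$probabilities)))
  invisible(x)
}

#' Write a probability-encoded PDB file for one binding surface
#'
#' The B-factor column becomes `50 * (1 + P_iK)` for residues of the
#' profile and 0.00 for all other residues; every other column of the
#' C-alpha records is preserved. Profile residues missing from the
#' structure are skipped with a warning.
#'
#' @param s a [ca_structure()].
#' @param profile a `cluster_profile`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_probability_pdb <- function(s, profile, path) {
  probs <- profile$probabilities
  missing <- setdiff(as.integer(names(probs)), s$residues)
  if (length(missing)) {
    warning(sprintf(
      "write_probability_pdb: residue(s) %s not in structure; skipped",
      paste(missing, collapse = ", ")), call. = FALSE)
    probs <- probs[!as.integer(names(probs)) %in% missing]
  }
  write_pdb(s, path, bfactors = 50 * (1 + probs))
}

#' Write the per-cluster artifacts of a clustering run
#'
#' Emits `clusters.tsv` (`cluster_id  interface_name`), a residue-by-cluster
#' probability table `residue_probabilities.tsv`, one probability PDB per
#' cluster (`<prefix>_cluster_<k>.pdb`, requires a reference structure), and
#' a plain-text merge trace.
#'
#' @param result a `clustering_result`.
#' @param s a [ca_structure()] or `NULL` to skip PDB output.
#' @param out_dir output directory, created if needed.
#' @param prefix file-name prefix for the probability PDBs.
#' @return character vector of written paths, invisibly.
#' @export
write_cluster_outputs <- function(result, s, out_dir, prefix = "surface") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  p <- file.path(out_dir, "clusters.tsv")
  utils::write.table(
    data.frame(cluster_id = result$assignment,
               interface_name = names(result$assignment)),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, p)
  tab <- do.call(rbind, lapply(result$profiles, function(pr) {
    if (!length(pr$probabilities)) return(NULL)
    data.frame(residue = as.integer(names(pr$probabilities)),
               cluster_id = pr$cluster_id,
               probability = as.numeric(pr$probabilities))
  }))
  if (is.null(tab))
    tab <- data.frame(residue = integer(0), cluster_id = integer(0),
                      probability = numeric(0))
  p <- file.path(out_dir, "residue_probabilities.tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, p)
  p <- file.path(out_dir, "merge_trace.txt")
  writeLines(result$merge_trace, p)
  written <- c(written, p)
  if (!is.null(s)) {
    for (pr in result$profiles) {
      p <- file.path(out_dir,
                     sprintf("%s_cluster_%d.pdb", prefix, pr$cluster_id))
      write_probability_pdb(s, pr, p)
      written <- c(written, p)
    }
  }
  invisible(written)
}
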