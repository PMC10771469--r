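#' @title Combinatorial ambiguous-interaction restraints
#'
#' @description
#' Given binding-surface clusterings of a receptor and a ligand, one set of
#' ambiguous interaction restraints (AIRs) is generated per (receptor
#' surface, ligand surface) combination — N_rec x N_lig sets in total, the
#' number whose logarithm is the recognition entropy. Within each surface
#' only residues consistently observed there enter the restraint set:
#' `P_iK >= p_thr`, default 0.3 (the comparison is inclusive so that
#' `p_thr = 1` keeps unanimously observed residues). The restraint dialect
#' is a HADDOCK-style ambiguous distance statement per receptor residue,
#' satisfied when it approaches any residue of the ligand list.
#'
#' @name restraints
NULL

#' Generate restraint combinations for all surface pairs
#'
#' @param rec receptor `clustering_result` (see [cluster_interfaces()]).
#' @param lig ligand `clustering_result`.
#' @param p_thr probability threshold in `[0, 1]`; residues with
#'   `P_iK >= p_thr` are kept. Default 0.3.
#' @return list of `restraint_combination` objects (fields
#'   `receptor_cluster`, `ligand_cluster`, `receptor_residues`,
#'   `ligand_residues`, `p_thr`); combinations empty on either side after
#'   filtering are dropped with a warning.
#' @export
generate_combinations <- function(rec, lig, p_thr = 0.3) {
  stopifnot(inherits(rec, "clustering_result"),
            inherits(lig, "clustering_result"))
  if (!is.numeric(p_thr) || p_thr < 0 || p_thr > 1)
    stop("generate_combinations: p_thr must be in [0, 1]", call. = FALSE)
  pick <- function(profile) {
    pr <- profile$probabilities
    if (!length(pr))
      stop(sprintf(
        "generate_combinations: cluster %d has no residue probabilities",
        profile$cluster_id), call. = FALSE)
    as.integer(names(pr)[pr >= p_thr])
  }
  combos <- list()
  dropped <- 0L
  for (rp in rec$profiles) {
    rres <- pick(rp)
    for (lp in lig$profiles) {
      lres <- pick(lp)
      if (length(rres) == 0L || length(lres) == 0L) {
        dropped <- dropped + 1L
        next
      }
      combos[[length(combos) + 1L]] <- structure(
        list(receptor_cluster = rp$cluster_id,
             ligand_cluster = lp$cluster_id,
             receptor_residues = rres, ligand_residues = lres,
             p_thr = p_thr),
        class = "restraint_combination")
    }
  }
  if (dropped > 0L)
    warning(sprintf(
      "generate_combinations: %d combination(s) dropped (empty after p_thr filter)",
      dropped), call. = FALSE)
  if (length(combos) == 0L)
    stop("generate_combinations: every combination empty at this p_thr",
         call. = FALSE)
  combos
}

#' @export
print.restraint_combination <- function(x, ...) {
  cat(sprintf(
    "<restraint_combination> receptor cluster %d (%d res) x ligand cluster %d (%d res), p_thr %.2f\n",
    x$receptor_cluster, length(x$receptor_residues), x$ligand_cluster,
    length(x$ligand_residues), x$p_thr))
  invisible(x)
}

# One ambiguous statement per receptor residue: the residue must come
# within `dist` Angstrom of any residue of the ligand list.
.format_air <- function(combo, rec_segid, lig_segid, dist) {
  out <- character(0)
  alt <- sprintf("        (resid %d and segid %s)",
                 combo$ligand_residues, lig_segid)
  body <- paste(alt, collapse = "\n     or\n")
  for (r in combo$receptor_residues) {
    out <- c(out,
             sprintf("assign (resid %d and segid %s)", r, rec_segid),
             "       (", body,
             sprintf("       ) %.1f %.1f 0.0", dist, dist),
             "")
  }
  out
}

#' Write restraint files for a list of combinations
#'
#' Per combination: `ambig_<r>_<l>.tbl`, a HADDOCK-style ambiguous-restraint
#' table with one statement per receptor residue, and a JSON sidecar
#' `ambig_<r>_<l>.json` recording both residue lists and the threshold.
#' Output is deterministic (residues in ascending order), so regeneration is
#' byte-identical.
#'
#' @param combos non-empty list of `restraint_combination` objects.
#' @param out_dir output directory, created if needed.
#' @param rec_segid,lig_segid segment identifiers used in the statements.
#' @param dist effective ambiguous distance in Angstrom (default 2.0).
#' @return character vector of written `.tbl` paths, invisibly.
#' @export
write_restraint_files <- function(combos, out_dir, rec_segid = "A",
                                  lig_segid = "B", dist = 2.0) {
  if (length(combos) == 0L)
    stop("write_restraint_files: empty combination list", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (combo in combos) {
    stem <- sprintf("ambig_%d_%d", combo$receptor_cluster,
                    combo$ligand_cluster)
    tbl <- file.path(out_dir, paste0(stem, ".tbl"))
    writeLines(.format_air(combo, rec_segid, lig_segid, dist), tbl)
    jsonlite::write_json(
      list(receptor_cluster = combo$receptor_cluster,
           ligand_cluster = combo$ligand_cluster,
           receptor_residues = combo$receptor_residues,
           ligand_residues = combo$ligand_residues,
           p_thr = combo$p_thr),
      file.path(out_dir, paste0(stem, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, tbl)
  }
  invisible(written)
}
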