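#' @title Synthetic structures with planted binding surfaces
#'
#' @description
#' Deterministic generator used throughout the test-suite: an ideal
#' alpha-helical C-alpha trace (rise 1.5 Angstrom per residue, 100 degrees
#' per turn, radius chosen so consecutive C-alpha atoms are exactly 3.8
#' Angstrom apart) carrying k sequence-contiguous residue patches, the
#' planted binding surfaces. Each surface is observed through several
#' replicate interfaces in which every patch residue is independently
#' omitted with probability `dropout`, emulating the incomplete interface
#' observations mined from different crystal structures. Patches are
#' separated along the chain so that their spatial separation far exceeds
#' the Gaussian coupling range, making between-surface similarity close to
#' orthogonal.
#'
#' @name fixtures
NULL

# Helix radius giving exactly 3.8 A between consecutive C-alpha positions
# for rise 1.5 A and 100 degrees per residue.
.helix_rise <- 1.5
.helix_turn <- 100 * pi / 180
.helix_radius <- sqrt(3.8^2 - .helix_rise^2) / (2 * sin(.helix_turn / 2))

#' Ideal alpha-helical C-alpha trace
#'
#' @param n number of residues.
#' @param jitter standard deviation (Angstrom) of isotropic Gaussian noise
#'   added to every coordinate; 0 for the ideal geometry.
#' @param chain_id chain label.
#' @return a [ca_structure()] with residues 1..n.
#' @export
helical_structure <- function(n, jitter = 0, chain_id = "A") {
  stopifnot(n >= 1)
  i <- seq_len(n)
  coords <- cbind(.helix_radius * cos(i * .helix_turn),
                  .helix_radius * sin(i * .helix_turn),
                  .helix_rise * i)
  if (jitter > 0)
    coords <- coords + matrix(stats::rnorm(3 * n, sd = jitter), ncol = 3)
  ca_structure(chain_id, i, coords, source_id = "synthetic-helix")
}

#' Generate a planted-surface scenario
#'
#' @param k number of planted surfaces (>= 1).
#' @param patch_size residues per surface patch.
#' @param replicates interfaces observed per surface.
#' @param dropout per-residue omission probability in `[0, 1)` for each
#'   replicate (at least one residue always survives).
#' @param seed integer seed; identical seeds give identical scenarios. The
#'   caller's RNG state is left untouched.
#' @param gap residues between consecutive patches (and before the first /
#'   after the last); default 10, i.e. >= 16.5 Angstrom of spatial
#'   separation, far beyond the coupling range 4*sigma = 7.6.
#' @param jitter coordinate noise passed to [helical_structure()].
#' @param chain_length optional explicit chain length; it is an error to
#'   request one too short to hold the patches.
#' @return list with `structure` (a [ca_structure()]), `interfaces` (an
#'   [interface_set()] of `k * replicates` interfaces named
#'   `S<k>r<rep>-synth`), and `truth` (named integer vector interface ->
#'   planted surface id).
#' @export
generate_scenario <- function(k, patch_size, replicates, dropout = 0,
                              seed = 1, gap = 10, jitter = 0,
                              chain_length = NULL) {
  stopifnot(k >= 1, patch_size >= 1, replicates >= 1,
            dropout >= 0, dropout < 1, gap >= 1)
  needed <- k * patch_size + (k + 1) * gap
  if (is.null(chain_length)) chain_length <- needed
  if (chain_length < needed)
    stop(sprintf(
      "generate_scenario: chain_length %d cannot hold %d patch(es) of %d residues with gap %d (need %d)",
      chain_length, k, patch_size, gap, needed), call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  s <- helical_structure(chain_length, jitter = jitter)
  starts <- gap + (seq_len(k) - 1L) * (patch_size + gap) + 1L
  patches <- lapply(starts, function(st) st:(st + patch_size - 1L))
  ifaces <- list()
  truth <- integer(0)
  for (ki in seq_len(k)) {
    for (r in seq_len(replicates)) {
      res <- patches[[ki]]
      if (dropout > 0) {
        keep <- stats::runif(length(res)) >= dropout
        if (!any(keep)) keep[sample.int(length(res), 1)] <- TRUE
        res <- res[keep]
      }
      nm <- sprintf("S%dr%d-synth", ki, r)
      ifaces[[length(ifaces) + 1L]] <- interface(nm, res)
      truth[nm] <- ki
    }
  }
  list(structure = s, interfaces = interface_set(ifaces, reference = s),
       truth = truth)
}

#' Write a scenario to disk
#'
#' Emits `fixture.pdb`, `interfaces.json`, and `truth.tsv`
#' (`interface_name  surface_id`) under `out_dir`.
#'
#' @param scenario output of [generate_scenario()].
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(out_dir, "fixture.pdb")
  write_pdb(scenario$structure, pdb)
  ifc <- file.path(out_dir, "interfaces.json")
  write_interface_file(scenario$interfaces, ifc)
  tru <- file.path(out_dir, "truth.tsv")
  utils::write.table(
    data.frame(interface_name = names(scenario$truth),
               surface_id = as.integer(scenario$truth)),
    tru, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pdb, ifc, tru))
}
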