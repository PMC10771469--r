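#' @title Structures, interfaces and their I/O
#'
#' @description
#' A `ca_structure` is the C-alpha trace of one protein chain: one record per
#' residue, ordered by ascending residue number, carrying the raw PDB ATOM
#' line so that rewriting preserves every column except the one being edited.
#' An `interface` is a named set of residue numbers (same numbering scheme as
#' the structure, typically canonical sequence numbering); an `interface_set`
#' is an ordered collection of uniquely named interfaces, optionally bound to
#' a reference structure.
#'
#' @name structures_io
NULL

#' Construct a C-alpha structure
#'
#' @param chain_id single-character chain label.
#' @param residues integer vector of residue numbers.
#' @param coords numeric matrix (length(residues) x 3) of C-alpha coordinates
#'   in Angstrom.
#' @param source_id free-text provenance label.
#' @param lines optional character vector of raw PDB ATOM lines, one per
#'   residue, used to preserve non-coordinate columns on output.
#' @return an object of class `ca_structure`.
#' @export
ca_structure <- function(chain_id, residues, coords, source_id = "",
                         lines = NULL) {
  residues <- as.integer(residues)
  coords <- as.matrix(coords)
  if (length(residues) == 0L)
    stop("ca_structure: empty residue list", call. = FALSE)
  if (nrow(coords) != length(residues) || ncol(coords) != 3L)
    stop("ca_structure: coords must be length(residues) x 3", call. = FALSE)
  if (anyDuplicated(residues))
    stop("ca_structure: duplicated residue numbers", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("ca_structure: non-finite coordinates", call. = FALSE)
  ord <- order(residues)
  residues <- residues[ord]
  coords <- coords[ord, , drop = FALSE]
  if (!is.null(lines)) lines <- lines[ord]
  dimnames(coords) <- list(as.character(residues), c("x", "y", "z"))
  structure(
    list(chain_id = chain_id, residues = residues, coords = coords,
         source_id = source_id, lines = lines),
    class = "ca_structure"
  )
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure> chain %s, %d residues (%d..%d)%s\n",
              x$chain_id, length(x$residues), min(x$residues),
              max(x$residues),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of residues in a structure
#' @param x a `ca_structure`.
#' @export
n_residues <- function(x) length(x$residues)

#' Construct an interface
#'
#' @param name identifier, conventionally `<partner>-<structure>`.
#' @param residues integer vector of residue numbers; duplicates are removed.
#' @return an object of class `interface`.
#' @export
interface <- function(name, residues) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0L)
    stop(sprintf("interface '%s': empty residue set", name), call. = FALSE)
  if (any(residues <= 0L))
    stop(sprintf("interface '%s': residue numbers must be positive", name),
         call. = FALSE)
  structure(list(name = name, residues = residues), class = "interface")
}

#' Construct an interface set
#'
#' @param interfaces list of `interface` objects.
#' @param reference optional `ca_structure` the interfaces are projected onto.
#' @return an object of class `interface_set`.
#' @export
interface_set <- function(interfaces, reference = NULL) {
  if (!is.list(interfaces))
    stop("interface_set: expected a list of interfaces", call. = FALSE)
  nms <- vapply(interfaces, function(i) i$name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("interface_set: duplicate interface name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  names(interfaces) <- nms
  structure(list(interfaces = interfaces, reference = reference),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  cat(sprintf("<interface_set> %d interface(s)\n", length(x$interfaces)))
  invisible(x)
}

#' @export
length.interface_set <- function(x) length(x$interfaces)

#' Names of the interfaces in a set
#' @param ifs an `interface_set`.
#' @export
interface_names <- function(ifs) names(ifs$interfaces)

# -- PDB parsing ---------------------------------------------------------

# fixed PDB columns (1-based, inclusive)
.pdb_cols <- list(name = c(13, 16), altloc = c(17, 17), resname = c(18, 20),
                  chain = c(22, 22), resseq = c(23, 26), icode = c(27, 27),
                  x = c(31, 38), y = c(39, 46), z = c(47, 54),
                  b = c(61, 66))

.field <- function(lines, col) substr(lines, col[1], col[2])

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Parses ATOM records only (HETATM and all non-CA atoms are ignored) and
#' keeps exactly one C-alpha per residue: the first record wins when
#' alternate locations duplicate a residue. Only the first model of a
#' multi-model file is read. Residues carrying insertion codes are rejected
#' so that residue keys remain plain integers.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; may be omitted when the file holds exactly
#'   one chain.
#' @return a [ca_structure()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path))
    stop(sprintf("read_pdb: no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atoms <- lines[startsWith(lines, "ATOM ") | startsWith(lines, "ATOM")]
  atoms <- atoms[startsWith(atoms, "ATOM")]
  if (length(atoms) == 0L)
    stop(sprintf("read_pdb: no ATOM records in %s", path), call. = FALSE)
  ca <- atoms[trimws(.field(atoms, .pdb_cols$name)) == "CA"]
  if (length(ca) == 0L)
    stop(sprintf("read_pdb: no CA atoms in %s", path), call. = FALSE)
  chains <- unique(.field(ca, .pdb_cols$chain))
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop(sprintf(
        "read_pdb: multiple chains present (%s); pass chain= to select one",
        paste(chains, collapse = ", ")), call. = FALSE)
    chain <- chains[1]
  }
  ca <- ca[.field(ca, .pdb_cols$chain) == chain]
  if (length(ca) == 0L)
    stop(sprintf("read_pdb: no CA atoms for chain '%s' (available: %s)",
                 chain, paste(chains, collapse = ", ")), call. = FALSE)
  icodes <- trimws(.field(ca, .pdb_cols$icode))
  if (any(nzchar(icodes)))
    stop(sprintf(
      "read_pdb: residue(s) with insertion codes (%s); renumber the input",
      paste(unique(paste0(trimws(.field(ca, .pdb_cols$resseq))[nzchar(icodes)],
                          icodes[nzchar(icodes)])), collapse = ", ")),
      call. = FALSE)
  resseq <- suppressWarnings(as.integer(trimws(.field(ca, .pdb_cols$resseq))))
  if (anyNA(resseq))
    stop("read_pdb: unparseable residue number in ATOM record", call. = FALSE)
  keep <- !duplicated(resseq)  # first altloc wins
  ca <- ca[keep]; resseq <- resseq[keep]
  coords <- cbind(
    as.numeric(.field(ca, .pdb_cols$x)),
    as.numeric(.field(ca, .pdb_cols$y)),
    as.numeric(.field(ca, .pdb_cols$z)))
  if (!all(is.finite(coords)))
    stop("read_pdb: unparseable coordinates in ATOM record", call. = FALSE)
  ca_structure(chain_id = chain, residues = resseq, coords = coords,
               source_id = basename(path), lines = ca)
}

# Render a minimal, format-correct ATOM line for a C-alpha record.
.format_atom_line <- function(serial, chain, resnum, x, y, z, b = 0,
                              resname = "ALA") {
  sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, resname, chain, resnum, x, y, z, 1.00, b, "C")
}

#' Write a C-alpha structure as a PDB file
#'
#' When the structure was read from a PDB file the original ATOM lines are
#' reproduced verbatim, optionally with the B-factor column (columns 61-66)
#' replaced; otherwise minimal ATOM records are generated.
#'
#' @param s a [ca_structure()].
#' @param path output file path.
#' @param bfactors optional numeric vector named by residue number; residues
#'   not named get B-factor 0.00.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, bfactors = NULL) {
  b <- rep(0, n_residues(s))
  if (!is.null(bfactors)) {
    idx <- match(names(bfactors), as.character(s$residues))
    b[idx[!is.na(idx)]] <- bfactors[!is.na(idx)]
  }
  if (!is.null(s$lines)) {
    lines <- s$lines
    pad <- nchar(lines) < 66L
    lines[pad] <- formatC(lines[pad], width = -66L)
    substr(lines, 61L, 66L) <- sprintf("%6.2f", b)
  } else {
    lines <- .format_atom_line(seq_along(s$residues), s$chain_id, s$residues,
                               s$coords[, 1], s$coords[, 2], s$coords[, 3], b)
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# -- interface file I/O --------------------------------------------------

#' Read an interface file
#'
#' The interface file is a JSON object whose keys are interface names and
#' whose values are arrays of integer residue numbers, e.g.
#' `{"P01070-1avx": [10, 11, 12]}`. File order is preserved; duplicate
#' residue numbers within one interface are deduplicated.
#'
#' @param path path to the JSON interface file.
#' @return an [interface_set()].
#' @export
read_interface_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_interface_file: no such file: %s", path),
         call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("read_interface_file: parse error in %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) && !(is.character(names(obj)) && length(obj)))
    stop("read_interface_file: expected a JSON object name -> residue array",
         call. = FALSE)
  if (is.null(names(obj)) || any(!nzchar(names(obj))))
    stop("read_interface_file: every interface needs a name", call. = FALSE)
  if (anyDuplicated(names(obj)))
    stop(sprintf("read_interface_file: duplicate interface name(s): %s",
                 paste(unique(names(obj)[duplicated(names(obj))]),
                       collapse = ", ")), call. = FALSE)
  ifaces <- lapply(seq_along(obj), function(i) {
    v <- obj[[i]]
    if (length(v) == 0L)
      stop(sprintf("read_interface_file: empty residue list for '%s'",
                   names(obj)[i]), call. = FALSE)
    if (!is.numeric(v) || any(v != floor(v)))
      stop(sprintf("read_interface_file: non-integer residues for '%s'",
                   names(obj)[i]), call. = FALSE)
    interface(names(obj)[i], v)
  })
  interface_set(ifaces)
}

#' Write an interface set as a JSON interface file
#'
#' @param ifs an [interface_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interface_file <- function(ifs, path) {
  obj <- lapply(ifs$interfaces, function(i) i$residues)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# -- coverage filtering and structure selection --------------------------

#' Filter interfaces by structural coverage
#'
#' An interface is retained when at least `cov_cutoff` of its residues are
#' present in the structure (the comparison is inclusive: exactly 70% passes
#' at the default cutoff). In retained interfaces, residues absent from the
#' structure are dropped, so that downstream geometry is well defined.
#'
#' @param ifs an [interface_set()].
#' @param s a [ca_structure()].
#' @param cov_cutoff coverage fraction in (0, 1]; default 0.7.
#' @param strict if `TRUE`, fail instead of silently dropping interfaces
#'   below the cutoff.
#' @return a filtered [interface_set()] with `reference` set to `s`.
#' @export
filter_interfaces <- function(ifs, s, cov_cutoff = 0.7, strict = FALSE) {
  stopifnot(cov_cutoff > 0, cov_cutoff <= 1)
  kept <- list()
  for (i in ifs$interfaces) {
    present <- i$residues[i$residues %in% s$residues]
    cov <- length(present) / length(i$residues)
    if (cov >= cov_cutoff) {
      kept[[length(kept) + 1L]] <- interface(i$name, present)
    } else if (strict) {
      stop(sprintf(
        "filter_interfaces: interface '%s' coverage %.2f < cutoff %.2f",
        i$name, cov, cov_cutoff), call. = FALSE)
    }
  }
  if (length(kept) == 0L)
    stop(paste("filter_interfaces: no interface meets the coverage cutoff;",
               "consider a different reference structure"), call. = FALSE)
  interface_set(kept, reference = s)
}

#' Select the candidate structure retaining the most interfaces
#'
#' Mirrors the reference-structure choice of the interface-mining pipeline:
#' among candidate chains the one on which the largest number of interfaces
#' survives the coverage filter wins; ties go to the earliest candidate
#' (candidates are assumed pre-ranked, e.g. by coverage/resolution).
#'
#' @param candidates non-empty list of [ca_structure()] objects.
#' @param ifs an [interface_set()].
#' @param cov_cutoff coverage fraction, see [filter_interfaces()].
#' @return the winning `ca_structure`.
#' @export
select_best_structure <- function(candidates, ifs, cov_cutoff = 0.7) {
  if (length(candidates) == 0L)
    stop("select_best_structure: no candidates", call. = FALSE)
  counts <- vapply(candidates, function(s) {
    res <- tryCatch(filter_interfaces(ifs, s, cov_cutoff),
                    error = function(e) NULL)
    if (is.null(res)) 0L else length(res)
  }, integer(1))
  candidates[[which.max(counts)]]
}
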