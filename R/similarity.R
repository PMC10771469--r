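#' @title Gaussian-coupling interface similarity
#'
#' @description
#' Each interface is regarded as an indicator function over the C-alpha
#' atoms of the reference chain, smoothed by a Gaussian kernel of width
#' `sigma`. The coupling between atoms i and j is
#' `J_ij = exp(-r_ij^2 / (4 sigma^2))` with `r_ij` their Euclidean distance.
#' From the couplings follow an interface norm `E(I)` (double sum of `J_ij`
#' over residue pairs of I, diagonal included), a scalar product
#' `<phi_I, phi_J>` between two interfaces, a Hilbert-space distance
#' `D(I,J) = sqrt(E(I) + E(J) - 2 <phi_I, phi_J>)`, and the angle between
#' interfaces, `cos(theta) = <phi_I, phi_J> / sqrt(E(I) E(J))`. The working
#' similarity is `sin(theta)`: 0 for identical patches, 1 for patches so far
#' apart that their smoothed footprints are orthogonal. The default
#' `sigma = 1.9` Angstrom is half the spacing between consecutive C-alpha
#' atoms along a protein backbone.
#'
#' @name similarity
NULL

#' Gaussian coupling matrix of a structure
#'
#' @param s a [ca_structure()].
#' @param sigma Gaussian width in Angstrom (default 1.9, half the consecutive
#'   C-alpha spacing of 3.8).
#' @return a `coupling_matrix`: the dense symmetric matrix
#'   `exp(-r^2/(4 sigma^2))` over all C-alpha pairs, with unit diagonal,
#'   rows/columns indexed by residue number.
#' @export
coupling_matrix <- function(s, sigma = 1.9) {
  stopifnot(inherits(s, "ca_structure"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("coupling_matrix: sigma must be a positive scalar", call. = FALSE)
  if (!all(is.finite(s$coords)))
    stop("coupling_matrix: non-finite coordinates", call. = FALSE)
  d2 <- as.matrix(stats::dist(s$coords))^2
  values <- exp(-d2 / (4 * sigma^2))
  diag(values) <- 1
  dimnames(values) <- list(as.character(s$residues), as.character(s$residues))
  structure(list(values = values, sigma = sigma, residue_index = s$residues),
            class = "coupling_matrix")
}

# Map interface residues onto coupling-matrix rows, failing loudly on a
# projection bug upstream.
.iface_rows <- function(I, J) {
  idx <- match(I$residues, J$residue_index)
  if (anyNA(idx))
    stop(sprintf(
      "interface '%s': residue(s) %s absent from the coupling matrix; project onto the structure first",
      I$name, paste(I$residues[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}

#' Interface norm E(I)
#'
#' Double sum of couplings over all ordered residue pairs of the interface,
#' diagonal terms included, so a single-residue interface has norm 1 and
#' `E(I) >= |I|` always.
#'
#' @param I an [interface()].
#' @param J a [coupling_matrix()].
#' @return a non-negative scalar.
#' @export
interface_norm <- function(I, J) {
  idx <- .iface_rows(I, J)
  sum(J$values[idx, idx])
}

#' Scalar product between two interfaces
#'
#' `sum_{i in I, j in K} J_ij`; reduces to [interface_norm()] when `I == K`.
#' Strictly positive for any pair because all couplings are positive.
#'
#' @param I,K [interface()] objects.
#' @param J a [coupling_matrix()].
#' @return a positive scalar.
#' @export
scalar_product <- function(I, K, J) {
  sum(J$values[.iface_rows(I, J), .iface_rows(K, J)])
}

#' Hilbert-space distance between two interfaces
#'
#' `sqrt(E(I) + E(K) - 2 <phi_I, phi_K>)`, with the radicand clamped at zero
#' against tiny negative floating error. Note this distance grows with
#' interface size even for co-located patches, which is why the angle-based
#' similarity below is used for clustering.
#'
#' @inheritParams scalar_product
#' @return a non-negative scalar.
#' @export
pair_distance <- function(I, K, J) {
  d2 <- interface_norm(I, J) + interface_norm(K, J) -
    2 * scalar_product(I, K, J)
  sqrt(max(d2, 0))
}

#' Sine of the angle between two interfaces
#'
#' `cos(theta) = <phi_I, phi_K> / sqrt(E(I) E(K))`, clipped into `[0, 1]`
#' (analytically non-negative since all couplings are positive; clipping
#' guards the subsequent square root against floating error), then
#' `sin(theta) = sqrt(1 - cos^2)`.
#'
#' @inheritParams scalar_product
#' @return a scalar in `[0, 1]`; 0 for identical interfaces.
#' @export
pair_sine <- function(I, K, J) {
  cth <- scalar_product(I, K, J) /
    sqrt(interface_norm(I, J) * interface_norm(K, J))
  cth <- min(max(cth, 0), 1)
  sqrt(1 - cth^2)
}

#' Pairwise sin-theta similarity matrix of an interface set
#'
#' @param ifs an [interface_set()] already projected onto `s` (see
#'   [filter_interfaces()]).
#' @param s a [ca_structure()].
#' @param sigma Gaussian width in Angstrom.
#' @return a `similarity_matrix`: symmetric m x m matrix of `sin(theta)`
#'   with exact zero diagonal, names in set order.
#' @export
similarity_matrix <- function(ifs, s, sigma = 1.9) {
  m <- length(ifs)
  if (m < 1L)
    stop("similarity_matrix: need at least one interface", call. = FALSE)
  J <- coupling_matrix(s, sigma)
  # vectorized route: cross-interface sums via an indicator matrix
  ind <- vapply(ifs$interfaces,
                function(i) as.numeric(J$residue_index %in% i$residues),
                numeric(length(J$residue_index)))
  gram <- crossprod(ind, J$values %*% ind)   # gram[a,b] = <phi_a, phi_b>
  gram <- (gram + t(gram)) / 2
  norms <- diag(gram)
  cth <- gram / sqrt(outer(norms, norms))
  cth <- pmin(pmax(cth, 0), 1)
  values <- sqrt(1 - cth^2)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(interface_names(ifs), interface_names(ifs))
  new_similarity_matrix(values)
}

#' Construct/validate a similarity matrix
#'
#' @param values symmetric numeric matrix with entries in `[0, 1]` and zero
#'   diagonal; dimnames give the interface names.
#' @return a `similarity_matrix`.
#' @export
new_similarity_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity_matrix: not square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8)
    stop("similarity_matrix: not symmetric", call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("similarity_matrix: entries outside [0, 1]", call. = FALSE)
  if (any(diag(values) != 0))
    stop("similarity_matrix: nonzero diagonal", call. = FALSE)
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("interface_", seq_len(nrow(values))),
                             paste0("interface_", seq_len(nrow(values))))
  structure(list(values = values, interface_names = rownames(values)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d interface(s)\n",
              length(x$interface_names)))
  invisible(x)
}

#' Sine of an angle given in degrees
#'
#' Utility behind the default clustering threshold: a 60-degree angle
#' between interfaces corresponds to `sin(theta) = 0.866`.
#'
#' @param degrees angle in degrees.
#' @return `sin(degrees * pi / 180)`.
#' @export
sine_of_angle <- function(degrees) sin(degrees * pi / 180)

#' Write a similarity matrix as whitespace-delimited text
#'
#' One upper-triangle record `name_i name_j sin_theta` per line, sine values
#' with 4 decimals.
#'
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  nm <- sim$interface_names
  lines <- character(0)
  if (length(nm) > 1L) {
    pairs <- utils::combn(seq_along(nm), 2)
    lines <- sprintf("%s %s %.4f", nm[pairs[1, ]], nm[pairs[2, ]],
                     sim$values[t(pairs)])
  }
  writeLines(lines, path)
  invisible(path)
}
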