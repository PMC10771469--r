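#' @title Recognition entropy and docking-quality score
#'
#' @description
#' Two scalar summaries connect binding-surface complexity to docking
#' difficulty. The recognition entropy of a complex is the Boltzmann-like
#' `S = ln(N_rec * N_lig)`, the log of the number of possible combinations
#' of binding surfaces on receptor and ligand. The docking-quality score
#' aggregates per-method best-model qualities over the top-(1, 5, 10, 50,
#' 100) cutoffs as `Q = sum_m sum_t Q_mt / t`, where t is the *rank index*
#' of the cutoff (t = 1 for top 1, t = 2 for top 5, ...), and `Q_mt` is 0-3
#' (incorrect / acceptable / medium / high quality best model).
#'
#' @name metrics
NULL

.top_array <- c(1, 5, 10, 50, 100)

#' Recognition entropy of a receptor/ligand pair
#'
#' @param n_rec_clusters number of binding surfaces on the receptor (>= 1).
#' @param n_lig_clusters number of binding surfaces on the ligand (>= 1).
#' @return `ln(n_rec_clusters * n_lig_clusters)` in nats.
#' @examples
#' recognition_entropy(13, 4)  # ln 52 = 3.95
#' recognition_entropy(1, 5)   # ln 5  = 1.61
#' @export
recognition_entropy <- function(n_rec_clusters, n_lig_clusters) {
  if (!is.numeric(n_rec_clusters) || !is.numeric(n_lig_clusters) ||
      n_rec_clusters < 1 || n_lig_clusters < 1 ||
      n_rec_clusters != floor(n_rec_clusters) ||
      n_lig_clusters != floor(n_lig_clusters))
    stop("recognition_entropy: cluster counts must be integers >= 1",
         call. = FALSE)
  log(n_rec_clusters * n_lig_clusters)
}

#' One method's best-model qualities over the top-N array
#'
#' @param method method identifier.
#' @param qualities numeric vector of length 5: best-model quality (0-3) at
#'   the top-1, top-5, top-10, top-50, top-100 cutoffs. Must be
#'   non-decreasing: enlarging the pool cannot worsen the best model.
#' @return a `docking_quality_record`.
#' @export
docking_quality_record <- function(method, qualities) {
  qualities <- as.numeric(qualities)
  if (length(qualities) != length(.top_array))
    stop(sprintf("docking_quality_record('%s'): need %d qualities (top %s)",
                 method, length(.top_array),
                 paste(.top_array, collapse = "/")), call. = FALSE)
  if (anyNA(qualities) || !all(qualities %in% 0:3))
    stop(sprintf("docking_quality_record('%s'): qualities must be in {0,1,2,3}",
                 method), call. = FALSE)
  if (is.unsorted(qualities))
    stop(sprintf(
      "docking_quality_record('%s'): qualities must be non-decreasing in t",
      method), call. = FALSE)
  structure(list(method = method, qualities = qualities),
            class = "docking_quality_record")
}

#' Composite docking-quality score
#'
#' `Q_docking = sum over methods and t of Q_mt / t`, t = 1..5 indexing the
#' top-(1, 5, 10, 50, 100) array. Bounded by `3 * H_5 = 137/20` per method.
#'
#' @param records list of [docking_quality_record()] objects.
#' @return a non-negative scalar.
#' @export
docking_quality <- function(records) {
  if (length(records) == 0L)
    stop("docking_quality: no records", call. = FALSE)
  sum(vapply(records, function(r) {
    stopifnot(inherits(r, "docking_quality_record"))
    sum(r$qualities / seq_along(r$qualities))
  }, numeric(1)))
}

#' Read a docking-quality table
#'
#' TSV with columns `complex`, `method`, `Q_top1`, `Q_top5`, `Q_top10`,
#' `Q_top50`, `Q_top100`.
#'
#' @param path TSV path.
#' @return named list: one list of [docking_quality_record()] per complex.
#' @export
read_docking_quality_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("complex", "method", paste0("Q_top", .top_array))
  if (!all(need %in% names(tab)))
    stop(sprintf("read_docking_quality_table: missing column(s): %s",
                 paste(setdiff(need, names(tab)), collapse = ", ")),
         call. = FALSE)
  split_rows <- split(seq_len(nrow(tab)), tab$complex)
  lapply(split_rows, function(rows) {
    lapply(rows, function(r)
      docking_quality_record(tab$method[r],
                             as.numeric(tab[r, paste0("Q_top", .top_array)])))
  })
}

#' Pearson correlation between recognition entropy and docking quality
#'
#' @param S numeric vector of recognition entropies.
#' @param Q numeric vector of docking-quality scores, same length.
#' @return Pearson r.
#' @export
entropy_quality_correlation <- function(S, Q) {
  if (length(S) != length(Q) || length(S) < 3L)
    stop("entropy_quality_correlation: need >= 3 paired observations",
         call. = FALSE)
  if (stats::sd(S) == 0 || stats::sd(Q) == 0)
    stop("entropy_quality_correlation: constant column, r undefined",
         call. = FALSE)
  stats::cor(S, Q)
}
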