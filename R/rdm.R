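#' Representational dissimilarity matrices
#'
#' An `rdm` stores the `choose(n, 2)` pairwise dissimilarities between
#' conditions as a vector in canonical order: pairs (i, j) with i < j sorted
#' by i then j, i.e. (1,2), (1,3), ..., (1,n), (2,3), ... This matches the
#' ordering used by [stats::dist()].
#'
#' @param values numeric vector of length `choose(n_conditions, 2)`.
#' @param n_conditions number of conditions.
#' @param metric name of the dissimilarity metric (e.g. `"sq_euclidean"`,
#'   `"ldc"`).
#' @return object of class `rdm`.
#' @export
new_rdm <- function(values, n_conditions, metric = "unknown") {
  values <- as.numeric(values)
  if (length(values) != choose(n_conditions, 2))
    stop("rdm length ", length(values), " does not match choose(",
         n_conditions, ", 2)")
  structure(values, class = "rdm", n_conditions = n_conditions,
            metric = metric)
}

#' Canonical pair index for n conditions
#'
#' @param n number of conditions.
#' @return data.frame with integer columns `i`, `j` (i < j), one row per pair
#'   in canonical order.
#' @export
pair_index <- function(n) {
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d conditions, %d pairs, metric = %s\n",
              attr(x, "n_conditions"), length(x), attr(x, "metric")))
  print(utils::head(as.numeric(x)))
  invisible(x)
}

#' Convert an RDM vector to a symmetric matrix (zero diagonal)
#' @param x an `rdm`.
#' @return square numeric matrix.
#' @export
rdm_to_matrix <- function(x) {
  n <- attr(x, "n_conditions")
  m <- matrix(0, n, n)
  pi <- pair_index(n)
  m[cbind(pi$i, pi$j)] <- as.numeric(x)
  m[cbind(pi$j, pi$i)] <- as.numeric(x)
  m
}

#' Extract the canonical pair vector from a symmetric matrix
#' @param m square symmetric matrix.
#' @param metric metric name to record.
#' @return an `rdm`.
#' @export
matrix_to_rdm <- function(m, metric = "unknown") {
  n <- nrow(m)
  pi <- pair_index(n)
  new_rdm(m[cbind(pi$i, pi$j)], n, metric)
}

#' Restrict an RDM to a subset of conditions
#'
#' @param x an `rdm`.
#' @param conditions integer indices of the conditions to keep, in the order
#'   they should appear in the restricted RDM.
#' @return an `rdm` over `length(conditions)` conditions.
#' @export
subset_rdm <- function(x, conditions) {
  m <- rdm_to_matrix(x)
  matrix_to_rdm(m[conditions, conditions, drop = FALSE], attr(x, "metric"))
}

#' Per-condition mean dissimilarity (row means of the square form)
#' @param x an `rdm`.
#' @return numeric vector, one mean-to-all-others value per condition.
#' @export
rdm_condition_means <- function(x) {
  n <- attr(x, "n_conditions")
  rowSums(rdm_to_matrix(x)) / (n - 1)
}
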