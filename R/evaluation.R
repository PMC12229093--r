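# Quantitative evaluation: candidate-set cross-modal retrieval accuracy,
# per-gene and per-spot Pearson correlation, MSE/MAE, and correlation
# histograms.

#' Build the spatially-adjacent candidate set for a query spot
#'
#' The pool is the query's true partner plus its `k` nearest spots by
#' Euclidean distance on the stored coordinates (ties by index), so chance
#' accuracy is `1 / (k + 1)`.
#'
#' @param coords n x 2 coordinate matrix
#' @param query query spot index
#' @param k number of adjacent spots to add (5 or 10 in the standard
#'   protocols)
#' @return a `candidate_set`
#' @export
adjacent_candidates <- function(coords, query, k) {
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  d <- sqrt(rowSums((coords - matrix(coords[query, ], n, 2L,
                                     byrow = TRUE))^2))
  others <- setdiff(order(d, seq_len(n)), query)
  structure(list(query_index = query,
                 candidate_indices = c(query, others[seq_len(k)]),
                 kind = "adjacent", k = as.integer(k)),
            class = "candidate_set")
}

#' Build a random candidate set for a query spot
#'
#' The pool is the true partner plus `k` spots drawn uniformly without
#' replacement from the remaining spots, seeded.
#'
#' @param n total number of spots
#' @param query query spot index
#' @param k number of random distractors
#' @param rng_seed integer seed
#' @return a `candidate_set`
#' @export
random_candidates <- function(n, query, k, rng_seed) {
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  others <- setdiff(seq_len(n), query)
  idx <- with_seed(rng_seed, others[sample.int(length(others), k)])
  structure(list(query_index = query,
                 candidate_indices = c(query, idx),
                 kind = "random", k = as.integer(k)),
            class = "candidate_set")
}

#' Candidate-set alignment accuracy
#'
#' A query counts as correct iff the cosine similarity between its image
#' embedding and its paired expression embedding is strictly the maximum
#' over the candidate pool (ties count as incorrect). Returns
#' `N_correct / N`.
#'
#' @param V image embedding matrix (one row per spot)
#' @param E expression embedding matrix, row-aligned with `V`
#' @param candidate_sets list of `candidate_set` objects
#' @return fraction in `[0, 1]`
#' @export
alignment_accuracy <- function(V, E, candidate_sets) {
  if (!length(candidate_sets)) stop("no candidate sets supplied")
  Vn <- l2_normalize(as.matrix(V))
  En <- l2_normalize(as.matrix(E))
  correct <- vapply(candidate_sets, function(cs) {
    cand <- cs$candidate_indices
    if (!length(cand)) stop("empty candidate set for query ",
                            cs$query_index)
    sims <- as.numeric(En[cand, , drop = FALSE] %*% Vn[cs$query_index, ])
    true_sim <- sims[match(cs$query_index, cand)]
    true_sim > max(sims[cand != cs$query_index])
  }, logical(1))
  mean(correct)
}

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation; constant vectors are undefined and return
#' `NA` with a warning rather than propagating NaN.
#'
#' @param x,y numeric vectors of equal length (>= 2)
#' @return correlation in `[-1, 1]`, or `NA` for a constant input
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    warning("constant vector: Pearson correlation undefined")
    return(NA_real_)
  }
  sum(xc * yc) / den
}

#' Mean squared and mean absolute error
#'
#' @param X,X_p matrices of identical shape
#' @return named numeric vector `c(mse, mae)`
#' @export
mse_mae <- function(X, X_p) {
  if (!identical(dim_of(X), dim_of(X_p)))
    stop("shape mismatch: ", paste(dim_of(X), collapse = "x"), " vs ",
         paste(dim_of(X_p), collapse = "x"))
  d <- X - X_p
  c(mse = mean(d^2), mae = mean(abs(d)))
}

#' Histogram of per-gene correlations
#'
#' Counts genes per half-open bin `[lo, hi)` over the given edges; values
#' below the first or at/above the last edge are not counted.
#'
#' @param pcc_gene numeric vector of per-gene correlations
#' @param bin_edges increasing vector of bin edges
#' @return named integer vector of counts, one per bin
#' @export
correlation_histogram <- function(pcc_gene, bin_edges) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  v <- pcc_gene[is.finite(pcc_gene)]
  idx <- findInterval(v, bin_edges, rightmost.closed = FALSE)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  names(counts) <- paste0("[", utils::head(bin_edges, -1L), ",",
                          utils::tail(bin_edges, -1L), ")")
  counts
}

#' Full evaluation report for predicted expression
#'
#' Per-gene Pearson (across spots), per-spot Pearson (across the panel),
#' MSE and MAE. Constant vectors yield `NA` correlations and are excluded
#' from the reported means.
#'
#' @param X spots x genes ground-truth matrix
#' @param X_p spots x genes predicted matrix
#' @return an `eval_report` list
#' @export
evaluate_predictions <- function(X, X_p) {
  if (!identical(dim_of(X), dim_of(X_p)))
    stop("shape mismatch between truth and prediction")
  pcc_gene <- vapply(seq_len(ncol(X)), function(j)
    suppressWarnings(pearson(X[, j], X_p[, j])), numeric(1))
  pcc_spot <- vapply(seq_len(nrow(X)), function(i)
    suppressWarnings(pearson(X[i, ], X_p[i, ])), numeric(1))
  em <- mse_mae(X, X_p)
  structure(list(pcc_gene = pcc_gene, pcc_spot = pcc_spot,
                 mean_pcc_gene = mean(pcc_gene, na.rm = TRUE),
                 mean_pcc_spot = mean(pcc_spot, na.rm = TRUE),
                 mse = unname(em["mse"]), mae = unname(em["mae"])),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n",
      sprintf("  mean per-gene PCC: %.4f\n", x$mean_pcc_gene),
      sprintf("  mean per-spot PCC: %.4f\n", x$mean_pcc_spot),
      sprintf("  MSE: %.4f   MAE: %.4f\n", x$mse, x$mae), sep = "")
  invisible(x)
}
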