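# Post-processing of the clustering chain: posterior similarity, a single
# representative partition, and Table-style summary profiles with
# '<' / '0' / '>' level codes.

#' Posterior co-clustering similarity matrix
#'
#' Entry (i, j) is the fraction of kept iterations in which subjects i and j
#' share a cluster.
#'
#' @param chain A [dp_cluster()] result.
#' @return Symmetric n x n matrix with unit diagonal.
#' @export
similarity <- function(chain) {
  z <- chain$z
  iters <- nrow(z)
  if (is.null(iters) || iters < 1) abort("chain has no kept iterations")
  n <- ncol(z)
  Cmax <- max(z)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = iters),
                            j = as.vector(z) + rep.int(seq_len(iters) - 1L, n) * Cmax,
                            x = 1,
                            dims = c(n, iters * Cmax))
  S <- as.matrix(Matrix::tcrossprod(A)) / iters
  dimnames(S) <- NULL
  S
}

#' Representative partition of the subjects
#'
#' Summarizes the posterior over partitions by one concrete clustering:
#' for each candidate number of clusters, partitioning around medoids of the
#' dissimilarity `1 - S` provides a starting allocation, which is then
#' refined by greedy reassignment until the least-squares distance to the
#' similarity matrix, `sum_ij (S_ij - 1[same cluster])^2`, stops improving;
#' the partition minimizing that criterion over the candidates is returned.
#'
#' @param S A [similarity()] matrix.
#' @param k_range Candidate cluster counts (default `1:10`).
#' @return List with `cluster` (integer allocation), `k`, `criterion`, and
#'   `criterion_by_k`.
#' @export
representative_partition <- function(S, k_range = 1:10) {
  n <- nrow(S)
  k_range <- k_range[k_range >= 1 & k_range <= n]
  if (!length(k_range)) abort("empty k_range")
  D <- stats::as.dist(1 - S)
  best <- NULL
  crit <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    g <- if (k == 1) rep(1L, n) else
      as.integer(cluster::pam(D, k, diss = TRUE, pamonce = 5,
                              cluster.only = TRUE))
    g <- refine_partition(S, g)
    sc <- partition_score(S, g)
    crit[i] <- sc
    if (is.null(best) || sc < best$criterion) {
      best <- list(cluster = g, k = max(g), criterion = sc)
    }
  }
  best$criterion_by_k <- crit
  best
}

# greedy descent on the least-squares criterion: move each subject to the
# cluster whose membership reduces the criterion most; equivalent to
# maximizing sum_{j in c} (S_ij - 1/2) over clusters c
refine_partition <- function(S, g, max_pass = 20) {
  K <- max(g)
  if (K == 1) return(g)
  for (pass in seq_len(max_pass)) {
    B <- matrix(0, length(g), K)
    B[cbind(seq_along(g), g)] <- 1
    sizes <- colSums(B)
    gain <- S %*% B - 0.5 * rep(sizes, each = nrow(B))
    # exclude the subject's own diagonal contribution
    gain <- gain - (diag(S) - 0.5) * B
    g_new <- max.col(gain, ties.method = "first")
    if (all(g_new == g)) break
    g <- g_new
    # drop emptied clusters, relabelling compactly
    g <- match(g, sort(unique(g)))
    K <- max(g)
    if (K == 1) break
  }
  as.integer(g)
}

partition_score <- function(S, g) {
  B <- outer(g, g, "==")
  sum((S - B)^2)
}

#' Summary profiles of the representative clusters
#'
#' For each kept iteration, the probability of observing level x of
#' covariate p in representative cluster A is the member-averaged model
#' probability `phi^gamma * pi^(1-gamma)` under the members' current
#' allocations, so iterations in which the covariate is switched off
#' contribute the fixed marginal. The 95% credible interval of the
#' difference between that probability and the observed sample frequency
#' yields the level code: `>` when the interval lies above zero, `<` below,
#' `0` when it covers zero.
#'
#' @param chain A [dp_cluster()] result.
#' @param partition A [representative_partition()] result (or bare integer
#'   vector covering all subjects).
#' @param level Credible level (default 0.95).
#' @return Object of class `profile_summary`: a tibble with columns
#'   `cluster`, `size`, `covariate`, `level`, `estimate`, `conf.low`,
#'   `conf.high`, `symbol`, carrying the posterior median selection
#'   probabilities as attribute `rho_medians`.
#' @export
summarize_profiles <- function(chain, partition, level = 0.95) {
  g <- if (is.list(partition)) partition$cluster else as.integer(partition)
  if (length(g) != chain$n) abort("partition does not cover all subjects")
  iters <- nrow(chain$z)
  K <- max(g)
  sizes <- tabulate(g, K)
  L <- length(chain$pi)
  rowp <- chain$rowp
  qarr <- array(NA_real_, c(L, K, iters))
  for (t in seq_len(iters)) {
    snap <- chain$snapshots[[t]]
    Cocc <- length(snap$ids)
    # effective level probabilities per occupied cluster
    E <- snap$phi * snap$gamma[rowp, , drop = FALSE] +
      chain$pi * (1 - snap$gamma)[rowp, , drop = FALSE]
    # cross-tabulate representative cluster x chain cluster
    zt <- match(chain$z[t, ], snap$ids)
    N <- matrix(tabulate((g - 1L) * Cocc + zt, K * Cocc), Cocc, K)
    qarr[, , t] <- E %*% N / rep(sizes, each = L)
  }
  alp <- (1 - level) / 2
  lo <- apply(qarr, c(1, 2), quantile, probs = alp, names = FALSE)
  hi <- apply(qarr, c(1, 2), quantile, probs = 1 - alp, names = FALSE)
  med <- apply(qarr, c(1, 2), median)
  spec <- chain$spec
  lev_id <- unlist(lapply(as.integer(spec), function(m) 0:(m - 1L)))
  out <- tidyr::expand_grid(cluster = seq_len(K), row = seq_len(L))
  out <- tibble::tibble(
    cluster = out$cluster,
    size = sizes[out$cluster],
    covariate = names(spec)[rowp[out$row]],
    level = lev_id[out$row],
    estimate = med[cbind(out$row, out$cluster)] - chain$pi[out$row],
    conf.low = lo[cbind(out$row, out$cluster)] - chain$pi[out$row],
    conf.high = hi[cbind(out$row, out$cluster)] - chain$pi[out$row])
  out$symbol <- dplyr::case_when(out$conf.low > 0 ~ ">",
                                 out$conf.high < 0 ~ "<",
                                 TRUE ~ "0")
  structure(out, rho_medians = rho_medians(chain),
            class = c("profile_summary", class(out)))
}

#' Compact layout of a profile summary
#'
#' One row per representative cluster, one column per covariate, each entry
#' the concatenated level codes (e.g. `"<0>"`), preceded by a row of
#' posterior median selection probabilities.
#'
#' @param profiles A [summarize_profiles()] result.
#' @return A tibble in the compact layout.
#' @export
profile_codes <- function(profiles) {
  wide <- profiles |>
    dplyr::group_by(.data$cluster, .data$size, .data$covariate) |>
    dplyr::summarise(code = paste(.data$symbol[order(.data$level)],
                                  collapse = ""), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "covariate", values_from = "code")
  rho <- attr(profiles, "rho_medians")
  hdr <- tibble::tibble(cluster = NA_integer_, size = NA_integer_)
  for (nm in names(wide)[-(1:2)]) hdr[[nm]] <- format(round(rho[[nm]], 2))
  dplyr::bind_rows(hdr, dplyr::mutate(wide, dplyr::across(-c(1, 2), as.character)))
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("<profile_summary> ", max(x$cluster), " representative clusters\n",
      sep = "")
  print(profile_codes(x), n = Inf)
  invisible(x)
}
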