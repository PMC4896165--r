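# The T-gamma edge-evidence matrix: a cluster-size-weighted, chain-averaged
# summary of joint covariate selection, rescaled to a maximum of one. Small
# entries flag covariate pairs unlikely to be joined by an edge in a highly
# supported graphical model; large entries are NOT evidence of edge presence.

#' Build the edge-evidence matrix from a clustering chain
#'
#' For every kept iteration and every cluster with more than one subject,
#' the pair (p1, p2) scores `gamma_p1c * gamma_p2c`; scores are summed over
#' clusters and iterations with cluster-size weights and the matrix is
#' rescaled so its largest element is one.
#'
#' @param chain A [dp_cluster()] result.
#' @return Object of class `tgamma_matrix`: symmetric P x P numeric matrix
#'   with entries in `[0, 1]` and `NA` on the diagonal.
#' @export
build_tgamma <- function(chain) {
  if (is.null(chain$snapshots) || !length(chain$snapshots)) {
    abort("chain does not carry selection switches")
  }
  P <- length(chain$spec)
  Tm <- matrix(0, P, P)
  for (snap in chain$snapshots) {
    keep <- snap$sizes > 1L
    if (!any(keep)) next
    G <- snap$gamma[, keep, drop = FALSE]
    Tm <- Tm + G %*% (snap$sizes[keep] * t(G))
  }
  diag(Tm) <- 0
  if (max(Tm) > 0) Tm <- Tm / max(Tm)
  diag(Tm) <- NA_real_
  dimnames(Tm) <- list(names(chain$spec), names(chain$spec))
  structure(Tm, class = c("tgamma_matrix", "matrix"))
}

#' Coerce a square matrix to an edge-evidence matrix
#'
#' Validates symmetry and the `[0, 1]` range of the off-diagonal entries;
#' the diagonal is set to `NA`.
#'
#' @param m Square numeric matrix with covariate dimnames.
#' @return A `tgamma_matrix`.
#' @export
as_tgamma <- function(m) new_tgamma(m)

#' @export
`[.tgamma_matrix` <- function(x, ...) {
  out <- unclass(x)[...]
  # a square submatrix over one covariate subset is itself an evidence matrix
  if (is.matrix(out) && nrow(out) == ncol(out) && nrow(out) > 1 &&
      !is.null(rownames(out)) && identical(rownames(out), colnames(out))) {
    out <- tryCatch(new_tgamma(out), error = function(e) out)
  }
  out
}

new_tgamma <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("edge-evidence matrix must be square")
  diag(m) <- NA_real_
  off <- m[upper.tri(m)]
  if (any(is.na(off)) || any(off < 0) || any(off > 1)) {
    abort("edge-evidence entries must lie in [0, 1]")
  }
  if (!isTRUE(all.equal(m[upper.tri(m)], t(m)[upper.tri(m)]))) {
    abort("edge-evidence matrix must be symmetric")
  }
  structure(m, class = c("tgamma_matrix", "matrix"))
}

#' @export
print.tgamma_matrix <- function(x, ...) {
  cat("<tgamma_matrix> ", nrow(x), " covariates\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Screen covariates by their posterior selection probability
#'
#' Covariates whose posterior median selection probability falls below the
#' threshold are flagged as marginally independent of all others and dropped
#' from the log-linear stage; the bookkeeping reports how much smaller the
#' resulting model space and contingency table are.
#'
#' @param rho_medians Named numeric vector of per-covariate posterior
#'   medians (see [rho_medians()]).
#' @param threshold Drop below this value (default 0.15).
#' @param spec Optional [factor_spec()] for the full covariate set; when
#'   given, the cell and model counts before/after reduction are reported.
#' @return Object of class `covariate_screen`: list with `kept`, `dropped`,
#'   `threshold`, and (with `spec`) a `reduction` tibble with columns
#'   `stage`, `n_covariates`, `log2_models`, `models`, `cells`.
#' @export
screen_covariates <- function(rho_medians, threshold = 0.15, spec = NULL) {
  if (is.null(names(rho_medians))) {
    names(rho_medians) <- paste0("x", seq_along(rho_medians))
  }
  kept <- names(rho_medians)[rho_medians >= threshold]
  dropped <- setdiff(names(rho_medians), kept)
  out <- list(kept = kept, dropped = dropped, threshold = threshold)
  if (!is.null(spec)) {
    if (!all(names(rho_medians) %in% names(spec))) {
      abort("rho medians and factor spec do not match")
    }
    sub <- spec[kept]
    n_kept <- length(kept)
    out$reduction <- tibble::tibble(
      stage = c("full", "screened"),
      n_covariates = c(length(spec), n_kept),
      log2_models = c(length(spec) * (length(spec) - 1) / 2,
                      n_kept * (n_kept - 1) / 2),
      models = c(count_graphical_models(length(spec)),
                 count_graphical_models(max(n_kept, 1))),
      cells = c(count_cells(spec),
                if (n_kept) count_cells(sub) else NA_real_))
  }
  structure(out, class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat("<covariate_screen> threshold ", x$threshold, "\n", sep = "")
  cat("kept (", length(x$kept), "): ", paste(x$kept, collapse = " "), "\n",
      sep = "")
  cat("dropped (", length(x$dropped), "): ",
      paste(x$dropped, collapse = " "), "\n", sep = "")
  if (!is.null(x$reduction)) {
    r <- x$reduction
    cat(sprintf("model space: 2^%d -> 2^%d graphs; cells: %s -> %s\n",
                r$log2_models[1], r$log2_models[2],
                format(r$cells[1], digits = 4),
                format(r$cells[2], digits = 4)))
  }
  invisible(x)
}
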