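# Plain-text interchange: covariate matrices, long-format contingency
# tables and edge-evidence matrices as CSV.

#' Read a subject-by-covariate CSV
#'
#' Header row gives covariate names; levels are integer coded from 0.
#'
#' @param path CSV file.
#' @param spec Optional [factor_spec()] to validate against.
#' @return Tibble of covariates (attribute `spec` attached).
#' @export
read_covariates <- function(path, spec = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(spec)) spec <- infer_spec(d) else check_levels(d, spec)
  structure(d[names(spec)], spec = spec)
}

#' @rdname read_covariates
#' @param data Covariate tibble.
#' @export
write_covariates <- function(data, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(data),
                                 -dplyr::starts_with(".")), path)
  invisible(path)
}

#' Read a long-format contingency table CSV
#'
#' One integer level column per factor plus a final `count` column; missing
#' cells are completed with zeros (with a warning).
#'
#' @param path CSV file.
#' @param spec Optional [factor_spec()].
#' @return A `contingency_tbl`.
#' @export
read_contingency <- function(path, spec = NULL) {
  contingency_table(readr::read_csv(path, show_col_types = FALSE), spec)
}

#' @rdname read_contingency
#' @param table A `contingency_tbl`.
#' @export
write_contingency <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Read or write an edge-evidence matrix CSV
#'
#' Stored as a labelled square matrix; on read, the upper triangle is
#' mirrored onto the lower and entries are validated to lie in `[0, 1]`.
#'
#' @param path CSV file.
#' @return A `tgamma_matrix`.
#' @export
read_tgamma <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  labs <- d[[1]]
  m <- as.matrix(d[, -1])
  if (nrow(m) != ncol(m)) abort("edge-evidence CSV must be square")
  dimnames(m) <- list(labs, colnames(m))
  if (!identical(as.character(labs), colnames(m))) {
    abort("row and column labels disagree")
  }
  up <- upper.tri(m)
  low_given <- !is.na(t(m)[up])
  if (any(!is.na(m[t(up)]) & abs(m - t(m))[t(up)] > 1e-8, na.rm = TRUE)) {
    abort("edge-evidence CSV is asymmetric")
  }
  m[t(up)] <- t(m)[t(up)]
  new_tgamma(m)
}

#' @rdname read_tgamma
#' @param tgamma A `tgamma_matrix`.
#' @export
write_tgamma <- function(tgamma, path) {
  m <- unclass(as.matrix(tgamma))
  m[lower.tri(m)] <- NA
  d <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(covariate = rownames(m)), d)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Run the full exploration pipeline
#'
#' Clusters the subjects, summarizes selection, builds the edge-evidence
#' matrix, screens marginally independent covariates, and searches the
#' reduced graphical-model space by reversible jump.
#'
#' @param data Subject-by-covariate data frame (integer levels) or a path to
#'   a covariate CSV.
#' @param cluster_burnin,cluster_iter Clustering chain lengths.
#' @param rj_iters,rj_burnin Model-search chain lengths.
#' @param threshold Screening threshold on posterior median selection
#'   probabilities.
#' @param strategy Edge-selection strategy for the search (default `"d"`).
#' @param seed Integer seed governing every stage.
#' @param options [dp_options()] for the clustering stage.
#' @param k_range Candidate cluster counts for the representative partition.
#' @param out_dir Optional directory: intermediates (rho draws, evidence
#'   matrix, reduced table, report) are written there as CSV/JSON.
#' @return Object of class `catdep_report`: list with `rho` (median
#'   selection probabilities), `profiles`, `tgamma`, `screen`, `search`
#'   (`rj_chain` on the reduced table, or `NULL` if fewer than two
#'   covariates survive), and `seed`.
#' @export
run_pipeline <- function(data, cluster_burnin = 500, cluster_iter = 1000,
                         rj_iters = 10000, rj_burnin = 1000,
                         threshold = 0.15, strategy = "d", seed = 1,
                         options = dp_options(), k_range = 1:10,
                         out_dir = NULL) {
  if (is.character(data)) data <- read_covariates(data)
  prep <- dp_data(data)
  chain <- dp_cluster(prep, burnin = cluster_burnin, iter = cluster_iter,
                      options = options, seed = seed)
  part <- representative_partition(similarity(chain), k_range)
  profiles <- summarize_profiles(chain, part)
  tg <- build_tgamma(chain)
  med <- rho_medians(chain)
  scr <- screen_covariates(med, threshold, spec = prep$spec)
  search <- NULL
  if (length(scr$kept) >= 2) {
    keep <- dplyr::select(tibble::as_tibble(data),
                          dplyr::all_of(scr$kept))
    tab <- as_contingency(keep, prep$spec[scr$kept])
    tg_red <- new_tgamma(unclass(tg)[scr$kept, scr$kept, drop = FALSE])
    search <- rj_search(tab, strategy = strategy, tgamma = tg_red,
                        iters = rj_iters, burnin = rj_burnin,
                        seed = seed + 1L)
  }
  report <- structure(list(rho = med, profiles = profiles, tgamma = tg,
                           screen = scr, search = search, seed = seed),
                      class = "catdep_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tibble::as_tibble(chain$rho), file.path(out_dir, "rho_draws.csv"))
    write_tgamma(tg, file.path(out_dir, "tgamma.csv"))
    readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
    if (!is.null(search)) {
      readr::write_csv(search$models, file.path(out_dir, "models.csv"))
    }
    jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_json <- function(x) {
  out <- list(seed = x$seed,
              rho_medians = as.list(x$rho),
              kept = x$screen$kept, dropped = x$screen$dropped,
              threshold = x$screen$threshold)
  if (!is.null(x$screen$reduction)) {
    r <- x$screen$reduction
    out$reduction <- list(log2_models = r$log2_models, cells = r$cells)
  }
  if (!is.null(x$search)) {
    out$search <- list(best = x$search$best,
                       first_hit = x$search$first_hit,
                       accept_rate_model = x$search$accept_rate_model,
                       top_models = head(x$search$models, 5))
  }
  out
}

#' @export
print.catdep_report <- function(x, ...) {
  cat("== catdep pipeline report (seed ", x$seed, ") ==\n", sep = "")
  cat("\nposterior median selection probabilities:\n")
  print(round(x$rho, 3))
  print(x$screen)
  if (!is.null(x$search)) {
    cat("\n")
    print(x$search)
  }
  invisible(x)
}
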