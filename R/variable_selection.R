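#' Squared multiple correlations
#'
#' The SMC of a variable is the R-squared of its least-squares regression on
#' all other variables (complete rows only); it indexes how redundant the
#' variable is with the rest of the candidate set.
#'
#' @param data numeric matrix or data frame, trials x variables.
#' @return named numeric vector of SMC values in \[0, 1\]; `NA` for constant
#'   columns.
#' @export
smc_scores <- function(data) {
  x <- as.matrix(data)
  stopifnot(ncol(x) >= 2L)
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) <= ncol(x))
    stop("SMC requires more complete rows than variables")
  out <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  const <- apply(x, 2L, function(v) stats::var(v) == 0)
  for (j in seq_len(ncol(x))) {
    if (const[j]) next
    others <- x[, -j, drop = FALSE]
    others <- others[, !const[-j], drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), x[, j])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    out[j] <- 1 - ss_res / ss_tot
  }
  out
}

#' Iterative multicollinearity filter
#'
#' While any variable's SMC exceeds `tolerance`, drops the variable with the
#' highest SMC (ties broken by variable-name order) and recomputes. The
#' default tolerance of 0.8 is a conservative threshold for concern about
#' multicollinearity in regression modelling.
#'
#' @param data trials x variables matrix or data frame.
#' @param tolerance SMC cutoff (default 0.8).
#' @return list with `retained` (column names kept), `dropped` (data frame
#'   of `variable`, `smc_at_drop`, `step`), `smc` (final SMC values).
#' @export
filter_multicollinear <- function(data, tolerance = 0.8) {
  x <- as.data.frame(data)
  dropped <- data.frame(variable = character(), smc_at_drop = numeric(),
                        step = integer(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    s <- smc_scores(x)
    s_ok <- s[!is.na(s)]
    if (length(s_ok) == 0L || max(s_ok) <= tolerance) break
    step <- step + 1L
    worst <- names(s_ok)[s_ok == max(s_ok)]
    worst <- sort(worst)[1L]
    dropped <- rbind(dropped,
                     data.frame(variable = worst, smc_at_drop = max(s_ok),
                                step = step, stringsAsFactors = FALSE))
    x[[worst]] <- NULL
    if (ncol(x) < 2L) break
  }
  list(retained = names(x), dropped = dropped,
       smc = if (ncol(x) >= 2L) smc_scores(x) else setNames(numeric(0), character(0)))
}

#' Eigenvalues of the correlation matrix and Kaiser factor count
#'
#' Principal-component eigenvalues of the variable correlation matrix
#' (complete rows), with the number of factors chosen by Kaiser's criterion
#' (eigenvalues strictly greater than 1).
#'
#' @param data trials x variables matrix or data frame.
#' @return list with `eigenvalues` (descending) and `n_factors`.
#' @export
pca_factor_count <- function(data) {
  x <- as.matrix(data)
  stopifnot(ncol(x) >= 3L)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ev[ev < 0 & ev > -1e-12] <- 0
  list(eigenvalues = ev, n_factors = sum(ev > 1))
}

#' Maximum-likelihood factor model with varimax rotation
#'
#' Fits an orthogonal factor model by maximum likelihood
#' ([stats::factanal()]) with varimax rotation, orders the factors by
#' descending explained variance (sum of squared loadings), and assigns each
#' variable to the factor on which it has its largest absolute loading.
#'
#' @param data trials x variables matrix or data frame.
#' @param n_factors number of factors (1 <= n_factors < n variables).
#' @param rotation rotation name passed to `factanal` (default `"varimax"`).
#' @return object of class `vp_factor_model`: list with `loadings`
#'   (variables x factors), `rotation`, `rep_scores`, `factor_assignment`,
#'   `explained_variance`.
#' @export
factor_model <- function(data, n_factors, rotation = "varimax") {
  x <- as.matrix(data)
  stopifnot(n_factors >= 1L, n_factors < ncol(x))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  fit <- tryCatch(
    stats::factanal(x, factors = n_factors, rotation = rotation),
    error = function(e) stop("factor model did not converge: ",
                             conditionMessage(e)))
  L <- unclass(fit$loadings)
  ssq <- colSums(L^2)
  ord <- order(ssq, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  colnames(L) <- paste0("factor", seq_len(ncol(L)))
  assign <- apply(abs(L), 1L, which.max)
  structure(list(loadings = L, rotation = rotation,
                 rep_scores = if (n_factors >= 2L) rep_scores(L) else NULL,
                 factor_assignment = assign,
                 explained_variance = sort(ssq, decreasing = TRUE)),
            class = "vp_factor_model")
}

#' Rep scores from a loading matrix
#'
#' A variable's rep score is its highest factor loading minus the signed sum
#' of its loadings on all other factors. High rep scores mark variables that
#' load selectively onto a single factor and are therefore good
#' representatives of it.
#'
#' @param loadings variables x factors numeric matrix (>= 2 factors).
#' @return named numeric vector of rep scores.
#' @export
rep_scores <- function(loadings) {
  L <- as.matrix(loadings)
  stopifnot(ncol(L) >= 2L)
  apply(L, 1L, function(r) {
    m <- max(r)
    m - (sum(r) - m)
  })
}

#' Select representative and independent regressors
#'
#' For each factor, selects the variable assigned to it (largest absolute
#' loading) whose absolute loading is at least `strong`, preferring the
#' highest rep score (ties broken by larger absolute loading, then variable
#' name); factors with no qualifying variable get no representative.
#' Variables whose maximum absolute loading is below `independent` are
#' returned as independents. A manual override list is honored and logged
#' with reason `"manual"`.
#'
#' @param model `vp_factor_model`.
#' @param strong minimum absolute loading for a representative (default 0.6).
#' @param independent maximum absolute loading for an independent variable
#'   (default 0.4).
#' @param manual character vector of variable names to force into the
#'   selection.
#' @return data frame with columns `variable`, `reason`
#'   (`representative`/`independent`/`manual`), `factor` (NA for
#'   independents), `rep_score`, `max_abs_loading`.
#' @export
select_regressors <- function(model, strong = 0.6, independent = 0.4,
                              manual = character()) {
  L <- model$loadings
  rs <- model$rep_scores
  if (is.null(rs)) rs <- setNames(rep(NA_real_, nrow(L)), rownames(L))
  max_abs <- apply(abs(L), 1L, max)
  assign <- model$factor_assignment
  rows <- list()
  for (f in seq_len(ncol(L))) {
    cand <- rownames(L)[assign == f & abs(L[, f]) >= strong]
    cand <- setdiff(cand, manual)
    if (length(cand) == 0L) next
    o <- order(-rs[cand], -max_abs[cand], cand)
    pick <- cand[o[1L]]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = pick, reason = "representative", factor = f,
      rep_score = rs[pick], max_abs_loading = max_abs[pick],
      stringsAsFactors = FALSE)
  }
  indep <- setdiff(rownames(L)[max_abs < independent], manual)
  for (v in indep) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, reason = "independent", factor = NA_integer_,
      rep_score = rs[v], max_abs_loading = max_abs[v],
      stringsAsFactors = FALSE)
  }
  for (v in manual) {
    if (!v %in% rownames(L))
      stop("manual override names unknown variable: ", v)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, reason = "manual", factor = assign[v],
      rep_score = rs[v], max_abs_loading = max_abs[v],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("empty regressor selection")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference factor-loading table
#'
#' Published five-factor varimax loading pattern for 18 locomotor variables
#' from a cued-approach study, with the printed rep-score column. Used as a
#' worked example and as ground truth for checking [rep_scores()] against an
#' independently computed column.
#'
#' @return data frame: `variable`, `factor1`..`factor5`, `rep_score_printed`.
#' @export
reference_factor_loadings <- function() {
  path <- system.file("extdata", "reference_factor_loadings.csv",
                      package = "cuevigor", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
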