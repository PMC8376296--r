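#' Build a per-neuron design matrix
#'
#' Retains correct-response DS trials on which the animal was still at cue
#' onset and all regressor values are present; the response is the spike
#' count in the chosen window after cue onset. Trials are dropped listwise
#' (with reasons) and the neuron is flagged unfittable when fewer than
#' `length(regressors) + 10` rows remain.
#'
#' @param features trial feature table ([trial_features()] output, or any
#'   data frame with the bookkeeping and regressor columns).
#' @param counts `vp_counts` for this neuron aligned to the same cue onsets
#'   as `features` rows (one count row per feature row).
#' @param window ms pair, response window (e.g. `c(40, 400)`).
#' @param regressors character vector of regressor column names.
#' @return object of class `vp_design`: list with `y`, `X` (data frame of
#'   regressor columns), `trials` (row indices retained), `dropped` (data
#'   frame of index + reason), `window`, `fittable`.
#' @export
build_design <- function(features, counts, window, regressors) {
  stopifnot(nrow(features) == nrow(counts$counts))
  lo <- counts$bin_edges_ms[-length(counts$bin_edges_ms)]
  hi <- counts$bin_edges_ms[-1L]
  sel <- which(lo >= window[1L] & hi <= window[2L])
  y_all <- as.integer(rowSums(counts$counts[, sel, drop = FALSE]))
  reason <- rep(NA_character_, nrow(features))
  reason[features$cue_type != "DS"] <- "not_DS"
  reason[is.na(reason) & !features$responded] <- "no_response"
  reason[is.na(reason) & !features$still_at_cue] <- "moving_at_cue"
  ok_regs <- if (length(regressors) > 0L)
    stats::complete.cases(features[, regressors, drop = FALSE])
  else rep(TRUE, nrow(features))
  reason[is.na(reason) & !ok_regs] <- "missing_regressor"
  keep <- which(is.na(reason))
  dropped <- data.frame(index = which(!is.na(reason)),
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  X <- features[keep, regressors, drop = FALSE]
  structure(list(y = y_all[keep], X = X, trials = keep, dropped = dropped,
                 window = window,
                 fittable = length(keep) >= length(regressors) + 10L),
            class = "vp_design")
}

#' Fit a Poisson GLM of cue-evoked spike counts
#'
#' Maximum-likelihood Poisson regression with logarithmic link of the
#' response-window spike count on the (unstandardized) regressors, with
#' intercept. Effect sizes are returned as IDR Firing Differences: the
#' percent change in predicted firing across each regressor's interdecile
#' range, `(exp(beta * IDR) - 1) * 100`.
#'
#' @param design `vp_design`.
#' @return object of class `vp_glm`: data frame `effects` (term, beta, se,
#'   z, p, idr, ifd_percent) plus `converged`, `n_trials`, `window`.
#' @export
fit_poisson_glm <- function(design) {
  if (!design$fittable)
    stop("design flagged unfittable (too few retained trials)")
  df <- cbind(data.frame(.y = design$y), design$X)
  fit <- if (ncol(df) == 1L) glm(.y ~ 1, data = df, family = poisson())
         else glm(.y ~ ., data = df, family = poisson())
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  eff <- data.frame(term = terms, beta = sm[, 1L], se = sm[, 2L],
                    z = sm[, 3L], p = sm[, 4L],
                    idr = NA_real_, ifd_percent = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(eff))) {
    if (eff$term[i] == "(Intercept)") next
    v <- design$X[[eff$term[i]]]
    res <- idr_firing_difference(eff$beta[i], v)
    eff$idr[i] <- res$idr
    eff$ifd_percent[i] <- res$ifd_percent
  }
  diverged <- any(abs(sm[, 1L]) > 1e3) || !fit$converged
  structure(list(effects = eff, converged = fit$converged && !diverged,
                 n_trials = length(design$y), window = design$window),
            class = "vp_glm")
}

#' IDR Firing Difference
#'
#' Converts a Poisson-GLM coefficient into the estimated percent change in
#' firing across the regressor's interdecile range (difference between its
#' 90th and 10th percentiles, linear-interpolation percentile rule):
#' `IFD = (exp(beta * IDR) - 1) * 100`.
#'
#' @param beta regression coefficient (per unit of the regressor).
#' @param regressor_values the regressor's values over the retained trials
#'   (>= 10 values).
#' @return list with `idr`, `ifd_percent`, `degenerate` (TRUE when the
#'   regressor is constant, in which case IFD is 0).
#' @export
idr_firing_difference <- function(beta, regressor_values) {
  stopifnot(length(regressor_values) >= 10L)
  q <- quantile(regressor_values, probs = c(0.1, 0.9), names = FALSE,
                type = 7)
  idr <- q[2L] - q[1L]
  if (idr == 0)
    return(list(idr = 0, ifd_percent = 0, degenerate = TRUE))
  list(idr = idr, ifd_percent = (exp(beta * idr) - 1) * 100,
       degenerate = FALSE)
}

#' Population tests of IDR Firing Differences
#'
#' For each regressor, a two-sided one-sample t test of the per-neuron IFD
#' values against zero, with Holm's step-down correction across the
#' regressor family within the window. Significance is declared at adjusted
#' p < 0.05.
#'
#' @param ifd neurons x regressors numeric matrix (or data frame) of IFD
#'   percentages.
#' @param window label recorded in the output (e.g. `"overall"`).
#' @param alpha significance level after adjustment (default 0.05).
#' @return data frame: `regressor`, `window`, `n`, `mean_ifd`, `se`, `t`,
#'   `df`, `p_raw`, `p_holm`, `significant`.
#' @export
population_ifd_tests <- function(ifd, window = "overall", alpha = 0.05) {
  m <- as.matrix(ifd)
  stopifnot(!is.null(colnames(m)))
  rows <- lapply(colnames(m), function(v) {
    x <- m[, v]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 3L)
      stop("population test requires >= 3 neurons per regressor")
    if (sd(x) == 0) {
      return(data.frame(regressor = v, window = window, n = n,
                        mean_ifd = mean(x), se = 0, t = NA_real_,
                        df = n - 1L, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(x, mu = 0)
    data.frame(regressor = v, window = window, n = n, mean_ifd = mean(x),
               se = sd(x) / sqrt(n), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  out
}

#' Cross-subject one-way ANOVA of IFD values
#'
#' Fixed-effects one-way ANOVA comparing mean IFD across subjects, used to
#' check that a population-level effect is not driven by one animal.
#' Subjects contributing fewer than 2 neurons are excluded with a warning.
#'
#' @param ifd per-neuron numeric vector.
#' @param subject per-neuron subject labels.
#' @return list with `F`, `df1`, `df2`, `p`, `n_subjects`.
#' @export
cross_subject_anova <- function(ifd, subject) {
  stopifnot(length(ifd) == length(subject))
  keep <- is.finite(ifd)
  ifd <- ifd[keep]; subject <- as.character(subject)[keep]
  tab <- table(subject)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warning("excluding subject(s) with < 2 neurons: ",
            paste(small, collapse = ", "))
    keep <- !(subject %in% small)
    ifd <- ifd[keep]; subject <- subject[keep]
  }
  if (length(unique(subject)) < 2L)
    stop("cross-subject ANOVA requires >= 2 subjects with >= 2 neurons")
  a <- anova(lm(ifd ~ factor(subject)))
  list(F = a[1L, "F value"], df1 = a[1L, "Df"], df2 = a[2L, "Df"],
       p = a[1L, "Pr(>F)"], n_subjects = length(unique(subject)))
}
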