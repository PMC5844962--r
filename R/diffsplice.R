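## Differential splicing shared by both pipelines: per event, a negative
## binomial GLM with isoform and condition main effects and their
## interaction; H0: no interaction, tested by a 1-df likelihood ratio test;
## BH adjustment across events; PSI / DeltaPSI effect sizes.

#' Fit the NB interaction model and test one event
#'
#' Counts follow log lambda_ijk = mu + alpha_i + beta_j + (alpha beta)_ij
#' with i the isoform (variant 1 = inclusion), j the condition and k the
#' replicate. The full and reduced (no-interaction) models share one NB
#' dispersion per event, estimated by the Pearson moment estimator under
#' the reduced model (the null); when the design has no replication within
#' isoform-condition cells the dispersion is inestimable and the fit falls
#' back to Poisson, as it does when the estimate collapses to zero. The
#' p-value comes from the LRT statistic against chi-square with one degree
#' of freedom.
#'
#' @param incl,excl Numeric count vectors per sample (same order).
#' @param condition Condition labels per sample (2 levels).
#' @param dispersion NB dispersion to use (var = mu + dispersion * mu^2);
#'   `NULL` estimates it from this event's within-cell replication
#'   ([estimate_dispersion()]); 0, a negative value or an inestimable case
#'   falls back to Poisson.
#' @return List: `p_value`, `lrt`, `theta` (NA for Poisson), `family`,
#'   `coef` (full-model coefficients), `loglik_full`, `loglik_reduced`,
#'   `degenerate` flag.
#' @export
fit_and_test <- function(incl, excl, condition, dispersion = NULL) {
  incl <- round(incl + 1e-9)  # half-up rounding of junction-mean counts
  excl <- round(excl + 1e-9)
  if (all(incl == 0) || all(excl == 0) || length(unique(condition)) < 2L) {
    return(list(p_value = NA_real_, lrt = NA_real_, theta = NA_real_,
                family = "degenerate", coef = NULL,
                loglik_full = NA_real_, loglik_reduced = NA_real_,
                degenerate = TRUE))
  }
  d <- data.frame(count = c(incl, excl),
                  isoform = factor(rep(c("inclusion", "exclusion"),
                                       each = length(incl)),
                                   levels = c("inclusion", "exclusion")),
                  condition = factor(rep(condition, 2L)))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(d$count, d$isoform, d$condition)
  theta <- if (is.finite(dispersion) && dispersion > 0) 1 / dispersion
  else NA_real_
  fam <- if (is.na(theta) || theta <= 0 || theta > 1e6) {
    stats::poisson()
  } else {
    MASS::negative.binomial(theta)
  }
  full <- suppressWarnings(stats::glm(count ~ isoform * condition,
                                      data = d, family = fam))
  red <- suppressWarnings(stats::glm(count ~ isoform + condition,
                                     data = d, family = fam))
  ll_full <- as.numeric(stats::logLik(full))
  ll_red <- as.numeric(stats::logLik(red))
  lrt <- max(0, 2 * (ll_full - ll_red))
  list(p_value = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
       lrt = lrt,
       theta = if (inherits(fam, "family") &&
                   fam$family == "poisson") NA_real_ else theta,
       family = fam$family, coef = stats::coef(full),
       loglik_full = ll_full, loglik_reduced = ll_red,
       degenerate = FALSE)
}

#' Moment estimation of the NB dispersion from within-cell replication
#'
#' For each isoform-condition cell with at least two replicates, the excess
#' of the within-cell sum of squares over its Poisson expectation estimates
#' `dispersion * mu^2` per residual degree of freedom; the cell
#' contributions are pooled. Returns NA when no cell is replicated
#' (single-replicate designs cannot separate dispersion from interaction).
#'
#' @param count,isoform,condition Parallel vectors (long format), possibly
#'   spanning several events via `event` interaction in `isoform`.
#' @return Dispersion estimate (may be negative when the data are
#'   underdispersed; callers treat values <= 0 as Poisson), or NA.
#' @export
estimate_dispersion <- function(count, isoform, condition) {
  cells <- split(count, paste(isoform, condition))
  num <- 0; den <- 0
  for (y in cells) {
    nc <- length(y)
    if (nc < 2L) next
    yb <- mean(y)
    if (yb <= 0) next
    num <- num + (sum((y - yb)^2) - (nc - 1L) * yb)
    den <- den + (nc - 1L) * yb^2
  }
  if (den > 0) num / den else NA_real_
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; undefined p-values are excluded from
#' the number of tests and reinserted as NA.
#'
#' @param p Numeric vector of p-values (may contain NA).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-condition PSI
#'
#' PSI = inclusion / (inclusion + exclusion), computed per replicate and
#' averaged within condition. A replicate PSI is undefined when its total
#' count falls below `min_count` (preventing large effect sizes derived
#' from low counts); a condition PSI is undefined when all its replicate
#' PSIs are.
#'
#' @param incl,excl Count vectors per sample.
#' @param condition Condition labels per sample.
#' @param min_count Minimum total count per replicate (default 10).
#' @return Named numeric vector of condition PSIs (NA when undefined).
#' @export
compute_psi <- function(incl, excl, condition, min_count = 10) {
  tot <- incl + excl
  psi_rep <- ifelse(tot >= min_count & tot > 0, incl / tot, NA_real_)
  vapply(split(psi_rep, condition), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' DeltaPSI between two conditions
#'
#' DeltaPSI = PSI(condition 1) - PSI(condition 2); undefined when either
#' condition PSI is.
#'
#' @param psi1,psi2 Condition PSIs.
#' @return DeltaPSI or NA.
#' @export
compute_delta_psi <- function(psi1, psi2) {
  if (is.na(psi1) || is.na(psi2)) NA_real_ else psi1 - psi2
}

#' Differential analysis of a count table
#'
#' Fits and tests every event, adjusts p-values across events and calls an
#' event significant when its adjusted p-value is at most `fdr` and its
#' |DeltaPSI| at least `min_delta_psi`.
#'
#' @param counts Long count table: event_id, isoform
#'   ("inclusion"/"exclusion"), condition, replicate, count. See
#'   [as_count_table()] to derive one from an event table.
#' @param psi_min_count PSI masking threshold (total counts per replicate).
#' @param fdr FDR level (default 0.05).
#' @param min_delta_psi Minimum |DeltaPSI| for a significant call
#'   (default 0.1).
#' @return A `diff_splice` data.table: event_id, p_value, padj, psi1, psi2,
#'   delta_psi, significant, degenerate.
#' @export
run_differential <- function(counts, psi_min_count = 10, fdr = 0.05,
                             min_delta_psi = 0.1) {
  counts <- as.data.table(counts)
  req <- c("event_id", "isoform", "condition", "replicate", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  wide <- dcast(counts, event_id + condition + replicate ~ isoform,
                value.var = "count", fill = 0)
  if (!"inclusion" %in% names(wide)) wide[, inclusion := 0]
  if (!"exclusion" %in% names(wide)) wide[, exclusion := 0]
  # one dispersion shared across events, pooled over the within-cell
  # replication of every event (cell = event x isoform x condition)
  common_disp <- estimate_dispersion(
    round(c(wide$inclusion, wide$exclusion) + 1e-9),
    paste(rep(wide$event_id, 2L), rep(c("i", "e"), each = nrow(wide))),
    rep(wide$condition, 2L))
  res <- wide[, {
    ft <- fit_and_test(inclusion, exclusion, condition,
                       dispersion = common_disp)
    psi <- compute_psi(inclusion, exclusion, condition, psi_min_count)
    conds <- sort(unique(condition))
    .(p_value = ft$p_value,
      psi1 = psi[[as.character(conds[1L])]],
      psi2 = if (length(conds) > 1L) psi[[as.character(conds[2L])]]
             else NA_real_,
      loglik_full = ft$loglik_full, loglik_reduced = ft$loglik_reduced,
      degenerate = ft$degenerate)
  }, by = event_id]
  res[, delta_psi := mapply(compute_delta_psi, psi1, psi2)]
  res[, padj := adjust_bh(p_value)]
  res[, significant := !is.na(padj) & padj <= fdr &
        !is.na(delta_psi) & abs(delta_psi) >= min_delta_psi]
  setcolorder(res, c("event_id", "p_value", "padj", "psi1", "psi2",
                     "delta_psi", "significant"))
  class(res) <- c("diff_splice", class(res))
  res[]
}

#' @export
print.diff_splice <- function(x, ...) {
  cat("Differential splicing:", nrow(x), "event(s);",
      sum(x$significant), "significant (padj <= 0.05, |DeltaPSI| >= 0.1);",
      sum(is.na(x$p_value)), "untestable\n")
  NextMethod()
  invisible(x)
}

#' @export
summary.diff_splice <- function(object, ...) {
  cat("events tested :", sum(!is.na(object$p_value)), "/", nrow(object), "\n")
  cat("significant   :", sum(object$significant), "\n")
  dp <- object$delta_psi[object$significant]
  if (length(dp)) cat("|DeltaPSI| of significant: median",
                      round(stats::median(abs(dp)), 3), "\n")
  invisible(object)
}

#' Build a long count table from an event table and a sample sheet
#'
#' @param events Event table with `incl_<sample>` / `excl_<sample>` columns.
#' @param samples Sample sheet (sample, condition, replicate).
#' @return Long count table for [run_differential()].
#' @export
as_count_table <- function(events, samples) {
  samples <- as.data.table(samples)
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    rows[[length(rows) + 1L]] <- data.table(
      event_id = events$event_id,
      isoform = "inclusion", condition = samples$condition[i],
      replicate = samples$replicate[i],
      count = events[[paste0("incl_", s)]])
    rows[[length(rows) + 1L]] <- data.table(
      event_id = events$event_id,
      isoform = "exclusion", condition = samples$condition[i],
      replicate = samples$replicate[i],
      count = events[[paste0("excl_", s)]])
  }
  rbindlist(rows)
}
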