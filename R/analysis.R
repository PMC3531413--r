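#' Temporal response classes
#'
#' The three temporal patterns of cytoskeletal response to a sustained
#' stretch, plus `"flat"` for unstretched controls whose trace never leaves
#' the tolerance band.  The fourth conceivable pattern -- reinforcement
#' followed by retraction -- is deliberately not a class: it was never
#' observed and is structurally unreachable in the sector model
#' (depolymerization happens only at the stretch event and growth is
#' monotone), so a trace exhibiting it is flagged as an anomaly instead.
#'
#' @return Character vector of the valid class labels.
#' @export
response_class_levels <- function() {
  c("monotonic_reinforcement", "retraction_then_reinforcement",
    "monotonic_retraction", "flat")
}

#' Classify a normalized fibrosity trace
#'
#' Applies a 3-point moving median to suppress single-frame noise, then
#' labels the trace from its minimum `m` and final value `f` (the reference
#' frame is 1):
#' monotonic reinforcement when the trace never dips materially
#' (`m >= 1 - delta`) and ends high (`f >= 1 + delta`); retraction followed
#' by reinforcement when it dips (`m <= 1 - delta`) but recovers
#' (`f >= m + delta`); monotonic retraction when it ends low without
#' recovery; flat when the maximum deviation from 1 stays below `delta`.
#' A trace that rises at least `delta` above 1 and then falls back by more
#' than `delta` from its peak -- reinforcement followed by retraction, a
#' pattern with no label -- is classified by the rules above but tagged with
#' attribute `anomaly = TRUE` and a warning.
#'
#' @param trace A [fibrosity_trace()] (or plain numeric vector of normalized
#'   values) with at least 3 time points.
#' @param delta Classification threshold on the normalized fibrosity scale.
#'   Default 0.10: about half the smallest stretch-induced fibrosity change
#'   observed experimentally (drops of 20-40%, rises of ~50%).
#' @return A length-1 character vector from [response_class_levels()], with
#'   attribute `anomaly`.
#' @examples
#' classify_trace(c(1, 1.2, 1.4, 1.5))         # monotonic_reinforcement
#' classify_trace(c(1, 0.7, 0.75, 1.0, 1.3))   # retraction_then_reinforcement
#' classify_trace(c(1, 0.7, 0.72, 0.7))        # monotonic_retraction
#' @export
classify_trace <- function(trace, delta = 0.10) {
  x <- if (inherits(trace, "fibrosity_trace")) trace$values else as.numeric(trace)
  if (length(x) < 3L) {
    stop("classification requires at least 3 time points", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("trace contains non-finite values", call. = FALSE)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  x <- stats::runmed(x, 3L, endrule = "keep")
  m <- min(x)
  f <- x[length(x)]
  cls <- if (max(abs(x - 1)) < delta) {
    "flat"
  } else if (m >= 1 - delta) {
    if (f >= 1 + delta) "monotonic_reinforcement"
    else if (f <= 1 - delta) "monotonic_retraction"
    else "flat"
  } else {
    if (f >= m + delta) "retraction_then_reinforcement"
    else "monotonic_retraction"
  }
  # reinforcement-followed-by-retraction has no label; detect and flag
  peak_idx <- which.max(x)
  anomaly <- x[peak_idx] >= 1 + delta &&
    peak_idx < length(x) &&
    f <= x[peak_idx] - delta
  if (anomaly) {
    warning("trace rises then falls: reinforcement followed by retraction ",
            "has no class label; flagging as anomaly", call. = FALSE)
  }
  structure(cls, anomaly = anomaly)
}

#' Contingency table of categorical responses
#'
#' @param counts Matrix of non-negative integer counts (at least 2x2), e.g.
#'   protrusion responses (extension / no response / retraction) by
#'   condition.
#' @param row_labels,col_labels Optional dimension labels.
#' @return An object of class `contingency_table` (an integer matrix).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the row
#' and column margins, `df = (R - 1) * (C - 1)`, and the p-value from the
#' upper tail of the chi-square distribution.  No continuity correction by
#' default; Yates' correction is available for 2x2 tables via `correct`.
#'
#' @param table A [contingency_table()] or plain count matrix.
#' @param correct Apply Yates' continuity correction (2x2 only).
#' @return A list with `statistic`, `df`, `p_value`, and `expected`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  tab <- unclass(as.matrix(table))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       expected = ht$expected)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing, with the margins fixed, the
#' hypergeometric probabilities of all tables as probable or less probable
#' than the one observed.
#'
#' @param table A 2x2 count matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  tab <- unclass(as.matrix(table))
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("Fisher's exact test here supports 2x2 tables only", call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}

#' Steady-state force from an isometric force trace
#'
#' Mean force over the final moving window of the recording, the standard
#' way to read a nominally steady post-relaxation level from a noisy
#' isometric force trace.
#'
#' @param trace A data frame with columns `time_min` and `force` (as produced
#'   by [gen_force_trace()]), or a list with those elements.
#' @param window Window length in minutes; must be shorter than the trace.
#' @return The mean force over the final window (same units as `force`).
#' @export
steady_force <- function(trace, window = 5) {
  t <- trace$time_min
  f <- trace$force
  if (is.null(t) || is.null(f)) {
    stop("trace must have time_min and force", call. = FALSE)
  }
  span <- max(t) - min(t)
  if (window <= 0 || window >= span) {
    stop("window must be positive and shorter than the trace", call. = FALSE)
  }
  mean(f[t >= max(t) - window])
}

#' Active contractile force per cell
#'
#' The drop in steady isometric force after pharmacological relaxation of
#' active contraction (e.g. ROCK inhibition) measures the total active force
#' the cell population exerted; dividing by the approximate number of cells
#' gives the per-cell active force.  An order-of-magnitude active stress
#' estimate `delta_F * L / (n_cells * V_cell)` is available behind
#' `estimate_stress` (it depends on coarse geometric factors, so it is
#' reported only on request).
#'
#' @param pre_drug,post_drug Force traces (see [steady_force()]) recorded at
#'   steady state before and after drug addition.  Forces in micronewtons.
#' @param n_cells Approximate number of cells in the construct.
#' @param window Steady-window length (min) for both traces.
#' @param estimate_stress Also report the active stress estimate.
#' @param L Spacing between loading bars (m); only for the stress estimate.
#' @param V_cell Cell volume (m^3); only for the stress estimate.
#' @return A list with `delta_F_total` (uN), `n_cells`, `per_cell_force_nN`,
#'   and optionally `active_stress_Pa`.
#' @export
active_force <- function(pre_drug, post_drug, n_cells, window = 5,
                         estimate_stress = FALSE, L = 0.007, V_cell = 1e-12) {
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  f_pre <- steady_force(pre_drug, window)
  f_post <- steady_force(post_drug, window)
  delta <- f_pre - f_post
  if (delta < 0) {
    warning("negative decrement: force increased after drug addition",
            call. = FALSE)
  }
  out <- list(delta_F_total = delta,
              n_cells = n_cells,
              per_cell_force_nN = delta * 1e3 / n_cells)
  if (estimate_stress) {
    out$active_stress_Pa <- (delta * 1e-6) * L / (n_cells * V_cell)
  }
  out
}
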