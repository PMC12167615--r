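#' Spearman rank correlation with two-tailed test
#'
#' Tie-corrected Spearman rho computed as the Pearson correlation of average
#' ranks.  The two-tailed p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (appropriate at cohort scale); for small samples an exact permutation
#' p-value over all `n!` orderings is available (`p_method = "permutation"`,
#' `n <= 10`).  Pairs with a missing value in either vector are removed.
#'
#' @param x,y Numeric vectors of equal length.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @return Object of class `spearman_cor`: `rho`, `p`, `n`, `method`.
#'   A constant input vector leaves `rho` and `p` as `NA` (flagged, not an
#'   error).
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  out <- structure(list(rho = NA_real_, p = NA_real_, n = n,
                        method = p_method), class = "spearman_cor")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(out)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  out$rho <- rho
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      out$p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 10L) stop("permutation p-value limited to n <= 10")
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    out$p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  out
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (is.na(x$rho)) {
    cat(sprintf("Spearman correlation undefined (constant input), n = %d\n", x$n))
  } else {
    cat(sprintf("Spearman rho = %.3f, two-tailed p = %.3g (n = %d, %s)\n",
                x$rho, x$p, x$n, x$method))
  }
  invisible(x)
}

#' TLV stratification scheme
#'
#' Six groups on total lesion volume, with half-open intervals:
#' TLV = 0 (`zero`), (0, 25] cm3 (`very_low`), (25, 189] (`low`),
#' (189, 532] (`moderate`), (532, 1355] (`high`) and > 1355 (`very_high`).
#'
#' @param bounds Strictly increasing interior cut-offs in cm3.
#' @param labels Group labels, one more than `bounds`... plus `zero`.
#' @return List of class `strat_scheme`.
#' @export
strat_scheme <- function(bounds = c(25, 189, 532, 1355),
                         labels = c("zero", "very_low", "low", "moderate",
                                    "high", "very_high")) {
  if (any(diff(bounds) <= 0) || any(bounds <= 0))
    stop("'bounds' must be positive and strictly increasing")
  if (length(labels) != length(bounds) + 2L)
    stop("need one label for zero plus one per interval")
  structure(list(bounds = bounds, labels = labels), class = "strat_scheme")
}

#' Stratify TLV values into burden groups
#'
#' @param tlv Numeric vector of TLV values in cm3, all `>= 0` (`NA` passes
#'   through).
#' @param scheme A [strat_scheme()].
#' @return Factor with the scheme's labels as levels.
#' @export
stratify_tlv <- function(tlv, scheme = strat_scheme()) {
  if (any(tlv < 0, na.rm = TRUE)) stop("TLV must be non-negative")
  lab <- scheme$labels
  breaks <- c(0, scheme$bounds, Inf)
  g <- cut(tlv, breaks = breaks, labels = lab[-1L], right = TRUE)
  g <- as.character(g)
  g[!is.na(tlv) & tlv == 0] <- lab[1L]
  factor(g, levels = lab)
}

#' log10(x + 1) transform
#'
#' The transform applied to TLV and TLU for scatter-plot display (base 10
#' for axis readability; rank statistics are invariant to the choice).
#'
#' @param v Non-negative numeric vector.
#' @return `log10(v + 1)`, so 0 maps to 0.
#' @export
log1_transform <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("negative input")
  log10(v + 1)
}

#' Median / IQR / range summary
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param v Non-empty numeric vector; `NA` removed.
#' @return Named list `n`, `median`, `q1`, `q3`, `iqr`, `min`, `max`.
#' @export
summarize_dist <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty vector")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
       iqr = q[3] - q[1], min = min(v), max = max(v))
}

.ORGANS <- c("kidneys", "liver", "parotids", "spleen")

#' Cohort-level analysis
#'
#' Assembles the cohort report from a per-patient table: (a) per-organ
#' median/IQR summaries of SUVmean; (b) Spearman correlations of TLV and
#' TLU against each organ's SUVmean (8 results), with pairwise deletion of
#' missing organs; (c) per-stratum patient counts and five-number SUVmean
#' summaries per organ; (d) scatter data with and without the log10(x+1)
#' transform.  By default all patients enter the correlations (zero-TLV
#' ties are handled by average ranks); `tumour_only = TRUE` restricts to
#' TLV > 0.
#'
#' @param table Data frame with columns `tlv`, `tlu` and one SUVmean column
#'   per organ (`kidneys`, `liver`, `parotids`, `spleen`; `NA` allowed).
#' @param tumour_only Restrict correlations to patients with TLV > 0.
#' @param scheme A [strat_scheme()].
#' @return Object of class `cohort_report` with elements `organ_summary`,
#'   `correlations`, `strata`, `strata_counts`, `scatter`, `settings`.
#' @export
run_cohort_analysis <- function(table, tumour_only = FALSE,
                                scheme = strat_scheme()) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 3L) stop("need at least 3 patients")
  organs <- .ORGANS[.ORGANS %in% names(table)]
  present <- organs[vapply(organs, function(o) any(is.finite(table[[o]])),
                           logical(1))]
  if (length(present) < length(organs))
    warning(sprintf("organ(s) absent in all rows, omitted: %s",
                    paste(setdiff(organs, present), collapse = ", ")))
  organs <- present

  organ_summary <- do.call(rbind, lapply(organs, function(o) {
    s <- summarize_dist(table[[o]])
    data.frame(organ = o, n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
               iqr = s$iqr, min = s$min, max = s$max)
  }))

  sub <- if (tumour_only) table[table$tlv > 0, , drop = FALSE] else table
  correlations <- do.call(rbind, lapply(c("tlv", "tlu"), function(m) {
    do.call(rbind, lapply(organs, function(o) {
      r <- spearman_cor(sub[[m]], sub[[o]])
      data.frame(metric = toupper(m), organ = o, rho = r$rho, p = r$p, n = r$n)
    }))
  }))

  group <- stratify_tlv(table$tlv, scheme)
  strata_counts <- as.data.frame(table(group), responseName = "n")
  strata <- do.call(rbind, lapply(levels(group), function(g) {
    rows <- table[group == g, , drop = FALSE]
    do.call(rbind, lapply(organs, function(o) {
      v <- rows[[o]]
      if (sum(is.finite(v)) == 0L) {
        data.frame(group = g, organ = o, n = 0L, median = NA_real_,
                   q1 = NA_real_, q3 = NA_real_, min = NA_real_, max = NA_real_)
      } else {
        s <- summarize_dist(v)
        data.frame(group = g, organ = o, n = s$n, median = s$median,
                   q1 = s$q1, q3 = s$q3, min = s$min, max = s$max)
      }
    }))
  }))

  scatter <- data.frame(tlv = table$tlv, tlu = table$tlu,
                        log_tlv = log1_transform(table$tlv),
                        log_tlu = log1_transform(table$tlu))
  for (o in organs) scatter[[o]] <- table[[o]]

  structure(list(organ_summary = organ_summary,
                 correlations = correlations,
                 strata = strata,
                 strata_counts = strata_counts,
                 scatter = scatter,
                 settings = list(tumour_only = tumour_only,
                                 quartile_type = 7,
                                 log_base = 10,
                                 scheme = scheme,
                                 n_patients = nrow(table))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d patients\n", x$settings$n_patients))
  cat("\nOrgan-at-risk SUVmean, median (IQR):\n")
  for (i in seq_len(nrow(x$organ_summary))) {
    r <- x$organ_summary[i, ]
    cat(sprintf("  %-9s %5.1f (%.1f)  n = %d\n", r$organ, r$median, r$iqr, r$n))
  }
  cat("\nSpearman correlations vs organ SUVmean (two-tailed):\n")
  for (i in seq_len(nrow(x$correlations))) {
    r <- x$correlations[i, ]
    cat(sprintf("  %s vs %-9s rho = %7.3f, p = %.3g (n = %d)\n",
                r$metric, r$organ, r$rho, r$p, r$n))
  }
  cat("\nPatients per TLV stratum:",
      paste(sprintf("%s = %d", x$strata_counts$group, x$strata_counts$n),
            collapse = ", "), "\n")
  invisible(x)
}

#' Boxplot / scatter figures for a cohort report
#'
#' Base-graphics analogues of the study figures: organ SUVmean boxplots,
#' burden-vs-uptake scatter (raw and log-transformed), and SUVmean by TLV
#' stratum.  Purely presentational; no statistic is computed here.
#'
#' @param x A `cohort_report`.
#' @param which `"organs"`, `"scatter"` or `"strata"`.
#' @param ... Passed to the underlying plot calls.
#' @return `invisible(x)`.
#' @export
plot.cohort_report <- function(x, which = c("organs", "scatter", "strata"),
                               ...) {
  which <- match.arg(which)
  organs <- unique(x$organ_summary$organ)
  if (which == "organs") {
    graphics::boxplot(x$scatter[organs], ylab = "SUVmean",
                      main = "Organ-at-risk uptake", ...)
  } else if (which == "scatter") {
    op <- graphics::par(mfrow = c(2, length(organs)))
    on.exit(graphics::par(op))
    for (o in organs)
      graphics::plot(x$scatter$tlv, x$scatter[[o]], xlab = "TLV (cm3)",
                     ylab = paste(o, "SUVmean"), ...)
    for (o in organs)
      graphics::plot(x$scatter$log_tlv, x$scatter[[o]],
                     xlab = "log10(TLV + 1)", ylab = paste(o, "SUVmean"), ...)
  } else {
    grp <- x$strata[x$strata$organ == organs[1L], ]
    graphics::barplot(grp$n, names.arg = grp$group, ylab = "patients",
                      main = "Patients per TLV stratum", ...)
  }
  invisible(x)
}
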