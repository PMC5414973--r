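#' Kruskal-Wallis omnibus test across groups
#'
#' Rank-based k-group comparison with midranks for ties and the standard
#' tie correction; the statistic H is referred to the chi-square
#' distribution with k - 1 degrees of freedom (the small-sample design of
#' the study, with zero-inflated percent scores, is exactly the regime
#' where ties are common, so the correction is always applied). If every
#' observation is identical the test is degenerate: H = 0, p = 1, and the
#' result carries an `all_tied` flag.
#'
#' @param samples list of >= 2 numeric vectors (one per group), each with
#'   >= 1 observation, total N >= 3.
#' @param alpha significance level used for the reported critical value.
#' @return object of class `kw_result`: `statistic` (H, reported as X^2),
#'   `df`, `p_value`, `chi2_crit`, `n` (group sizes), `all_tied`.
#' @export
kruskal_wallis <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("usage error: need at least 2 groups")
  }
  n <- vapply(samples, length, integer(1))
  if (any(n < 1L)) stop("usage error: every group needs >= 1 observation")
  x <- unlist(samples, use.names = FALSE)
  if (length(x) < 3L) stop("usage error: total N must be >= 3")
  if (any(!is.finite(x))) stop("usage error: scores must be finite")
  k <- length(samples)
  all_tied <- length(unique(x)) == 1L
  if (all_tied) {
    warning("all observations identical; H = 0, p = 1")
    H <- 0
    p <- 1
  } else {
    g <- factor(rep(seq_len(k), n))
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(statistic = H, df = k - 1L, p_value = p,
                 chi2_crit = chi2_critical(k - 1L, alpha), alpha = alpha,
                 n = n, all_tied = all_tied),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: X^2 = %.2f, X^2_crit = %.2f, df = %d, p = %s\n",
              x$statistic, x$chi2_crit, x$df, format_p(x$p_value)))
  invisible(x)
}

#' Upper-tail chi-square critical value
#'
#' @param df degrees of freedom, >= 1.
#' @param alpha upper-tail probability in (0, 1).
#' @return the upper-`alpha` quantile of the chi-square distribution.
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (!is_count(df)) stop("domain error: df must be an integer >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("domain error: alpha must be in (0, 1)")
  qchisq(1 - alpha, df)
}

#' Dunn's post-hoc pairwise tests
#'
#' For every unordered pair of groups, the rank-based z statistic
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where ranks are midranks over the pooled sample and `T = sum(t^3 - t)`
#' over tie groups; two-sided p from the standard normal, then adjusted for
#' the number of pairs (adjusted p capped at 1, hence the exact 1.000
#' entries typical of such tables).
#'
#' @param samples named list of >= 2 numeric group vectors.
#' @param adjustment `"bonferroni"` (default), `"holm"`, `"sidak"`, `"none"`.
#' @return object of class `dunn_result`: a `pairs` data.frame (group_i,
#'   group_j, z, p_unadjusted, p_adjusted), symmetric `z_matrix` /
#'   `p_matrix`, and the adjustment label.
#' @export
dunn_posthoc <- function(samples,
                         adjustment = c("bonferroni", "holm", "sidak", "none")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(samples) || length(samples) < 2L) {
    stop("usage error: need at least 2 groups")
  }
  k <- length(samples)
  labels <- names(samples)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  n <- vapply(samples, length, integer(1))
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  r <- rank(x)  # midranks
  grp <- rep(seq_len(k), n)
  rbar <- tapply(r, grp, mean)
  ties <- table(x)
  tiesum <- sum(ties^3 - ties)
  varterm <- N * (N + 1) / 12 - tiesum / (12 * (N - 1))

  pr <- t(utils::combn(k, 2L))
  z <- numeric(nrow(pr))
  for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1L]; j <- pr[q, 2L]
    se2 <- varterm * (1 / n[i] + 1 / n[j])
    z[q] <- if (se2 <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(se2)
  }
  p_un <- 2 * pnorm(-abs(z))
  m <- length(p_un)
  p_adj <- switch(adjustment,
    none = p_un,
    bonferroni = p.adjust(p_un, "bonferroni"),
    holm = p.adjust(p_un, "holm"),
    sidak = pmin(1, 1 - (1 - p_un)^m))

  pairs <- data.frame(group_i = labels[pr[, 1L]], group_j = labels[pr[, 2L]],
                      z = z, p_unadjusted = p_un, p_adjusted = p_adj,
                      stringsAsFactors = FALSE)
  zm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pm <- zm
  for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1L]; j <- pr[q, 2L]
    zm[i, j] <- z[q]; zm[j, i] <- -z[q]
    pm[i, j] <- p_adj[q]; pm[j, i] <- p_adj[q]
  }
  structure(list(pairs = pairs, z_matrix = zm, p_matrix = pm,
                 adjustment = adjustment, n = setNames(n, labels)),
            class = "dunn_result")
}

#' @export
print.dunn_result <- function(x, ...) {
  cat("Dunn's post-hoc pairwise tests (", x$adjustment, "-adjusted p)\n",
      sep = "")
  pm <- x$p_matrix
  pm[lower.tri(pm, diag = TRUE)] <- NA
  print(round(pm[-nrow(pm), -1L, drop = FALSE], 3))
  invisible(x)
}

#' Assemble study-style omnibus and post-hoc tables
#'
#' For one metric and one filter configuration, runs a Kruskal-Wallis test
#' per body part across all groups present (abdomen/cephalothorax have all
#' five groups, df = 4; right leg 1 lacks immatures, df = 3) and, where the
#' omnibus test is significant at `alpha` (or `force_posthoc = TRUE`),
#' Dunn's pairwise tests with the chosen adjustment.
#'
#' @param records specimen table (see [generate_specimen_table()]).
#' @param metric `"mean_intensity"` or `"percent_brightest"`.
#' @param filter_config `"dichroic_only"` or `"blocking"`.
#' @param alpha omnibus significance level.
#' @param adjustment Dunn adjustment, see [dunn_posthoc()].
#' @param force_posthoc run pairwise tests even for non-significant omnibus
#'   rows.
#' @return object of class `study_tables`: `omnibus` data.frame (body_part,
#'   statistic, chi2_crit, df, p_value, p_display, significant), `posthoc`
#'   named list of [dunn_posthoc()] results (NULL where not run),
#'   `group_summary` (n, mean, sd per group x body part), and metadata.
#' @export
assemble_study_tables <- function(records,
                                  metric = c("mean_intensity",
                                             "percent_brightest"),
                                  filter_config = "dichroic_only",
                                  alpha = 0.05,
                                  adjustment = "bonferroni",
                                  force_posthoc = FALSE) {
  metric <- match.arg(metric)
  sel <- records[records$filter_config == filter_config, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop("usage error: no records for filter_config '", filter_config, "'")
  }
  parts <- intersect(study_body_parts, unique(sel$body_part))
  omni <- list()
  posthoc <- list()
  summ <- list()
  for (part in parts) {
    pp <- sel[sel$body_part == part, , drop = FALSE]
    groups_here <- intersect(study_groups, unique(pp$group))
    if (length(groups_here) < 2L) {
      stop("usage error: fewer than 2 groups for body part '", part, "'")
    }
    samples <- setNames(lapply(groups_here, function(g) pp[[metric]][pp$group == g]),
                        groups_here)
    kw <- kruskal_wallis(samples, alpha = alpha)
    omni[[part]] <- data.frame(
      body_part = part, statistic = kw$statistic, chi2_crit = kw$chi2_crit,
      df = kw$df, p_value = kw$p_value, p_display = format_p(kw$p_value),
      significant = kw$p_value < alpha, stringsAsFactors = FALSE)
    posthoc[[part]] <- if (kw$p_value < alpha || force_posthoc) {
      dunn_posthoc(samples, adjustment = adjustment)
    } else NULL
    summ[[part]] <- do.call(rbind, lapply(groups_here, function(g) {
      v <- samples[[g]]
      data.frame(body_part = part, group = g, n = length(v),
                 mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    omnibus = do.call(rbind, c(omni, list(make.row.names = FALSE))),
    posthoc = posthoc,
    group_summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
    metadata = list(metric = metric, filter_config = filter_config,
                    alpha = alpha, adjustment = adjustment,
                    force_posthoc = force_posthoc)
  ), class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("Omnibus Kruskal-Wallis (%s, %s):\n", x$metadata$metric,
              x$metadata$filter_config))
  tab <- x$omnibus
  tab$statistic <- round(tab$statistic, 2)
  tab$chi2_crit <- round(tab$chi2_crit, 2)
  tab$star <- ifelse(tab$significant, "*", "")
  print(tab[, c("body_part", "statistic", "chi2_crit", "df", "p_display",
                "star")], row.names = FALSE)
  for (part in names(x$posthoc)) {
    if (!is.null(x$posthoc[[part]])) {
      cat("\n[", part, "]\n", sep = "")
      print(x$posthoc[[part]])
    }
  }
  invisible(x)
}
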