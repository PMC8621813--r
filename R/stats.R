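# Nonparametric three-group comparison battery.
#
# Kruskal-Wallis omnibus per parameter; parameters reaching omnibus
# p < 0.05 are followed up with all pairwise Mann-Whitney U tests, declared
# significant at the Bonferroni-adjusted threshold p < 0.017 (= 0.05 / 3
# pairwise comparisons). Fisher's exact test covers categorical
# demographics. The tests delegate to the standard implementations in
# stats; the wrappers add the conventions used here (U = min of the two
# one-sided statistics, symmetric-center p fixed at 1, tie-degenerate
# omnibus reported as H = 0).

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group comparison with average-rank tie handling and tie
#' correction; p from the chi-square approximation with k - 1 df. When all
#' observations are tied the tie correction degenerates and the statistic
#' is reported as H = 0, p = 1.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List with `H`, `p`, `df`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n == 0)) stop("every group needs >= 1 observation", call. = FALSE)
  if (sum(n) < 3) stop("need >= 3 observations in total", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  df <- length(groups) - 1L
  if (diff(range(x)) == 0) {
    return(list(H = 0, p = 1, df = df))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (!is.finite(H)) { H <- 0; p <- 1 }
  list(H = H, p = p, df = df)
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports `U = min(U_a, U_b)`. The p-value is exact by enumeration when
#' `n_a * n_b <= 400` and the data are untied, otherwise a normal
#' approximation with tie and continuity corrections is used. When U sits
#' exactly at the null center `n_a * n_b / 2` the two-sided p is 1 (the
#' permutation distribution of U is symmetric about its center even under
#' ties).
#'
#' @param a,b Nonempty numeric vectors.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return List with `U`, `p`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
                  auto = na * nb <= 400 && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  Ua <- unname(wt$statistic)          # wilcox.test's W is U for sample a
  U <- min(Ua, na * nb - Ua)
  p <- wt$p.value
  if (isTRUE(all.equal(Ua, na * nb / 2))) p <- 1
  list(U = U, p = min(p, 1),
       method = if (exact) "exact" else "normal approximation")
}

#' Fisher's exact test for an r x c contingency table
#'
#' Exact conditional p-value over all tables with the observed margins,
#' summing the probabilities of tables no more probable than the observed
#' one. Intended for small demographic tables (e.g. sex across three
#' groups); tables with a grand total above `budget` are rejected with a
#' pointer to the chi-square approximation.
#'
#' @param table Matrix of nonnegative integer counts, at least 2 x 2.
#' @param budget Maximum grand total accepted (default 200).
#' @return The p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))  # 1
fisher_exact <- function(table, budget = 200) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("table must hold nonnegative integer counts", call. = FALSE)
  }
  if (sum(table) > budget) {
    stop("table total ", sum(table), " exceeds the enumeration budget (",
         budget, "); use a chi-square test instead", call. = FALSE)
  }
  # rows/columns of zeros carry no information and can trip the enumeration
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) return(1)
  stats::fisher.test(table)$p.value
}

#' Group comparison battery over cyclogram parameters
#'
#' For each parameter: per-group mean +/- SD, the Kruskal-Wallis omnibus,
#' and — only when the omnibus reaches p < `alpha` — all pairwise
#' Mann-Whitney U tests with significance flagged at the
#' Bonferroni-adjusted threshold (`alpha / n_pairs`, i.e. 0.017 for three
#' groups). Ungated pairwise entries are reported as `NA` with an `"N.S."`
#' label, mirroring the usual table layout.
#'
#' @param data `data.frame` with a `group` column and the parameter columns
#'   (one row per participant, holding participant-level means).
#' @param parameters Columns to compare (default all eight cyclogram
#'   parameters).
#' @param alpha Omnibus significance level (default 0.05).
#' @param mode Passed to [mann_whitney_u()].
#' @return List of `comparison_result` objects (one per parameter), each a
#'   list with `parameter`, `group_summary` (`group`, `n`, `mean`, `sd`),
#'   `omnibus_stat`, `omnibus_p`, `pairwise` (`data.frame`: `pair`, `U`,
#'   `p`, `significant`, `label`), `significant_pairs`.
#' @export
compare_groups <- function(data, parameters = cyclogram_param_names(),
                           alpha = 0.05, mode = "auto") {
  stopifnot("group" %in% names(data), all(parameters %in% names(data)))
  groups <- split(data, data$group)
  if (length(groups) < 2 || any(vapply(groups, nrow, integer(1)) < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  gnames <- names(groups)
  pairs <- utils::combn(gnames, 2)
  n_pairs <- ncol(pairs)
  thr <- alpha / n_pairs

  out <- lapply(parameters, function(par) {
    vals <- lapply(groups, `[[`, par)
    omni <- kruskal_wallis(vals)
    gs <- data.frame(
      group = gnames,
      n = vapply(vals, length, integer(1)),
      mean = vapply(vals, mean, numeric(1)),
      sd = vapply(vals, stats::sd, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
    pw <- data.frame(
      pair = apply(pairs, 2, paste, collapse = " vs "),
      U = NA_real_, p = NA_real_, significant = NA,
      label = "N.S.", stringsAsFactors = FALSE
    )
    if (omni$p < alpha) {
      for (j in seq_len(n_pairs)) {
        mw <- mann_whitney_u(vals[[pairs[1, j]]], vals[[pairs[2, j]]],
                             mode = mode)
        pw$U[j] <- mw$U
        pw$p[j] <- mw$p
        pw$significant[j] <- mw$p < thr
        pw$label[j] <- if (mw$p < thr) format_pval(mw$p) else "N.S."
      }
    }
    structure(
      list(parameter = par, group_summary = gs,
           omnibus_stat = omni$H, omnibus_p = omni$p,
           pairwise = pw,
           significant_pairs = pw$pair[isTRUE_vec(pw$significant)],
           pairwise_threshold = thr),
      class = "comparison_result"
    )
  })
  names(out) <- parameters
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

format_pval <- function(p) {
  if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison '%s'>  H = %.3f, omnibus p = %s\n",
              x$parameter, x$omnibus_stat, format_pval(x$omnibus_p)))
  for (j in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %-40s %s\n", x$pairwise$pair[j], x$pairwise$label[j]))
  }
  invisible(x)
}

#' Flatten a comparison battery into a table
#'
#' @param results List returned by [compare_groups()].
#' @return `data.frame` with one row per parameter: group means/SDs,
#'   omnibus H and p, and each pairwise p with its significance flag.
#' @export
comparison_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    row <- data.frame(parameter = r$parameter, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(r$group_summary))) {
      g <- r$group_summary$group[i]
      row[[paste0(g, "_mean")]] <- r$group_summary$mean[i]
      row[[paste0(g, "_sd")]] <- r$group_summary$sd[i]
    }
    row$omnibus_H <- r$omnibus_stat
    row$omnibus_p <- r$omnibus_p
    for (j in seq_len(nrow(r$pairwise))) {
      key <- gsub(" vs ", "_vs_", r$pairwise$pair[j])
      row[[paste0("p_", key)]] <- r$pairwise$p[j]
      row[[paste0("sig_", key)]] <- r$pairwise$label[j]
    }
    row
  }))
}
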