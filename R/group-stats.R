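#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within decomposition via
#' [stats::aov()]), returned as the bare F, p and degrees of freedom used
#' by the letter display.
#'
#' @param x Numeric response values.
#' @param g Group labels (coerced to factor).
#' @return List with `F`, `p`, `df` (numerator, denominator), `ms_within`,
#'   and `flags`.
#' @export
anova_one_way <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("each group needs n >= 2", call. = FALSE)
  dfb <- nlevels(g) - 1L
  dfw <- length(x) - nlevels(g)
  if (all(tapply(x, g, stats::var) == 0)) {  # zero within-group variance
    if (stats::var(as.numeric(tapply(x, g, mean))) > 0) {
      return(list(F = Inf, p = 0, df = c(dfb, dfw), ms_within = 0,
                  flags = "zero-within-variance"))
    }
    return(list(F = NA_real_, p = NA_real_, df = c(dfb, dfw), ms_within = 0,
                flags = "degenerate-anova"))
  }
  tab <- stats::anova(stats::aov(x ~ g))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(tab$Df[1], tab$Df[2]), ms_within = tab$`Mean Sq`[2],
       flags = "")
}

#' Group means and standard errors
#'
#' @inheritParams anova_one_way
#' @return Data frame with `group`, `n`, `mean`, `se` (SD/sqrt(n)).
#' @export
summarize_mean_se <- function(x, g) {
  g <- factor(g)
  if (any(table(g) < 2)) {
    stop("SE undefined for groups with n < 2", call. = FALSE)
  }
  out <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(x, g, mean)),
    se = as.numeric(tapply(x, g, function(v) stats::sd(v) / sqrt(length(v)))))
  rownames(out) <- NULL
  out
}

#' Student-Newman-Keuls multiple comparison with letter groupings
#'
#' Stepwise studentized-range comparisons across ordered group means: the
#' range spanning p ordered means is tested against the upper-alpha
#' studentized-range quantile for p means and the ANOVA residual degrees of
#' freedom, stepping down from the full range; ranges inside a
#' non-significant range are not tested (declared non-significant), which
#' is what distinguishes SNK from Tukey's HSD. Groups are then labeled with
#' a compact letter display: groups sharing no letter differ at `alpha`.
#'
#' Unequal group sizes are handled with the harmonic mean of the sizes
#' (flagged). Ties between means are broken stably by group label.
#'
#' @inheritParams anova_one_way
#' @param alpha Significance level (default 0.05).
#' @return List of class `"snk_result"`: `groups` (data frame ordered by
#'   descending mean with `group`, `n`, `mean`, `se`, `letters`), `F`, `p`,
#'   `df`, `alpha`, `flags`.
#' @export
snk_letters <- function(x, g, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  g <- factor(g)
  av <- anova_one_way(x, g)
  sm <- summarize_mean_se(x, g)
  ns <- sm$n
  flags <- av$flags
  n_h <- length(ns) / sum(1 / ns)
  if (length(unique(ns)) > 1) {
    flags <- paste(c(flags[nzchar(flags)], "unequal-n-harmonic-mean"),
                   collapse = ";")
  }
  # order descending by mean, ties stable by label
  ord <- order(-sm$mean, as.character(sm$group))
  sm <- sm[ord, ]
  k <- nrow(sm)
  dfw <- av$df[2]
  msw <- av$ms_within
  se_range <- sqrt(msw / n_h)

  # sig[i, j]: means i..j (i < j in descending order) differ at alpha
  sig <- matrix(FALSE, k, k)
  protected <- matrix(FALSE, k, k)  # inside a non-significant range
  for (span in seq(k, 2)) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (protected[i, j]) next
      diff_ij <- sm$mean[i] - sm$mean[j]
      is_sig <- if (se_range == 0) diff_ij > 0 else {
        (diff_ij / se_range) >= stats::qtukey(1 - alpha, span, dfw)
      }
      if (is_sig) {
        sig[i, j] <- TRUE
      } else {
        for (a in i:j) for (b in a:j) protected[a, b] <- TRUE
      }
    }
  }

  # compact letters: maximal contiguous non-significant intervals
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !(sig[i, j + 1L])) j <- j + 1L
    j
  }, 0L)
  intervals <- unique(lapply(seq_len(k), function(i) c(i, reach[i])))
  keep <- Filter(function(iv) {
    !any(vapply(intervals, function(o) {
      !identical(o, iv) && o[1] <= iv[1] && o[2] >= iv[2]
    }, TRUE))
  }, intervals)
  letters_vec <- character(k)
  for (idx in seq_along(keep)) {
    iv <- keep[[idx]]
    sel <- iv[1]:iv[2]
    letters_vec[sel] <- paste0(letters_vec[sel], letters[idx])
  }
  sm$letters <- letters_vec

  pairs <- which(upper.tri(sig), arr.ind = TRUE)
  significant_pairs <- data.frame(
    group1 = sm$group[pairs[, 1]], group2 = sm$group[pairs[, 2]],
    significant = sig[pairs])

  structure(list(groups = sm, significant_pairs = significant_pairs,
                 F = av$F, p = av$p, df = av$df,
                 alpha = alpha, flags = flags),
            class = "snk_result")
}

#' @export
print.snk_result <- function(x, digits = 3, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s\n",
              x$df[1], x$df[2], format(signif(x$F, digits)),
              format(signif(x$p, digits))))
  cat("SNK letter groupings (alpha =", x$alpha, "):\n")
  print(format_num_df(x$groups, digits))
  if (nzchar(x$flags)) cat("Flags:", x$flags, "\n")
  invisible(x)
}
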