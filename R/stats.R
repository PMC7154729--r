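# Statistical stage: polynomial OLS with confidence bands, one-way ANOVA
# with Tukey HSD and compact letter display, paired t tests, and the
# perfusion-FI linkage recovery fit.

#' Ordinary least-squares polynomial fit
#'
#' Degree-1 (linear) or degree-2 (quadratic) least-squares fit with r^2,
#' overall-F p value and a pointwise 95% confidence band evaluated on a
#' grid.
#'
#' @param x,y Paired numeric vectors.
#' @param degree 1 or 2.
#' @param band_n Number of grid points for the confidence band.
#' @param conf_level Confidence level for the band (default 0.95).
#' @return Object of class `caprare_fit`: `coefficients` (with standard
#'   errors), `r_squared`, `p_value`, `band` (grid, fit, lwr, upr),
#'   `residuals`, `n`, `degree`, and the underlying `lm` fit.
#' @export
fit_ols <- function(x, y, degree = 1L, band_n = 101L, conf_level = 0.95) {
  stopifnot(degree %in% c(1L, 2L))
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("x and y must be finite")
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n <= degree + 1L) stop("need n > degree + 1 observations")
  if (length(unique(x)) <= degree) {
    stop("design is rank deficient: x has too few distinct values for ",
         "degree ", degree)
  }
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ poly(x, degree, raw = TRUE), data = df)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) {
    r2 <- 0          # constant response: no variance to explain
    pval <- 1
  } else {
    sm <- summary(fit)
    r2 <- sm$r.squared
    fstat <- sm$fstatistic
    pval <- unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  }
  grid <- data.frame(x = seq(min(x), max(x), length.out = band_n))
  band <- cbind(grid,
                as.data.frame(predict(fit, grid, interval = "confidence",
                                      level = conf_level)))
  cf <- coef(fit)
  names(cf) <- paste0("b", seq_along(cf) - 1L)
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(cf)
  structure(list(coefficients = cf, se = se, r_squared = r2,
                 p_value = pval, band = band,
                 residuals = unname(fit$residuals), n = n,
                 degree = degree, conf_level = conf_level, lm = fit),
            class = "caprare_fit")
}

#' @export
print.caprare_fit <- function(x, ...) {
  cat("<caprare_fit> degree", x$degree, "on n =", x$n, "\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.4g (SE %.3g)", names(x$coefficients),
                    x$coefficients, x$se), collapse = ", "), "\n")
  cat(sprintf("  r^2 = %.3f, p = %.4g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' Plot a fit with its confidence band
#' @param x A `caprare_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.caprare_fit <- function(x, ...) {
  m <- x$lm$model
  xv <- m[, 2L][, 1L]
  plot(xv, m[, 1L], xlab = "x", ylab = "y", ...)
  polygon(c(x$band$x, rev(x$band$x)), c(x$band$lwr, rev(x$band$upr)),
          col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  lines(x$band$x, x$band$fit, col = "steelblue", lwd = 2)
  invisible(x)
}

# insert-and-absorb compact letter display from a pairwise significance
# matrix (TRUE = significantly different)
cld_letters <- function(sig) {
  g <- rownames(sig)
  sets <- list(seq_along(g))
  for (i in seq_along(g)) {
    for (j in seq_len(i - 1L)) {
      if (!sig[i, j]) next
      for (k in seq_along(sets)) {
        s <- sets[[k]]
        if (i %in% s && j %in% s) {
          sets[[k]] <- setdiff(s, i)
          sets[[length(sets) + 1L]] <- setdiff(s, j)
        }
      }
      # absorb duplicated / contained sets
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(sets[[a]] %in% sets[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  lab <- rep("", length(g))
  for (k in seq_along(sets)) {
    lab[sets[[k]]] <- paste0(lab[sets[[k]]], letters[k])
  }
  setNames(lab, g)
}

#' One-way ANOVA with Tukey HSD and letter display
#'
#' @param values Numeric response vector, or a named list of group vectors.
#' @param groups Group labels (when `values` is a vector).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `group_comparison`: ANOVA `f`, `p`, Tukey table
#'   (`tukey`), group means, and compact letters (groups sharing a letter do
#'   not differ at `alpha`).
#' @export
anova_tukey <- function(values, groups = NULL, alpha = 0.05) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) {
    stop("each group needs at least 2 observations for Tukey HSD")
  }
  fit <- aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$g
  sig <- matrix(FALSE, nlevels(g), nlevels(g),
                dimnames = list(levels(g), levels(g)))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_len(nrow(tk))) {
    a <- prs[[r]][1L]; b <- prs[[r]][2L]
    sig[a, b] <- sig[b, a] <- tk[r, "p adj"] < alpha
  }
  structure(list(
    f = an[["F value"]][1L],
    p = an[["Pr(>F)"]][1L],
    tukey = as.data.frame(tk),
    means = tapply(values, g, mean),
    letters = cld_letters(sig),
    alpha = alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.3f, p = %.4g\n", x$f, x$p))
  for (g in names(x$means)) {
    cat(sprintf("  %-12s %.4g %s\n", g, x$means[[g]], x$letters[[g]]))
  }
  invisible(x)
}

#' Paired two-sided t test
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @return List with `statistic`, `p_value`, `mean_difference`, `df`.
#'   All-zero differences give t = 0, p = 1; constant non-zero differences
#'   give infinite t and p = 0.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- a - b
  if (sd(d) <= 1e-12 * (abs(mean(d)) + 1e-12)) {
    if (all(abs(d) <= 1e-300)) {
      return(list(statistic = 0, p_value = 1, mean_difference = 0,
                  df = length(d) - 1L))
    }
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                mean_difference = mean(d), df = length(d) - 1L))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = unname(tt$estimate), df = unname(tt$parameter))
}

#' Recover the perfusion-FI linkage from a cohort
#'
#' Fits relative FI against the perfusion index with a degree-2 (default)
#' polynomial, the form used to summarise the perfusion-fatigue
#' relationship.
#'
#' @param cohort A data frame with columns `perfusion_index` and `rel_fi`
#'   (e.g. from [generate_linkage_cohort()]), or a `cohort_dataset` whose
#'   animals carry both columns.
#' @param degree Polynomial degree (default 2).
#' @return A `caprare_fit`.
#' @export
recover_linkage <- function(cohort, degree = 2L) {
  df <- if (inherits(cohort, "cohort_dataset")) cohort$animals else cohort
  if (!all(c("perfusion_index", "rel_fi") %in% names(df))) {
    stop("cohort must provide perfusion_index and rel_fi per animal")
  }
  ok <- complete.cases(df[, c("perfusion_index", "rel_fi")])
  fit_ols(df$perfusion_index[ok], df$rel_fi[ok], degree = degree)
}
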