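#' One-way ANOVA with Fisher's-LSD letter grouping
#'
#' Tests whether a quantitative trait (e.g. proanthocyanidin content) differs
#' among genotype classes, the analysis behind genotype-phenotype association
#' at a diagnostic indel. Fits a fixed-effects one-way ANOVA
#' (`F = MS_between / MS_within`, df `k - 1` and `N - k`) via [stats::aov()],
#' then performs Fisher's least-significant-difference comparisons with the
#' pooled error: groups i and j differ iff
#' `|mean_i - mean_j| > t(1 - alpha/2, N - k) * sqrt(MSE * (1/n_i + 1/n_j))`.
#' The compact letter display is computed by insert-and-absorb on the means
#' sorted in decreasing order, so groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' Classes with fewer than 2 observations are excluded with a warning; fewer
#' than 2 remaining classes is an error. If all residual variance is zero the
#' degenerate fit is handled directly: identical means share one letter,
#' distinct means get distinct letters.
#'
#' @param tbl Data frame of per-sample records.
#' @param value,group Column names (strings) of the trait value and the
#'   genotype class; defaults `"trait_value"`, `"genotype_class"`.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `lsd_fit`; see [tidy.lsd_fit()] and
#'   [glance.lsd_fit()].
#' @export
anova_lsd <- function(tbl, value = "trait_value", group = "genotype_class",
                      alpha = 0.05) {
  stopifnot(value %in% names(tbl), group %in% names(tbl))
  df <- tibble(g = as.character(tbl[[group]]), y = as.numeric(tbl[[value]]))
  df <- df[!is.na(df$y) & !is.na(df$g), , drop = FALSE]
  sizes <- table(df$g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding class(es) with < 2 observations: ",
                paste(small, collapse = ", ")))
    df <- df[!df$g %in% small, , drop = FALSE]
  }
  k <- length(unique(df$g))
  if (k < 2) abort("need at least 2 classes with >= 2 observations")

  means <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))

  fit <- aov(y ~ g, data = df)
  an <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      # zero residual variance is a supported degenerate input here
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mse <- an[["Mean Sq"]][2]
  df_resid <- an[["Df"]][2]

  if (mse <= .Machine$double.eps * max(1, mean(df$y)^2)) {
    # zero residual variance: LSD threshold degenerates to equality of means
    sig <- function(i, j) means$mean[i] != means$mean[j]
    f_stat <- if (an[["Mean Sq"]][1] > 0) Inf else NA_real_
    p_val <- if (is.finite(f_stat)) 0 else NA_real_
  } else {
    tcrit <- qt(1 - alpha / 2, df_resid)
    sig <- function(i, j) {
      lsd <- tcrit * sqrt(mse * (1 / means$n[i] + 1 / means$n[j]))
      abs(means$mean[i] - means$mean[j]) > lsd
    }
    f_stat <- an[["F value"]][1]
    p_val <- an[["Pr(>F)"]][1]
  }

  letters_vec <- cld_insert_absorb(nrow(means), sig)
  means$letters <- letters_vec

  lsd_value <- if (mse > 0)
    qt(1 - alpha / 2, df_resid) * sqrt(mse * 2 / mean(means$n)) else 0

  structure(
    list(
      groups = means, f_statistic = f_stat, p_value = p_val,
      mse = mse, df_between = an[["Df"]][1], df_within = df_resid,
      alpha = alpha, lsd_mean_n = lsd_value
    ),
    class = "lsd_fit"
  )
}

# compact letter display by insert-and-absorb: for each group (means sorted
# decreasing) extend the maximal run of consecutive groups that are all
# pairwise non-significant, then absorb runs contained in earlier runs.
cld_insert_absorb <- function(k, sig) {
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k) {
      ok <- all(vapply(i:j, function(a) !sig(a, j + 1L), TRUE))
      if (!ok) break
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
  }
  # absorb runs contained in another run
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) {
    for (b in seq_along(runs)) {
      if (a != b && keep[a] && keep[b] && all(runs[[a]] %in% runs[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  runs <- runs[keep]
  out <- character(k)
  for (r in seq_along(runs)) {
    out[runs[[r]]] <- paste0(out[runs[[r]]], letters[r])
  }
  out
}

#' @exportS3Method base::print
print.lsd_fit <- function(x, ...) {
  cat(sprintf("<lsd_fit> one-way ANOVA: F(%d, %d) = %.4g, p = %.3g, MSE = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value, x$mse))
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Tidy an LSD fit into per-group rows
#'
#' @param x An `lsd_fit` from [anova_lsd()].
#' @param ... Unused.
#' @return Tibble `group`, `mean`, `n`, `letters`.
#' @export
tidy.lsd_fit <- function(x, ...) {
  dplyr::rename(x$groups, group = "g")
}

#' One-row summary of an LSD fit
#'
#' @param x An `lsd_fit`.
#' @param ... Unused.
#' @return Tibble `f_statistic`, `p_value`, `mse`, `df_between`, `df_within`,
#'   `alpha`.
#' @export
glance.lsd_fit <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value, mse = x$mse,
         df_between = x$df_between, df_within = x$df_within, alpha = x$alpha)
}
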