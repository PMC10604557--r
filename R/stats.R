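# Group comparison of deconvolved band quantities: one-way ANOVA, Tukey HSD
# with a compact letter display, and the band-table comparison reproducing the
# significance-letter logic of the source band table.

#' One-way analysis of variance
#'
#' Classic between/within decomposition with the p-value from the F
#' distribution.
#'
#' @param data Data frame of observations.
#' @param value Column of values (tidy-eval).
#' @param group Column of group labels (tidy-eval).
#' @return One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  check_groups(v, g)
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  tibble::tibble(
    f_statistic = unname(ft$statistic),
    df_between = as.integer(unname(ft$parameter[1])),
    df_within = as.integer(unname(ft$parameter[2])),
    p_value = unname(ft$p.value)
  )
}

check_groups <- function(v, g) {
  if (any(!is.finite(v))) stop("values must be finite", call. = FALSE)
  sizes <- table(g)
  if (length(sizes) < 2) stop("at least two groups required", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  invisible(NULL)
}

#' Tukey honestly-significant-difference comparisons with letters
#'
#' Pairwise studentized-range comparisons with pooled within-group variance
#' (the Tukey-Kramer rule for unequal sizes, via [stats::TukeyHSD()]), plus a
#' compact letter display: groups sharing no letter differ at `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level.
#' @return List of class `tukey_cld`: `pairs` tibble (`group1`, `group2`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`) and `letters` tibble
#'   (`group`, `mean`, `letters`).
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  check_groups(v, g)
  fit <- stats::aov(v ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble::tibble(
    group1 = vapply(cmp, `[`, "", 1),
    group2 = vapply(cmp, `[`, "", 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  means <- sort(tapply(v, g, mean), decreasing = TRUE)
  letters_tbl <- tibble::tibble(
    group = names(means), mean = unname(means),
    letters = compact_letters(names(means), pairs)
  )
  structure(list(pairs = pairs, letters = letters_tbl, alpha = alpha),
            class = "tukey_cld")
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("Tukey HSD at alpha =", x$alpha, "\n")
  print(x$pairs)
  print(x$letters)
  invisible(x)
}

# greedy clique cover of the "not significantly different" graph; groups
# ordered by descending mean get letters a, b, c, ...
compact_letters <- function(groups_by_mean, pairs) {
  differs <- function(a, b) {
    hit <- (pairs$group1 == a & pairs$group2 == b) |
      (pairs$group1 == b & pairs$group2 == a)
    any(pairs$significant[hit])
  }
  cliques <- list()
  for (g in groups_by_mean) {
    placed <- FALSE
    for (i in seq_along(cliques)) {
      if (!any(vapply(cliques[[i]], differs, logical(1), b = g))) {
        cliques[[i]] <- c(cliques[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1]] <- g
  }
  vapply(groups_by_mean, function(g) {
    paste(letters[which(vapply(cliques, function(cl) g %in% cl, logical(1)))],
          collapse = "")
  }, "")
}

#' Compare deconvolved band tables between two groups
#'
#' Bands are summarized per group, matched across groups by nearest mean
#' center within `match_tol`; matched pairs get ANOVA/Tukey comparisons of the
#' per-sample relative areas and centers, unmatched bands are flagged as
#' group-unique (the logic that singles out a disease-specific band).
#'
#' @param bands_a,bands_b Per-sample band tibbles from [deconvolve()], one
#'   group each.
#' @param alpha Significance level.
#' @param match_tol Center matching tolerance across groups (cm-1).
#' @param merge_distance Within-group band clustering tolerance (cm-1).
#' @param min_frac Minimum detection fraction for a band to enter the
#'   comparison.
#' @return Tibble with one row per band: group centers and areas
#'   (mean +/- sd), p-values for area and center, significance flags, and
#'   `unique_to` for unmatched bands.
#' @export
compare_band_tables <- function(bands_a, bands_b, alpha = 0.05, match_tol = 10,
                                merge_distance = 8, min_frac = 0.5) {
  lab_a <- unique(bands_a$label)
  lab_b <- unique(bands_b$label)
  stopifnot(length(lab_a) == 1, length(lab_b) == 1)
  assign_clusters <- function(bands) {
    bands <- dplyr::arrange(bands, .data$center)
    bands$band <- cumsum(c(1, diff(bands$center) > merge_distance))
    bands
  }
  a <- assign_clusters(bands_a)
  b <- assign_clusters(bands_b)
  sum_a <- summarize_bands(bands_a, merge_distance, min_frac)
  sum_b <- summarize_bands(bands_b, merge_distance, min_frac)
  used_b <- logical(nrow(sum_b))
  rows <- list()
  for (i in seq_len(nrow(sum_a))) {
    d <- abs(sum_b$center_mean - sum_a$center_mean[i])
    d[used_b] <- Inf
    j <- if (nrow(sum_b)) which.min(d) else integer(0)
    if (length(j) && d[j] <= match_tol) {
      used_b[j] <- TRUE
      va <- a[abs(a$center - sum_a$center_mean[i]) <= merge_distance, ]
      vb <- b[abs(b$center - sum_b$center_mean[j]) <= merge_distance, ]
      both <- dplyr::bind_rows(va, vb)
      p_area <- one_way_anova(both, .data$pct_area, .data$label)$p_value
      p_center <- one_way_anova(both, .data$center, .data$label)$p_value
      rows[[length(rows) + 1]] <- tibble::tibble(
        center_a = sum_a$center_mean[i], center_b = sum_b$center_mean[j],
        n_a = sum_a$n[i], n_b = sum_b$n[j],
        pct_area_a = sum_a$pct_area_mean[i], pct_area_sd_a = sum_a$pct_area_sd[i],
        pct_area_b = sum_b$pct_area_mean[j], pct_area_sd_b = sum_b$pct_area_sd[j],
        p_area = p_area, p_center = p_center,
        significant_area = p_area < alpha,
        significant_center = p_center < alpha,
        unique_to = NA_character_
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        center_a = sum_a$center_mean[i], center_b = NA_real_,
        n_a = sum_a$n[i], n_b = NA_integer_,
        pct_area_a = sum_a$pct_area_mean[i], pct_area_sd_a = sum_a$pct_area_sd[i],
        pct_area_b = NA_real_, pct_area_sd_b = NA_real_,
        p_area = NA_real_, p_center = NA_real_,
        significant_area = NA, significant_center = NA,
        unique_to = lab_a
      )
    }
  }
  for (j in which(!used_b)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      center_a = NA_real_, center_b = sum_b$center_mean[j],
      n_a = NA_integer_, n_b = sum_b$n[j],
      pct_area_a = NA_real_, pct_area_sd_a = NA_real_,
      pct_area_b = sum_b$pct_area_mean[j], pct_area_sd_b = sum_b$pct_area_sd[j],
      p_area = NA_real_, p_center = NA_real_,
      significant_area = NA, significant_center = NA,
      unique_to = lab_b
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, group_a = lab_a, group_b = lab_b, .before = 1)
  dplyr::arrange(out, pmin(.data$center_a, .data$center_b, na.rm = TRUE))
}
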