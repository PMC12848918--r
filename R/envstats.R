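# Seasonal/stand summary statistics, correlation screens, one-way ANOVA
# with LSD compact letter displays, and permutation variable importance.

ENV_VARS <- c("ph", "som", "soc", "tn", "tp", "an", "ap", "prcp", "temp", "rh")

#' Seasonal stand-level summaries
#'
#' Mean/sd/n of a measured variable per stand x season (seasons assigned by
#' [assign_season()]).
#'
#' @param records measurement table.
#' @param variable one of `"rs"`, `"soil_temp_10cm"`, `"soil_moisture"`.
#' @return data frame stand_id, season, variable, mean, sd, n.
#' @export
seasonal_summary <- function(records, variable = c("rs", "soil_temp_10cm",
                                                   "soil_moisture")) {
  variable <- match.arg(variable)
  records <- validate_measurements(records)
  season <- assign_season(records$date)
  key <- paste(records$stand_id, season, sep = "\t")
  groups <- split(records[[variable]], key)
  ids <- do.call(rbind, strsplit(names(groups), "\t", fixed = TRUE))
  out <- data.frame(stand_id = ids[, 1L], season = ids[, 2L],
                    variable = variable,
                    mean = vapply(groups, mean, 0),
                    sd = vapply(groups, stats::sd, 0),
                    n = vapply(groups, length, 0L), row.names = NULL)
  out[order(out$stand_id, out$season), , drop = FALSE]
}

#' Percent difference relative to a reference mean
#'
#' `100 * (other / reference - 1)`, the convention used when one stand is
#' said to exceed another by some percentage.
#'
#' @param reference reference mean (> 0).
#' @param other comparison mean.
#' @param digits rounding applied in reports (default 2).
#' @return percent difference.
#' @examples
#' percent_difference(900.33, 1484.84)  # 64.92
#' @export
percent_difference <- function(reference, other, digits = 2L) {
  if (any(reference <= 0))
    abort_fs("reference mean must be positive", "fs_domain_error")
  round(100 * (other / reference - 1), digits)
}

#' Wet/dry seasonal ratio of a variable per stand
#'
#' @inheritParams seasonal_summary
#' @return named numeric vector of wet-mean / dry-mean per stand.
#' @export
wet_dry_ratio <- function(records, variable = c("rs", "soil_temp_10cm",
                                                "soil_moisture")) {
  variable <- match.arg(variable)
  s <- seasonal_summary(records, variable)
  stands <- sort(unique(s$stand_id))
  vapply(stands, function(id) {
    dry <- s$mean[s$stand_id == id & s$season == "dry"]
    wet <- s$mean[s$stand_id == id & s$season == "wet"]
    if (!length(dry) || !length(wet))
      abort_fs(sprintf("stand %s lacks one of the seasons", id),
               "fs_coverage_error")
    if (dry <= 0)
      abort_fs(sprintf("stand %s has non-positive dry-season mean", id),
               "fs_domain_error")
    wet / dry
  }, 0)
}

#' Pearson correlation screen of respiration against environmental factors
#'
#' Computes pairwise Pearson correlations between a response column and
#' each environmental factor column, with two-sided t-based p-values and
#' the usual star convention (** p < 0.01, * p < 0.05). Constant columns
#' yield an `NA` correlation flagged in the result rather than an error.
#'
#' @param table data frame of aggregate rows (e.g. stand x season or stand x
#'   month) holding the response and factor columns.
#' @param response response column name (default `"rs"`).
#' @param variables factor column names (default: the ten standard
#'   environmental variables present in `table`).
#' @return data frame variable, r, p_value, n, star, flag.
#' @export
pearson_screen <- function(table, response = "rs",
                           variables = intersect(ENV_VARS, names(table))) {
  if (!response %in% names(table))
    abort_fs(sprintf("response column `%s` not found", response),
             "fs_argument_error")
  if (!length(variables))
    abort_fs("no environmental factor columns found", "fs_argument_error")
  rows <- lapply(variables, function(v) {
    ok <- is.finite(table[[response]]) & is.finite(table[[v]])
    x <- table[[response]][ok]; y <- table[[v]][ok]
    if (length(x) < 3)
      abort_fs(sprintf("fewer than 3 paired observations for %s", v),
               "fs_argument_error")
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(data.frame(variable = v, r = NA_real_, p_value = NA_real_,
                        n = length(x), star = "", flag = "constant column"))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x),
               star = significance_star(ct$p.value), flag = "")
  })
  do.call(rbind, rows)
}

# Piepho-style insert-and-absorb compact letter display from a logical
# significance matrix (TRUE = the pair differs). Guarantees: two groups
# share a letter iff their pair is not significant.
cld_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))           # letter columns as index sets
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      set <- cols[[ci]]
      if (all(c(i, j) %in% set)) {
        cols[[ci]] <- setdiff(set, i)
        cols[[length(cols) + 1L]] <- setdiff(set, j)
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[cj] && keep[ci] &&
          all(cols[[ci]] %in% cols[[cj]]) &&
          !(all(cols[[cj]] %in% cols[[ci]]) && ci < cj))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by the best (highest-mean-ranked) group they contain so
  # "a" goes to the leading group
  ord <- order(vapply(cols, min, 0L))
  cols <- cols[ord]
  vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, function(s) g %in% s, TRUE))],
          collapse = ""),
    "")
}

#' One-way ANOVA with LSD post-hoc compact letter display
#'
#' One-way ANOVA followed by Fisher's LSD: unadjusted pairwise t-tests on
#' the pooled within-group mean square. Letters are built by
#' insert-and-absorb so that two groups share a letter if and only if their
#' pairwise LSD test is non-significant at `alpha`. Groups are lettered in
#' descending mean order (the largest mean gets "a"). LSD performs no
#' multiplicity correction and is anti-conservative with many groups.
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return a `group_comparison` list: `summary` (group, mean, sd, n,
#'   letters), `F`, `p_value`, `df`, `pairwise` (p-value matrix), `alpha`.
#' @export
anova_lsd_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    abort_fs("values and groups differ in length", "fs_argument_error")
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    abort_fs("need >= 2 groups with n >= 2 each", "fs_argument_error")
  av <- stats::anova(stats::lm(values ~ groups))
  mse <- av[["Mean Sq"]][2L]
  dfe <- av[["Df"]][2L]
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  g <- names(means)[ord]
  k <- length(g)
  pmat <- matrix(NA_real_, k, k, dimnames = list(g, g))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    se <- sqrt(mse * (1 / sizes[[g[i]]] + 1 / sizes[[g[j]]]))
    tval <- (means[[g[i]]] - means[[g[j]]]) / se
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(abs(tval), dfe, lower.tail = FALSE)
  }
  sig <- !is.na(pmat) & pmat < alpha
  letters_ord <- cld_letters(sig)
  summary <- data.frame(
    group = g,
    mean = as.numeric(means[g]),
    sd = as.numeric(tapply(values, groups, stats::sd)[g]),
    n = as.integer(sizes[g]),
    letters = letters_ord, row.names = NULL)
  structure(list(summary = summary,
                 F = av[["F value"]][1L], p_value = av[["Pr(>F)"]][1L],
                 df = c(av[["Df"]][1L], dfe), pairwise = pmat, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
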