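#' Significance tier of a p-value
#'
#' Tiers follow the reporting convention `*` p < 0.1, `**` p < 0.05,
#' `***` p < 0.01, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of tiers.
#' @export
p_tier <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "ns")))
}

#' Gate between Dunnett and Steel many-to-one tests
#'
#' Each group is tested for normality (Shapiro-Wilk) and the set for equal
#' variances (Bartlett).  If neither normality nor homoscedasticity is
#' rejected at `alpha_gate`, the parametric Dunnett test is chosen; otherwise
#' the nonparametric Steel test.
#'
#' @param groups list of numeric vectors, each of length >= 3.
#' @param alpha_gate gate significance level (default 0.05).
#' @return list with `test` (`"Dunnett"` or `"Steel"`), `shapiro_p` (per
#'   group) and `bartlett_p`.
#' @export
gate_test_choice <- function(groups, alpha_gate = 0.05) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("every group must have at least 3 values")
  shapiro_p <- vapply(groups, function(g) {
    if (length(unique(g)) == 1) return(0)  # constant: normality untestable, treat as rejected
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  values <- unlist(groups)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  bartlett_p <- if (any(shapiro_p == 0)) 0 else
    stats::bartlett.test(values, grp)$p.value
  test <- if (all(shapiro_p > alpha_gate) && bartlett_p > alpha_gate)
    "Dunnett" else "Steel"
  list(test = test, shapiro_p = shapiro_p, bartlett_p = bartlett_p)
}

#' Dunnett many-to-one comparisons against a reference group
#'
#' Parametric many-to-one mean comparisons with single-step multiplicity
#' adjustment, via `multcomp::glht` on a one-way fit.
#'
#' @param groups list of numeric vectors.
#' @param reference_index index of the reference group (default 1).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (treatment
#'   relative to reference).
#' @return tibble with `contrast`, `estimate`, `p`, `tier`, `test`.
#' @export
dunnett_many_to_one <- function(groups, reference_index = 1,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  if (length(groups[[reference_index]]) == 0) stop("reference group is empty")
  ord <- c(reference_index, setdiff(seq_len(k), reference_index))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  values <- unlist(groups[ord])
  grp <- factor(rep(nm[ord], lengths(groups[ord])), levels = nm[ord])
  contrast <- paste(nm[ord][-1], "vs", nm[reference_index])
  if (stats::var(values) == 0) {
    # all observations identical: no evidence of any difference
    return(tibble::tibble(contrast = contrast, estimate = 0, p = 1,
                          tier = "ns", test = "Dunnett"))
  }
  fit <- stats::aov(values ~ grp, data = data.frame(values, grp))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"),
                       alternative = alternative)
  sm <- summary(gl)
  p <- as.numeric(sm$test$pvalues)
  tibble::tibble(contrast = contrast,
                 estimate = as.numeric(sm$test$coefficients),
                 p = p, tier = p_tier(p), test = "Dunnett")
}

# pairwise rank-sum statistic of treatment vs control with tie correction
steel_z <- function(treat, control) {
  n0 <- length(control); n1 <- length(treat)
  r <- rank(c(control, treat))
  W <- sum(r[(n0 + 1):(n0 + n1)])
  N <- n0 + n1
  E <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  V <- n0 * n1 / 12 * (N + 1 - tie_term)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel many-to-one rank comparisons against a reference group
#'
#' Nonparametric analogue of the Dunnett test: each treatment is compared to
#' the reference by a pairwise rank sum, and familywise adjustment uses the
#' multivariate normal distribution of the standardized statistics with
#' correlation `sqrt(n_i n_j / ((n_0 + n_i)(n_0 + n_j)))`.  When any group is
#' too small for the normal approximation, a conservative fallback —
#' Bonferroni-adjusted exact Wilcoxon rank-sum tests — is used instead
#' (`method = "auto"`).
#'
#' @param groups list of numeric vectors.
#' @param reference_index index of the reference group (default 1).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (treatment
#'   relative to reference).
#' @param method `"auto"`, `"mvn"` or `"bonferroni"`.
#' @param min_n_mvn smallest group size for which the multivariate normal
#'   approximation is used under `"auto"` (default 6).
#' @return tibble with `contrast`, `estimate` (Hodges-Lehmann shift), `p`,
#'   `tier`, `test`.
#' @export
steel_many_to_one <- function(groups, reference_index = 1,
                              alternative = c("two.sided", "greater", "less"),
                              method = c("auto", "mvn", "bonferroni"),
                              min_n_mvn = 6) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  control <- groups[[reference_index]]
  if (length(control) == 0) stop("reference group is empty")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  tr_idx <- setdiff(seq_len(k), reference_index)
  contrast <- paste(nm[tr_idx], "vs", nm[reference_index])
  if (method == "auto") {
    method <- if (min(lengths(groups)) >= min_n_mvn) "mvn" else "bonferroni"
  }
  est <- vapply(tr_idx, function(i) {
    stats::median(outer(groups[[i]], control, "-"))
  }, numeric(1))
  if (method == "bonferroni") {
    p <- vapply(tr_idx, function(i) {
      alt <- switch(alternative, two.sided = "two.sided",
                    greater = "greater", less = "less")
      min(1, stats::wilcox.test(groups[[i]], control,
                                alternative = alt)$p.value * length(tr_idx))
    }, numeric(1))
  } else {
    z <- vapply(tr_idx, function(i) steel_z(groups[[i]], control), numeric(1))
    n0 <- length(control)
    ni <- lengths(groups)[tr_idx]
    lam <- sqrt(ni / (n0 + ni))
    corr <- outer(lam, lam)
    diag(corr) <- 1
    m <- length(z)
    p <- vapply(seq_len(m), function(i) {
      if (m == 1) {
        # one comparison: reduces to the normal-approximation rank-sum test
        return(switch(alternative,
                      two.sided = 2 * stats::pnorm(-abs(z[i])),
                      greater = stats::pnorm(z[i], lower.tail = FALSE),
                      less = stats::pnorm(z[i])))
      }
      if (alternative == "two.sided") {
        1 - mvtnorm::pmvnorm(lower = rep(-abs(z[i]), m),
                             upper = rep(abs(z[i]), m), corr = corr)[1]
      } else if (alternative == "greater") {
        1 - mvtnorm::pmvnorm(lower = rep(-Inf, m), upper = rep(z[i], m),
                             corr = corr)[1]
      } else {
        1 - mvtnorm::pmvnorm(lower = rep(-z[i], m), upper = rep(Inf, m),
                             corr = corr)[1]
      }
    }, numeric(1))
    p <- pmin(pmax(p, 0), 1)
  }
  tibble::tibble(contrast = contrast, estimate = est, p = p,
                 tier = p_tier(p), test = "Steel")
}

#' Two-group Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Exact when sample sizes permit and there are no ties.  The alternative
#' follows `stats::wilcox.test` semantics for the first argument: use
#' `"less"` to test that `b` tends to be greater than `a`.
#'
#' @param a,b nonempty numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return a one-row tibble with `contrast`, `p`, `tier`, `test`.
#' @export
mann_whitney_two_group <- function(a, b, alternative = c("two.sided",
                                                         "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  p <- suppressWarnings(stats::wilcox.test(a, b,
                                           alternative = alternative)$p.value)
  if (is.nan(p)) p <- 1  # degenerate all-tied case carries no evidence
  tibble::tibble(contrast = "a vs b", p = p, tier = p_tier(p),
                 test = "Mann-Whitney")
}

#' Run the gated day-wise contrasts on a study table
#'
#' For the Days 1-4 scheme, each condition's daily groups are compared
#' many-to-one against the reference day (Day 1); for the Day-5 scheme, each
#' Day-5 manipulation group is compared against the intact reference.  The
#' Shapiro/Bartlett gate selects Dunnett or Steel per (condition, index)
#' family.
#'
#' @param table study table (data frame) with columns `condition`, `day` and
#'   the index column.
#' @param index name of the value column to analyse (e.g. `"area"`,
#'   `"speed"`, `"omega"`).
#' @param scheme `"days"` (Days vs Day 1, per condition) or `"day5"`
#'   (conditions vs a reference condition at one day).
#' @param reference_day reference day for the `"days"` scheme (default 1).
#' @param reference_condition reference condition for the `"day5"` scheme
#'   (default `"day5_intact"`).
#' @param day5 the day analysed under the `"day5"` scheme (default 5).
#' @param alternative passed to the selected test.
#' @param alpha_gate gate level (default 0.05).
#' @return tibble with `index`, `condition`, `contrast`, `test`, `p`, `tier`.
#' @export
run_study_contrasts <- function(table, index, scheme = c("days", "day5"),
                                reference_day = 1,
                                reference_condition = "day5_intact",
                                day5 = 5,
                                alternative = "two.sided",
                                alpha_gate = 0.05) {
  scheme <- match.arg(scheme)
  if (!index %in% names(table)) stop("index column not found: ", index)
  out <- list()
  if (scheme == "days") {
    for (cond in unique(table$condition)) {
      sub <- table[table$condition == cond, ]
      days <- sort(unique(sub$day))
      if (!reference_day %in% days)
        stop("reference day ", reference_day, " missing for condition ", cond)
      groups <- lapply(days, function(d) sub[[index]][sub$day == d])
      names(groups) <- paste("Day", days)
      res <- gated_many_to_one(groups, which(days == reference_day),
                               alternative, alpha_gate)
      res$condition <- cond
      out[[cond]] <- res
    }
  } else {
    sub <- table[table$day == day5, ]
    conds <- unique(sub$condition)
    if (!reference_condition %in% conds)
      stop("reference condition ", reference_condition, " missing on day ", day5)
    conds <- c(reference_condition, setdiff(conds, reference_condition))
    groups <- lapply(conds, function(cn) sub[[index]][sub$condition == cn])
    names(groups) <- conds
    res <- gated_many_to_one(groups, 1L, alternative, alpha_gate)
    res$condition <- paste("Day", day5)
    out[["day5"]] <- res
  }
  res <- do.call(rbind, out)
  tibble::tibble(index = index, condition = res$condition,
                 contrast = res$contrast, test = res$test, p = res$p,
                 tier = res$tier)
}

gated_many_to_one <- function(groups, reference_index, alternative,
                              alpha_gate) {
  gate <- gate_test_choice(groups, alpha_gate)
  if (gate$test == "Dunnett")
    dunnett_many_to_one(groups, reference_index, alternative)
  else
    steel_many_to_one(groups, reference_index, alternative)
}

#' Rank correlation between an oscillation index and a behavioural index
#'
#' Convenience wrapper around Spearman's rank correlation for exploring
#' frequency-behaviour relations.
#'
#' @param x,y numeric vectors.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
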