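## Pre/post comparisons and group descriptives.

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Differences of zero are dropped (Wilcoxon's convention); ties receive
#' midranks. The statistic is the sum of ranks of positive differences
#' (`W`). For `n <= exact_limit` retained pairs the two-sided p-value is
#' computed from the exact signed-rank distribution (shift convolution
#' over all 2^n sign assignments, feasible because the support of the
#' doubled rank sum is small); otherwise the normal approximation with
#' tie correction is used. A `z` statistic is always reported.
#'
#' @param pre,post Paired numeric vectors (pairs with any `NA` dropped).
#' @param exact_limit Maximum n for the exact distribution (default 25).
#' @return List: `statistic` (W, positive-rank sum of post - pre),
#'   `p_value`, `z`, `n` (nonzero pairs), `method`, `median_diff`,
#'   plus `ci_low`/`ci_high` (Hodges-Lehmann interval when available).
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_limit = 25L) {
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, z = NA_real_,
                n = 0L, method = "undefined (all differences zero)",
                median_diff = 0, ci_low = NA_real_, ci_high = NA_real_))
  }
  rk <- rank(abs(d)) # midranks
  w <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  # variance with tie correction
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else NA_real_

  if (n <= exact_limit) {
    p <- .signed_rank_exact_p(rk, w)
    method <- "exact signed-rank"
  } else {
    p <- if (is.na(z)) NA_real_ else min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  hl <- tryCatch(suppressWarnings(
    stats::wilcox.test(post[ok], pre[ok], paired = TRUE, conf.int = TRUE)),
    error = function(e) NULL)
  list(statistic = w, p_value = p, z = z, n = n, method = method,
       median_diff = stats::median(post[ok] - pre[ok]),
       ci_low = if (!is.null(hl)) unname(hl$conf.int[1]) else NA_real_,
       ci_high = if (!is.null(hl)) unname(hl$conf.int[2]) else NA_real_)
}

## Exact two-sided p for the positive-rank sum given the (mid)ranks.
## Works on doubled ranks so midranks become integers; the distribution
## of the doubled positive-rank sum is built by shift convolution.
.signed_rank_exact_p <- function(ranks, w) {
  w2 <- round(2 * ranks)
  total <- sum(w2)
  dist <- numeric(total + 1L)
  dist[1] <- 1
  for (wt in w2) {
    shifted <- c(numeric(wt), dist[seq_len(total + 1L - wt)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  wobs <- round(2 * w)
  support <- 0:total
  p_le <- sum(dist[support <= wobs])
  p_ge <- sum(dist[support >= wobs])
  min(1, 2 * min(p_le, p_ge))
}

#' Pre/post outcome tests for the cohort
#'
#' Depressive symptoms (GDS) and sleep quality (PSQI) change from pre to
#' post by exact Wilcoxon signed-rank; system usability (SUS) by paired
#' t-test; age moderation of the usability change by a 2 x 2 mixed
#' ANOVA (time within, age group between: over 75 vs 65-74). Only
#' participants with complete pre and post values enter each test.
#'
#' @param profiles Participant table with `baseline_gds`/`gds_post`,
#'   `baseline_psqi`/`psqi_post`, `sus_pre`/`sus_post`, `age`.
#' @return List with elements `gds`, `psqi` (signed-rank results),
#'   `sus` (paired t), and `sus_age_moderation` (interaction F test).
#' @export
pre_post_tests <- function(profiles) {
  gds <- wilcoxon_signed_rank(profiles$baseline_gds, profiles$gds_post)
  psqi <- wilcoxon_signed_rank(profiles$baseline_psqi, profiles$psqi_post)

  ok <- !is.na(profiles$sus_pre) & !is.na(profiles$sus_post)
  if (sum(ok) >= 2L) {
    tt <- stats::t.test(profiles$sus_post[ok], profiles$sus_pre[ok],
                        paired = TRUE)
    sus <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, mean_diff = unname(tt$estimate),
                ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                n = sum(ok))
  } else {
    sus <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_diff = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = sum(ok))
  }

  mod <- NULL
  if (sum(ok) >= 4L) {
    long <- data.frame(
      pid = rep(profiles$participant_id[ok], 2L),
      sus = c(profiles$sus_pre[ok], profiles$sus_post[ok]),
      time = rep(c("pre", "post"), each = sum(ok)),
      age_group = rep(age_group(profiles$age[ok]), 2L))
    if (length(unique(long$age_group)) == 2L) {
      fit <- stats::aov(sus ~ time * age_group + Error(pid / time), data = long)
      tab <- summary(fit)[["Error: pid:time"]][[1]]
      irow <- grep("time:age_group", rownames(tab))
      mod <- list(F = tab[irow, "F value"], df1 = tab[irow, "Df"],
                  df2 = tab["Residuals", "Df"],
                  p_value = tab[irow, "Pr(>F)"])
    }
  }
  if (is.null(mod)) {
    mod <- list(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p_value = NA_real_)
  }
  list(gds = gds, psqi = psqi, sus = sus, sus_age_moderation = mod)
}

#' Age grouping used for the usability moderation analysis
#'
#' @param age Numeric ages in years.
#' @return Factor: `"oldest"` for age strictly above 75, else
#'   `"younger"`.
#' @export
age_group <- function(age) {
  factor(ifelse(age > 75, "oldest", "younger"), levels = c("younger", "oldest"))
}

#' Group comparison table (depressed vs non-depressed at baseline)
#'
#' Splits participants at a baseline depression score of 5 or higher and
#' compares each requested variable: Welch t-test for continuous
#' variables, chi-square for categorical, Fisher's exact test
#' (hypergeometric enumeration, as done by [stats::fisher.test()]) where
#' requested.
#'
#' @param profiles Participant table.
#' @param vars Named character vector mapping variable name to test type
#'   (`"continuous"`, `"categorical"`, `"fisher"`).
#' @param cutoff Baseline depression cutoff (default 5, the mild-risk
#'   threshold).
#' @return Data frame: `variable`, `test`, `statistic`, `p_value`,
#'   `n_depressed`, `n_not`.
#' @export
descriptive_table <- function(profiles,
                              vars = c(age = "continuous",
                                       sex = "categorical",
                                       n_chronic = "continuous",
                                       baseline_psqi = "continuous"),
                              cutoff = 5) {
  grp <- profiles$baseline_gds >= cutoff
  if (all(grp) || !any(grp)) stop("one baseline group is empty")
  rows <- lapply(names(vars), function(v) {
    type <- vars[[v]]
    x <- profiles[[v]]
    stat <- p <- NA_real_
    if (type == "continuous") {
      tt <- stats::t.test(x[grp], x[!grp])
      stat <- unname(tt$statistic); p <- tt$p.value
    } else if (type == "categorical") {
      tab <- table(x, grp)
      ct <- suppressWarnings(stats::chisq.test(tab))
      stat <- unname(ct$statistic); p <- ct$p.value
    } else if (type == "fisher") {
      tab <- table(x, grp)
      ft <- stats::fisher.test(tab)
      stat <- NA_real_; p <- ft$p.value
    } else stop("unknown test type: ", type)
    data.frame(variable = v, test = type, statistic = stat, p_value = p,
               n_depressed = sum(grp), n_not = sum(!grp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
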