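#' Wilcoxon signed-rank test with an exact sign-flip distribution
#'
#' Paired, donor-matched comparison of `b` against `a` using differences
#' `d = b - a`. Absolute differences are ranked with mid-ranks; the
#' statistic `V` is the rank sum of the positive differences. For
#' `n <= exact_limit` non-zero pairs the p-value is exact, computed from
#' the full sign-flip distribution of `V` (a dynamic-programming
#' convolution equivalent to enumerating all `2^n` sign assignments, valid
#' with tied ranks); otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' Zero differences are dropped before ranking by default (Wilcoxon's
#' original treatment); `zero_method = "pratt"` ranks them but drops them
#' from the statistic.
#'
#' @param a,b Numeric vectors of paired values (same length).
#' @param alternative `"two.sided"` (default), `"greater"` (b tends larger
#'   than a) or `"less"`.
#' @param zero_method `"wilcoxon"` (drop zero differences) or `"pratt"`.
#' @param exact_limit Largest n for which the exact distribution is used.
#' @return List with `statistic` (V), `p_value`, `n` (pairs used),
#'   `method`, `alternative`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "greater", "less"),
                                 zero_method = c("wilcoxon", "pratt"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (length(a) != length(b)) stop("a and b must have the same length")
  keep <- complete.cases(a, b)
  d <- (b - a)[keep]
  if (!length(d)) stop("no complete pairs")
  if (all(d == 0)) {
    warning("all paired differences are zero; no evidence either way")
    return(list(statistic = 0, p_value = 1, n = 0L,
                method = "degenerate", alternative = alternative))
  }
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))     # zeros receive the lowest ranks
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    s <- as.integer(round(2 * r))
    S <- sum(s)
    g <- numeric(S + 1)       # g[w+1] = #sign assignments with 2*V == w
    g[1] <- 1
    for (si in s) {
      shifted <- c(numeric(si), g[seq_len(S + 1 - si)])
      g <- g + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * V))
    p_le <- sum(g[seq_len(w2 + 1)]) / tot
    p_ge <- sum(g[(w2 + 1):(S + 1)]) / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact sign-flip distribution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = V, p_value = p, n = n, method = method,
       alternative = alternative)
}

# all permutations of 1..k, one per row
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- sub + (sub >= i)
    cbind(rep(i, nrow(sub)), rest)
  }))
}

friedman_statistic <- function(R, n, k, A) {
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) return(0)
  (k - 1) * sum((R - n * (k + 1) / 2)^2) / denom
}

#' Friedman rank test for donor-blocked repeated measures
#'
#' Nonparametric comparison of `k >= 3` matched conditions across blocks
#' (donors). Values are ranked within each block with mid-rank ties; the
#' tie-corrected chi-square statistic is
#' `(k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with `A` the sum of squared
#' ranks and `C = nk(k+1)^2/4` (reducing to the classical statistic
#' without ties). The default p-value is the chi-square approximation on
#' `k - 1` degrees of freedom; `exact = TRUE` computes the full
#' within-block permutation distribution (all `(k!)^n` equiprobable
#' re-orderings, aggregated by dynamic programming over column rank sums),
#' conditional on the observed tie pattern.
#'
#' @param values Blocks-by-conditions numeric matrix, or a data frame with
#'   `value`, `condition` and `block` columns (reshaped internally).
#'   Blocks with any missing value are dropped (listwise deletion).
#' @param exact Compute the exact permutation p-value (requires `k <= 5`
#'   and `n <= 12`).
#' @return List with `statistic`, `df`, `p_value`, `n_blocks`, `k`,
#'   `method`.
#' @export
friedman_rm <- function(values, exact = FALSE) {
  if (is.data.frame(values)) {
    need <- c("value", "condition", "block")
    if (!all(need %in% names(values)))
      stop("data frame input needs columns value, condition, block")
    wide <- tapply(values$value, list(values$block, values$condition), mean)
    values <- wide
  }
  values <- as.matrix(values)
  complete <- stats::complete.cases(values)
  if (sum(!complete)) {
    warning("dropping ", sum(!complete), " incomplete block(s)")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values); k <- ncol(values)
  if (k < 3L) stop("Friedman test needs at least 3 conditions")
  if (n < 3L) stop("fewer than 3 complete blocks")
  ranks <- t(apply(values, 1, rank))
  A <- sum(ranks^2)
  R <- colSums(ranks)
  stat <- friedman_statistic(R, n, k, A)
  if (!exact) {
    return(list(statistic = stat, df = k - 1L,
                p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
                n_blocks = n, k = k, method = "chi-square approximation"))
  }
  if (k > 5L || n > 12L)
    stop("exact permutation distribution limited to k <= 5, n <= 12")
  perms <- all_permutations(k)
  # DP over scaled (x2, integer) column sums of the first k-1 conditions
  states <- new.env(parent = emptyenv())
  assign(paste(rep(0L, k - 1L), collapse = "_"), 1, envir = states)
  for (i in seq_len(n)) {
    r2 <- as.integer(round(2 * ranks[i, ]))
    nxt <- new.env(parent = emptyenv())
    for (key in ls(states)) {
      cnt <- get(key, envir = states)
      base <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
      for (p in seq_len(nrow(perms))) {
        v <- base + r2[perms[p, ]][seq_len(k - 1L)]
        nk <- paste(v, collapse = "_")
        prev <- if (exists(nk, envir = nxt, inherits = FALSE))
          get(nk, envir = nxt) else 0
        assign(nk, prev + cnt, envir = nxt)
      }
    }
    states <- nxt
  }
  total_ranks <- sum(ranks)   # = n * k(k+1)/2, invariant
  keys <- ls(states)
  cnts <- vapply(keys, get, numeric(1), envir = states)
  stats_perm <- vapply(keys, function(key) {
    v <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]]) / 2
    friedman_statistic(c(v, total_ranks - sum(v)), n, k, A)
  }, numeric(1))
  p <- sum(cnts[stats_perm >= stat - 1e-9]) / sum(cnts)
  list(statistic = stat, df = k - 1L, p_value = p, n_blocks = n, k = k,
       method = "exact within-block permutation distribution")
}

#' Efficiency-corrected relative expression ratio
#'
#' Pfaffl-style relative quantification of a target gene against a
#' reference (housekeeping) gene:
#' `ratio = E_target^(Ct_target,control - Ct_target,sample) /
#'          E_ref^(Ct_ref,control - Ct_ref,sample)`,
#' where `E` are amplification efficiencies (2 = perfect doubling per
#' cycle). Vectorized over samples.
#'
#' @param ct_target_sample,ct_target_control Target-gene Ct values in the
#'   sample and calibrator/control.
#' @param ct_ref_sample,ct_ref_control Reference-gene Ct values.
#' @param e_target,e_ref Amplification efficiencies, in `[1, 2.2]`
#'   (default 2, assumed when not measured).
#' @return Numeric expression ratio(s).
#' @examples
#' pfaffl_ratio(24, 25, 20, 20)  # one cycle earlier at E = 2: ratio 2
#' @export
pfaffl_ratio <- function(ct_target_sample, ct_target_control,
                         ct_ref_sample, ct_ref_control,
                         e_target = 2, e_ref = 2) {
  if (any(c(e_target, e_ref) < 1) || any(c(e_target, e_ref) > 2.2))
    stop("amplification efficiencies must lie in [1, 2.2]")
  cts <- c(ct_target_sample, ct_target_control, ct_ref_sample, ct_ref_control)
  if (any(cts[!is.na(cts)] <= 0)) stop("Ct values must be positive")
  e_target^(ct_target_control - ct_target_sample) /
    e_ref^(ct_ref_control - ct_ref_sample)
}

#' Normalize expression ratios to within-donor controls
#'
#' Divides each ratio by the matched control-condition ratio of the same
#' donor (and any further grouping columns present, e.g. culture system,
#' day, gene), so control rows become exactly 1 and other conditions are
#' fold changes relative to their own donor's control.
#'
#' @param ratios Tibble with at least `donor`, `condition` and the value
#'   column.
#' @param control_condition Condition label of the control.
#' @param value_col Name of the ratio column (default `"ratio"`).
#' @return The input tibble with a `fold_change` column; rows without a
#'   matched control get `NA` with a warning.
#' @export
fold_change_normalize <- function(ratios, control_condition = "control",
                                  value_col = "ratio") {
  if (!all(c("donor", "condition", value_col) %in% names(ratios)))
    stop("ratios needs columns donor, condition and ", value_col)
  grouping <- setdiff(names(ratios), c("condition", value_col, "fold_change"))
  out <- ratios |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(
      .ctrl = {
        v <- .data[[value_col]][.data$condition == control_condition]
        if (length(v)) v[1] else NA_real_
      },
      fold_change = .data[[value_col]] / .data$.ctrl
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".ctrl")
  if (anyNA(out$fold_change) && !anyNA(ratios[[value_col]]))
    warning("some rows have no matched control; fold change set to NA")
  out
}

#' Population doubling (generation) time
#'
#' `GT = elapsed * log(2) / (log(n_end) - log(n_start))`: the time needed
#' for one doubling under exponential growth between two cell counts.
#'
#' @param n_start,n_end Cell counts (`n_end > n_start > 0` for a defined
#'   value).
#' @param elapsed Elapsed culture time (hours).
#' @return Generation time in the units of `elapsed`; `NA` with a warning
#'   when no growth occurred.
#' @examples
#' generation_time(1e5, 2e5, 24)  # one doubling in 24 h
#' @export
generation_time <- function(n_start, n_end, elapsed) {
  if (any(n_start <= 0)) stop("n_start must be positive")
  out <- elapsed * log(2) / (log(n_end) - log(n_start))
  bad <- n_end <= n_start
  if (any(bad)) {
    warning("n_end <= n_start: generation time undefined (no growth)")
    out[bad] <- NA_real_
  }
  out
}
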