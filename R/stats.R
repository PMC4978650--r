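# The statistical battery used to compare the three protocols across a
# cohort: one-way repeated-measures ANOVA with paired t / Holm follow-ups for
# SNR, the tie-corrected Friedman test with Wilcoxon signed-rank / Holm
# follow-ups for ordinal grades, and Cohen's kappa for interobserver
# agreement. Reference distributions (F, chi-square, t, normal, signed-rank)
# come from base R; the Friedman and signed-rank statistics themselves are
# implemented here so the tie and zero-difference conventions are pinned.

.check_rm <- function(values, min_cols = 2L) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    .stopf("repeated-measures data must be a finite numeric matrix")
  if (ncol(values) < min_cols)
    .stopf("need at least %d protocol columns, got %d", min_cols, ncol(values))
  if (nrow(values) < 3L)
    .stopf("need at least 3 subjects, got %d", nrow(values))
  values
}

.test_result <- function(statistic, p_value, method, ...) {
  structure(list(statistic = statistic, p_value = p_value, method = method, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Subjects are the blocks: the total sum of squares is decomposed into
#' subject, protocol and residual components, and
#' `F = MS_protocol / MS_residual` with `(k - 1)` and `(n - 1)(k - 1)`
#' degrees of freedom. No sphericity correction is applied.
#'
#' @param values `n_subjects x k_protocols` numeric matrix.
#' @return A `test_result` with `df` and the sums of squares.
#' @export
rm_anova <- function(values) {
  x <- .check_rm(values)
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ss_sub <- k * sum((rowMeans(x) - gm)^2)
  ss_prot <- n * sum((colMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- ss_tot - ss_sub - ss_prot
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  if (ss_prot <= 0 || ss_err < 0) {
    f <- 0; p <- 1
  } else if (ss_err == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_prot / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  .test_result(f, p, "repeated-measures one-way ANOVA",
               df = c(df1, df2),
               ss = c(subject = ss_sub, protocol = ss_prot, error = ss_err))
}

# Paired t test with explicit handling of degenerate differences.
.paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2L) .stopf("paired t needs >= 2 subjects")
  if (all(d == 0))
    return(.test_result(0, 1, "paired t test", degenerate = TRUE, n = n))
  s <- stats::sd(d)
  if (s == 0)
    return(.test_result(sign(d[1L]) * Inf, 0, "paired t test",
                        degenerate = TRUE, n = n))
  t <- mean(d) / (s / sqrt(n))
  .test_result(t, 2 * stats::pt(-abs(t), n - 1L), "paired t test",
               degenerate = FALSE, n = n)
}

.pairwise_holm <- function(values, pairs, test_fun) {
  x <- .check_rm(values)
  if (is.null(pairs)) pairs <- utils::combn(ncol(x), 2L, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    out <- test_fun(x[, pr[1L]], x[, pr[2L]])
    out$comparison <- paste(colnames(x)[pr] %||% pr, collapse = " vs ")
    out$pair <- pr
    out
  })
  adj <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p_value"),
                         method = "holm")
  for (i in seq_along(res)) res[[i]]$adjusted_p <- adj[i]
  res
}

#' Pairwise paired t tests with Holm correction
#'
#' @param values `n x k` numeric matrix.
#' @param pairs List of length-2 column index vectors; default all pairs.
#' @return A list of `test_result`s, each with an `adjusted_p` field
#'   (Holm step-down over the family).
#' @export
paired_t_holm <- function(values, pairs = NULL) {
  .pairwise_holm(values, pairs, .paired_t)
}

# All permutations of 1..k (k small).
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in 0:(k - 1L))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

# Exact permutation distribution of the column rank sums: each row's rank
# vector is rearranged by each of the k! within-row orderings with equal
# probability; states are accumulated by convolution over rows. Returns a
# data frame of (sum of squared column rank sums, probability).
.friedman_exact_dist <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  perms <- .permutations(k)
  states <- new.env(hash = TRUE, parent = emptyenv())
  assign("0", list(R = rep(0, k), p = 1), envir = states)
  for (i in seq_len(n)) {
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(states)) {
      st <- get(key, envir = states)
      for (pm in perms) {
        r2 <- st$R + ranks[i, pm]
        k2 <- paste(round(2 * r2), collapse = ",")
        if (exists(k2, envir = nxt, inherits = FALSE)) {
          cur <- get(k2, envir = nxt)
          cur$p <- cur$p + st$p / length(perms)
          assign(k2, cur, envir = nxt)
        } else {
          assign(k2, list(R = r2, p = st$p / length(perms)), envir = nxt)
        }
      }
    }
    states <- nxt
  }
  keys <- ls(states)
  data.frame(
    sumsq = vapply(keys, function(kk) sum(get(kk, envir = states)$R^2), numeric(1)),
    prob = vapply(keys, function(kk) get(kk, envir = states)$p, numeric(1)))
}

#' Friedman test with tie correction
#'
#' Within-subject ranks (average ranks on ties) are summed per protocol and
#' the tie-corrected chi-square statistic
#' `T = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` is computed, with
#' `A` the sum of squared ranks and `C = n k (k+1)^2 / 4`; without ties this
#' reduces to the classical Friedman chi-square. The p-value comes from the
#' chi-square reference distribution with `k - 1` df, or — for `n <= 8`
#' subjects (or when `exact = TRUE`) — from the exact permutation null over
#' all within-subject orderings.
#'
#' @param values `n x k` matrix of grades or numeric scores.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   path; default `NULL` uses it for `n <= 8`.
#' @return A `test_result`; the `method` label records which path was used.
#' @export
friedman_rm <- function(values, exact = NULL) {
  x <- .check_rm(values)
  n <- nrow(x); k <- ncol(x)
  ranks <- t(apply(x, 1L, rank))
  rj <- colSums(ranks)
  a <- sum(ranks^2)
  cc <- n * k * (k + 1)^2 / 4
  num <- sum((rj - n * (k + 1) / 2)^2)
  if (a - cc <= 1e-12) {
    return(.test_result(0, 1, "Friedman test (degenerate: all tied)",
                        df = k - 1L))
  }
  stat <- (k - 1) * num / (a - cc)
  use_exact <- if (is.null(exact)) n <= 8L else isTRUE(exact)
  if (use_exact && k <= 5L) {
    dist <- .friedman_exact_dist(ranks)
    # statistic is a monotone function of sum(Rj^2) given the fixed rank table
    p <- sum(dist$prob[dist$sumsq >= sum(rj^2) - 1e-9])
    method <- "Friedman test (tie-corrected, exact permutation)"
  } else {
    p <- stats::pchisq(stat, k - 1L, lower.tail = FALSE)
    method <- "Friedman test (tie-corrected, chi-square)"
  }
  .test_result(stat, p, method, df = k - 1L, rank_sums = rj)
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the conventions pinned as: zero differences
#' are dropped (Wilcoxon's original convention); for `n <= 25` remaining
#' pairs without tied absolute differences the exact signed-rank null is
#' used; otherwise the normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @return A `test_result` with statistic `V` (sum of positive ranks),
#'   `n_used`, `n_zeros` and `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) .stopf("paired vectors must have equal length")
  d <- x - y
  n_zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(.test_result(0, 1, "Wilcoxon signed-rank test",
                        degenerate = TRUE, n_used = 0L, n_zeros = n_zeros))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= 25L && !ties) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        stats::psignrank(v - 1, n, lower.tail = FALSE)))
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }
  .test_result(v, p, method, degenerate = FALSE, n_used = n,
               n_zeros = n_zeros)
}

#' Pairwise Wilcoxon signed-rank tests with Holm correction
#'
#' @inheritParams paired_t_holm
#' @return A list of `test_result`s with `adjusted_p` fields.
#' @export
wilcoxon_holm <- function(values, pairs = NULL) {
  .pairwise_holm(values, pairs, wilcoxon_signed_rank)
}

# Agreement-scale labels with the printed closed upper boundaries
# (a kappa of exactly 0.60 is "moderate", 0.80 "substantial", ...).
.kappa_label <- function(kappa) {
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "near-perfect"
}

#' Cohen's kappa for a two-rater agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' diagonal fraction and chance agreement `p_e` from the marginal products.
#' The qualitative label follows the conventional scale: <= 0.20 poor,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00
#' near-perfect.
#'
#' @param table Square `k x k` matrix of non-negative counts (rater 1 in
#'   rows, rater 2 in columns).
#' @return A list `(kappa, label, p_o, p_e, n)`.
#' @export
cohen_kappa <- function(table) {
  tb <- as.matrix(table)
  if (nrow(tb) != ncol(tb)) .stopf("agreement table must be square")
  if (any(tb < 0) || any(!is.finite(tb)) || any(tb != round(tb)))
    .stopf("agreement table must hold non-negative integer counts")
  n <- sum(tb)
  if (n <= 0) .stopf("agreement table is empty")
  po <- sum(diag(tb)) / n
  pe <- sum(rowSums(tb) * colSums(tb)) / n^2
  if (abs(1 - pe) < 1e-12)
    .stopf("degenerate marginals (p_e = 1): kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  list(kappa = kappa, label = .kappa_label(kappa), p_o = po, p_e = pe, n = n)
}
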