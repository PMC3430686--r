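# Paired-comparison battery: two-tailed paired t-tests on behavioural
# summaries — within-pair initiation asymmetries and pre/post-satiation
# contrasts, run per pairing category.

#' Two-tailed paired t-test
#'
#' Computed from the closed form: with differences `d = x - y`,
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, p from the two-sided t
#' tail.  If every difference is zero the test is a non-event (`t = 0`,
#' `p = 1`); if the differences have zero variance but nonzero mean the t
#' statistic is infinite and `p` is reported as 0 with
#' `zero_variance = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `n >= 2` (paired
#'   observations).
#' @return List of class `paired_t_result`: `t`, `df`, `p`, `mean_diff`,
#'   `n`, `zero_variance`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- x - y
  if (anyNA(d)) stop("missing values in paired differences", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  zero_var <- s == 0
  if (zero_var) {
    tval <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tval <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), df = n - 1L)
  }
  structure(list(t = tval, df = n - 1L, p = p, mean_diff = m, n = n,
                 zero_variance = zero_var),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("paired t-test: t_%d = %.3f, p = %.4g (mean diff %.4g, n = %d)%s\n",
              x$df, x$t, x$p, x$mean_diff, x$n,
              if (x$zero_variance) " [zero-variance differences]" else ""))
  invisible(x)
}

result_row <- function(category, comparison, metric, fish, r) {
  data.frame(category = category, comparison = comparison, metric = metric,
             fish = fish, n = r$n, t = r$t, df = r$df, p = r$p,
             mean_diff = r$mean_diff)
}

# reshape a summaries table into one row per (pair, session) with focal and
# partner columns, carrying category and boldness
pairwise_summaries <- function(summaries) {
  f <- summaries[summaries$fish == "focal", , drop = FALSE]
  p <- summaries[summaries$fish == "partner", , drop = FALSE]
  key <- paste(f$pair_id, f$session)
  p <- p[match(key, paste(p$pair_id, p$session)), , drop = FALSE]
  if (anyNA(p$pair_id)) stop("summaries missing a partner row", call. = FALSE)
  list(focal = f, partner = p)
}

#' Within-pair joint-trip initiation asymmetry tests
#'
#' Per category, a paired t-test of joint-trip initiation counts between
#' the two pair members in one session.  Framing:
#' * `"bolder_vs_shyer"` — the pre-satiation question: does the bolder
#'   member initiate more joint trips? (ties in boldness assign the focal
#'   fish to the bolder arm);
#' * `"focal_vs_partner"` — the post-satiation question (the focal fish is
#'   the satiated one).
#'
#' @param summaries A [summaries_table()] data frame.
#' @param session Session to test (`"control"` or `"satiated"`).
#' @param framing `"bolder_vs_shyer"` or `"focal_vs_partner"`.
#' @param categories Categories to test (default: those present).
#' @return Named list of [paired_t_test()] results per category, with a
#'   `"table"` attribute in the results-CSV layout.
#' @export
initiation_asymmetry_tests <- function(summaries, session = "control",
                                       framing = c("bolder_vs_shyer",
                                                   "focal_vs_partner"),
                                       categories = NULL) {
  framing <- match.arg(framing)
  s <- summaries[summaries$session == session, , drop = FALSE]
  if (is.null(categories)) categories <- unique(s$category)
  out <- list()
  rows <- list()
  for (cat in categories) {
    sc <- s[s$category == cat, , drop = FALSE]
    ps <- pairwise_summaries(sc)
    if (nrow(ps$focal) < 2L) {
      stop(sprintf("category %s has fewer than 2 pairs", cat), call. = FALSE)
    }
    if (framing == "bolder_vs_shyer") {
      focal_bolder <- ps$focal$focal_boldness >= ps$focal$partner_boldness
      x <- ifelse(focal_bolder, ps$focal$n_joint_initiations,
                  ps$partner$n_joint_initiations)
      y <- ifelse(focal_bolder, ps$partner$n_joint_initiations,
                  ps$focal$n_joint_initiations)
      arms <- "bolder_vs_shyer"
    } else {
      x <- ps$focal$n_joint_initiations
      y <- ps$partner$n_joint_initiations
      arms <- "focal_vs_partner"
    }
    r <- paired_t_test(x, y)
    out[[cat]] <- r
    rows[[cat]] <- result_row(cat, paste0("initiation_asymmetry_", session),
                              "n_joint_initiations", arms, r)
  }
  attr(out, "table") <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Pre/post-satiation paired contrasts
#'
#' Per category, a paired t-test of a summary metric between the control
#' and satiated sessions of each pair, for one fish.  Pairs missing either
#' session are dropped listwise with a warning.
#'
#' @param summaries A [summaries_table()] data frame (both sessions).
#' @param metric One of `"prop_time_out"`, `"n_trips"`,
#'   `"n_joint_initiations"`, `"n_attempted_initiations"`, `"n_follows"`.
#' @param fish `"focal"` or `"partner"`.
#' @param categories Categories to test (default: those present).
#' @return Named list of [paired_t_test()] results (control minus
#'   satiated), with a `"table"` attribute in the results-CSV layout.
#' @export
pre_post_tests <- function(summaries,
                           metric = c("prop_time_out", "n_trips",
                                      "n_joint_initiations",
                                      "n_attempted_initiations", "n_follows"),
                           fish = c("focal", "partner"), categories = NULL) {
  metric <- match.arg(metric)
  fish <- match.arg(fish)
  s <- summaries[summaries$fish == fish, , drop = FALSE]
  pre <- s[s$session == "control", , drop = FALSE]
  post <- s[s$session == "satiated", , drop = FALSE]
  keep <- intersect(pre$pair_id, post$pair_id)
  dropped <- setdiff(union(pre$pair_id, post$pair_id), keep)
  if (length(dropped)) {
    warning(sprintf("dropping %d pair(s) missing a session: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  pre <- pre[match(keep, pre$pair_id), , drop = FALSE]
  post <- post[match(keep, post$pair_id), , drop = FALSE]
  if (is.null(categories)) categories <- unique(pre$category)
  out <- list()
  rows <- list()
  for (cat in categories) {
    sel <- pre$category == cat
    if (sum(sel) < 2L) {
      stop(sprintf("category %s has fewer than 2 complete pairs", cat),
           call. = FALSE)
    }
    r <- paired_t_test(pre[[metric]][sel], post[[metric]][sel])
    out[[cat]] <- r
    rows[[cat]] <- result_row(cat, "pre_vs_post", metric, fish, r)
  }
  attr(out, "table") <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Holm adjustment across a results table
#'
#' @param table A results data frame with a `p` column (as produced by the
#'   `"table"` attributes of the test batteries).
#' @return The table with an extra `p_holm` column.
#' @export
holm_adjust <- function(table) {
  table$p_holm <- stats::p.adjust(table$p, method = "holm")
  table
}
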