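#' Two-sample Student's t-test
#'
#' Two-sided comparison of two replicate groups. The default
#' \code{"pooled"} variant is the classical equal-variance Student test
#' (matching the study's stated analysis); \code{"welch"} drops the
#' equal-variance assumption. Degenerate inputs are resolved by
#' convention rather than error: zero variance in both groups gives
#' p = 1 for equal means and p = 0 for separated means.
#'
#' @param x,y Numeric replicate vectors (each n >= 2, finite).
#' @param variant \code{"pooled"} or \code{"welch"}.
#' @return List with \code{t}, \code{p} (two-sided), \code{df}.
#' @export
ttest_two_sample <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = length(x) + length(y) - 2))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Star annotation of a p-value
#'
#' The study's figure convention: two stars for p < 0.01, one star for
#' p < 0.05, otherwise none — strict inequalities, so p = 0.05 earns no
#' star and p = 0.01 exactly one.
#'
#' @param p A p-value in [0, 1].
#' @return \code{""}, \code{"*"} or \code{"**"}; vectorised.
#' @export
annotate_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Per-day two-group comparison of a measurement series
#'
#' For every day on which both groups are present: group means, standard
#' errors (SD / sqrt(n)), a two-sided Student's t-test, and the star
#' annotation. Days missing a group are skipped with a message. No
#' multiple-testing correction is applied, matching the original
#' per-figure convention; the output attribute notes this.
#'
#' @param series Long data frame with columns \code{day}, \code{group}
#'   (exactly two levels), \code{value}.
#' @param variant t-test variant, see [ttest_two_sample()].
#' @return Data frame: \code{day}, \code{mean_<g1>}, \code{se_<g1>},
#'   \code{mean_<g2>}, \code{se_<g2>}, \code{t}, \code{p}, \code{stars},
#'   \code{n_<g1>}, \code{n_<g2>} where g1/g2 are the sorted group
#'   names.
#' @export
daily_comparison <- function(series, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(series),
            all(c("day", "group", "value") %in% names(series)))
  groups <- sort(unique(as.character(series$group)))
  if (length(groups) != 2) stop("series must contain exactly two groups", call. = FALSE)
  g1 <- groups[1]; g2 <- groups[2]
  se_ <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  rows <- lapply(sort(unique(series$day)), function(d) {
    x <- series$value[series$day == d & series$group == g1]
    y <- series$value[series$day == d & series$group == g2]
    if (length(x) == 0 || length(y) == 0) {
      message("day ", d, ": one group absent; skipped")
      return(NULL)
    }
    tt <- if (length(x) >= 2 && length(y) >= 2) ttest_two_sample(x, y, variant)
          else list(t = NA_real_, p = NA_real_)
    r <- data.frame(day = d, m1 = mean(x), s1 = se_(x), m2 = mean(y),
                    s2 = se_(y), t = tt$t, p = tt$p,
                    stars = if (is.na(tt$p)) "" else annotate_stars(tt$p),
                    n1 = length(x), n2 = length(y))
    names(r) <- c("day", paste0("mean_", g1), paste0("se_", g1),
                  paste0("mean_", g2), paste0("se_", g2), "t", "p", "stars",
                  paste0("n_", g1), paste0("n_", g2))
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "note") <- "no multiple-testing correction applied"
  attr(out, "variant") <- variant
  out
}
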