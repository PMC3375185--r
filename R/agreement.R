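#' Agreement statistics for paired binary ratings
#'
#' Percent agreement and (unweighted) Cohen's kappa over a 2 x 2
#' contingency table, plus the seventh-decile dichotomization used to
#' turn continuous staining scores into low/high labels.
#'
#' @name agreement
NULL

#' Construct a 2 x 2 contingency table
#'
#' `contingency_table(a, b, c, d)` takes the four cell counts directly
#' (rows = method 1, columns = method 2; `a` = both negative/low, `d` =
#' both positive/high). `contingency()` cross-tabulates two equal-length
#' binary label vectors (logical, or anything coercible with `TRUE` =
#' positive).
#'
#' @param a,b,c,d non-negative cell counts.
#' @return object of class `contingency_2x2` with fields `a, b, c, d, n`.
#' @export
contingency_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, n = n), class = "contingency_2x2")
}

#' @rdname contingency_table
#' @param labels_a,labels_b equal-length binary label vectors.
#' @export
contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  A <- as.logical(labels_a); B <- as.logical(labels_b)
  if (anyNA(A) || anyNA(B)) stop("labels must be binary without NA", call. = FALSE)
  contingency_table(a = sum(!A & !B), b = sum(!A & B),
                    c = sum(A & !B), d = sum(A & B))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(method1 = c("neg", "pos"),
                              method2 = c("neg", "pos")))
  print(m)
  invisible(x)
}

#' Percent agreement
#'
#' `100 * (a + d) / n`: the percentage of observations both methods
#' assign to the same class.
#'
#' @param t a [contingency_table()].
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  100 * (t$a + t$d) / t$n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (a + d)/n` and expected agreement
#' `p_e = [(a+b)(a+c) + (c+d)(b+d)] / n^2`. Unweighted (the classes are
#' binary). Degenerate marginals with `p_e = 1` are an error.
#'
#' @param t a [contingency_table()].
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    stop("expected agreement is 1 (degenerate marginals); kappa undefined",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Both agreement statistics at once
#'
#' @param t a [contingency_table()].
#' @return list with `percent_agreement` and `kappa`.
#' @export
agreement_stats <- function(t) {
  list(percent_agreement = percent_agreement(t), kappa = cohens_kappa(t))
}

#' Dichotomize continuous scores at a decile cut-off
#'
#' The cut-off is the `decile/10` quantile under the linear
#' interpolation definition (R quantile type 7); a value is labelled
#' high only when strictly above the cut-off, so ties at the cut-off
#' are low. The seventh decile is the conventional cut-off for Ki-67
#' positivity fractions.
#'
#' @param values numeric vector (>= 10 values give a meaningful decile).
#' @param decile which decile to cut at (default 7).
#' @return list with `labels` (logical, TRUE = high) and `cutoff`.
#' @export
dichotomize_decile <- function(values, decile = 7) {
  if (length(values) == 0) stop("no values to dichotomize", call. = FALSE)
  stopifnot(decile >= 1, decile <= 9)
  cutoff <- stats::quantile(values, probs = decile / 10, type = 7,
                            names = FALSE)
  list(labels = values > cutoff, cutoff = cutoff)
}
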