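#' Initial-value objective: sum of squared relative simulation errors
#'
#' The classic GM(1,1) time-response function is forced through the first
#' observation, which least-squares logic does not justify: the fitted
#' accumulated curve need not pass through `(1, x(1))`. Treating the
#' initial condition `C` as free, this objective scores a candidate by the
#' sum of squared relative errors of the restored model,
#' \deqn{\tilde\Delta(C) = \sum_k \left(\frac{\hat x(k) - x(k)}{x(k)}\right)^2,}
#' with `hat x(k) = (1 - e^a)(C - b/a) e^{-a(k-1)}` for `k = 2..n`.
#'
#' The first-year term is ambiguous because the reported first fitted value
#' is the observation itself. Three conventions are provided:
#' \describe{
#'   \item{`ratio_to_first` (default)}{the `k = 1` residual is
#'     `(C - x(1)) / x(1)` — the reported first value is `C` on the
#'     original scale, penalising departure from the first observation.}
#'   \item{`restored_formula`}{the `k = 1` residual uses the restored
#'     formula value `(1 - e^a)(C - b/a)`.}
#'   \item{`exclude`}{the sum runs over `k = 2..n` only.}
#' }
#' Each is a sum of squares of affine functions of `C`, hence a strictly
#' convex quadratic with a unique minimizer.
#'
#' @param fit a `gm11_fit`.
#' @param C numeric candidate initial condition(s); vectorised.
#' @param objective_k1 first-year convention, see Details.
#' @return Numeric vector of objective values, one per element of `C`.
#' @seealso [optimize_initial()] for the closed-form minimizer.
#' @export
gm11_objective <- function(fit, C,
                           objective_k1 = c("ratio_to_first",
                                            "restored_formula", "exclude")) {
  objective_k1 <- match.arg(objective_k1)
  terms <- objective_terms(fit, objective_k1)
  vapply(C, function(ci) sum((terms$p * ci + terms$q)^2), numeric(1))
}

# Each residual is affine in C: r_k = p_k C + q_k. For k >= 2,
# r_k = (phi_k (C - b/a) - x_k) / x_k with phi_k = (1 - e^a) e^{-a(k-1)};
# the k = 1 term depends on the convention. In the a -> 0 limit the
# restored value is the constant b, independent of C (p = 0).
objective_terms <- function(fit, objective_k1) {
  x <- as.numeric(fit$series)
  if (any(x <= 0))
    stop("relative-error objective needs strictly positive observations",
         call. = FALSE)
  a <- fit$a; b <- fit$b
  n <- length(x)
  if (abs(a) < .gm_a_tol) {
    p <- rep(0, n - 1L)
    q <- (b - x[-1L]) / x[-1L]
  } else {
    phi <- gm_phi(a, 2:n)
    p <- phi / x[-1L]
    q <- (-phi * b / a - x[-1L]) / x[-1L]
  }
  k1 <- switch(objective_k1,
    ratio_to_first = list(p = 1 / x[1L], q = -1),
    restored_formula = {
      if (abs(a) < .gm_a_tol) list(p = 0, q = (b - x[1L]) / x[1L])
      else {
        phi1 <- gm_phi(a, 1)
        list(p = phi1 / x[1L], q = (-phi1 * b / a - x[1L]) / x[1L])
      }
    },
    exclude = list(p = numeric(0), q = numeric(0)))
  list(p = c(k1$p, p), q = c(k1$q, q))
}

#' Construct an initial-value object
#'
#' @param C numeric initial condition (accumulated-scale).
#' @param variant one of `"classic"`, `"optimized"`, `"supplied"`.
#' @param objective_value the objective at `C`, if known.
#' @return An `initial_value` list.
#' @export
initial_value <- function(C, variant = "supplied", objective_value = NA_real_) {
  structure(list(C = as.numeric(C)[1L], variant = variant,
                 objective_value = objective_value),
            class = "initial_value")
}

#' @export
print.initial_value <- function(x, ...) {
  cat("Initial condition C = ", format(round(x$C, 4)), " (", x$variant,
      "), objective = ", format(signif(x$objective_value, 6)), "\n", sep = "")
  invisible(x)
}

#' Optimize the initial condition of the time-response function
#'
#' Minimizes [gm11_objective()] over `C` in closed form. Because every
#' residual is affine in `C`, `r_k = p_k C + q_k`, the stationarity
#' condition `sum(r_k p_k) = 0` gives
#' \deqn{C^* = -\frac{\sum_k p_k q_k}{\sum_k p_k^2},}
#' the unique minimum of the convex quadratic. The optimizer can never be
#' worse than the classic choice `C = x(1)`.
#'
#' In the `a -> 0` degenerate limit the restored values do not depend on
#' `C` at all; the classic initial value is then returned (under the
#' default convention the `k = 1` term alone still pins `C = x(1)`).
#'
#' @param fit a `gm11_fit`.
#' @param objective_k1 first-year convention passed to [gm11_objective()].
#' @return An `initial_value` with `variant = "optimized"` and the achieved
#'   `objective_value`.
#' @examples
#' w2 <- annual_series(c(5.93, 6.23, 6.15, 7.06, 7.31, 7.87, 7.94), 2008)
#' fit <- gm11(w2, init = "classic")
#' optimize_initial(fit)   # C* close to 5.93
#' @export
optimize_initial <- function(fit, objective_k1 = c("ratio_to_first",
                                                   "restored_formula",
                                                   "exclude")) {
  objective_k1 <- match.arg(objective_k1)
  terms <- objective_terms(fit, objective_k1)
  spp <- sum(terms$p^2)
  C_star <- if (spp > 0) -sum(terms$p * terms$q) / spp
            else as.numeric(fit$series)[1L]
  initial_value(C_star, variant = "optimized",
                objective_value = sum((terms$p * C_star + terms$q)^2))
}
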