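#' Item bank for the two-parameter normal ogive model
#'
#' Holds per-item discriminations \eqn{a_k > 0} and difficulties
#' \eqn{b_k}, plus the index of the anchor item whose parameters are held
#' fixed at \eqn{(a, b) = (1, 0)} to identify the latent scale.
#'
#' @param a numeric vector of positive discriminations.
#' @param b numeric vector of difficulties (same length as `a`).
#' @param anchor index of the anchor item (default 1).
#' @param identified if `TRUE` (default) the anchor item's parameters are
#'   forced to \eqn{a = 1}, \eqn{b = 0}.
#' @return Object of class `"item_bank"`: list with `a`, `b`, `anchor`.
#' @export
item_bank <- function(a, b, anchor = 1L, identified = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("all discriminations must be positive and finite", call. = FALSE)
  }
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > length(a)) {
    stop("'anchor' out of range", call. = FALSE)
  }
  if (identified) {
    a[anchor] <- 1
    b[anchor] <- 0
  }
  structure(list(a = a, b = b, anchor = anchor), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items (anchor item %d fixed at a = 1, b = 0)\n",
              length(x$a), x$anchor))
  print(data.frame(item = seq_along(x$a), a = x$a, b = x$b),
        row.names = FALSE)
  invisible(x)
}

#' Validate a dichotomous response matrix
#'
#' Responses are stored as an integer matrix over \{0, 1, `NA`\}; `NA`
#' marks planned (booklet-design) or incidental missingness.  Every person
#' must answer at least one item and every item must be answered by at
#' least one person.
#'
#' @param y matrix (or data frame) of responses.
#' @return The validated integer matrix, invisibly classed
#'   `"response_matrix"`.
#' @export
response_matrix <- function(y) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  bad <- which(!is.na(y) & y != 0L & y != 1L, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary response at row %d, column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  rows <- rowSums(!is.na(y))
  cols <- colSums(!is.na(y))
  if (any(rows == 0L)) {
    stop(sprintf("person %d has no observed responses",
                 which(rows == 0L)[1]), call. = FALSE)
  }
  if (any(cols == 0L)) {
    stop(sprintf("item %d has no observed responses",
                 which(cols == 0L)[1]), call. = FALSE)
  }
  class(y) <- c("response_matrix", class(y))
  y
}

#' 2PNO probability of a correct response
#'
#' \eqn{P(Y = 1 \mid \theta) = \Phi(a(\theta - b))} with \eqn{\Phi} the
#' standard normal CDF.  Vectorized over all arguments with recycling.
#'
#' @param theta latent trait value(s).
#' @param a positive discrimination(s).
#' @param b difficulty(ies).
#' @return Probabilities in (0, 1).
#' @export
prob_correct <- function(theta, a, b) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("discrimination 'a' must be positive", call. = FALSE)
  }
  stats::pnorm(a * (theta - b))
}

#' Simulate 2PNO responses
#'
#' Independent Bernoulli draws with success probability
#' \eqn{\Phi(a_k(\theta_i - b_k))}.  Cells flagged in `missing_mask` are
#' set to `NA` (booklet-style planned missingness).
#'
#' @param theta vector of person abilities.
#' @param items an [item_bank()].
#' @param missing_mask optional logical matrix (persons x items); `TRUE`
#'   cells become `NA`.
#' @return A [response_matrix()].
#' @export
simulate_responses <- function(theta, items, missing_mask = NULL) {
  n <- length(theta); K <- length(items$a)
  p <- stats::pnorm(outer(theta, items$b, "-") *
                      matrix(items$a, n, K, byrow = TRUE))
  y <- matrix(as.integer(stats::runif(n * K) < p), n, K)
  if (!is.null(missing_mask)) {
    if (!identical(dim(missing_mask), dim(y))) {
      stop("'missing_mask' dimensions must match persons x items",
           call. = FALSE)
    }
    y[missing_mask] <- NA_integer_
  }
  colnames(y) <- paste0("item", seq_len(K))
  response_matrix(y)
}

#' Observed-data Bernoulli log-likelihood of the 2PNO model
#'
#' Sum over non-missing cells of
#' \eqn{y \log p + (1-y)\log(1-p)}; missing cells contribute zero.
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` to avoid `-Inf` from
#' floating-point underflow at extreme \eqn{a(\theta-b)}.
#'
#' @param responses response matrix (0/1/`NA`).
#' @param theta vector of abilities, one per row of `responses`.
#' @param items an [item_bank()].
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(responses, theta, items) {
  y <- as.matrix(responses)
  n <- nrow(y); K <- ncol(y)
  if (length(theta) != n || length(items$a) != K) {
    stop("dimension mismatch between responses, theta, and items",
         call. = FALSE)
  }
  p <- stats::pnorm(outer(theta, items$b, "-") *
                      matrix(items$a, n, K, byrow = TRUE))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- y * log(p) + (1 - y) * log1p(-p)
  sum(ll[!is.na(y)])
}
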