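#' Pairwise-comparison matrix
#'
#' Validates and labels a positive reciprocal matrix of pairwise importance
#' judgments: unit diagonal, `a_ij = 1/a_ji`, all entries positive.
#'
#' @param m A square numeric matrix.
#' @param labels Optional item labels (defaults to existing dimnames or
#'   `item1..itemn`).
#' @return The matrix with class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m) || n < 1)
    stop("invalid input: matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("invalid input: pairwise matrix entries must be positive",
         call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-9))
    stop("invalid input: diagonal must be 1", call. = FALSE)
  if (any(abs(m * t(m) - 1) > 1e-7))
    stop("invalid input: matrix is not reciprocal (a_ij != 1/a_ji)",
         call. = FALSE)
  if (is.null(labels))
    labels <- if (!is.null(rownames(m))) rownames(m)
              else paste0("item", seq_len(n))
  dimnames(m) <- list(labels, labels)
  class(m) <- c("pairwise_matrix", "matrix", "array")
  m
}

# Saaty's random consistency indices, n = 1..10.
ahp_random_index <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP priorities from a pairwise matrix
#'
#' Derives the priority vector as the normalized principal right eigenvector
#' (power iteration), with the principal eigenvalue from the Rayleigh
#' quotient, and the standard consistency diagnostics:
#' `CI = (lambda_max - n)/(n - 1)` and `CR = CI / RI(n)` with Saaty's
#' random-index table. A geometric-mean ("row geometric mean") prioritization
#' is available as a cross-check.
#'
#' @param m A [pairwise_matrix()] (or a matrix passing its validation).
#' @param method `"eigen"` (canonical) or `"geomean"`.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap.
#' @return An object of class `ahp_result`: list with `priorities` (named,
#'   sums to 1), `lambda_max`, `ci`, `cr`, `n`, `labels`.
#' @examples
#' ahp_priorities(pairwise_matrix(rbind(c(1, 3), c(1/3, 1))))
#' @export
ahp_priorities <- function(m, method = c("eigen", "geomean"),
                           tol = 1e-12, max_iter = 10000) {
  method <- match.arg(method)
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  n <- nrow(m)
  labels <- rownames(m)
  mm <- unclass(m)
  if (n == 1L) {
    w <- 1
  } else if (method == "geomean") {
    g <- apply(mm, 1, function(r) exp(mean(log(r))))
    w <- g / sum(g)
  } else {
    w <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      w_new <- as.vector(mm %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w) / pmax(w, .Machine$double.eps)) < tol) {
        w <- w_new
        break
      }
      w <- w_new
    }
  }
  mv <- as.vector(mm %*% w)
  lambda <- sum(w * mv) / sum(w * w)   # Rayleigh quotient
  ci <- if (n >= 2) (lambda - n) / (n - 1) else 0
  ri <- if (n <= length(ahp_random_index)) ahp_random_index[n] else 1.49
  cr <- if (ri > 0) ci / ri else 0
  structure(list(priorities = setNames(w, labels), lambda_max = lambda,
                 ci = ci, cr = cr, n = n, labels = labels),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("<ahp_result> n = %d, lambda_max = %.4f, CI = %.4f, CR = %.4f\n",
              x$n, x$lambda_max, x$ci, x$cr))
  print(round(x$priorities, 4))
  invisible(x)
}

#' Build a pairwise matrix from binary preference votes
#'
#' Survey respondents answer each pair with a binary preference; the vote
#' tally is turned into Saaty-scale comparison entries with smoothed odds:
#' `a_ij = (votes_ij + smoothing) / (votes_ji + smoothing)`, clamped to
#' `[1/cap, cap]`. Reciprocity holds by construction. This construction is
#' explicit and configurable because published binary-survey aggregations
#' vary.
#'
#' @param tally Either an n x n count matrix (`tally[i, j]` = respondents
#'   preferring i over j) or a data.frame with columns
#'   `item_i,item_j,votes_ij,votes_ji`.
#' @param smoothing Additive smoothing count (default 0.5).
#' @param cap Saaty-scale cap (default 9).
#' @return A [pairwise_matrix()].
#' @examples
#' aggregate_binary_votes(rbind(c(0, 38), c(16, 0)))
#' @export
aggregate_binary_votes <- function(tally, smoothing = 0.5, cap = 9) {
  if (is.data.frame(tally)) {
    need <- c("item_i", "item_j", "votes_ij", "votes_ji")
    miss <- setdiff(need, names(tally))
    if (length(miss))
      stop("vote tally missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    items <- unique(c(tally$item_i, tally$item_j))
    mm <- matrix(0, length(items), length(items),
                 dimnames = list(items, items))
    for (r in seq_len(nrow(tally))) {
      i <- tally$item_i[r]; j <- tally$item_j[r]
      mm[i, j] <- mm[i, j] + tally$votes_ij[r]
      mm[j, i] <- mm[j, i] + tally$votes_ji[r]
    }
    tally <- mm
  }
  tally <- as.matrix(tally)
  n <- nrow(tally)
  if (n != ncol(tally) || n < 1 || !sum(tally))
    stop("invalid input: empty or non-square vote tally", call. = FALSE)
  if (any(tally < 0))
    stop("invalid input: vote counts must be >= 0", call. = FALSE)
  a <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    r <- (tally[i, j] + smoothing) / (tally[j, i] + smoothing)
    r <- min(cap, max(1 / cap, r))
    a[i, j] <- r
    a[j, i] <- 1 / r
  }
  labels <- rownames(tally)
  pairwise_matrix(a, labels = labels)
}

#' Read a vote tally CSV
#'
#' Expects header `item_i,item_j,votes_ij,votes_ji`.
#'
#' @param path CSV path.
#' @return A data.frame suitable for [aggregate_binary_votes()].
#' @export
read_vote_tally <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_i", "item_j", "votes_ij", "votes_ji")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("vote tally CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Assemble a weight hierarchy from AHP results
#'
#' Combines a first-level AHP result over the criteria with per-criterion
#' second-level results into a [weight_hierarchy()]. Criteria without a
#' second-level entry become singleton leaves (weight 1) named after the
#' criterion — the oxygen criterion of the default hierarchy is such a leaf.
#'
#' @param first_level An [ahp_priorities()] result whose labels are the
#'   criterion names.
#' @param second_level Named list of [ahp_priorities()] results (names must be
#'   a subset of the criterion labels).
#' @return A [weight_hierarchy()].
#' @export
synthesize_hierarchy <- function(first_level, second_level = list()) {
  stopifnot(inherits(first_level, "ahp_result"))
  extra <- setdiff(names(second_level), first_level$labels)
  if (length(extra))
    stop("configuration error: second-level criteria not in first level: ",
         paste(extra, collapse = ", "), call. = FALSE)
  second <- lapply(seq_along(first_level$labels), function(i) {
    cr <- first_level$labels[i]
    if (cr %in% names(second_level)) {
      res <- second_level[[cr]]
      stopifnot(inherits(res, "ahp_result"))
      res$priorities
    } else setNames(1, cr)
  })
  names(second) <- first_level$labels
  weight_hierarchy(first_level$priorities, second)
}
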