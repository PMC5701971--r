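#' Permutation-entropy parameters
#'
#' Bundles the embedding dimension \code{m} and delay \code{l} used for
#' ordinal-pattern extraction. The defaults (m = 4, l = 1) are appropriate for
#' short BOLD series of around 130 timepoints; see [validate_pe_params()] for
#' the length constraints that motivate them.
#'
#' @param m Embedding dimension (integer >= 2). Values in 3..7 are the usual
#'   working range: below 3 the pattern alphabet is too small to be
#'   informative, above 7 the alphabet (m! states) outgrows any realistic
#'   series length.
#' @param l Delay between successive samples inside a window (integer >= 1).
#' @return An object of class \code{pe_params}.
#' @examples
#' pe_params()        # m = 4, l = 1
#' pe_params(3, 2)
#' @export
pe_params <- function(m = 4L, l = 1L) {
  m <- as.integer(m)
  l <- as.integer(l)
  if (length(m) != 1L || is.na(m) || m < 2L)
    stop("embedding dimension 'm' must be a single integer >= 2")
  if (length(l) != 1L || is.na(l) || l < 1L)
    stop("delay 'l' must be a single integer >= 1")
  structure(list(m = m, l = l), class = "pe_params")
}

#' @export
print.pe_params <- function(x, ...) {
  cat(sprintf("PE parameters: m = %d, l = %d (alphabet %d patterns)\n",
              x$m, x$l, factorial(x$m)))
  invisible(x)
}

#' Check series length against the permutation-entropy validity constraints
#'
#' A series of length \code{n} supports ordinal patterns of dimension \code{m}
#' and delay \code{l} only if every pattern can in principle occur,
#' \code{m! <= n - (m-1)*l}, and the series is long enough to avoid
#' undersampling the pattern alphabet, \code{n >= (m+1)!}. Both constraints
#' are checked; the verdict is returned, not raised, so callers can decide to
#' log and proceed for exploratory settings.
#'
#' @param n Series length (number of timepoints actually entering the
#'   entropy computation, e.g. 130 for a 140-volume acquisition after
#'   discarding 10).
#' @param params A [pe_params()] object (or anything with \code{$m},
#'   \code{$l}).
#' @return A list with elements \code{valid} (logical), \code{message}
#'   (diagnostic string naming any failed constraint), and the individual
#'   checks \code{coverage_ok} and \code{sampling_ok}.
#' @examples
#' validate_pe_params(130, pe_params(4, 1))$valid   # TRUE
#' validate_pe_params(130, pe_params(5, 1))$valid   # FALSE: 6! = 720 > 130
#' @export
validate_pe_params <- function(n, params = pe_params()) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a single positive integer")
  m <- params$m; l <- params$l
  n_windows <- n - (m - 1L) * l
  coverage_ok <- factorial(m) <= n_windows
  sampling_ok <- n >= factorial(m + 1L)
  msgs <- character(0)
  if (!coverage_ok)
    msgs <- c(msgs, sprintf(
      "pattern coverage fails: m! = %d > %d = n - (m-1)*l", factorial(m), n_windows))
  if (!sampling_ok)
    msgs <- c(msgs, sprintf(
      "undersampling: n = %d < (m+1)! = %d", n, factorial(m + 1L)))
  list(valid = coverage_ok && sampling_ok,
       message = if (length(msgs)) paste(msgs, collapse = "; ") else "ok",
       coverage_ok = coverage_ok, sampling_ok = sampling_ok)
}

#' Ordinal pattern of a single embedding window
#'
#' Returns the ascending-order index sequence (j1, ..., jm) of the window:
#' the 1-based positions of the window's values sorted ascending, with ties
#' broken by smaller original position first (stable sort). Equality is exact
#' floating-point equality; BOLD values essentially never tie, and when
#' constructed data do, the position rule makes the pattern deterministic.
#'
#' @param window Numeric vector, one embedding window of length m.
#' @return Integer vector of length m, a permutation of 1..m.
#' @examples
#' ordinal_pattern(c(1, 2, 3, 4))        # 1 2 3 4
#' ordinal_pattern(c(2, 2, 1))           # 3 1 2  (ties by position)
#' ordinal_pattern(c(0.7, -1.2, 0.7, 3)) # 2 1 3 4
#' @export
ordinal_pattern <- function(window) {
  if (!is.numeric(window) || length(window) < 2L)
    stop("'window' must be a numeric vector of length >= 2")
  if (anyNA(window)) stop("missing values are not permitted in a window")
  order(window)  # base order() is stable: ties keep position order
}

# Vectorized ordinal-pattern codes for a matrix of series (rows = series).
# For window element j, its 0-based slot in the stable ascending sort is
#   s_j = #{i < j : x_i <= x_j} + #{i > j : x_i < x_j};
# the code sum(s_j * m^(j-1)) identifies the pattern uniquely.
ordinal_codes <- function(X, m, l) {
  n <- ncol(X)
  nw <- n - (m - 1L) * l
  if (nw < 1L)
    stop(sprintf("series length %d admits no window of span %d", n, (m - 1L) * l + 1L))
  E <- lapply(seq_len(m), function(j) X[, seq_len(nw) + (j - 1L) * l, drop = FALSE])
  code <- matrix(0, nrow(X), nw)
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(m)) {
      if (i < j) s <- s + (E[[i]] <= E[[j]])
      else if (i > j) s <- s + (E[[i]] < E[[j]])
    }
    code <- code + s * m^(j - 1)
  }
  code
}

# Decode a pattern code back to its (j1..jm) index sequence.
decode_pattern <- function(code, m) {
  s <- (code %/% m^(seq_len(m) - 1)) %% m
  order(s)
}

#' Ordinal-pattern probability distribution of a time series
#'
#' Slides a window of span (m-1)*l + 1 along the series with unit step,
#' producing n - (m-1)*l overlapping windows, maps each to its ordinal
#' pattern, and tabulates relative frequencies over the patterns observed.
#'
#' @param x Numeric vector, the time series (no missing values).
#' @param params A [pe_params()] object.
#' @return An object of class \code{pattern_distribution}: a list with
#'   \code{probs} (named numeric vector of relative frequencies; names are
#'   the index sequences such as \code{"2-1-3-4"}), \code{patterns} (integer
#'   matrix, one row per observed pattern), \code{m}, and \code{n_windows}.
#' @examples
#' pd <- pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), pe_params(3, 1))
#' pd$probs
#' @export
pattern_distribution <- function(x, params = pe_params()) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be a numeric vector of length >= 2")
  if (anyNA(x)) stop("missing values are not permitted in the series")
  m <- params$m; l <- params$l
  codes <- drop(ordinal_codes(matrix(x, nrow = 1L), m, l))
  nw <- length(codes)
  counts <- table(codes)
  ucodes <- as.numeric(names(counts))
  pats <- t(vapply(ucodes, decode_pattern, integer(m), m = m))
  probs <- as.numeric(counts) / nw
  names(probs) <- apply(pats, 1L, paste, collapse = "-")
  structure(list(probs = probs, patterns = pats, m = m, n_windows = nw),
            class = "pattern_distribution")
}

#' Uniform distribution over all m! ordinal patterns
#'
#' Constructs the maximum-entropy pattern distribution in which each of the
#' m! patterns has probability 1/m!, the configuration at which permutation
#' entropy attains its upper bound ln(m!).
#'
#' @param m Embedding dimension.
#' @return A \code{pattern_distribution} with equal probabilities.
#' @export
uniform_pattern_distribution <- function(m = 4L) {
  m <- as.integer(m)
  perms <- all_permutations(m)
  k <- nrow(perms)
  probs <- rep(1 / k, k)
  names(probs) <- apply(perms, 1L, paste, collapse = "-")
  structure(list(probs = probs, patterns = perms, m = m, n_windows = NA_integer_),
            class = "pattern_distribution")
}

# All permutations of 1..m, one per row (recursive; m <= 7 in practice).
all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(m)) {
      out[r + pos, ] <- append(sub[i, ], m, after = pos - 1L)
    }
    r <- r + m
  }
  out
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("Ordinal pattern distribution: m = %d, %d observed of %d patterns",
              x$m, length(x$probs), factorial(x$m)))
  if (!is.na(x$n_windows)) cat(sprintf(", %d windows", x$n_windows))
  cat("\n")
  print(utils::head(sort(x$probs, decreasing = TRUE), 8L))
  invisible(x)
}

#' Permutation entropy of a time series or pattern distribution
#'
#' Shannon entropy, in nats, of the ordinal-pattern distribution:
#' \code{PE = -sum(P_g * log(P_g))}, with \code{0 * log(0)} taken as 0, and
#' its normalized form \code{PE / log(m!)} which lies in \[0, 1\]. A series
#' with a single recurring pattern (e.g. strictly monotone) gives 0; a series
#' visiting all m! patterns equally often gives 1. Because only ranks enter,
#' the value is invariant under any strictly increasing transform of the
#' series.
#'
#' @param x A numeric time series, or a \code{pattern_distribution}.
#' @param params A [pe_params()] object (ignored when \code{x} is already a
#'   distribution).
#' @param check If \code{TRUE} (default), warn when [validate_pe_params()]
#'   fails for the series length; the value is still computed.
#' @return An object of class \code{entropy_value}: list with \code{pe}
#'   (nats) and \code{pe_norm} (dimensionless, in \[0, 1\]).
#' @examples
#' permutation_entropy(seq_len(130))$pe_norm                    # 0
#' permutation_entropy(uniform_pattern_distribution(4))$pe_norm # 1
#' @export
permutation_entropy <- function(x, params = pe_params(), check = TRUE) {
  UseMethod("permutation_entropy")
}

#' @export
permutation_entropy.pattern_distribution <- function(x, params = pe_params(),
                                                     check = TRUE) {
  p <- x$probs
  if (abs(sum(p) - 1) > 1e-9)
    stop("pattern probabilities must sum to 1")
  p <- p[p > 0]
  pe <- -sum(p * log(p)) + 0  # + 0 folds a signed zero back to 0
  structure(list(pe = pe, pe_norm = pe / log(factorial(x$m)), m = x$m),
            class = "entropy_value")
}

#' @export
permutation_entropy.default <- function(x, params = pe_params(), check = TRUE) {
  if (check) {
    v <- validate_pe_params(length(x), params)
    if (!v$valid)
      warning("PE parameter validation failed: ", v$message, call. = FALSE)
  }
  permutation_entropy(pattern_distribution(x, params))
}

#' @export
print.entropy_value <- function(x, ...) {
  cat(sprintf("PE = %.6f nats, normalized = %.6f (m = %d)\n",
              x$pe, x$pe_norm, x$m))
  invisible(x)
}

# Normalized PE for each row of a series matrix; the workhorse behind pe_map().
# Returns a vector of pe_norm values, one per row.
row_pe_norm <- function(X, params = pe_params()) {
  m <- params$m
  codes <- ordinal_codes(X, m, params$l)
  nw <- ncol(codes)
  lognw <- log(nw)
  logfm <- log(factorial(m))
  vapply(seq_len(nrow(codes)), function(i) {
    cnt <- rle(sort.int(codes[i, ]))$lengths
    # -sum(c/nw * log(c/nw)) rewritten to avoid the division inside the log
    (lognw - sum(cnt * log(cnt)) / nw) / logfm
  }, numeric(1))
}
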