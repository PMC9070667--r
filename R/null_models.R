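#' Null probability of a motif occurrence in a random window
#'
#' Computes the probability that a random RNA fragment of length
#' `window_len`, drawn i.i.d. from `background`, contains at least one
#' bona fide motif word.
#'
#' Two counting conventions are exposed:
#'
#' * `summed_pattern_counts` — the per-pattern word counts of the four bona
#'   fide patterns are summed without deduplicating words shared between
#'   patterns (13 words under the default grammar). Under a uniform
#'   background and the positional-independence approximation
#'   `1 - (1 - 13/4^7)^(L-6)` this reproduces the conventional expected
#'   frequency of 3.4% for 50-nt fragments.
#' * `distinct_words` — the deduplicated word set (11 words). By default the
#'   probability is computed exactly by a transfer-matrix dynamic programme
#'   over 6-mer suffix states, which accounts for overlap/clumping of matches
#'   (U-runs especially); the independence approximation is available via
#'   `method = "independence"`.
#'
#' @param window_len fragment length in nt; values below 7 return
#'   probability 0 with a warning.
#' @param mode counting convention, see Details.
#' @param background length-4 base-probability vector (A, C, G, U order)
#'   summing to 1.
#' @param method `"exact"` (transfer matrix; default for `distinct_words`) or
#'   `"independence"` (default for `summed_pattern_counts`; the only method
#'   meaningful for that mode, since summing duplicate words has no exact
#'   counterpart).
#' @param grammar a [motif_grammar()]; only its bona fide patterns are used.
#' @return an object of class `null_model_result`: a list with `window_len`,
#'   `background`, `mode`, `method`, `probability` and `per_position_p`.
#' @examples
#' null_window_probability(50)                      # ~0.0343, the 3.4% convention
#' null_window_probability(50, "distinct_words")    # exact, ~0.0281
#' @export
null_window_probability <- function(window_len,
                                    mode = c("summed_pattern_counts", "distinct_words"),
                                    background = rep(0.25, 4),
                                    method = NULL,
                                    grammar = motif_grammar()) {
  mode <- match.arg(mode)
  check_background(background)
  if (window_len < 7) {
    warning("window_len < 7: no 7-nt window fits; probability is 0")
    return(new_null_result(window_len, background, mode, method %||% "independence",
                           probability = 0, per_position_p = 0))
  }
  if (is.null(method)) {
    method <- if (mode == "distinct_words") "exact" else "independence"
  }
  method <- match.arg(method, c("exact", "independence"))
  bona_patterns <- grammar$patterns$pattern_id[grammar$patterns$motif_class == "bona_fide"]
  if (mode == "summed_pattern_counts") {
    if (method == "exact") {
      stop("exact computation is only defined for mode = 'distinct_words'",
           call. = FALSE)
    }
    p_pos <- sum(vapply(bona_patterns, function(p) {
      sum(word_probs(expand_degenerate(p), background))
    }, numeric(1)))
    prob <- 1 - (1 - p_pos)^(window_len - 6)
  } else {
    words <- names(grammar$words)
    p_pos <- sum(word_probs(words, background))
    prob <- if (method == "exact") {
      exact_match_probability(words, window_len, background)
    } else {
      1 - (1 - p_pos)^(window_len - 6)
    }
  }
  new_null_result(window_len, background, mode, method, prob, p_pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_background <- function(background) {
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 non-negative probabilities (A,C,G,U) summing to 1",
         call. = FALSE)
  }
}

new_null_result <- function(window_len, background, mode, method,
                            probability, per_position_p,
                            standard_error = NULL, n_samples = NULL, seed = NULL) {
  structure(list(window_len = window_len, background = background,
                 mode = mode, method = method, probability = probability,
                 per_position_p = per_position_p,
                 standard_error = standard_error,
                 n_samples = n_samples, seed = seed),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Null model (%s, %s): P(>=1 match in %d nt) = %.6g",
              x$mode, x$method, x$window_len, x$probability))
  if (!is.null(x$standard_error)) {
    cat(sprintf(" +/- %.2g (SE, n = %g, seed = %s)",
                x$standard_error, x$n_samples, format(x$seed)))
  }
  cat("\n")
  invisible(x)
}

# Probability of each concrete word under an i.i.d. background.
word_probs <- function(words, background) {
  vapply(words, function(w) {
    prod(background[base_codes(w) + 1L])
  }, numeric(1))
}

# Exact P(>=1 occurrence of any word in the set in an L-mer), i.i.d.
# background, by dynamic programming over the last-6-bases suffix state.
# Handles overlapping occurrences correctly (unlike the independence
# approximation).
exact_match_probability <- function(words, window_len, background) {
  k <- 7L
  n_state <- 4L^(k - 1L)  # 4096 suffix states
  in_set <- logical(4L^k)
  in_set[kmer_codes_of(words) + 1L] <- TRUE
  idx6 <- 0:(n_state - 1L)
  # P(first 6 bases form state s)
  v <- rep(1, n_state)
  for (pos in 1:6) {
    v <- v * background[(idx6 %/% 4L^(6L - pos)) %% 4L + 1L]
  }
  # precompute transitions: appending base c to state s yields 7-mer s*4+c
  trans <- lapply(0:3, function(cc) {
    w7 <- idx6 * 4L + cc
    list(new_state = w7 %% n_state + 1L, safe = !in_set[w7 + 1L], p = background[cc + 1L])
  })
  for (step in seq_len(window_len - 6L)) {
    nv <- numeric(n_state)
    for (tr in trans) {
      contrib <- v * tr$p
      contrib[!tr$safe] <- 0
      # accumulate by destination state
      agg <- rowsum(contrib, tr$new_state)
      dst <- as.integer(rownames(agg))
      nv[dst] <- nv[dst] + agg[, 1L]
    }
    v <- nv
  }
  1 - sum(v)
}

#' Monte-Carlo estimate of the motif-occurrence null
#'
#' Draws `n_samples` i.i.d. random windows from `background`, scans each for
#' grammar matches, and returns the hit fraction with its binomial standard
#' error. Deterministic for a fixed `seed`.
#'
#' @inheritParams null_window_probability
#' @param n_samples number of random windows (>= 1).
#' @param seed integer seed; the generator state is restored on exit.
#' @param grammar_class `"bona_fide_only"` counts only bona fide matches;
#'   `"full_grammar"` counts bona fide or U-rich.
#' @return a `null_model_result` with `probability` (hit fraction),
#'   `standard_error = sqrt(p(1-p)/n)`, `n_samples` and `seed`.
#' @export
null_monte_carlo <- function(window_len, n_samples, seed,
                             background = rep(0.25, 4),
                             grammar_class = c("bona_fide_only", "full_grammar"),
                             grammar = motif_grammar()) {
  grammar_class <- match.arg(grammar_class)
  check_background(background)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (window_len < 7) {
    warning("window_len < 7: no 7-nt window fits; probability is 0")
    return(new_null_result(window_len, background, "monte_carlo", grammar_class,
                           0, 0, standard_error = 0, n_samples = n_samples,
                           seed = seed))
  }
  lk <- grammar_lookup(grammar)
  lut <- lk$bona
  if (grammar_class == "full_grammar") lut <- lut | lk$urich
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  L <- as.integer(window_len)
  npos <- L - 6L
  chunk <- 200000L
  hits <- 0
  done <- 0
  while (done < n_samples) {
    m_n <- min(chunk, n_samples - done)
    m <- matrix(sample.int(4L, m_n * L, replace = TRUE, prob = background) - 1L,
                nrow = m_n)
    code <- m[, 1L]
    for (j in 2:7) code <- code * 4L + m[, j]
    hit <- lut[code + 1L]
    if (npos > 1L) {
      for (s in 2:npos) {
        code <- (code %% 4096L) * 4L + m[, s + 6L]
        hit <- hit | lut[code + 1L]
      }
    }
    hits <- hits + sum(hit)
    done <- done + m_n
  }
  p <- hits / n_samples
  new_null_result(L, background, "monte_carlo", grammar_class, p,
                  per_position_p = NA_real_,
                  standard_error = sqrt(p * (1 - p) / n_samples),
                  n_samples = n_samples, seed = seed)
}

#' Enrichment ratio of observed vs expected motif frequency
#'
#' @param observed_fraction observed fraction in `[0,1]`.
#' @param expected_fraction expected (null) fraction in `(0,1]`.
#' @return the ratio `observed/expected`.
#' @examples
#' enrichment_ratio(65 / 214, 0.0343)  # ~ ninefold
#' @export
enrichment_ratio <- function(observed_fraction, expected_fraction) {
  if (any(expected_fraction == 0)) {
    stop("undefined enrichment: expected_fraction is 0", call. = FALSE)
  }
  if (any(observed_fraction < 0 | observed_fraction > 1) ||
      any(expected_fraction < 0 | expected_fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  observed_fraction / expected_fraction
}
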