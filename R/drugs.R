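#' Reversal score of a drug signature against up/down gene lists
#'
#' Normalized four-cell overlap contrast:
#' `score = (|up ^ sig.down| + |down ^ sig.up| - |up ^ sig.up| - |down ^ sig.down|) / (|up| + |down|)`
#' (`^` = intersection). +1 is perfect reversal (the drug targets the input's
#' up genes down and vice versa), -1 perfect mimicry; signatures disjoint
#' from both lists score 0. Swapping a drug's up/down sets negates the score.
#'
#' @param up,down Non-empty disjoint gene lists (the input regulatory state).
#' @param sig A `drug_signature` (list with `up`, `down`).
#' @param universe Gene universe; all sets must be contained in it.
#' @return Scalar score in `[-1, 1]` with attribute `overlaps` (4 counts).
#' @export
reversal_score <- function(up, down, sig, universe) {
  if (length(up) == 0 || length(down) == 0)
    stop("input up/down gene lists must be non-empty")
  stopifnot(length(intersect(up, down)) == 0,
            all(c(up, down, sig$up, sig$down) %in% universe))
  a <- length(intersect(up, sig$down))
  b <- length(intersect(down, sig$up))
  cc <- length(intersect(up, sig$up))
  d <- length(intersect(down, sig$down))
  structure((a + b - cc - d) / (length(up) + length(down)),
            overlaps = c(up_rev = a, down_rev = b, up_mimic = cc, down_mimic = d))
}

#' Match gene lists against a drug signature library with a resampling null
#'
#' Scores every drug in the library against the input up/down lists, then
#' builds a per-drug null by rescoring the same drug against random up/down
#' lists sampled without replacement from the universe — with sizes matched
#' to the input (default) or jittered by +/-20% (`vary_lengths = TRUE`).
#' The empirical p-value is `(1 + #{null >= observed}) / (1 + n_resamples)`;
#' it is monotone nonincreasing in the observed score by construction.
#'
#' @param up,down Input gene lists.
#' @param library Named list of `drug_signature`s.
#' @param universe Gene universe (must be larger than `|up| + |down|`).
#' @param n_resamples Null size (>= 100; default 10000).
#' @param seed Integer seed.
#' @param vary_lengths Jitter resampled list sizes by +/-20%.
#' @return data.frame sorted by score (descending, p ascending tiebreak):
#'   `drug`, `score`, `p` and the four overlap counts.
#' @export
match_drugs <- function(up, down, library, universe, n_resamples = 10000,
                        seed = 1L, vary_lengths = FALSE) {
  stopifnot(n_resamples >= 100, length(library) > 0)
  nu <- length(up); nd <- length(down)
  if (length(universe) < nu + nd)
    stop("universe smaller than |up| + |down|")

  obs <- lapply(library, function(sig) reversal_score(up, down, sig, universe))
  obs_score <- vapply(obs, as.numeric, numeric(1))
  # v[g, drug] = [g in sig.down] - [g in sig.up]; a resampled score is then
  # (sum of v over the random up list - sum over the random down list) / total
  V <- vapply(library, function(sig)
    as.numeric(universe %in% sig$down) - as.numeric(universe %in% sig$up),
    numeric(length(universe)))
  exceed <- matrix(0L, n_resamples, length(library))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      ku <- nu; kd <- nd
      if (vary_lengths) {
        ku <- max(1L, round(nu * runif(1, 0.8, 1.2)))
        kd <- max(1L, round(nd * runif(1, 0.8, 1.2)))
        ku <- min(ku, length(universe) - 1L)
        kd <- min(kd, length(universe) - ku)
      }
      idx <- sample.int(length(universe), ku + kd)
      s_null <- (colSums(V[idx[seq_len(ku)], , drop = FALSE]) -
                   colSums(V[idx[ku + seq_len(kd)], , drop = FALSE])) / (ku + kd)
      exceed[r, ] <- s_null >= obs_score
    }
  })
  p <- (1 + colSums(exceed)) / (1 + n_resamples)
  ov <- t(vapply(obs, attr, numeric(4), "overlaps"))
  out <- data.frame(drug = names(library), score = obs_score, p = p,
                    up_rev = ov[, 1], down_rev = ov[, 2],
                    up_mimic = ov[, 3], down_mimic = ov[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$score, out$p), ]
}
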