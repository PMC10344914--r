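#' Scoring weights for the four docking factors
#'
#' Fixed weighting of the composite variant score: 10% binding energy (A),
#' 30% hydrogen-bond count (B), 40% serine attack distance (C), 20% cavity
#' volume (D). The attack distance carries the largest weight because it is
#' the direct geometric proxy for nucleophilic-attack competence.
#'
#' @param w_A,w_B,w_C,w_D factor weights, each in `[0, 1]`, summing to 1.
#' @return list of class `ScoringWeights`.
#' @export
scoring_weights <- function(w_A = 0.10, w_B = 0.30, w_C = 0.40, w_D = 0.20) {
  w <- c(A = w_A, B = w_B, C = w_C, D = w_D)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(w)), ")")
  }
  structure(as.list(w), class = "ScoringWeights")
}

#' Min-max normalize the four factors
#'
#' Each factor column is rescaled to `[0, 1]` by `(x - min) / (max - min)`.
#' Binding energy (A) and attack distance (C) are lower-is-better, so they
#' enter the score as `1 - fraction`; hydrogen bonds (B) and cavity volume
#' (D) are higher-is-better and enter directly. A degenerate column
#' (max == min) carries no information and is assigned a neutral 0.5 for
#' every variant.
#'
#' @param records data.frame with columns `variant_id`, `A_binding_energy`,
#'   `B_hbond_count`, `C_attack_distance`, `D_cavity_volume`.
#' @return data.frame `variant_id, a, b, c, d` with the per-factor score
#'   contributions in `[0, 1]` (inversion already applied to a and c).
#' @export
normalize_factors <- function(records) {
  if (nrow(records) < 1L) stop("need at least one factor record")
  cols <- c(A = "A_binding_energy", B = "B_hbond_count",
            C = "C_attack_distance", D = "D_cavity_volume")
  for (cn in cols) {
    bad <- !is.finite(records[[cn]])
    if (any(bad)) {
      stop("non-finite ", cn, " for variant ",
           records$variant_id[which(bad)[1]])
    }
  }
  frac <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x))
    else (x - rng[1]) / diff(rng)
  }
  data.frame(
    variant_id = records$variant_id,
    a = 1 - frac(records$A_binding_energy),   # lower (more negative) wins
    b = frac(records$B_hbond_count),          # more hydrogen bonds win
    c = 1 - frac(records$C_attack_distance),  # shorter attack distance wins
    d = frac(records$D_cavity_volume)         # larger cavity wins
  )
}

#' Composite weighted score for truncation variants
#'
#' Applies the fixed weights to the min-max-normalized factors:
#' `score = 0.10 a + 0.30 b + 0.40 c + 0.20 d` (defaults). A variant that
#' is best on all four factors among two or more scores exactly 1; worst on
#' all four scores exactly 0. Ranks are descending by score with ties
#' broken by smaller attack distance, then lexicographic variant id.
#'
#' @param records factor records (see [normalize_factors()]).
#' @param weights a [scoring_weights()].
#' @return data.frame `variant_id, a, b, c, d, score, rank`, in input
#'   order; `rank` is a permutation of `1..n`.
#' @export
score_variants <- function(records, weights = scoring_weights()) {
  stopifnot(inherits(weights, "ScoringWeights"))
  nm <- normalize_factors(records)
  nm$score <- weights$A * nm$a + weights$B * nm$b +
    weights$C * nm$c + weights$D * nm$d
  ord <- order(-nm$score, records$C_attack_distance,
               as.character(nm$variant_id))
  nm$rank <- integer(nrow(nm))
  nm$rank[ord] <- seq_len(nrow(nm))
  nm
}

#' Top-ranked variant ids
#'
#' @param table output of [score_variants()].
#' @param top_k number of variants to return.
#' @return character vector of variant ids, best first.
#' @export
rank_variants <- function(table, top_k = 1L) {
  if (nrow(table) == 0L) stop("empty score table")
  if (top_k <= 0) stop("top_k must be positive")
  as.character(table$variant_id[order(table$rank)])[seq_len(min(top_k, nrow(table)))]
}
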