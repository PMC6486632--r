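#' Scored RNA sequence
#'
#' Pairing of the two predictor outputs for one RNA sequence: a binary
#' interaction-propensity score and a binding-strength (affinity) score,
#' both in \[0, 1\].
#'
#' @param id Sequence identifier.
#' @param length_nt Sequence length in nucleotides.
#' @param interaction_score Interaction-propensity predictor output,
#'   \[0, 1\].
#' @param affinity_score Binding-strength predictor output, \[0, 1\].
#' @return A one-row data frame of class `scored_sequence`.
#' @export
scored_sequence <- function(id, length_nt, interaction_score,
                            affinity_score) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  }
  chk01(interaction_score, "interaction_score")
  chk01(affinity_score, "affinity_score")
  structure(data.frame(id = id, length_nt = length_nt,
                       interaction_score = interaction_score,
                       affinity_score = affinity_score),
            class = c("scored_sequence", "data.frame"))
}

#' Threshold classification of a predicted binding-strength score
#'
#' An RNA is called an interactor when its affinity score meets the
#' predictor's significance threshold; the comparison is inclusive
#' (score equal to the threshold is an interactor).
#'
#' @param affinity Affinity score(s) in \[0, 1\].
#' @param threshold Significance threshold (default 0.25).
#' @return Character vector: `"interactor"` or `"non_interactor"`.
#' @export
#' @examples
#' classify_interactor(c(0.27, 0.24, 0.14))
classify_interactor <- function(affinity, threshold = 0.25) {
  if (!is.numeric(affinity) || anyNA(affinity) ||
      any(affinity < 0) || any(affinity > 1))
    stop("affinity scores must lie in [0, 1]", call. = FALSE)
  ifelse(affinity >= threshold, "interactor", "non_interactor")
}

#' Combined interaction score and percentile rank
#'
#' Linearly combines the two predictor scores into a single combined
#' interaction score and ranks a target sequence against a length-matched
#' background. Each score is min-max normalised over the pooled set
#' (background plus target); when a score has zero spread every sequence
#' receives 0.5 for it. The combined score is the weighted mean of the two
#' normalised scores (equal weights by default). The percentile is the
#' fraction of the pooled set whose combined score is at least the
#' target's, so a target strictly dominating an n-sequence background is at
#' percentile 1/(n+1).
#'
#' @param target A one-row data frame (or [scored_sequence()]) with columns
#'   `length_nt`, `interaction_score`, `affinity_score`.
#' @param background Data frame of background sequences with the same
#'   columns; all lengths must equal the target length.
#' @param weights Length-2 non-negative weights for
#'   (interaction, affinity); normalised to sum to 1.
#' @return A list with `combined_score` (target), `percentile`, and
#'   `pool` (the pooled table with normalised and combined scores, target
#'   last).
#' @export
combined_rank <- function(target, background, weights = c(0.5, 0.5)) {
  stopifnot(is.data.frame(target), nrow(target) == 1L)
  if (!is.data.frame(background) || nrow(background) == 0L)
    stop("`background` must be a non-empty data frame", call. = FALSE)
  need <- c("length_nt", "interaction_score", "affinity_score")
  stopifnot(all(need %in% names(target)), all(need %in% names(background)))
  if (any(background$length_nt != target$length_nt))
    stop("background sequences must match the target length",
         call. = FALSE)
  stopifnot(length(weights) == 2L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  pool <- rbind(background[need], target[need])
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x))
    else (x - rng[1]) / diff(rng)
  }
  n1 <- norm01(pool$interaction_score)
  n2 <- norm01(pool$affinity_score)
  combined <- w[1] * n1 + w[2] * n2
  target_combined <- combined[length(combined)]
  pool$combined_score <- combined
  list(combined_score = unname(target_combined),
       percentile = mean(combined >= target_combined),
       pool = pool)
}
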